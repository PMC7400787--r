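test_that("VCF reading decomposes MNVs, drops indels and checks ref alleles", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTTAACCGGTTAACC"))
  vcf <- write_vcf_text(c(
    "chr1\t3\t.\tCC\tTT\t80\tPASS\tDP=150",     # MNV -> 2 SNVs
    "chr1\t5\t.\tG\tGA\t80\tPASS\tDP=150",      # insertion -> dropped
    "chr1\t7\t.\tT\tC\t80\tPASS\tDP=150",       # clean SNV
    "chr1\t9\t.\tC\tG\t80\tPASS\tDP=150",       # ref mismatch (A at 9)
    "chr1\t11\t.\tC\tA,G\t80\tPASS\tDP=150"))   # multi-allelic -> 2 SNVs
  v <- read_variants(vcf, ref)
  log <- attr(v, "log")
  expect_equal(log$n_indels_dropped, 1)
  expect_equal(log$n_mnv_decomposed, 1)
  expect_equal(log$n_ref_mismatch, 1)
  expect_equal(nrow(v), 5)  # 2 (MNV) + 1 + 2 (multi-allelic)
  mnv <- v[v$pos %in% c(3, 4), ]
  expect_identical(mnv$ref, c("C", "C"))
  expect_identical(mnv$alt, c("T", "T"))
})

test_that("MAF reading maps standard column names", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACCGGTT"))
  maf <- withr::local_tempfile(fileext = ".maf")
  write.table(data.frame(Chromosome = "chr1", Start_Position = 4,
                         Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
                         Tumor_Sample_Barcode = "s1"),
              maf, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- read_variants(maf, ref)
  expect_equal(nrow(v), 1)
  expect_identical(v$sample, "s1")
  expect_true(is.na(v$qual))
})

test_that("quality, depth and region filters use the stated boundaries", {
  v <- make_variant_set("chr1", pos = c(10, 20, 30, 40),
                        ref = "C", alt = "T",
                        qual = c(49, 50, 999, 999),
                        depth = c(500, 500, 99, 100))
  f <- filter_variants(v)
  expect_identical(f$pos, c(20L, 40L))

  # BED is 0-based half-open: "chr1 4 7" covers 1-based positions 5..7
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t4\t7", bed)
  v2 <- make_variant_set("chr1", pos = c(4, 5, 7, 8), ref = "C", alt = "T")
  f2 <- filter_variants(v2, regions = bed)
  expect_identical(f2$pos, c(5L, 7L))

  empty_bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty_bed)
  expect_equal(nrow(filter_variants(v2, regions = empty_bed)), 0)
})

test_that("context windows are centered and clipped at contig ends", {
  ref <- synth_reference(1000, seed = 1)
  w <- extract_window(ref, "contig1", 100)
  expect_equal(nchar(w$seq), 41)
  expect_equal(w$focal_offset, 20)

  w5 <- extract_window(ref, "contig1", 5)
  expect_equal(nchar(w5$seq), 25)
  expect_equal(w5$focal_offset, 4)
  expect_equal(w5$start, 1)

  wend <- extract_window(ref, "contig1", 995)
  expect_equal(nchar(wend$seq), 41 - 15)
  expect_error(extract_window(ref, "chrX", 5), "contig absent")
})

test_that("channel tallies match the hand-counted toy window", {
  ref <- toy_window_reference()
  v <- make_variant_set("chr1", 21, "C", "T")
  sig <- load_signature()
  cc <- tally_channel_counts(v, ref, sig)
  row <- cc[cc$key == "T[C>T]C", ]
  expect_equal(row$mut_m, 1)
  expect_equal(row$con_m, 3)   # TCC x2 + GGA x1
  expect_equal(row$mut_b, 1)
  expect_equal(row$con_b, 10)  # C/G letters in the window
  expect_equal(channel_enrichment(cc, "T[C>T]C"), 10 / 3)
  # the purine-strand twin channel folds onto the same counts
  twin <- cc[cc$key == "G[G>A]A", ]
  expect_equal(unname(unlist(twin[c("mut_m", "con_m", "mut_b", "con_b")])),
               c(1, 3, 1, 10))
})

test_that("tallies are invariant under strand complementation", {
  ref <- toy_window_reference()
  v <- make_variant_set("chr1", 21, "C", "T")
  sig <- load_signature()
  cc <- tally_channel_counts(v, ref, sig)

  rc <- Biostrings::reverseComplement(ref[[1]])
  ref2 <- Biostrings::DNAStringSet(setNames(as.character(rc), "chr1"))
  v2 <- make_variant_set("chr1", Biostrings::width(ref2)[1] + 1 - 21,
                         "G", "A")
  cc2 <- tally_channel_counts(v2, ref2, sig)
  expect_equal(cc2$mut_m, cc$mut_m)
  expect_equal(cc2$con_m, cc$con_m)
  expect_equal(cc2$mut_b, cc$mut_b)
  expect_equal(cc2$con_b, cc$con_b)
  r1 <- signature_enrichment(cc, sig)
  r2 <- signature_enrichment(cc2, sig)
  expect_equal(r2$score, r1$score, tolerance = 1e-12)
})

test_that("zero variants give all-zero counts and a zero score", {
  ref <- toy_window_reference()
  v <- make_variant_set("chr1", integer(0), character(0), character(0))
  sig <- load_signature()
  cc <- tally_channel_counts(v, ref, sig)
  expect_true(all(cc$mut_m == 0 & cc$con_m == 0))
  res <- signature_enrichment(cc, sig)
  expect_equal(res$score, 0)
  expect_equal(length(res$degenerate_channels), 192)
})

test_that("per-channel enrichment follows the fold-excess formula", {
  cc <- structure(data.frame(key = c("k1", "k2", "k3"),
                             pair = "C>T",
                             mut_m = c(2, 4, 0), con_m = c(10, 10, 0),
                             mut_b = c(4, 40, 0), con_b = c(40, 100, 0)),
                  class = c("channel_counts", "data.frame"))
  e <- channel_enrichment(cc)
  expect_equal(unname(e["k1"]), 2)        # direct arithmetic
  expect_equal(unname(e["k2"]), 1)        # context-proportional null
  expect_equal(unname(e["k3"]), 0)        # degenerate -> 0
  expect_equal(channel_enrichment(cc, "k1"), 2)
  expect_error(channel_enrichment(cc, "nope"), "unknown channel")
})

test_that("a degenerate one-channel signature scores that channel's E", {
  ref <- toy_window_reference()
  v <- make_variant_set("chr1", 21, "C", "T")
  pt <- point_signature("T", "C", "T", "C")
  cc <- tally_channel_counts(v, ref, pt)
  res <- signature_enrichment(cc, pt)
  expect_equal(res$score, channel_enrichment(cc, "T[C>T]C"))
})

test_that("duplicating every variant leaves each enrichment unchanged", {
  ref <- synth_reference(5000, seed = 21)
  sig <- load_signature()
  v <- synth_variants(ref, sig, n = 40, f = 0.6, seed = 22)
  v2 <- rbind(v, v)
  v2 <- structure(v2, class = c("variant_set", "data.frame"), log = list())
  e1 <- channel_enrichment(tally_channel_counts(v, ref, sig))
  e2 <- channel_enrichment(tally_channel_counts(v2, ref, sig))
  expect_equal(e2, e1, tolerance = 1e-12)
})

test_that("enrichments equal an independent brute-force recount", {
  ref <- synth_reference(4000, seed = 31)
  sig <- load_signature()
  for (s in 1:3) {
    v <- synth_variants(ref, sig, n = 8, f = 0.5, seed = 40 + s)
    cc <- tally_channel_counts(v, ref, sig)
    e <- channel_enrichment(cc)
    e_oracle <- brute_force_enrichment(v, ref, sig)
    expect_equal(e, e_oracle, tolerance = 1e-12)
  }
})

test_that("UVMSE increases monotonically with the UV mixing fraction", {
  ref <- synth_reference(30000, seed = 51)
  sig <- load_signature()
  scores <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f)
    uvmse_score(synth_variants(ref, sig, n = 500, f = f, seed = 52),
                ref, sig)$score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("the end-to-end score pipeline reports the weighted load", {
  ref <- synth_reference(20000, seed = 61)
  sig <- load_signature()
  path <- withr::local_tempfile(fileext = ".vcf")
  synth_variants(ref, sig, n = 100, f = 1, seed = 62, path = path)
  res <- uvmse_score(path, ref, sig)
  expect_equal(res$n_variants_used, 100)
  expect_equal(res$weighted_load, 100 * res$score)
  expect_gt(res$score, 1)

  expect_identical(weighted_uv_load(100, 0.8), 80)
  expect_identical(weighted_uv_load(5, 0), 0)
  expect_identical(weighted_uv_load(0, 2.5), 0)
  expect_error(weighted_uv_load(-1, 1), ">= 0")
})
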