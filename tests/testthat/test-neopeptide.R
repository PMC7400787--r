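# a long toy CDS: 30 codons with a Ser (TCC) at codon 15, no internal stops
toy_cds <- function() {
  codons <- rep(c("GCT", "AAA", "GGC"), 10)   # Ala/Lys/Gly filler
  codons[15] <- "TCC"
  paste(codons, collapse = "")
}

toy_transcript <- function() {
  list(id = "tx1", cds = toy_cds(), expression = 10, internal_stop = FALSE)
}

test_that("transcript mutation identifies changed residues", {
  tr <- list(id = "t", cds = "TCCGAGAAA", expression = NA,
             internal_stop = FALSE)
  m <- mutate_transcript(tr, 2, "C", "T")  # TCC -> TTC, Ser1 -> Phe1
  expect_identical(m$peptide_before, "SEK")
  expect_identical(m$peptide_after, "FEK")
  expect_identical(m$changed, 1L)

  syn <- mutate_transcript(tr, 3, "C", "T")  # TCC -> TCT, still Ser
  expect_length(syn$changed, 0)
  expect_equal(nrow(enumerate_neopeptides(syn)), 0)

  sg <- mutate_transcript(tr, 4, "G", "T")  # GAG -> TAG stop-gain
  expect_identical(sg$peptide_after, "S")
  expect_lt(nchar(sg$peptide_after), nchar(sg$peptide_before))

  expect_error(mutate_transcript(tr, 50, "A", "T"), "outside the CDS")
  expect_error(mutate_transcript(tr, 2, "G", "T"), "mismatch")
})

test_that("full-length deltas follow the hydropathy arithmetic", {
  kd <- load_hydropathy_scale()
  tr <- list(id = "t", cds = "TCCGAGAAA")
  m <- mutate_transcript(tr, 2, "C", "T")
  expect_equal(full_length_delta(m, kd), 3.6)  # Ser -> Phe

  syn <- mutate_transcript(tr, 3, "C", "T")
  expect_equal(full_length_delta(syn, kd), 0)

  # stop-gain loses the tail: -(E + K) = -(-3.5 + -3.9)
  sg <- mutate_transcript(tr, 4, "G", "T")
  expect_equal(full_length_delta(sg, kd), 3.5 + 3.9)
})

test_that("neopeptide windows enumerate and clip correctly", {
  m <- mutate_transcript(toy_transcript(), 44, "C", "T")  # codon 15 TCC->TTC
  expect_identical(m$changed, 15L)
  set <- enumerate_neopeptides(m)
  expect_equal(nrow(set), 27)
  expect_equal(as.vector(table(set$k)), c(8, 9, 10))
  expect_true(all(mapply(function(s, k) 15 >= s && 15 <= s + k - 1,
                         set$start, set$k)))

  # changed residue at position 1: one window per k
  tr <- list(id = "t", cds = toy_cds())
  m1 <- mutate_transcript(tr, 2, "C", "T")  # GCT -> GTT, Ala1 -> Val1
  expect_identical(m1$changed, 1L)
  expect_equal(nrow(enumerate_neopeptides(m1)), 3)
})

test_that("window counts degrade correctly near termini (exhaustive)", {
  # brute-force oracle: count windows of length k covering position r
  oracle <- function(len, r) {
    sum(vapply(8:10, function(k) {
      if (len < k) return(0L)
      starts <- 1:(len - k + 1)
      sum(starts <= r & r <= starts + k - 1)
    }, integer(1)))
  }
  filler <- c("GCT", "AAA", "GGC")
  for (len in c(8, 9, 12, 20)) {
    codons <- rep_len(filler, len)
    for (r in unique(c(1, 2, len %/% 2, len - 1, len))) {
      codons_r <- codons; codons_r[r] <- "TCC"
      tr <- list(id = "t", cds = paste(codons_r, collapse = ""))
      m <- mutate_transcript(tr, (r - 1) * 3 + 2, "C", "T")
      expect_equal(nrow(enumerate_neopeptides(m)), oracle(len, r),
                   info = sprintf("len=%d r=%d", len, r))
    }
  }
})

test_that("neopeptide deltas sum the per-window changes", {
  kd <- load_hydropathy_scale()
  m <- mutate_transcript(toy_transcript(), 44, "C", "T")
  set <- enumerate_neopeptides(m)
  expect_equal(neopeptide_delta(set, kd), 27 * 3.6)
  # consistency with the full-length delta for an interior missense
  expect_equal(neopeptide_delta(set, kd), 27 * full_length_delta(m, kd))
  expect_equal(neopeptide_delta(set, kd, expression = 0), 0)
  expect_equal(neopeptide_delta(set, kd, expression = 0.5), 27 * 3.6 * 0.5)
  expect_error(neopeptide_delta(set, kd, expression = -1), "non-negative")
})

test_that("per-sample profiles add independent mutations", {
  cds <- c(tx1 = toy_cds(), tx2 = toy_cds())
  tx <- read_transcripts(cds,
                         data.frame(transcript_id = c("tx1", "tx2"),
                                    expression = c(5, 5)))
  map <- data.frame(sample = c("s1", "s1", "s2"),
                    transcript_id = c("tx1", "tx2", "tx1"),
                    cds_pos = 44, ref = "C", alt = "T")
  prof <- sample_hydrophobicity_profile(map, tx, mode = "neopeptide")
  expect_equal(prof$delta_au[prof$sample == "s1"], 2 * 27 * 3.6)
  expect_equal(prof$delta_au[prof$sample == "s2"], 27 * 3.6)

  # uniform expression: weighted profile is proportional to unweighted
  profw <- sample_hydrophobicity_profile(map, tx, mode = "neopeptide",
                                         weighted = TRUE)
  expect_equal(profw$delta_au, prof$delta_au * 0.5)

  # unmapped transcripts are logged, not fatal
  map2 <- rbind(map, data.frame(sample = "s2", transcript_id = "missing",
                                cds_pos = 2, ref = "C", alt = "T"))
  prof2 <- sample_hydrophobicity_profile(map2, tx)
  expect_equal(prof2$n_unmapped[prof2$sample == "s2"], 1)
})

test_that("UV-heavy samples gain more hydrophobicity than background", {
  tx <- synth_transcriptome(n_transcripts = 15, n_samples = 6,
                            n_mutations = 25,
                            uv_fraction = rep(c(1, 0), each = 3), seed = 9)
  prof <- sample_hydrophobicity_profile(tx$map, tx$transcripts)
  uv_mean <- mean(prof$delta_au[1:3])
  bg_mean <- mean(prof$delta_au[4:6])
  expect_gt(uv_mean, bg_mean)
})

test_that("hydrophobicity-load correlation behaves at its edges", {
  load <- c(1, 2, 3, 4, 5)
  fit <- correlate_hydrophobicity_load(2 + 3 * load, load)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 3)

  # known linear effect plus gaussian noise: R^2 near its expected value
  set.seed(11)
  n <- 60; b <- 2; sigma <- 4
  load2 <- runif(n, 0, 10)
  expected_r2 <- 1 / (1 + sigma^2 / (b^2 * var(load2)))
  delta <- b * load2 + rnorm(n, 0, sigma)
  fit2 <- correlate_hydrophobicity_load(delta, load2)
  expect_equal(fit2$r_squared, expected_r2, tolerance = 0.15)

  # permuted labels decorrelate
  fit3 <- correlate_hydrophobicity_load(delta, sample(load2))
  expect_lt(fit3$r_squared, 0.15)

  expect_error(correlate_hydrophobicity_load(1:2, 1:2), "at least 3")
  flat <- correlate_hydrophobicity_load(rep(1, 5), 1:5)
  expect_true(is.na(flat$r_squared))
})
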