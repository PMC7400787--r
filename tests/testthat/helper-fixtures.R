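# Shared fixture builders. All fixtures are constructed in code; tables are
# written to per-test tempfiles through the package's own writers/dialect.

sig_channel_grid <- function() {
  g <- expand.grid(ctx5 = c("A", "C", "G", "T"), ref = c("A", "C", "G", "T"),
                   alt = c("A", "C", "G", "T"), ctx3 = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g[g$ref != g$alt, ]
}

write_signature_tsv <- function(df, path = withr::local_tempfile(
                                  fileext = ".tsv",
                                  .local_envir = parent.frame())) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# uniform signature over all 192 strand-resolved channels
uniform_signature <- function() {
  g <- sig_channel_grid()
  g$prob <- 1 / nrow(g)
  load_signature(write_signature_tsv(g), name = "uniform")
}

# all probability mass on the named channels (equal split)
point_signature <- function(ctx5, ref, alt, ctx3) {
  g <- sig_channel_grid()
  g$prob <- 0
  for (i in seq_along(ctx5)) {
    hit <- g$ctx5 == ctx5[i] & g$ref == ref[i] & g$alt == alt[i] &
      g$ctx3 == ctx3[i]
    stopifnot(sum(hit) == 1)
    g$prob[hit] <- 1 / length(ctx5)
  }
  load_signature(write_signature_tsv(g), name = "point")
}

# structurally valid signature object with all-zero probabilities (bypasses
# the loader's normalization check, for identity tests)
zero_signature <- function() {
  sig <- uniform_signature()
  sig$prob <- 0
  sig
}

uniform_codon_usage <- function() {
  codons <- sort(do.call(paste0, expand.grid(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"),
                                             stringsAsFactors = FALSE)))
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(data.frame(codon = codons, freq = 1), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  load_codon_usage(path)
}

# a 41-nt toy window with known content: TCC at 5-7 and 20-22, GGA at 30-32
# (3 motif occurrences counting reverse complements), 10 C/G letters, and a
# focal C at position 21 in a T_C context
toy_window_contig <- function() "AATATCCAACAACATAATATCCAATATAAGGATATGATGAT"

toy_window_reference <- function() {
  Biostrings::DNAStringSet(c(chr1 = toy_window_contig()))
}

make_variant_set <- function(contig, pos, ref, alt, qual = 999,
                             depth = 200, sample = "toy") {
  n <- length(pos)
  df <- data.frame(contig = rep_len(contig, n), pos = as.integer(pos),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   qual = rep_len(qual, n), depth = rep_len(depth, n),
                   sample = rep_len(sample, n), stringsAsFactors = FALSE)
  structure(df, class = c("variant_set", "data.frame"), log = list())
}

write_vcf_text <- function(lines, path = withr::local_tempfile(
                             fileext = ".vcf",
                             .local_envir = parent.frame())) {
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               lines), path)
  path
}

# independent brute-force recount of Eq.-1 enrichments on small variant sets
brute_force_enrichment <- function(variants, reference, signature,
                                   half_width = 20) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  count_overlap <- function(hay, needle) {
    n <- 0; start <- 1
    repeat {
      hit <- regexpr(needle, substring(hay, start), fixed = TRUE)
      if (hit < 0) break
      n <- n + 1; start <- start + hit
    }
    n
  }
  wins <- ctx5 <- ctx3 <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    s <- as.character(reference[[variants$contig[i]]])
    a <- max(1, variants$pos[i] - half_width)
    b <- min(nchar(s), variants$pos[i] + half_width)
    wins[i] <- substring(s, a, b)
    ctx5[i] <- substring(s, variants$pos[i] - 1, variants$pos[i] - 1)
    ctx3[i] <- substring(s, variants$pos[i] + 1, variants$pos[i] + 1)
  }
  fold <- function(c5, r, a, c3) {
    if (r %in% c("C", "T")) c(c5, r, a, c3)
    else c(comp[c3], comp[r], comp[a], comp[c5])
  }
  vfold <- t(mapply(fold, ctx5, variants$ref, variants$alt, ctx3))
  vpair <- paste0(vfold[, 2], ">", vfold[, 3])
  e <- numeric(nrow(signature))
  for (j in seq_len(nrow(signature))) {
    f <- fold(signature$ctx5[j], signature$ref[j], signature$alt[j],
              signature$ctx3[j])
    pair <- paste0(f[2], ">", f[3])
    motif <- paste0(f[1], f[2], f[4])
    in_class <- vpair == pair
    mut_b <- sum(in_class)
    mut_m <- sum(in_class & vfold[, 1] == f[1] & vfold[, 3] == f[3] &
                   vfold[, 4] == f[4])
    wb <- wins[in_class]
    con_b <- sum(vapply(wb, function(w)
      count_overlap(w, f[2]) + count_overlap(w, comp[[f[2]]]), numeric(1)))
    con_m <- sum(vapply(wb, function(w)
      count_overlap(w, motif) + count_overlap(w, rc(motif)), numeric(1)))
    e[j] <- if (mut_b == 0 || con_m == 0) 0 else
      (mut_m * con_b) / (mut_b * con_m)
  }
  names(e) <- signature$key
  e
}
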