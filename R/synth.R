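#' @importFrom stats runif rnorm rexp rgamma rbinom
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a reference sequence
#'
#' Random reference contigs with a requested GC fraction. Deterministic
#' under (arguments, seed); writing the same spec twice produces identical
#' bytes.
#'
#' @param length Total bases per contig (>= 100).
#' @param gc GC fraction in \code{[0, 1]}.
#' @param n_contigs Number of contigs.
#' @param seed RNG seed.
#' @param path Optional FASTA output path (a `.fai` index is written next to
#'   it).
#' @return A DNAStringSet (invisibly returns `path` when writing).
#' @export
synth_reference <- function(length = 10000, gc = 0.41, n_contigs = 1,
                            seed = 1, path = NULL) {
  stopifnot(length >= 100, gc >= 0, gc <= 1)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_contigs), function(i)
      paste(sample(DNA_BASES, length, replace = TRUE, prob = prob),
            collapse = ""), character(1))
  })
  ref <- Biostrings::DNAStringSet(setNames(seqs,
                                           paste0("contig", seq_len(n_contigs))))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(ref, path)
    tryCatch(Rsamtools::indexFa(path), error = function(e) NULL)
    return(invisible(ref))
  }
  ref
}

# start positions of every trinucleotide on each contig
motif_position_index <- function(reference) {
  lapply(as.character(reference), function(s) {
    n <- nchar(s)
    mers <- substring(s, 1:(n - 2), 3:n)
    split(seq_len(n - 2), mers)
  })
}

#' Synthesize a signature-mixed somatic variant set
#'
#' With probability `f` a variant is placed by drawing a channel from the
#' signature, choosing uniformly among reference positions whose
#' trinucleotide context matches the channel, and applying the channel's
#' substitution; otherwise the variant is a uniform random SNV. QUAL and
#' depth fields are sampled above the default filter thresholds. The UVMSE
#' of an `f = 1` set therefore exceeds that of an `f = 0` set of the same
#' size, and `f = 0` sets give per-channel enrichments of ~1 on average.
#'
#' Draws are coupled across mixing fractions at a fixed seed (common random
#' numbers): both a signature-drawn and a background candidate are realized
#' for every variant slot and `f` only decides which is emitted, so raising
#' `f` converts background variants into signature-drawn ones while leaving
#' the rest untouched. Scores are therefore monotone in `f` along a fixed
#' seed.
#'
#' @param reference A DNAStringSet or FASTA path.
#' @param signature A `uv_signature` to draw contexts from.
#' @param n Number of variants.
#' @param f Signature mixing fraction in \code{[0, 1]}.
#' @param seed RNG seed.
#' @param sample_name Sample label.
#' @param qual_range,depth_range Ranges for the simulated QUAL / DP fields.
#' @param path Optional VCF output path.
#' @return A `variant_set` (also written as VCF v4.2 when `path` is given);
#'   the `log` attribute counts channels redrawn for lack of a matching
#'   motif.
#' @export
synth_variants <- function(reference, signature = load_signature(), n = 500,
                           f = 0.5, seed = 1, sample_name = "synthetic",
                           qual_range = c(60, 1000),
                           depth_range = c(120, 400), path = NULL) {
  stopifnot(n >= 0, f >= 0, f <= 1)
  reference <- as_reference(reference)
  idx <- motif_position_index(reference)
  contigs <- names(reference)
  lens <- Biostrings::width(reference)
  redrawn <- 0L
  df <- with_seed(seed, {
    u <- runif(n)
    # signature-drawn candidate for every slot (RNG use independent of f)
    uv_rows <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        ch <- sample.int(nrow(signature), 1, prob = signature$prob)
        motif <- paste0(signature$ctx5[ch], signature$ref[ch],
                        signature$ctx3[ch])
        hits <- lapply(idx, function(m) m[[motif]])
        n_hits <- vapply(hits, function(h) length(h %||% integer(0)),
                         numeric(1))
        if (sum(n_hits) == 0) { redrawn <- redrawn + 1L; next }
        ci <- sample.int(length(contigs), 1, prob = n_hits)
        pos <- hits[[ci]][sample.int(length(hits[[ci]]), 1)] + 1L
        uv_rows[[i]] <- data.frame(contig = contigs[ci], pos = pos,
                                   ref = signature$ref[ch],
                                   alt = signature$alt[ch],
                                   stringsAsFactors = FALSE)
        break
      }
    }
    # background candidate for every slot
    bg_rows <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- sample.int(length(contigs), 1, prob = lens)
      pos <- sample(2:(lens[ci] - 1), 1)
      ref_b <- substring(as.character(reference[[ci]]), pos, pos)
      bg_rows[[i]] <- data.frame(contig = contigs[ci], pos = pos,
                                 ref = ref_b,
                                 alt = sample(setdiff(DNA_BASES, ref_b), 1),
                                 stringsAsFactors = FALSE)
    }
    rows <- bg_rows
    rows[u < f] <- uv_rows[u < f]
    out <- if (n > 0) do.call(rbind, rows)
    else data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0))
    out$qual <- round(runif(n, qual_range[1], qual_range[2]), 1)
    out$depth <- if (n > 0)
      sample(depth_range[1]:depth_range[2], n, replace = TRUE) else integer(0)
    out$sample <- rep(sample_name, n)
    out[order(out$contig, out$pos), , drop = FALSE]
  })
  vs <- new_variant_set(df, list(n_input = n, n_channels_redrawn = redrawn))
  if (!is.null(path)) write_vcf(vs, reference, path)
  vs
}

write_vcf <- function(variants, reference, path) {
  reference <- as_reference(reference)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(reference),
                       Biostrings::width(reference)),
               '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  if (nrow(variants) > 0)
    writeLines(paste(variants$contig, variants$pos, ".", variants$ref,
                     variants$alt, variants$qual, "PASS",
                     paste0("DP=", variants$depth), sep = "\t"), con)
  invisible(path)
}

#' Synthesize a toy transcriptome with expression and a variant map
#'
#' Generates in-frame CDS records (start codon, no internal stops, terminal
#' stop), gamma-distributed expression levels, and a per-sample
#' variant-to-CDS map in which each sample's mutations are signature-drawn
#' with per-sample probability `uv_fraction` (uniform random SNVs
#' otherwise).
#'
#' @param n_transcripts Number of transcripts.
#' @param n_codons Range (min, max) of coding codons per transcript.
#' @param n_samples Number of samples in the variant map.
#' @param n_mutations Mutations per sample (recycled over samples).
#' @param uv_fraction Per-sample probability that a mutation is
#'   signature-drawn (recycled over samples).
#' @param signature A `uv_signature`.
#' @param codon_usage A `codon_usage` for drawing codons.
#' @param seed RNG seed.
#' @param plant Optional list(`transcript`, `codon`, `seq`) forcing a known
#'   codon at a known position (for worked examples).
#' @param dir Optional output directory (writes `cds.fasta`,
#'   `expression.tsv`, `variant_map.tsv`).
#' @return List with `transcripts` (a `transcript_set`), `expression`
#'   (data.frame) and `map` (data.frame `sample`, `transcript_id`,
#'   `cds_pos`, `ref`, `alt`, `uv`).
#' @export
synth_transcriptome <- function(n_transcripts = 20, n_codons = c(100, 300),
                                n_samples = 10, n_mutations = 20,
                                uv_fraction = 0.5,
                                signature = load_signature(),
                                codon_usage = load_codon_usage(), seed = 1,
                                plant = NULL, dir = NULL) {
  codons <- names(codon_usage)
  coding <- codons[Biostrings::GENETIC_CODE[codons] != "*"]
  p_cod <- codon_usage[coding] / sum(codon_usage[coding])
  out <- with_seed(seed, {
    cds <- vapply(seq_len(n_transcripts), function(i) {
      nc <- sample(n_codons[1]:n_codons[2], 1)
      paste0("ATG",
             paste(sample(coding, nc, replace = TRUE, prob = p_cod),
                   collapse = ""),
             "TAA")
    }, character(1))
    names(cds) <- sprintf("tx%03d", seq_len(n_transcripts))
    if (!is.null(plant)) {
      id <- names(cds)[plant$transcript]
      s <- cds[[id]]
      at <- (plant$codon - 1) * 3 + 1
      cds[[id]] <- paste0(substring(s, 1, at - 1), plant$seq,
                          substring(s, at + 3, nchar(s)))
    }
    expression <- data.frame(transcript_id = names(cds),
                             expression = round(rgamma(n_transcripts,
                                                       shape = 2,
                                                       scale = 50), 3))
    ref <- Biostrings::DNAStringSet(cds)
    idx <- motif_position_index(ref)
    nm <- rep_len(n_mutations, n_samples)
    uvf <- rep_len(uv_fraction, n_samples)
    map <- list()
    for (s in seq_len(n_samples)) {
      for (j in seq_len(nm[s])) {
        if (runif(1) < uvf[s]) {
          repeat {
            ch <- sample.int(nrow(signature), 1, prob = signature$prob)
            motif <- paste0(signature$ctx5[ch], signature$ref[ch],
                            signature$ctx3[ch])
            hits <- lapply(idx, function(m) m[[motif]])
            n_hits <- vapply(hits, function(h) length(h %||% integer(0)),
                             numeric(1))
            if (sum(n_hits) > 0) break
          }
          ti <- sample.int(length(cds), 1, prob = n_hits)
          pos <- hits[[ti]][sample.int(length(hits[[ti]]), 1)] + 1L
          rb <- signature$ref[ch]; ab <- signature$alt[ch]; uv <- TRUE
        } else {
          ti <- sample.int(length(cds), 1)
          pos <- sample(2:(nchar(cds[[ti]]) - 1), 1)
          rb <- substring(cds[[ti]], pos, pos)
          ab <- sample(setdiff(DNA_BASES, rb), 1)
          uv <- FALSE
        }
        map[[length(map) + 1]] <- data.frame(
          sample = sprintf("sample%02d", s), transcript_id = names(cds)[ti],
          cds_pos = pos, ref = rb, alt = ab, uv = uv,
          stringsAsFactors = FALSE)
      }
    }
    list(cds = cds, expression = expression, map = do.call(rbind, map))
  })
  transcripts <- read_transcripts(out$cds, out$expression)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$cds),
                                file.path(dir, "cds.fasta"))
    write.table(out$expression, file.path(dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$map, file.path(dir, "variant_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(transcripts = transcripts, expression = out$expression,
       map = out$map)
}

#' Synthesize an immunotherapy outcome cohort with a planted UV effect
#'
#' Patients get a TMB category, a UV group and a UVMSE score consistent with
#' it, a best response drawn from group-specific response probabilities, and
#' exponential PFS/OS with group-specific medians, censored uniformly over a
#' follow-up window. The planted effect follows the clinical finding being
#' modelled: UV-high improves response and survival only in the pooled
#' low/intermediate-TMB stratum; the high-TMB stratum has no UV effect.
#'
#' @param n Cohort size (>= 20).
#' @param seed RNG seed.
#' @param uv_high_frac Fraction of UV-high patients.
#' @param tmb_probs Probabilities of (low, intermediate, high) TMB.
#' @param response_low_int,response_high Response probabilities
#'   `c(uv_high, uv_low)` within each stratum. Defaults plant the reported
#'   clinical rates (45% vs 14% in low/intermediate; 58% vs 57% in high).
#' @param pfs_medians_low_int,os_medians_low_int Exponential survival
#'   medians `c(uv_high, uv_low)` in months for the low/intermediate
#'   stratum (defaults 9.3 vs 3.2 for PFS and 40 vs 21 for OS).
#' @param pfs_median_high,os_median_high Shared medians in the high-TMB
#'   stratum (no UV effect).
#' @param censor_window Uniform censoring-time window in months.
#' @param uvmse_params `list(high = c(mean, sd), low = c(mean, sd))` for the
#'   simulated UVMSE scores.
#' @param path Optional TSV output path.
#' @return The cohort data.frame (columns of [read_cohort()] plus
#'   `uv_group`).
#' @export
synth_cohort <- function(n = 151, seed = 1, uv_high_frac = 0.3,
                         tmb_probs = c(0.5, 0.4, 0.1),
                         response_low_int = c(uv_high = 0.45, uv_low = 0.14),
                         response_high = c(uv_high = 0.58, uv_low = 0.57),
                         pfs_medians_low_int = c(uv_high = 9.3, uv_low = 3.2),
                         os_medians_low_int = c(uv_high = 40, uv_low = 21),
                         pfs_median_high = 6, os_median_high = 25,
                         censor_window = c(6, 60),
                         uvmse_params = list(high = c(0.82, 0.02),
                                             low = c(0.765, 0.015)),
                         path = NULL) {
  stopifnot(n >= 20)
  cohort <- with_seed(seed, {
    uv_high <- runif(n) < uv_high_frac
    tmb_cat <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                      prob = tmb_probs)
    tmb <- ifelse(tmb_cat == "low", sample(1:5, n, replace = TRUE),
                  ifelse(tmb_cat == "intermediate",
                         sample(6:19, n, replace = TRUE),
                         sample(20:60, n, replace = TRUE)))
    uvmse <- ifelse(uv_high,
                    rnorm(n, uvmse_params$high[1], uvmse_params$high[2]),
                    rnorm(n, uvmse_params$low[1], uvmse_params$low[2]))
    hi_strat <- tmb_cat == "high"
    p_resp <- ifelse(hi_strat,
                     ifelse(uv_high, response_high[1], response_high[2]),
                     ifelse(uv_high, response_low_int[1],
                            response_low_int[2]))
    responder <- runif(n) < p_resp
    response <- ifelse(responder,
                       sample(c("CR", "PR"), n, replace = TRUE,
                              prob = c(0.2, 0.8)),
                       sample(c("SD", "PD"), n, replace = TRUE,
                              prob = c(0.3, 0.7)))
    draw_surv <- function(median_months) {
      t_event <- rexp(n, rate = log(2) / median_months)
      t_cens <- runif(n, censor_window[1], censor_window[2])
      list(time = round(pmin(t_event, t_cens), 2),
           event = as.integer(t_event <= t_cens))
    }
    pfs_med <- ifelse(hi_strat, pfs_median_high,
                      ifelse(uv_high, pfs_medians_low_int[1],
                             pfs_medians_low_int[2]))
    os_med <- ifelse(hi_strat, os_median_high,
                     ifelse(uv_high, os_medians_low_int[1],
                            os_medians_low_int[2]))
    pfs <- draw_surv(pfs_med)
    os <- draw_surv(os_med)
    data.frame(id = sprintf("pt%03d", seq_len(n)),
               uvmse = round(uvmse, 4), tmb = tmb, response = response,
               pfs_months = pfs$time, pfs_event = pfs$event,
               os_months = os$time, os_event = os$event,
               uv_group = ifelse(uv_high, "uv_high", "uv_low"),
               stringsAsFactors = FALSE)
  })
  if (!is.null(path))
    write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort
}
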