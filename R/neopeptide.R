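#' @importFrom stats lm cor cor.test coef
NULL

codon_translate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                      seq(3, nchar(cds), by = 3))
  paste(gc[codons], collapse = "")
}

# peptide = translation up to (excluding) the first stop
peptide_of <- function(cds) {
  aa <- codon_translate(cds)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
}

#' Read a transcript set (CDS FASTA plus optional expression table)
#'
#' CDS records must be in frame (length divisible by 3). Records with an
#' internal stop codon are kept but flagged. Expression is a TSV with
#' columns `transcript_id` and `expression` (non-negative).
#'
#' @param cds_fasta FASTA of coding sequences (or a named character vector).
#' @param expression Optional TSV path or data.frame with columns
#'   `transcript_id`, `expression`.
#' @return A `transcript_set`: named list of transcript models (`id`, `cds`,
#'   `expression`, `internal_stop`).
#' @export
read_transcripts <- function(cds_fasta, expression = NULL) {
  seqs <- if (is.character(cds_fasta) && length(cds_fasta) == 1 &&
              file.exists(cds_fasta)) {
    x <- Biostrings::readDNAStringSet(cds_fasta)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (!is.null(names(cds_fasta))) toupper(cds_fasta)
  else stop("cds_fasta must be a FASTA path or a named character vector")
  expr <- NULL
  if (!is.null(expression)) {
    etab <- if (is.character(expression)) read.delim(expression) else expression
    if (!all(c("transcript_id", "expression") %in% names(etab)))
      stop("expression table needs columns transcript_id, expression")
    if (any(etab$expression < 0)) stop("negative expression level")
    expr <- setNames(etab$expression, etab$transcript_id)
  }
  models <- lapply(names(seqs), function(id) {
    cds <- toupper(seqs[[id]])
    if (nchar(cds) %% 3 != 0)
      stop("CDS length of ", id, " is not divisible by 3")
    aa <- codon_translate(cds)
    internal_stop <- grepl("\\*.", aa)
    list(id = id, cds = cds,
         expression = if (!is.null(expr)) unname(expr[id]) else NA_real_,
         internal_stop = internal_stop)
  })
  structure(setNames(models, names(seqs)), class = "transcript_set")
}

#' Apply a coding variant to a transcript
#'
#' Edits the CDS at a CDS-relative coordinate and translates before and
#' after. Substitutions of equal length replace in place (a missense SNV
#' changes exactly one residue; a stop-gain truncates the after-peptide);
#' length-changing edits shift the frame and the edited CDS is translated to
#' the first downstream stop.
#'
#' @param transcript A transcript model from [read_transcripts()] (or a list
#'   with `id` and `cds`).
#' @param cds_pos 1-based position within the CDS.
#' @param ref,alt Reference and alternate allele (CDS strand).
#' @return A `mutated_transcript`: list with `id`, `cds_before`, `cds_after`,
#'   `peptide_before`, `peptide_after`, `changed` (changed residue indices on
#'   the before-peptide coordinate system).
#' @export
mutate_transcript <- function(transcript, cds_pos, ref, alt) {
  cds <- transcript$cds
  ref <- toupper(ref); alt <- toupper(alt)
  if (cds_pos < 1 || cds_pos + nchar(ref) - 1 > nchar(cds))
    stop("variant position outside the CDS of ", transcript$id)
  if (substring(cds, cds_pos, cds_pos + nchar(ref) - 1) != ref)
    stop("reference allele mismatch at CDS position ", cds_pos, " of ",
         transcript$id)
  edited <- paste0(substring(cds, 1, cds_pos - 1), alt,
                   substring(cds, cds_pos + nchar(ref), nchar(cds)))
  if (nchar(edited) %% 3 != 0)   # frameshift: pad for whole-codon translation
    edited_t <- substring(edited, 1, nchar(edited) - nchar(edited) %% 3)
  else edited_t <- edited
  before <- peptide_of(cds)
  after <- peptide_of(edited_t)
  lmin <- min(nchar(before), nchar(after))
  changed <- if (lmin > 0)
    which(strsplit(substr(before, 1, lmin), "")[[1]] !=
          strsplit(substr(after, 1, lmin), "")[[1]]) else integer(0)
  if (nchar(after) != nchar(before))
    changed <- sort(union(changed, lmin + 1L))
  structure(list(id = transcript$id, cds_before = cds, cds_after = edited,
                 peptide_before = before, peptide_after = after,
                 changed = changed),
            class = "mutated_transcript")
}

#' Full-length hydrophobicity change of a mutated transcript
#'
#' Difference in total hydropathy of the full-length peptide product, after
#' minus before mutation. A stop-gain's loss of the downstream residues
#' contributes the negated hydropathy of the truncated tail.
#'
#' @param m A `mutated_transcript`.
#' @param scale A `hydropathy_scale`.
#' @return The change in AU.
#' @export
full_length_delta <- function(m, scale = load_hydropathy_scale()) {
  hydropathy_sum(m$peptide_after, scale) -
    hydropathy_sum(m$peptide_before, scale)
}

#' Enumerate 8-10-mer neopeptides spanning a mutation
#'
#' All windows of each length in `k_range` that contain at least one changed
#' residue, clipped at the peptide termini, each paired with the
#' same-coordinate window of the unmutated peptide. An interior missense
#' residue with at least `max(k_range) - 1` residues on both sides yields
#' `sum(k_range)` pairs (27 for 8-10-mers).
#'
#' @param m A `mutated_transcript` with at least one changed residue
#'   (an empty set is returned for synonymous changes).
#' @param k_range Peptide lengths to enumerate (default 8:10, the MHC class I
#'   presentation range).
#' @return A `neopeptide_set`: data.frame with columns `k`, `start`,
#'   `before`, `after`.
#' @export
enumerate_neopeptides <- function(m, k_range = 8:10) {
  len_b <- nchar(m$peptide_before)
  len_a <- nchar(m$peptide_after)
  L <- max(len_b, len_a)
  rows <- list()
  for (k in k_range) {
    starts <- seq_len(max(L - k + 1, 0))
    keep <- vapply(starts, function(s)
      any(m$changed >= s & m$changed <= s + k - 1), logical(1))
    for (s in starts[keep]) {
      rows[[length(rows) + 1]] <- data.frame(
        k = k, start = s,
        before = substr(m$peptide_before, s, min(s + k - 1, len_b)),
        after = substr(m$peptide_after, s, min(s + k - 1, len_a)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(k = integer(0), start = integer(0),
                  before = character(0), after = character(0))
  structure(out, class = c("neopeptide_set", "data.frame"))
}

#' Total neopeptide hydrophobicity change
#'
#' Sums the after-minus-before hydropathy over every enumerated neopeptide
#' pair; optionally multiplied by a (normalized, non-negative) expression
#' level so that unexpressed transcripts contribute nothing.
#'
#' @param set A `neopeptide_set`.
#' @param scale A `hydropathy_scale`.
#' @param expression Optional non-negative expression weight.
#' @return The (optionally weighted) total change in AU.
#' @export
neopeptide_delta <- function(set, scale = load_hydropathy_scale(),
                             expression = NULL) {
  stopifnot(inherits(set, "neopeptide_set"))
  total <- sum(hydropathy_sum(set$after, scale) -
               hydropathy_sum(set$before, scale))
  if (!is.null(expression)) {
    if (is.na(expression) || expression < 0)
      stop("expression weight must be non-negative")
    total <- total * expression
  }
  total
}

#' Per-sample hydrophobicity change profile
#'
#' Applies each sample's coding mutations to its transcripts and sums the
#' per-mutation hydropathy changes, in either full-length or neopeptide
#' (8-10-mer) mode, optionally weighted by each transcript's share of total
#' expression.
#'
#' @param variant_map data.frame with columns `sample`, `transcript_id`,
#'   `cds_pos`, `ref`, `alt` (CDS coordinates; or a path to such a TSV).
#' @param transcripts A `transcript_set`.
#' @param scale A `hydropathy_scale`.
#' @param mode `"neopeptide"` (default) or `"full_length"`.
#' @param weighted Weight each mutation's delta by the transcript's fraction
#'   of total expression.
#' @param k_range Peptide lengths for neopeptide mode.
#' @return data.frame with one row per sample: `sample`, `delta_au`,
#'   `n_mutations`, `n_unmapped`.
#' @export
sample_hydrophobicity_profile <- function(variant_map, transcripts,
                                          scale = load_hydropathy_scale(),
                                          mode = c("neopeptide",
                                                   "full_length"),
                                          weighted = FALSE, k_range = 8:10) {
  mode <- match.arg(mode)
  if (is.character(variant_map)) variant_map <- read.delim(variant_map)
  need <- c("sample", "transcript_id", "cds_pos", "ref", "alt")
  stopifnot(all(need %in% names(variant_map)))
  expr <- vapply(transcripts, function(t) t$expression %||% NA_real_,
                 numeric(1))
  if (weighted) {
    if (anyNA(expr)) stop("weighted mode needs expression for all transcripts")
    wts <- expr / sum(expr)
  }
  out <- lapply(split(variant_map, variant_map$sample), function(vm) {
    delta <- 0; used <- 0L; unmapped <- 0L
    for (i in seq_len(nrow(vm))) {
      tid <- as.character(vm$transcript_id[i])
      tr <- transcripts[[tid]]
      if (is.null(tr)) { unmapped <- unmapped + 1L; next }
      m <- tryCatch(mutate_transcript(tr, vm$cds_pos[i], vm$ref[i],
                                      vm$alt[i]),
                    error = function(e) NULL)
      if (is.null(m)) { unmapped <- unmapped + 1L; next }
      d <- if (mode == "full_length") full_length_delta(m, scale)
      else neopeptide_delta(enumerate_neopeptides(m, k_range), scale)
      if (weighted) d <- d * wts[[tid]]
      delta <- delta + d
      used <- used + 1L
    }
    data.frame(sample = vm$sample[1], delta_au = delta, n_mutations = used,
               n_unmapped = unmapped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlate per-sample hydrophobicity change with UV-weighted load
#'
#' Linear fit plus rank statistics between per-sample hydrophobicity change
#' and the UV-weighted mutation load.
#'
#' @param delta_au Per-sample hydrophobicity changes (AU).
#' @param weighted_load Per-sample UV-weighted mutation loads.
#' @return A list with `r_squared`, `pearson`, `spearman`, `slope`,
#'   `slope_p`, `n` and the scatter `data`; degenerate (zero-variance) input
#'   is reported with `r_squared = NA` and a `note`.
#' @export
correlate_hydrophobicity_load <- function(delta_au, weighted_load) {
  if (length(delta_au) != length(weighted_load))
    stop("inputs must have equal length")
  if (length(delta_au) < 3) stop("need at least 3 samples")
  dat <- data.frame(load = weighted_load, delta = delta_au)
  if (sd(dat$load) == 0 || sd(dat$delta) == 0)
    return(list(r_squared = NA_real_, pearson = NA_real_,
                spearman = NA_real_, slope = NA_real_, slope_p = NA_real_,
                n = nrow(dat), data = dat,
                note = "zero variance: correlation undefined"))
  fit <- lm(delta ~ load, data = dat)
  r <- cor(dat$load, dat$delta)
  # slope p for a simple regression equals the correlation test's p, which
  # stays quiet on an exactly collinear fit
  ct <- cor.test(dat$load, dat$delta)
  list(r_squared = r^2,
       pearson = r,
       spearman = cor(dat$load, dat$delta, method = "spearman"),
       slope = unname(coef(fit)[2]),
       slope_p = ct$p.value,
       n = nrow(dat), data = dat)
}
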