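#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
PYRIMIDINES <- c("C", "T")

#' Paths to the tables bundled with the package
#'
#' `uv_signature_file()` points at the bundled strand-resolved (192-channel)
#' UV substitution signature. The bundled table is a *synthetic* stand-in
#' constructed from the known qualitative features of UV mutagenesis
#' (C>T transitions at dipyrimidine contexts dominate, with a transcriptional
#' strand bias disfavouring the purine-reference representation); its
#' TCC>TTC channel is pinned at the published probability 0.2887. See the
#' provenance header inside the file and the methods vignette.
#'
#' `codon_usage_file()` points at the bundled human codon-usage table
#' (Kazusa-style per-mille frequencies); `hydropathy_file()` at the bundled
#' Kyte-Doolittle hydropathy scale.
#'
#' @return A file path.
#' @export
uv_signature_file <- function() {
  system.file("extdata", "uv_signature_synthetic_192.tsv",
              package = "uvsig", mustWork = TRUE)
}

#' @rdname uv_signature_file
#' @export
codon_usage_file <- function() {
  system.file("extdata", "codon_usage_human_kazusa.tsv",
              package = "uvsig", mustWork = TRUE)
}

#' @rdname uv_signature_file
#' @export
hydropathy_file <- function() {
  system.file("extdata", "kyte_doolittle.tsv",
              package = "uvsig", mustWork = TRUE)
}

channel_key <- function(ctx5, ref, alt, ctx3) {
  paste0(ctx5, "[", ref, ">", alt, "]", ctx3)
}

all_channel_keys <- function() {
  g <- expand.grid(ctx5 = DNA_BASES, ref = DNA_BASES, alt = DNA_BASES,
                   ctx3 = DNA_BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  channel_key(g$ctx5, g$ref, g$alt, g$ctx3)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(DNA_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Load a substitution signature table
#'
#' Reads a tab-separated signature with columns `ctx5`, `ref`, `alt`, `ctx3`
#' and `prob`, one row per strand-resolved channel (a single-base substitution
#' with its immediate 5' and 3' flanking bases). A strand-resolved signature
#' has 192 channels; a 96-channel pyrimidine-folded table is accepted and
#' symmetrized (each channel's mass is split equally between the channel and
#' its reverse complement), with a warning.
#'
#' @param path Path to the TSV file (defaults to the bundled UV signature).
#' @param strand_resolved Logical; if `TRUE` (default) a 192-channel table is
#'   expected and a 96-channel one is symmetrized with a warning.
#' @param name Label stored with the signature.
#' @return A `uv_signature`: a data.frame with columns `ctx5`, `ref`, `alt`,
#'   `ctx3`, `prob` and (row-aligned) `key`, carrying attributes `name` and
#'   `strand_resolved`.
#' @export
load_signature <- function(path = uv_signature_file(), strand_resolved = TRUE,
                           name = basename(path)) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("ctx5", "ref", "alt", "ctx3", "prob")
  if (!all(need %in% names(raw)))
    stop("signature file must have columns: ", paste(need, collapse = ", "))
  raw <- raw[need]
  for (col in c("ctx5", "ref", "alt", "ctx3")) {
    raw[[col]] <- toupper(raw[[col]])
    bad <- !raw[[col]] %in% DNA_BASES
    if (any(bad))
      stop("non-ACGT base in column ", col, " at row(s) ",
           paste(head(which(bad)), collapse = ", "))
  }
  if (any(raw$ref == raw$alt))
    stop("ref equals alt at row(s) ",
         paste(head(which(raw$ref == raw$alt)), collapse = ", "))
  if (any(raw$prob < 0)) {
    bad <- which(raw$prob < 0)[1]
    stop("negative probability for channel ",
         channel_key(raw$ctx5[bad], raw$ref[bad], raw$alt[bad], raw$ctx3[bad]))
  }
  raw$key <- channel_key(raw$ctx5, raw$ref, raw$alt, raw$ctx3)
  dup <- duplicated(raw$key)
  if (any(dup)) stop("duplicate channel ", raw$key[which(dup)[1]])

  if (nrow(raw) == 96 && strand_resolved) {
    warning("96-channel (strand-folded) signature: symmetrizing with halved ",
            "mass over both strands")
    if (!all(raw$ref %in% PYRIMIDINES))
      stop("96-channel signature must have pyrimidine reference bases")
    rc <- data.frame(ctx5 = revcomp_chr(raw$ctx3),
                     ref  = DNA_COMPLEMENT[raw$ref],
                     alt  = DNA_COMPLEMENT[raw$alt],
                     ctx3 = revcomp_chr(raw$ctx5),
                     prob = raw$prob / 2, stringsAsFactors = FALSE)
    rc$key <- channel_key(rc$ctx5, rc$ref, rc$alt, rc$ctx3)
    raw$prob <- raw$prob / 2
    raw <- rbind(raw, rc)
  }
  missing <- setdiff(all_channel_keys(), raw$key)
  if (length(missing) > 0)
    stop("signature is missing channel(s): ",
         paste(head(missing, 3), collapse = ", "),
         if (length(missing) > 3) sprintf(" (and %d more)", length(missing) - 3))
  total <- sum(raw$prob)
  if (abs(total - 1) > 1e-6)
    stop(sprintf("signature probabilities sum to %.8f, not 1 (tolerance 1e-6)",
                 total))
  raw <- raw[order(raw$key), ]
  rownames(raw) <- NULL
  structure(raw, class = c("uv_signature", "data.frame"),
            name = name, strand_resolved = TRUE)
}

#' Write a signature table back to disk
#'
#' Inverse of [load_signature()]; values round-trip bit-for-bit at full
#' double precision (probabilities are written with 17 significant digits).
#'
#' @param sig A `uv_signature`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "uv_signature"))
  out <- data.frame(ctx5 = sig$ctx5, ref = sig$ref, alt = sig$alt,
                    ctx3 = sig$ctx3,
                    prob = formatC(sig$prob, digits = 17, format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up signature channel probabilities
#'
#' @param sig A `uv_signature`.
#' @param ctx5,ref,alt,ctx3 Base vectors describing channels (recycled to a
#'   common length).
#' @return Numeric vector of channel probabilities (0 for absent channels,
#'   which cannot occur for a validated 192-channel signature).
#' @export
signature_probability <- function(sig, ctx5, ref, alt, ctx3) {
  p <- setNames(sig$prob, sig$key)
  out <- p[channel_key(ctx5, ref, alt, ctx3)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Load a codon-usage table
#'
#' Reads a TSV with columns `codon` and `freq`. Frequencies in any consistent
#' unit (fractions, percent, per-mille counts) are rescaled to fractions by
#' dividing by their total. All 64 codons must be present.
#'
#' @param path Path to the TSV (defaults to the bundled human table).
#' @return A `codon_usage`: a named numeric vector of 64 codon fractions
#'   summing to 1, sorted by codon.
#' @export
load_codon_usage <- function(path = codon_usage_file()) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("codon", "freq") %in% names(raw)))
    stop("codon usage file must have columns codon, freq")
  raw$codon <- toupper(gsub("U", "T", toupper(raw$codon)))
  all_codons <- sort(do.call(paste0,
    expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)))
  missing <- setdiff(all_codons, raw$codon)
  if (length(missing) > 0)
    stop("codon usage table is missing codon(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(raw$codon)) stop("duplicate codon rows")
  if (any(raw$freq < 0)) stop("negative codon frequency")
  total <- sum(raw$freq)
  if (total <= 0) stop("codon frequencies sum to zero")
  freq <- setNames(raw$freq / total, raw$codon)[all_codons]
  structure(freq, class = "codon_usage")
}

#' @rdname write_signature
#' @param cu A `codon_usage`.
#' @export
write_codon_usage <- function(cu, path) {
  stopifnot(inherits(cu, "codon_usage"))
  out <- data.frame(codon = names(cu),
                    freq = formatC(as.numeric(cu), digits = 17, format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an amino-acid hydropathy scale
#'
#' Reads a TSV with columns `residue` (one-letter code) and `index`
#' (hydropathy in arbitrary units, AU; positive = hydrophobic). The bundled
#' default is the Kyte-Doolittle scale. A stop symbol `*` is appended with a
#' configurable hydropathy (default 0 AU) so translated stop codons can be
#' scored; stop codons are additionally tracked as a census by the simulator.
#'
#' @param path Path to the scale TSV (defaults to the bundled scale).
#' @param stop_value Hydropathy assigned to the stop symbol `*`.
#' @return A `hydropathy_scale`: named numeric vector over the 20 residues
#'   plus `*`.
#' @export
load_hydropathy_scale <- function(path = hydropathy_file(), stop_value = 0) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "index") %in% names(raw)))
    stop("hydropathy file must have columns residue, index")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  missing <- setdiff(aa, raw$residue)
  if (length(missing) > 0)
    stop("hydropathy scale is missing residue(s): ",
         paste(missing, collapse = ", "))
  scale <- setNames(raw$index, raw$residue)[aa]
  scale["*"] <- stop_value
  structure(scale, class = "hydropathy_scale")
}

#' Classify a substitution into a signature channel
#'
#' Maps a single-base substitution and its flanking bases to a canonical
#' channel key. With `fold = TRUE`, substitutions whose reference base is a
#' purine are reverse-complemented onto the pyrimidine-reference channel, so
#' a substitution and its reverse complement classify identically (e.g.
#' G>A in context G_A folds onto the TCC>TTC channel).
#'
#' @param ref,alt Reference and alternate base (vectors are recycled).
#' @param ctx5,ctx3 The 5' and 3' flanking reference bases.
#' @param fold Fold purine-reference substitutions onto their
#'   pyrimidine-reference complement channel.
#' @return A data.frame with columns `ctx5`, `ref`, `alt`, `ctx3`, `key`
#'   (canonical channel key) and `strand` (`"+"` if the input was already
#'   pyrimidine-reference, `"-"` if it was folded).
#' @export
classify_channel <- function(ref, alt, ctx5, ctx3, fold = TRUE) {
  n <- max(length(ref), length(alt), length(ctx5), length(ctx3))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  ctx5 <- rep_len(toupper(ctx5), n); ctx3 <- rep_len(toupper(ctx3), n)
  for (v in list(ref, alt, ctx5, ctx3))
    if (!all(v %in% DNA_BASES)) stop("non-ACGT base in channel classification")
  if (any(ref == alt)) stop("ref equals alt: not a substitution")
  strand <- ifelse(ref %in% PYRIMIDINES, "+", "-")
  flip <- strand == "-" & fold
  out <- data.frame(ctx5 = ifelse(flip, DNA_COMPLEMENT[ctx3], ctx5),
                    ref  = ifelse(flip, DNA_COMPLEMENT[ref], ref),
                    alt  = ifelse(flip, DNA_COMPLEMENT[alt], alt),
                    ctx3 = ifelse(flip, DNA_COMPLEMENT[ctx5], ctx3),
                    strand = strand, stringsAsFactors = FALSE)
  out$key <- channel_key(out$ctx5, out$ref, out$alt, out$ctx3)
  rownames(out) <- NULL
  out
}

#' Total hydropathy of peptides
#'
#' Sums per-residue hydropathy indices over each peptide. The empty peptide
#' sums to 0 AU; an unknown residue symbol is an error.
#'
#' @param peptide Character vector of peptide strings (one-letter codes,
#'   optionally containing the stop symbol `*`).
#' @param scale A `hydropathy_scale` (default: bundled Kyte-Doolittle).
#' @return Numeric vector of total hydropathies (AU), one per peptide.
#' @export
hydropathy_sum <- function(peptide, scale = load_hydropathy_scale()) {
  vapply(peptide, function(p) {
    if (is.na(p) || nchar(p) == 0) return(0)
    res <- strsplit(p, "")[[1]]
    unknown <- setdiff(res, names(scale))
    if (length(unknown) > 0)
      stop("unknown residue symbol(s): ", paste(unique(unknown), collapse = ""))
    sum(scale[res])
  }, numeric(1), USE.NAMES = FALSE)
}
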