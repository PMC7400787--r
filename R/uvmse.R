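#' @importFrom methods is
NULL

FOLDED_PAIRS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

as_reference <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    names(reference) <- sub("\\s.*$", "", names(reference))
    return(reference)
  }
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  stop("reference must be a DNAStringSet or a FASTA file path")
}

ref_base_at <- function(reference, contig, pos) {
  out <- character(length(contig))
  for (ct in unique(contig)) {
    if (!ct %in% names(reference)) stop("contig absent from reference: ", ct)
    i <- contig == ct
    s <- as.character(reference[[ct]])
    out[i] <- substring(s, pos[i], pos[i])
  }
  out
}

new_variant_set <- function(df, log) {
  rownames(df) <- NULL
  structure(df, class = c("variant_set", "data.frame"), log = log)
}

#' Read somatic variants from a VCF or MAF file
#'
#' Retains single-nucleotide substitutions. Multi-nucleotide substitutions
#' (e.g. the UV-typical CC>TT dinucleotide) are decomposed into their
#' component SNVs; indels are dropped and counted. Every retained record's
#' reference allele is verified against the reference sequence; mismatching
#' records are rejected and counted.
#'
#' @param path VCF (v4.x) or MAF file. MAF needs columns for chromosome,
#'   position, reference/alternate allele and sample (standard MAF headers
#'   are recognized).
#' @param reference A DNAStringSet or FASTA path.
#' @param format `"auto"` (by extension), `"vcf"` or `"maf"`.
#' @return A `variant_set`: data.frame with columns `contig`, `pos`
#'   (1-based), `ref`, `alt`, `qual`, `depth`, `sample`; attribute `log`
#'   records the numbers of input rows, decomposed MNVs, dropped indels and
#'   reference mismatches.
#' @export
read_variants <- function(path, reference,
                          format = c("auto", "vcf", "maf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.maf(\\.gz)?$|\\.tsv$", path, ignore.case = TRUE))
      "maf" else "vcf"
  reference <- as_reference(reference)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      return(new_variant_set(
        data.frame(contig = character(), pos = integer(), ref = character(),
                   alt = character(), qual = numeric(), depth = numeric(),
                   sample = character()),
        list(n_input = 0L, n_mnv_decomposed = 0L, n_indels_dropped = 0L,
             n_ref_mismatch = 0L)))
    }
    depth <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, "DP")))
    smp <- if (ncol(vcf@gt %||% matrix(nrow = 0, ncol = 1)) > 1)
      colnames(vcf@gt)[2] else sub("\\.vcf(\\.gz)?$", "", basename(path))
    raw <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = toupper(fix$REF), alt = toupper(fix$ALT),
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      depth = depth, sample = smp,
                      stringsAsFactors = FALSE)
  } else {
    # colClasses: a lone "T" allele must not become logical TRUE
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character")
    pick <- function(...) {
      cand <- c(...)
      hit <- cand[tolower(cand) %in% tolower(names(tab))][1]
      if (is.na(hit)) stop("MAF is missing a column for ", cand[1])
      tab[[match(tolower(hit), tolower(names(tab)))]]
    }
    raw <- data.frame(
      contig = as.character(pick("chrom", "Chromosome", "chr")),
      pos = as.integer(pick("pos", "Start_Position", "Start_position")),
      ref = toupper(pick("ref", "Reference_Allele")),
      alt = toupper(pick("alt", "Tumor_Seq_Allele2", "Alt_Allele")),
      qual = NA_real_, depth = NA_real_, stringsAsFactors = FALSE)
    raw$sample <- as.character(pick("sample", "Tumor_Sample_Barcode"))
  }
  # split multi-allelic ALT
  multi <- grepl(",", raw$alt)
  if (any(multi)) {
    parts <- strsplit(raw$alt[multi], ",")
    expanded <- raw[rep(which(multi), lengths(parts)), ]
    expanded$alt <- unlist(parts)
    raw <- rbind(raw[!multi, ], expanded)
  }
  n_input <- nrow(raw)
  is_indel <- nchar(raw$ref) != nchar(raw$alt) |
    grepl("[^ACGT]", raw$ref) | grepl("[^ACGT]", raw$alt)
  n_indel <- sum(is_indel)
  raw <- raw[!is_indel, , drop = FALSE]
  # decompose MNVs into component SNVs
  n_mnv <- 0L
  mnv <- nchar(raw$ref) > 1
  if (any(mnv)) {
    n_mnv <- sum(mnv)
    pieces <- lapply(which(mnv), function(i) {
      rb <- strsplit(raw$ref[i], "")[[1]]
      ab <- strsplit(raw$alt[i], "")[[1]]
      off <- which(rb != ab)
      if (length(off) == 0) return(NULL)
      data.frame(contig = raw$contig[i], pos = raw$pos[i] + off - 1L,
                 ref = rb[off], alt = ab[off], qual = raw$qual[i],
                 depth = raw$depth[i], sample = raw$sample[i],
                 stringsAsFactors = FALSE)
    })
    raw <- rbind(raw[!mnv, , drop = FALSE], do.call(rbind, pieces))
  }
  raw <- raw[raw$ref != raw$alt, , drop = FALSE]
  # reference consistency
  n_mismatch <- 0L
  if (nrow(raw) > 0) {
    obs <- ref_base_at(reference, raw$contig, raw$pos)
    bad <- obs != raw$ref
    n_mismatch <- sum(bad)
    raw <- raw[!bad, , drop = FALSE]
  }
  new_variant_set(raw, list(n_input = n_input, n_mnv_decomposed = n_mnv,
                            n_indels_dropped = n_indel,
                            n_ref_mismatch = n_mismatch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter variants on quality, depth and target regions
#'
#' Records with `QUAL < min_qual` or depth `< min_depth` are removed
#' (boundary values are kept; missing values pass, since MAF input carries
#' neither field). If `regions` is given (a BED path or a GRanges), only
#' variants falling inside the intervals are kept; BED input is 0-based
#' half-open and is converted on import.
#'
#' @param variants A `variant_set`.
#' @param min_qual,min_depth Inclusive keep-side thresholds.
#' @param regions Optional BED path or GRanges of targeted regions.
#' @return The filtered `variant_set`; the `log` attribute gains the counts
#'   removed at each step.
#' @export
filter_variants <- function(variants, min_qual = 50, min_depth = 100,
                            regions = NULL) {
  log <- attr(variants, "log") %||% list()
  keep <- (is.na(variants$qual) | variants$qual >= min_qual) &
    (is.na(variants$depth) | variants$depth >= min_depth)
  log$n_low_quality <- sum(!keep)
  out <- variants[keep, , drop = FALSE]
  if (!is.null(regions)) {
    gr <- if (is.character(regions)) rtracklayer::import(regions) else regions
    if (!is(gr, "GRanges")) stop("regions must be a BED path or a GRanges")
    if (nrow(out) > 0) {
      vgr <- GenomicRanges::GRanges(out$contig,
                                    IRanges::IRanges(out$pos, out$pos))
      hit <- IRanges::overlapsAny(vgr, gr, ignore.strand = TRUE)
    } else hit <- logical(0)
    log$n_outside_regions <- sum(!hit)
    out <- out[hit, , drop = FALSE]
  }
  new_variant_set(out, log)
}

#' Extract the reference context window around a variant
#'
#' Returns the reference sequence `half_width` bases either side of the
#' position (41 nt for the default), truncated at contig ends.
#'
#' @param reference A DNAStringSet or FASTA path.
#' @param contig,pos Variant location (1-based).
#' @param half_width Bases either side of the focal position.
#' @return A list with `seq` (character), `focal_offset` (0-based offset of
#'   the focal base within `seq`) and `start` (1-based window start).
#' @export
extract_window <- function(reference, contig, pos, half_width = 20) {
  reference <- as_reference(reference)
  if (!contig %in% names(reference))
    stop("contig absent from reference: ", contig)
  len <- Biostrings::width(reference[contig])
  start <- max(1L, pos - half_width)
  end <- min(len, pos + half_width)
  list(seq = as.character(Biostrings::subseq(reference[[contig]], start, end)),
       focal_offset = pos - start, start = start)
}

extract_windows <- function(variants, reference, half_width = 20) {
  n <- nrow(variants)
  seqs <- character(n); offs <- integer(n)
  for (ct in unique(variants$contig)) {
    if (!ct %in% names(reference)) stop("contig absent from reference: ", ct)
    i <- which(variants$contig == ct)
    s <- as.character(reference[[ct]])
    len <- nchar(s)
    start <- pmax(1L, variants$pos[i] - half_width)
    end <- pmin(len, variants$pos[i] + half_width)
    seqs[i] <- substring(s, start, end)
    offs[i] <- variants$pos[i] - start
  }
  list(seq = seqs, focal_offset = offs)
}

fold_pair <- function(ref, alt) {
  flip <- !ref %in% PYRIMIDINES
  paste0(ifelse(flip, DNA_COMPLEMENT[ref], ref), ">",
         ifelse(flip, DNA_COMPLEMENT[alt], alt))
}

count_letters <- function(windows, letters) {
  if (length(windows) == 0) return(0L)
  sum(vapply(letters, function(b)
    sum(nchar(windows) - nchar(gsub(b, "", windows, fixed = TRUE))),
    numeric(1)))
}

count_3mers <- function(windows) {
  if (length(windows) == 0) return(table(character(0)))
  mers <- unlist(lapply(windows, function(w) {
    n <- nchar(w)
    if (n < 3) return(character(0))
    substring(w, 1:(n - 2), 3:n)
  }))
  table(mers)
}

#' Tally per-channel mutation and context counts
#'
#' Builds, from a sample's variants and their 41-nt reference windows, the
#' four counts that enter the per-channel enrichment: `mut_m` (variants
#' matching channel m or its reverse complement), `con_m` (occurrences of
#' m's trinucleotide motif, plus its reverse complement, in the reference
#' windows of m's substitution class), and the class totals `mut_b` / `con_b`
#' (variants of the same folded substitution pair, and occurrences of the
#' reference base plus its complement, over those same windows). Counts are
#' aggregated over all of the sample's windows before any ratio is formed.
#'
#' @param variants A `variant_set` (after filtering).
#' @param reference A DNAStringSet or FASTA path.
#' @param signature A `uv_signature` defining the channel universe.
#' @param half_width Window half-width (default 20, i.e. 41-nt windows).
#' @return A `channel_counts`: data.frame with one row per signature channel
#'   (`key`, `ctx5`, `ref`, `alt`, `ctx3`, `pair`, `mut_m`, `con_m`, `mut_b`,
#'   `con_b`); attributes record the number of variants used and any records
#'   excluded for lacking a flanking base.
#' @export
tally_channel_counts <- function(variants, reference, signature,
                                 half_width = 20) {
  reference <- as_reference(reference)
  chan <- data.frame(ctx5 = signature$ctx5, ref = signature$ref,
                     alt = signature$alt, ctx3 = signature$ctx3,
                     key = signature$key, stringsAsFactors = FALSE)
  folded <- classify_channel(chan$ref, chan$alt, chan$ctx5, chan$ctx3)
  chan$pair <- paste0(folded$ref, ">", folded$alt)
  chan$folded_motif <- paste0(folded$ctx5, folded$ref, folded$ctx3)
  chan$folded_key <- folded$key

  n <- nrow(variants)
  if (n > 0) {
    win <- extract_windows(variants, reference, half_width)
    focal <- substring(win$seq, win$focal_offset + 1, win$focal_offset + 1)
    if (any(focal != variants$ref))
      stop("window focal base disagrees with variant ref allele")
    has_flanks <- win$focal_offset >= 1 &
      win$focal_offset + 2 <= nchar(win$seq)
    n_edge <- sum(!has_flanks)
    v <- variants[has_flanks, , drop = FALSE]
    wseq <- win$seq[has_flanks]
    off <- win$focal_offset[has_flanks]
    ctx5 <- substring(wseq, off, off)
    ctx3 <- substring(wseq, off + 2, off + 2)
    vchan <- classify_channel(v$ref, v$alt, ctx5, ctx3)
    vpair <- paste0(vchan$ref, ">", vchan$alt)
  } else {
    n_edge <- 0L
    vchan <- data.frame(key = character(0))
    vpair <- character(0)
    wseq <- character(0)
  }

  mut_m <- con_m <- mut_b <- con_b <- numeric(nrow(chan))
  for (b in FOLDED_PAIRS) {
    rows <- chan$pair == b
    in_class <- vpair == b
    wins_b <- wseq[in_class]
    base <- substr(b, 1, 1)
    mut_b[rows] <- sum(in_class)
    con_b[rows] <- count_letters(wins_b, c(base, DNA_COMPLEMENT[[base]]))
    tab <- count_3mers(wins_b)
    motifs <- chan$folded_motif[rows]
    cm <- as.numeric(tab[motifs]) ; cm[is.na(cm)] <- 0
    cr <- as.numeric(tab[revcomp_chr(motifs)]) ; cr[is.na(cr)] <- 0
    con_m[rows] <- cm + cr
    mut_m[rows] <- vapply(chan$folded_key[rows],
                          function(k) sum(vchan$key[in_class] == k),
                          numeric(1))
  }
  out <- data.frame(key = chan$key, ctx5 = chan$ctx5, ref = chan$ref,
                    alt = chan$alt, ctx3 = chan$ctx3, pair = chan$pair,
                    mut_m = mut_m, con_m = con_m, mut_b = mut_b,
                    con_b = con_b, stringsAsFactors = FALSE)
  structure(out, class = c("channel_counts", "data.frame"),
            n_variants_used = if (n > 0) nrow(v) else 0L,
            n_excluded_edge = n_edge)
}

#' Per-channel context enrichment
#'
#' The fold-excess of channel-m mutations relative to the availability of
#' m's context motif, normalized by the same ratio over all mutations of the
#' channel's substitution class:
#' `E_m = (mut_m * con_b) / (mut_b * con_m)`.
#' Degenerate denominators (no class mutations, or motif absent from the
#' windows) yield `E_m = 0`, the conservative choice for short panels.
#'
#' @param counts A `channel_counts`.
#' @param channel Optional channel key; if given, the scalar `E` for that
#'   channel is returned.
#' @return Numeric vector of enrichments (named by channel key), or a scalar
#'   if `channel` is given.
#' @export
channel_enrichment <- function(counts, channel = NULL) {
  stopifnot(inherits(counts, "channel_counts"))
  e <- with(counts, ifelse(mut_b == 0 | con_m == 0, 0,
                           (mut_m * con_b) / (mut_b * con_m)))
  names(e) <- counts$key
  if (!is.null(channel)) {
    if (!channel %in% counts$key) stop("unknown channel: ", channel)
    return(unname(e[channel]))
  }
  e
}

#' Signature enrichment score (UVMSE when used with the UV signature)
#'
#' Weights every channel's context enrichment by the channel's signature
#' probability and sums over the whole signature:
#' `score = sum_m p_m * E_m`. Under context-independent mutagenesis every
#' `E_m` is ~1 and the score is ~1; signature-driven mutagenesis inflates the
#' heavily weighted channels.
#'
#' @param counts A `channel_counts`.
#' @param signature The `uv_signature` supplying the weights.
#' @return An `enrichment_result`: list with `score`, `per_channel`
#'   (data.frame of `key`, `p`, `e` and the product), `n_variants_used` and
#'   `degenerate_channels` (keys whose enrichment was undefined and counted
#'   as 0).
#' @export
signature_enrichment <- function(counts, signature) {
  stopifnot(inherits(counts, "channel_counts"))
  e <- channel_enrichment(counts)
  p <- setNames(signature$prob, signature$key)[counts$key]
  degenerate <- counts$key[counts$con_m == 0 | counts$mut_b == 0]
  per <- data.frame(key = counts$key, p = unname(p), e = unname(e),
                    contribution = unname(p * e), stringsAsFactors = FALSE)
  structure(list(score = sum(per$contribution), per_channel = per,
                 n_variants_used = attr(counts, "n_variants_used"),
                 degenerate_channels = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("signature enrichment score: %.4f (%d variants, %d degenerate channels)\n",
              x$score, x$n_variants_used, length(x$degenerate_channels)))
  invisible(x)
}

#' Compute the UVMSE score for a variant file
#'
#' End-to-end wrapper: read variants, apply the quality/depth/region
#' filters, tally channel counts over 41-nt context windows and return the
#' probability-weighted enrichment score.
#'
#' @param path VCF or MAF file (or an already-read `variant_set`).
#' @param reference A DNAStringSet or FASTA path.
#' @param signature A `uv_signature` (bundled UV signature by default).
#' @param min_qual,min_depth,regions Passed to [filter_variants()].
#' @param half_width Context window half-width.
#' @return An `enrichment_result` (see [signature_enrichment()]) with an
#'   added `weighted_load` element (`n_variants_used * score`) and the filter
#'   `log`.
#' @export
uvmse_score <- function(path, reference, signature = load_signature(),
                        min_qual = 50, min_depth = 100, regions = NULL,
                        half_width = 20) {
  reference <- as_reference(reference)
  variants <- if (inherits(path, "variant_set")) path
              else read_variants(path, reference)
  variants <- filter_variants(variants, min_qual, min_depth, regions)
  counts <- tally_channel_counts(variants, reference, signature, half_width)
  res <- signature_enrichment(counts, signature)
  res$weighted_load <- weighted_uv_load(res$n_variants_used, res$score)
  res$log <- attr(variants, "log")
  res
}

#' UV-weighted mutation load
#'
#' The sample's mutation count multiplied by its enrichment score, used as a
#' proxy for the number of UV-induced mutations.
#'
#' @param n_mutations Number of (filtered) mutations, >= 0.
#' @param uvmse The sample's enrichment score.
#' @return `n_mutations * uvmse`.
#' @export
weighted_uv_load <- function(n_mutations, uvmse) {
  if (any(n_mutations < 0)) stop("n_mutations must be >= 0")
  n_mutations * uvmse
}
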