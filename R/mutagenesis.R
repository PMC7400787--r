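#' @importFrom Matrix sparseMatrix rowSums crossprod
#' @importFrom stats wilcox.test median quantile sd qt
NULL

all_stretches <- function(stretch_length = 6) {
  sort(do.call(paste0,
    expand.grid(rep(list(DNA_BASES), stretch_length),
                stringsAsFactors = FALSE)[, stretch_length:1]))
}

codon_slots <- function(stretch_length) {
  if (stretch_length == 6) list(c(1, 3), c(4, 6))
  else if (stretch_length == 5) list(c(2, 4))
  else stop("stretch_length must be 5 or 6")
}

translate_stretch <- function(stretches, stretch_length = 6) {
  gc <- Biostrings::GENETIC_CODE
  slots <- codon_slots(stretch_length)
  vapply(slots, function(sl)
    unname(gc[substr(stretches, sl[1], sl[2])]), character(length(stretches)))
}

stretch_hydropathy <- function(stretches, scale, stretch_length = 6) {
  aa <- translate_stretch(stretches, stretch_length)
  if (is.null(dim(aa))) aa <- matrix(aa, ncol = 1)
  rowSums(matrix(scale[aa], nrow = nrow(aa)))
}

#' Initialize the stretch probability distribution
#'
#' Enumerates all nucleotide stretches of the requested length and assigns
#' each its prior probability under a codon-usage model. For 6-nucleotide
#' stretches (two in-frame codons) the prior is the product of the two codon
#' frequencies; for the 5-nucleotide reduction (one codon with one flanking
#' base on each side) it is the codon frequency times a uniform 1/16 over the
#' flanks.
#'
#' @param codon_usage A `codon_usage` table.
#' @param stretch_length 6 (default) or 5.
#' @return A `stretch_distribution`: list with `stretches` (character),
#'   `mass` (probabilities summing to 1), `iteration` and `stretch_length`.
#' @export
init_stretch_distribution <- function(codon_usage = load_codon_usage(),
                                      stretch_length = 6) {
  stopifnot(inherits(codon_usage, "codon_usage"))
  stretches <- all_stretches(stretch_length)
  slots <- codon_slots(stretch_length)
  mass <- rep(1, length(stretches))
  for (sl in slots)
    mass <- mass * unname(codon_usage[substr(stretches, sl[1], sl[2])])
  n_flank <- stretch_length - sum(vapply(slots, function(s) s[2] - s[1] + 1,
                                         numeric(1)))
  mass <- mass / 4^n_flank
  mass <- mass / sum(mass)   # exact unit mass despite rounding
  structure(list(stretches = stretches, mass = mass, iteration = 0L,
                 stretch_length = stretch_length),
            class = "stretch_distribution")
}

#' Enumerate all single-base mutants of every stretch
#'
#' Every position that has both flanking bases inside the stretch (positions
#' 2 to L-1) is substituted by each of the three alternative bases; terminal
#' positions are never mutated because the signature needs both flanks. For
#' 6-nucleotide stretches this yields 4096 x 4 x 3 = 49,152 records.
#'
#' @param stretch_length 6 (default) or 5.
#' @return A data.frame with columns `stretch`, `position`, `ref`, `alt`,
#'   `mutant`.
#' @export
enumerate_single_mutants <- function(stretch_length = 6) {
  stretches <- all_stretches(stretch_length)
  pos <- 2:(stretch_length - 1)
  g <- expand.grid(stretch = stretches, position = pos, alt = DNA_BASES,
                   stringsAsFactors = FALSE)
  g$ref <- substr(g$stretch, g$position, g$position)
  g <- g[g$ref != g$alt, ]
  g$mutant <- paste0(substr(g$stretch, 1, g$position - 1), g$alt,
                     substr(g$stretch, g$position + 1, stretch_length))
  g <- g[order(g$stretch, g$position, g$alt),
         c("stretch", "position", "ref", "alt", "mutant")]
  rownames(g) <- NULL
  g
}

#' Signature probability of a specific substitution within a stretch
#'
#' Looks up the signature channel defined by the stretch position's flanking
#' bases. With `include_reciprocal = TRUE` the complement-strand channel is
#' credited as well (a lesion on the reciprocal strand producing the same
#' observed change), doubling the channel universe applied per stretch.
#'
#' @param stretch Stretch sequence(s).
#' @param position Mutated position(s), each with both flanks in the stretch.
#' @param alt Alternate base(s).
#' @param signature A `uv_signature`.
#' @param include_reciprocal Credit the reciprocal-strand channel too.
#' @return Numeric vector of per-opportunity substitution probabilities.
#' @export
mutation_probability <- function(stretch, position, alt, signature,
                                 include_reciprocal = FALSE) {
  n <- max(length(stretch), length(position), length(alt))
  stretch <- rep_len(stretch, n); position <- rep_len(position, n)
  alt <- rep_len(alt, n)
  if (any(position < 2 | position > nchar(stretch) - 1))
    stop("position must have both flanking bases within the stretch")
  ctx5 <- substr(stretch, position - 1, position - 1)
  ref <- substr(stretch, position, position)
  ctx3 <- substr(stretch, position + 1, position + 1)
  q <- signature_probability(signature, ctx5, ref, alt, ctx3)
  if (include_reciprocal)
    q <- q + signature_probability(signature,
                                   DNA_COMPLEMENT[ctx3], DNA_COMPLEMENT[ref],
                                   DNA_COMPLEMENT[alt], DNA_COMPLEMENT[ctx5])
  q
}

# Precomputed sparse transition machinery shared by iterations.
build_transitions <- function(signature, include_reciprocal = FALSE,
                              stretch_length = 6) {
  mut <- enumerate_single_mutants(stretch_length)
  stretches <- all_stretches(stretch_length)
  idx <- setNames(seq_along(stretches), stretches)
  q <- mutation_probability(mut$stretch, mut$position, mut$alt, signature,
                            include_reciprocal)
  src <- unname(idx[mut$stretch])
  dst <- unname(idx[mut$mutant])
  Q <- Matrix::sparseMatrix(i = src, j = dst, x = q,
                            dims = rep(length(stretches), 2))
  outflow <- Matrix::rowSums(Q)
  if (any(outflow > 1 + 1e-12))
    stop("signature is not interpretable as per-opportunity rates: ",
         "total substitution probability exceeds 1 for stretch ",
         stretches[which.max(outflow)])
  list(Q = Q, outflow = outflow, stretches = stretches)
}

#' Apply one iteration of in-silico UV mutagenesis
#'
#' For each stretch s and each of its single-base mutants m, probability mass
#' `mass(s) * q(s -> m)` moves from s to m, where q is the signature
#' probability of the corresponding channel; unselected mass stays on s.
#' Total mass is conserved exactly. The returned hydropathy delta is
#' `sum_s mass(s) * sum_m q(s -> m) * (AU(m) - AU(s))`.
#'
#' @param dist A `stretch_distribution`.
#' @param signature A `uv_signature`.
#' @param scale A `hydropathy_scale` used for the reported delta.
#' @param include_reciprocal Credit reciprocal-strand channels.
#' @param transitions Optional precomputed transition object (internal reuse).
#' @return A list with `dist` (the advanced distribution) and `delta`
#'   (hydropathy change in AU for this iteration).
#' @export
apply_iteration <- function(dist, signature, scale = load_hydropathy_scale(),
                            include_reciprocal = FALSE, transitions = NULL) {
  stopifnot(inherits(dist, "stretch_distribution"))
  if (is.null(transitions))
    transitions <- build_transitions(signature, include_reciprocal,
                                     dist$stretch_length)
  au <- stretch_hydropathy(dist$stretches, scale, dist$stretch_length)
  m <- dist$mass
  inflow <- as.numeric(Matrix::crossprod(transitions$Q, m))
  new_mass <- m - m * transitions$outflow + inflow
  new_au <- sum(new_mass * au)
  delta <- new_au - sum(m * au)
  dist$mass <- new_mass
  dist$iteration <- dist$iteration + 1L
  list(dist = dist, delta = delta)
}

#' Run the iterative UV mutagenesis simulation
#'
#' Evolves the stretch distribution for `n_iterations` cycles of probabilistic
#' single-base mutagenesis (one substitution opportunity per stretch per
#' cycle; each cycle corresponds to one dose of UV exposure) and reports, per
#' iteration, the expected exome hydropathy, its change, the probability mass
#' on stop-codon-containing stretches and its gain relative to baseline. The
#' computation is deterministic.
#'
#' @param n_iterations Number of mutagenesis cycles (>= 0).
#' @param codon_usage,signature,scale The model tables (bundled defaults).
#' @param include_reciprocal Credit reciprocal-strand channels (default off).
#' @param stretch_length 6 (default) or 5.
#' @return A `mutagenesis_report`: data.frame with columns `iteration`,
#'   `hydropathy` (expected AU), `delta`, `stop_mass`, `stop_gain_pct`
#'   (percent vs iteration 0), with attributes `census` (list of per-iteration
#'   amino-acid frequency matrices), `stretch_table` (per-stretch
#'   mass-weighted before/after AU values for the first iteration, when
#'   `n_iterations >= 1`), `final_dist` and `options`.
#' @export
run_uv_simulation <- function(n_iterations, codon_usage = load_codon_usage(),
                              signature = load_signature(),
                              scale = load_hydropathy_scale(),
                              include_reciprocal = FALSE, stretch_length = 6) {
  stopifnot(n_iterations >= 0)
  dist <- init_stretch_distribution(codon_usage, stretch_length)
  au <- stretch_hydropathy(dist$stretches, scale, stretch_length)
  aa <- translate_stretch(dist$stretches, stretch_length)
  if (is.null(dim(aa))) aa <- matrix(aa, ncol = 1)
  stop_count <- rowSums(aa == "*")
  transitions <- build_transitions(signature, include_reciprocal,
                                   stretch_length)
  n <- n_iterations
  hydropathy <- delta <- stop_mass <- numeric(n + 1)
  census <- vector("list", n + 1)
  hydropathy[1] <- sum(dist$mass * au)
  stop_mass[1] <- sum(dist$mass * stop_count)
  census[[1]] <- amino_acid_census(dist)
  stretch_table <- NULL
  for (it in seq_len(n)) {
    before_mass <- dist$mass
    step <- apply_iteration(dist, signature, scale, include_reciprocal,
                            transitions)
    dist <- step$dist
    delta[it + 1] <- step$delta
    hydropathy[it + 1] <- sum(dist$mass * au)
    stop_mass[it + 1] <- sum(dist$mass * stop_count)
    census[[it + 1]] <- amino_acid_census(dist)
    if (it == 1) {
      # per-stretch after value: residual mass keeps AU(s), outgoing mass
      # carries the mutant AUs, attributed back to the source stretch so the
      # before/after pairs stay comparable
      before <- before_mass * au
      after <- (before_mass - before_mass * transitions$outflow) * au +
        flow_au(transitions, before_mass, au)
      stretch_table <- data.frame(stretch = dist$stretches,
                                  mass = before_mass, au = au,
                                  before = before, after = after)
    }
  }
  report <- data.frame(iteration = 0:n, hydropathy = hydropathy,
                       delta = delta, stop_mass = stop_mass,
                       stop_gain_pct = 100 * (stop_mass / stop_mass[1] - 1))
  structure(report,
            class = c("mutagenesis_report", "data.frame"),
            census = census, stretch_table = stretch_table,
            final_dist = dist,
            options = list(include_reciprocal = include_reciprocal,
                           stretch_length = stretch_length))
}

# AU carried into each destination stretch by incoming flows, attributed back
# to the source stretch so per-stretch before/after pairs stay comparable:
# after(s) = residual mass on s times AU(s) + sum over mutants m of
#            mass(s) q(s->m) AU(m).
flow_au <- function(transitions, mass, au) {
  as.numeric(transitions$Q %*% au) * mass
}

#' Amino-acid census of a stretch distribution
#'
#' Mass-weighted frequency of each amino acid (plus stop) encoded at each
#' codon slot of the stretches. Frequencies sum to 1 per slot.
#'
#' @param dist A `stretch_distribution`.
#' @return A numeric matrix, 21 rows (20 residues + `*`) by one column per
#'   codon slot; attribute `pseudo_count` carries the same numbers scaled by
#'   the number of stretches.
#' @export
amino_acid_census <- function(dist) {
  stopifnot(inherits(dist, "stretch_distribution"))
  aa <- translate_stretch(dist$stretches, dist$stretch_length)
  if (is.null(dim(aa))) aa <- matrix(aa, ncol = 1)
  residues <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  out <- vapply(seq_len(ncol(aa)), function(j) {
    v <- vapply(residues, function(r) sum(dist$mass[aa[, j] == r]),
                numeric(1))
    v / sum(v)
  }, numeric(length(residues)))
  out <- matrix(out, nrow = length(residues),
                dimnames = list(residues,
                                paste0("slot", seq_len(ncol(aa)))))
  attr(out, "pseudo_count") <- out * length(dist$stretches)
  out
}

#' Summary statistics for one mutagenesis iteration
#'
#' Location and spread of the per-stretch mass-weighted hydropathies before
#' and after the first iteration of mutagenesis, plus their paired difference
#' and a Wilcoxon signed-rank test, in the layout conventional for reporting
#' the hexamer simulation.
#'
#' @param report A `mutagenesis_report` from a run with at least 1 iteration.
#' @param conf_level Confidence level for the mean's interval.
#' @return A data.frame with one row per statistic (n, median, quartiles,
#'   mean, sd, se, CI bounds, sum) and columns `before`, `after`, `diff`;
#'   attribute `wilcoxon_p` holds the paired signed-rank p-value.
#' @export
iteration_summary <- function(report, conf_level = 0.95) {
  tab <- attr(report, "stretch_table")
  if (is.null(tab))
    stop("report has no per-stretch table; run with n_iterations >= 1")
  cols <- list(before = tab$before, after = tab$after,
               diff = tab$after - tab$before)
  stat <- function(x) {
    n <- length(x)
    se <- sd(x) / sqrt(n)
    tq <- qt(1 - (1 - conf_level) / 2, n - 1)
    c(n = n, median = median(x), q25 = unname(quantile(x, 0.25)),
      q75 = unname(quantile(x, 0.75)), mean = mean(x), sd = sd(x), se = se,
      ci_lower = mean(x) - tq * se, ci_upper = mean(x) + tq * se, sum = sum(x))
  }
  out <- data.frame(lapply(cols, stat))
  w <- wilcox.test(tab$after, tab$before, paired = TRUE, exact = FALSE)
  attr(out, "wilcoxon_p") <- w$p.value
  out
}
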