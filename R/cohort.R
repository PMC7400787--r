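#' @importFrom stats fisher.test pchisq qnorm
#' @importFrom survival Surv survfit survdiff
NULL

#' Categorize tumor mutational burden
#'
#' Standard clinical categories: low (1-5 mutations/Mb; values below 1 are
#' folded into low), intermediate (6-19) and high (>= 20).
#'
#' @param tmb Mutations per megabase, >= 0.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
tmb_category <- function(tmb) {
  if (any(tmb < 0, na.rm = TRUE)) stop("tmb must be >= 0")
  cut(tmb, breaks = c(-Inf, 5.5, 19.5, Inf),
      labels = c("low", "intermediate", "high"))
}

#' Optimal dichotomization threshold from the ROC curve
#'
#' Selects the score threshold maximizing Youden's J statistic
#' (sensitivity + specificity - 1) for discriminating a binary outcome,
#' with higher scores taken as the positive direction. For perfectly
#' separated groups the midpoint of the gap is returned. Dichotomization
#' downstream uses `score >= threshold` as the high group.
#'
#' @param scores Numeric scores.
#' @param outcome Binary outcome (logical, 0/1, or two-level factor).
#' @return The threshold (numeric scalar), with attributes `sensitivity` and
#'   `specificity` at the threshold.
#' @export
roc_threshold <- function(scores, outcome) {
  outcome <- as.factor(outcome)
  if (nlevels(droplevels(outcome)) != 2)
    stop("outcome must contain exactly two classes")
  r <- pROC::roc(response = outcome, predictor = scores, quiet = TRUE,
                 direction = "<", levels = levels(droplevels(outcome)))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, ]   # first optimum on ties
  structure(best$threshold, sensitivity = best$sensitivity,
            specificity = best$specificity)
}

#' Fisher's exact association for a 2x2 response table
#'
#' Reports the cross-product odds ratio `(a*d)/(b*c)`, its 95% CI from the
#' log-OR normal approximation, and the two-sided exact p-value. A table
#' with a zero cell gets the Haldane-Anscombe 0.5 continuity correction for
#' the OR and CI (noted in the result); the exact p needs no correction.
#'
#' @param a,b,c,d Cell counts: `a` = responders in group 1, `b` =
#'   non-responders in group 1, `c` = responders in group 2, `d` =
#'   non-responders in group 2. Alternatively `a` may be a 2x2 matrix.
#' @param conf_level Confidence level.
#' @return List with `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `table` and `continuity` (whether the correction was applied).
#' @export
fisher_odds_ratio <- function(a, b = NULL, c = NULL, d = NULL,
                              conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    tab <- a
  } else tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  p <- fisher.test(tab)$p.value
  cont <- any(tab == 0)
  tt <- if (cont) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[2, 1] * tt[1, 2])
  se <- sqrt(sum(1 / tt))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = or,
       ci_lower = exp(log(or) - z * se),
       ci_upper = exp(log(or) + z * se),
       p_value = p, table = tab, continuity = cont)
}

#' Kaplan-Meier medians and log-rank test
#'
#' Product-limit median survival per group (NA when the curve never crosses
#' 0.5, i.e. the median is not reached) and the two-sided Mantel-Cox
#' log-rank p-value.
#'
#' @param times Follow-up times (months), >= 0.
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param groups Group labels.
#' @return List with `medians` (named numeric; NA = not reached),
#'   `p_value`, `n_events` and the `survfit` object.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times < 0)) stop("times must be >= 0")
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(droplevels(groups)) < 2)
    stop("need at least two non-empty groups")
  events <- as.integer(as.logical(events))
  if (sum(events) < 1) stop("need at least one event")
  fit <- survfit(Surv(times, events) ~ groups)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  medians <- setNames(tab[, "median"],
                      sub("^groups=", "", rownames(tab)))
  sd_ <- survdiff(Surv(times, events) ~ groups)
  p <- pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  list(medians = medians, p_value = p, n_events = sum(events), fit = fit)
}

#' Read a cohort outcome table
#'
#' TSV with columns `id`, `uvmse`, `tmb`, `response` (CR/PR/SD/PD),
#' `pfs_months`, `pfs_event`, `os_months`, `os_event` and optional
#' covariates.
#'
#' @param path TSV path.
#' @return The validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  cohort <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "uvmse", "tmb", "response", "pfs_months", "pfs_event",
            "os_months", "os_event")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0)
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(cohort$response %in% c("CR", "PR", "SD", "PD")))
    stop("response must be one of CR, PR, SD, PD")
  if (any(cohort$tmb < 0) || any(cohort$pfs_months < 0) ||
      any(cohort$os_months < 0))
    stop("tmb and survival times must be >= 0")
  cohort
}

#' UV-stratified outcome report by TMB category
#'
#' Dichotomizes patients into UV-high (`uvmse >= threshold`) versus UV-low
#' and, separately within the pooled low/intermediate-TMB stratum and the
#' high-TMB stratum, computes the response odds ratio (responder = CR/PR)
#' and the PFS and OS log-rank comparisons between the UV groups.
#'
#' @param cohort A cohort data.frame (see [read_cohort()]).
#' @param threshold UVMSE dichotomization threshold (`NULL` selects it from
#'   the ROC curve against response via [roc_threshold()]).
#' @return A `stratified_report`: list with `threshold` and one block per
#'   stratum, each holding `n`, the 2x2 `response` statistics and the `pfs` /
#'   `os` log-rank results (a stratum with fewer than 2 patients or a single
#'   UV group is reported with a `note` instead).
#' @export
stratified_report <- function(cohort, threshold = NULL) {
  responder <- cohort$response %in% c("CR", "PR")
  if (is.null(threshold))
    threshold <- as.numeric(roc_threshold(cohort$uvmse, responder))
  uv_high <- cohort$uvmse >= threshold
  if (all(uv_high) || all(!uv_high))
    warning("threshold leaves a single UV group; report is degenerate")
  strata <- ifelse(tmb_category(cohort$tmb) == "high",
                   "high", "low_intermediate")
  blocks <- lapply(c("low_intermediate", "high"), function(st) {
    i <- strata == st
    if (sum(i) < 2)
      return(list(stratum = st, n = sum(i),
                  note = "fewer than 2 patients; skipped"))
    uh <- uv_high[i]; rs <- responder[i]
    if (all(uh) || all(!uh))
      return(list(stratum = st, n = sum(i),
                  note = "single UV group in stratum; skipped"))
    resp <- fisher_odds_ratio(sum(rs & uh), sum(!rs & uh),
                              sum(rs & !uh), sum(!rs & !uh))
    grp <- ifelse(uh, "uv_high", "uv_low")
    pfs <- tryCatch(km_logrank(cohort$pfs_months[i], cohort$pfs_event[i],
                               grp),
                    error = function(e) list(note = conditionMessage(e)))
    os <- tryCatch(km_logrank(cohort$os_months[i], cohort$os_event[i], grp),
                   error = function(e) list(note = conditionMessage(e)))
    list(stratum = st, n = sum(i),
         n_uv_high = sum(uh), n_uv_low = sum(!uh),
         response = resp, pfs = pfs, os = os)
  })
  names(blocks) <- c("low_intermediate", "high")
  structure(c(list(threshold = threshold), blocks),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat(sprintf("UV dichotomization threshold: %.4f\n", x$threshold))
  for (st in c("low_intermediate", "high")) {
    b <- x[[st]]
    cat(sprintf("-- TMB %s (n = %d)\n", b$stratum, b$n))
    if (!is.null(b$note)) { cat("   ", b$note, "\n"); next }
    cat(sprintf("   response OR %.2f (%.2f-%.2f), p = %.4f\n",
                b$response$odds_ratio, b$response$ci_lower,
                b$response$ci_upper, b$response$p_value))
    if (is.null(b$pfs$note))
      cat(sprintf("   PFS log-rank p = %.4f\n", b$pfs$p_value))
    if (is.null(b$os$note))
      cat(sprintf("   OS log-rank p = %.4f\n", b$os$p_value))
  }
  invisible(x)
}
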