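test_that("TMB categories use the clinical bounds", {
  expect_identical(as.character(tmb_category(c(0, 1, 5, 6, 19, 20, 55))),
                   c("low", "low", "low", "intermediate", "intermediate",
                     "high", "high"))
  expect_error(tmb_category(-1), ">= 0")
})

test_that("ROC threshold maximizes Youden's J", {
  # perfectly separated: midpoint of the gap
  scores <- c(1, 2, 3, 10, 11, 12)
  outcome <- c(0, 0, 0, 1, 1, 1)
  th <- roc_threshold(scores, outcome)
  expect_equal(as.numeric(th), 6.5)
  expect_equal(attr(th, "sensitivity"), 1)
  expect_equal(attr(th, "specificity"), 1)

  # overlapping toy: exhaustive sweep oracle over candidate cut points
  set.seed(3)
  s2 <- c(rnorm(40, 0, 1), rnorm(40, 1.2, 1))
  o2 <- rep(c(0, 1), each = 40)
  th2 <- as.numeric(roc_threshold(s2, o2))
  youden <- function(t) mean(s2[o2 == 1] >= t) + mean(s2[o2 == 0] < t) - 1
  cand <- sort(unique(s2))
  best_j <- max(vapply(cand, youden, numeric(1)))
  expect_equal(youden(th2), best_j, tolerance = 1e-12)

  # invariant to monotone transformation (same dichotomization)
  th3 <- as.numeric(roc_threshold(exp(s2), o2))
  expect_identical(exp(s2) >= th3, s2 >= th2)

  expect_error(roc_threshold(1:5, rep(1, 5)), "two classes")
})

test_that("the odds ratio reproduces the printed 2x2 statistics", {
  # 10/22 responders UV-high vs 13/91 UV-low
  r1 <- fisher_odds_ratio(10, 12, 13, 78)
  expect_equal(round(r1$odds_ratio, 1), 5.0)
  expect_equal(round(r1$ci_lower, 1), 1.8)
  expect_equal(round(r1$ci_upper, 1), 13.9)
  expect_equal(round(r1$p_value, 4), 0.0026)

  # 14/24 vs 8/14: cross-product 84/80 = 1.05, printed as 1.1 at 1 d.p.
  r2 <- fisher_odds_ratio(14, 10, 8, 6)
  expect_equal(r2$odds_ratio, 1.05)
  expect_lte(abs(r2$odds_ratio - 1.1), 0.05 + 1e-9)
  expect_equal(round(r2$ci_lower, 1), 0.3)
  expect_equal(round(r2$ci_upper, 1), 4.0)
  expect_equal(round(r2$p_value, 4), 1)

  r3 <- fisher_odds_ratio(1, 1, 1, 1)
  expect_equal(r3$odds_ratio, 1)

  r4 <- fisher_odds_ratio(3, 0, 1, 4)
  expect_true(r4$continuity)
  expect_error(fisher_odds_ratio(1.5, 1, 1, 1), "integers")
})

test_that("exact p-values match a hypergeometric enumeration oracle", {
  # two-sided Fisher p: sum of probabilities of tables as or less likely
  fisher_oracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:10) {
    cells <- as.integer(sample(0:8, 4, replace = TRUE))
    r <- fisher_odds_ratio(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$p_value,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("Kaplan-Meier medians and log-rank match hand computation", {
  # 6 subjects: group A events at 2, 4, 6; group B event 5, censor 8, event 10
  tm <- c(2, 4, 6, 5, 8, 10)
  ev <- c(1, 1, 1, 1, 0, 1)
  gr <- rep(c("A", "B"), each = 3)
  km <- km_logrank(tm, ev, gr)
  # product-limit by hand: A drops 2/3, 1/3, 0 -> median 4;
  # B drops to 2/3 at t=5, to 0 at t=10 -> median 10
  expect_equal(unname(km$medians["A"]), 4)
  expect_equal(unname(km$medians["B"]), 10)

  # independent log-rank oracle: observed vs expected over event times
  logrank_oracle <- function(tm, ev, gr) {
    g <- unique(gr)
    o1 <- e1 <- v <- 0
    for (t in sort(unique(tm[ev == 1]))) {
      at_risk <- tm >= t
      n <- sum(at_risk); n1 <- sum(at_risk & gr == g[1])
      d <- sum(tm == t & ev == 1)
      d1 <- sum(tm == t & ev == 1 & gr == g[1])
      o1 <- o1 + d1
      e1 <- e1 + d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    pchisq((o1 - e1)^2 / v, df = 1, lower.tail = FALSE)
  }
  expect_equal(km$p_value, logrank_oracle(tm, ev, gr), tolerance = 1e-9)

  # identical groups: p = 1
  km2 <- km_logrank(rep(tm[1:3], 2), rep(ev[1:3], 2), rep(c("A", "B"), 3))
  expect_equal(km2$p_value, 1)

  # all-censored group: median not reached (NA)
  km3 <- km_logrank(c(1, 2, 3, 9, 9, 9), c(1, 1, 1, 0, 0, 0),
                    rep(c("A", "B"), each = 3))
  expect_true(is.na(km3$medians["B"]))
  expect_lt(km3$p_value, 0.2)

  # strongly separated toy
  km4 <- km_logrank(c(1, 1, 2, 2, 30, 30, 35, 40), rep(1, 8),
                    rep(c("A", "B"), each = 4))
  expect_lt(km4$p_value, 0.01)

  expect_error(km_logrank(1:3, c(0, 0, 0), c("A", "A", "B")), "event")
  expect_error(km_logrank(1:3, c(1, 1, 1), c("A", "A", "A")), "two non-empty")
})

test_that("the stratified report recovers a planted UV effect", {
  co <- synth_cohort(n = 400, seed = 17)
  rep <- stratified_report(co, threshold = 0.7917)
  li <- rep$low_intermediate
  expect_gt(li$response$odds_ratio, 1)
  expect_lt(li$response$p_value, 0.05)
  expect_lt(li$pfs$p_value, 0.05)
  # UV-high lives longer where the effect is planted
  expect_gt(li$pfs$medians[["uv_high"]], li$pfs$medians[["uv_low"]])
  # no planted effect in the high-TMB stratum: CI covers 1
  hi <- rep$high
  expect_true(hi$response$ci_lower < 1 && hi$response$ci_upper > 1)
})

test_that("degenerate thresholds are reported, not crashed", {
  co <- synth_cohort(n = 60, seed = 23)
  expect_warning(rep <- stratified_report(co, threshold = 99), "single UV")
  expect_match(rep$low_intermediate$note, "single UV group")
})

test_that("cohort tables round-trip through the reader with validation", {
  co <- synth_cohort(n = 40, seed = 29)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(co, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cohort(path)
  expect_equal(back$uvmse, co$uvmse)
  bad <- co; bad$response[1] <- "XX"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(path2), "response")
})
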