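test_that("rank-sum CP estimator: worked examples, tie rule, and oracle equivalence", {
  e <- estimate_cp(c(2, 4, 6), c(1, 4, 5), min_total = 6, min_per_choice = 3)
  expect_equal(e$cp, 5.5 / 9, tolerance = 1e-12)
  e2 <- estimate_cp(c(3, 5, 5, 8), c(3, 5, 5, 8), min_total = 8)
  expect_equal(e2$cp, 0.5)
  e3 <- estimate_cp(c(5, 6, 7, 8), c(1, 2, 3, 4), min_total = 8)
  expect_equal(e3$cp, 1)
  set.seed(41)
  for (rep in 1:20) {
    x <- rpois(sample(8:30, 1), 10)
    y <- rpois(sample(8:30, 1), 12)
    est <- estimate_cp(x, y, min_total = 10)
    w <- suppressWarnings(wilcox.test(x, y))  # W / (n1 n2) is the same AUC
    expect_equal(est$cp, unname(w$statistic) / (length(x) * length(y)),
                 tolerance = 1e-12)
  }
})

test_that("CP estimator invariances: monotone transforms and group swap", {
  set.seed(43)
  x <- rpois(20, 9); y <- rpois(25, 11)
  base <- estimate_cp(x, y)$cp
  expect_equal(estimate_cp(exp(x / 3), exp(y / 3))$cp, base)
  expect_equal(estimate_cp(3 * x + 2, 3 * y + 2)$cp, base)
  expect_equal(estimate_cp(y, x)$cp, 1 - base, tolerance = 1e-12)
})

test_that("inclusion criteria produce an exclusion sentinel, not an error", {
  e <- estimate_cp(rpois(3, 10), rpois(20, 10))
  expect_true(e$excluded)
  expect_match(e$reason, "for one choice")
  e2 <- estimate_cp(rpois(5, 10), rpois(5, 10))
  expect_true(e2$excluded)
  expect_match(e2$reason, "in total")
  expect_false(estimate_cp(rpois(8, 10), rpois(8, 10))$excluded)
})

test_that("CP standard error approximation", {
  expect_equal(cp_sem(30, 0.9), 0.1757, tolerance = 1e-3)
  expect_equal(round(cp_sem(30, 0.9), 2), 0.18)
  expect_equal(cp_sem(30, 0.5), 1 / sqrt(90), tolerance = 1e-12)
  expect_equal(cp_sem(120, 0.7), cp_sem(30, 0.7) / 2, tolerance = 1e-12)
  expect_error(cp_sem(30, 1), "p_cr")
})

test_that("psychometric fit recovers a known observer and is monotone", {
  set.seed(47)
  lev <- c(-12.8, -6.4, -3.2, -1.6, 0, 1.6, 3.2, 6.4, 12.8)
  mu_true <- 0.8; sigma_true <- 6
  ch <- unlist(lapply(lev, function(s)
    ifelse(runif(200) < pnorm((s - mu_true) / sigma_true), 1L, -1L)))
  co <- rep(lev, each = 200)
  fit <- fit_psychometric(co, ch)
  expect_equal(fit$sigma, sigma_true, tolerance = 0.1 * sigma_true)
  expect_lt(abs(fit$mu - mu_true), 1)
  p <- predict(fit, lev)
  expect_true(all(diff(p) > 0))
  # unbiased symmetric observer: pCR(0) near 0.5
  ch0 <- ifelse(runif(2000) < pnorm(rep(lev, length.out = 2000) / 6), 1L, -1L)
  fit0 <- fit_psychometric(rep(lev, length.out = 2000), ch0)
  expect_lt(abs(predict(fit0, 0) - 0.5), 0.05)
  expect_error(fit_psychometric(co, rep(1L, length(co))), "degenerate")
})

test_that("profile construction: bin assignment and inverse-error weighting", {
  set.seed(53)
  # psychometric with sigma = 10 so levels map cleanly onto the five bins
  lev <- c(-12.8, -6.4, -3.2, 0, 3.2, 6.4, 12.8)
  ch <- unlist(lapply(lev, function(s)
    ifelse(runif(300) < pnorm(s / 10), 1L, -1L)))
  ps <- fit_psychometric(rep(lev, each = 300), ch)
  tab <- sim_constant_cp_cell(levels = lev, psych_sigma = 10)
  pr <- build_cell_profile(tab, ps)
  expect_s3_class(pr, "cp_profile")
  expect_true(pr$complete)
  expect_equal(pr$n_levels, c(2L, 1L, 1L, 1L, 2L))
  expect_true(all(pr$sem > 0))
  # weights within a bin are the normalized K p (1-p); reproduce bin 1 by hand
  p_lev <- predict(ps, lev)
  cp1 <- estimate_cp(tab$count[tab$coherence == lev[1] & tab$choice == 1],
                     tab$count[tab$coherence == lev[1] & tab$choice == -1],
                     p_cr = p_lev[1])$cp
  cp2 <- estimate_cp(tab$count[tab$coherence == lev[2] & tab$choice == 1],
                     tab$count[tab$coherence == lev[2] & tab$choice == -1],
                     p_cr = p_lev[2])$cp
  w1 <- 30 * p_lev[1] * (1 - p_lev[1]); w2 <- 45 * p_lev[2] * (1 - p_lev[2])
  expect_equal(pr$cp[1], (w1 * cp1 + w2 * cp2) / (w1 + w2), tolerance = 1e-12)
  expect_equal(pr$sem[1], 1 / sqrt(12 * (w1 + w2)), tolerance = 1e-12)
  # bin SEM never exceeds the largest contributing level SEM
  expect_lt(pr$sem[1], max(1 / sqrt(12 * w1), 1 / sqrt(12 * w2)))
})

test_that("two-level weighted average matches the hand-computed normalization", {
  # levels (K=60, pCR=0.5) and (K=30, pCR=0.9): unnormalized weights 15, 2.7
  w_u <- c(60 * 0.5 * 0.5, 30 * 0.9 * 0.1)
  expect_equal(w_u, c(15, 2.7))
  cps <- c(0.52, 0.70)
  expect_equal(sum(w_u / sum(w_u) * cps), (15 * 0.52 + 2.7 * 0.70) / 17.7,
               tolerance = 1e-12)
})

test_that("averaging profiles: identical cells, grouping, and the 0.5 tie-break", {
  mk <- function(cp, id) structure(
    list(cell_id = id, cp = cp, sem = rep(0.05, 5), w_u = rep(10, 5),
         n_levels = rep(1L, 5), bin_pcr = c(0.15, 0.4, 0.5, 0.6, 0.85),
         mean_cp = mean(cp), epsilon = 0.02, complete = TRUE),
    class = "cp_profile")
  p_hi <- mk(c(0.62, 0.58, 0.55, 0.58, 0.62), "a")
  avg <- average_profiles(list(p_hi, mk(c(0.62, 0.58, 0.55, 0.58, 0.62), "b")),
                          "above")
  expect_equal(avg$cp, p_hi$cp, tolerance = 1e-12)
  expect_equal(avg$n_cells, 2L)
  # a cell with mean CP exactly 0.5 is assigned to the "above" group
  p_tie <- mk(rep(0.5, 5), "tie")
  expect_equal(average_profiles(list(p_tie), "above")$n_cells, 1L)
  expect_error(average_profiles(list(p_tie), "below"), "no complete")
  # incomplete profiles never enter the average
  p_inc <- mk(c(0.6, NA, 0.5, 0.6, 0.6), "inc"); p_inc$complete <- FALSE
  expect_equal(average_profiles(list(p_hi, p_inc), "above")$n_cells, 1L)
})

test_that("binned empirical CPs on threshold-model data match the exact solution", {
  set.seed(59)
  # one synthetic cell with known rho; choice rate varies by level
  rho <- 0.35
  lev_pcr <- c(0.12, 0.3, 0.42, 0.5, 0.58, 0.7, 0.88)
  lev <- qnorm(lev_pcr) * 8
  rows <- lapply(seq_along(lev), function(i) {
    sim <- sim_bvn_threshold(rho, lev_pcr[i], 400)
    data.frame(cell_id = "z", trial_id = i * 1e4 + seq_len(400),
               coherence = lev[i], choice = sim$D,
               count = sim$r)  # continuous responses; CP is rank-based
  })
  tab <- do.call(rbind, rows)
  ps <- fit_psychometric(tab$coherence, tab$choice)
  pr <- build_cell_profile(tab, ps)
  expect_true(pr$complete)
  for (k in 1:5) {
    cp_th <- cp_exact(threshold_params(rho, pr$bin_pcr[k]))
    expect_lt(abs(pr$cp[k] - cp_th), 3 * pr$sem[k])
  }
})
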