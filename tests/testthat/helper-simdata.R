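# Shared fixtures, built in code.

# Bivariate-Gaussian threshold-model sampler: the Monte-Carlo oracle for the
# exact CP solution (independent of the package's analytic path).
sim_bvn_threshold <- function(rho, p_cr, n) {
  theta <- -qnorm(p_cr)
  d <- rnorm(n)
  r <- rho * d + sqrt(1 - rho^2) * rnorm(n)
  list(r = r, d = d, D = ifelse(d > theta, 1L, -1L))
}

# rank-based AUC (oracle route, written independently of cpstim:::.cp_rank)
auc_rank <- function(x, y) {
  nx <- as.numeric(length(x))
  ny <- as.numeric(length(y))
  rk <- rank(c(x, y))
  (sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

# Hanley-McNeil style standard error of an AUC estimate (for MC tolerances)
auc_se <- function(auc, n1, n2) {
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
}

# One cell whose CP is constant across levels by construction: counts are
# drawn from level-independent choice-conditional distributions; choices
# follow a probit psychometric. Binomial per-choice counts are truncated to
# keep every level estimable (>= 4 per choice), which does not affect the CP.
sim_constant_cp_cell <- function(levels = c(-12.8, -6.4, -3.2, 0, 3.2, 6.4, 12.8),
                                 K = c(30, 45, 45, 60, 45, 45, 30),
                                 psych_sigma = 10, mu_neg = 10, mu_pos = 11,
                                 cell_id = "c1") {
  out <- lapply(seq_along(levels), function(i) {
    p <- pnorm(levels[i] / psych_sigma)
    n_pos <- rbinom(1, K[i], p)
    n_pos <- min(max(n_pos, 4L), K[i] - 4L)
    n_neg <- K[i] - n_pos
    data.frame(cell_id = cell_id,
               trial_id = i * 1000L + seq_len(K[i]),
               coherence = levels[i],
               choice = rep(c(1L, -1L), c(n_pos, n_neg)),
               count = c(rpois(n_pos, mu_pos), rpois(n_neg, mu_neg)))
  })
  do.call(rbind, out)
}

# One cell generated directly from the interaction GLM:
# log mu = a0 + b(level) * D, with choices from a probit psychometric.
sim_glm_cell <- function(b_by_bin, n_per_level = 60, a0 = log(10),
                         a1 = 0.04,
                         levels = c(-12.8, -6.4, -3.2, 0, 3.2, 6.4, 12.8),
                         psych_sigma = 10, cell_id = "g1") {
  out <- lapply(seq_along(levels), function(i) {
    p <- pnorm(levels[i] / psych_sigma)
    D <- ifelse(runif(n_per_level) < p, 1L, -1L)
    bin <- cut(p, c(0, 0.3, 0.45, 0.55, 0.7, 1), labels = FALSE)
    mu <- exp(a0 + a1 * levels[i] + b_by_bin[bin] * D)
    data.frame(cell_id = cell_id, trial_id = i * 1000L + seq_len(n_per_level),
               coherence = levels[i], choice = D,
               count = rpois(n_per_level, mu))
  })
  do.call(rbind, out)
}

# A small gain-model population whose readout is balanced (w^T f0 ~ 0), with
# coherence levels placed so all five pCR bins are covered.
balanced_population <- function(n = 10, sigma_g2 = 0.1, f0 = NULL,
                                fprime = 0.4) {
  if (is.null(f0)) f0 <- seq(8, 26, length.out = n)
  fprime0 <- rep(c(1, -1), length.out = n) * fprime
  population_encoding(f0, fprime0, sigma_g2 = sigma_g2)
}

# coherence levels hitting target pCR values under the model psychometric
levels_for_pcr <- function(enc, pcr, w = optimal_weights(enc)) {
  sd_d <- sqrt(drop(crossprod(w, total_covariance(enc, enc$s0) %*% w)))
  sd_d * qnorm(pcr)
}
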