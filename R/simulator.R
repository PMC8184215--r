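# Synthetic-data generator for the full generative model: linearized tuning,
# a shared multiplicative gain drawn per trial from a gamma distribution with
# mean 1 and variance sigma_g2 (so spike counts are negative-binomial
# marginally), conditionally Poisson spiking, a linear readout d = w^T r and
# a threshold choice D = sign(d - theta). Defaults emulate the trial design
# of classic single-unit motion-discrimination recordings: ~11 signed
# coherence levels, 30 trials at high coherence, more at low coherence.

#' Default trial counts per coherence level
#'
#' 60 trials at zero coherence, 45 at weak levels (|coherence| <= 3.2%),
#' 30 at stronger levels, mirroring typical archive designs.
#'
#' @param coherences vector of signed coherence levels (%).
#' @return integer vector of trial counts.
#' @export
default_trials_per_level <- function(coherences) {
  ifelse(coherences == 0, 60L, ifelse(abs(coherences) <= 3.2, 45L, 30L))
}

#' Simulation configuration
#'
#' Bundles a population encoding with the task design. With the default
#' encoding, 20 neurons span rates 5-30 counts/trial with alternating
#' preferred direction, Poisson-level base variance, and gain variance 0.1.
#'
#' @param enc a \code{\link{population_encoding}}; default described above.
#' @param coherences signed stimulus levels (%); default
#'   \code{c(-25.6, -12.8, -6.4, -3.2, -1.6, 0, 1.6, 3.2, 6.4, 12.8, 25.6)}.
#' @param trials_per_level integer scalar or vector parallel to
#'   \code{coherences}; default \code{\link{default_trials_per_level}}.
#' @param threshold decision threshold; default \code{NULL} uses the unbiased
#'   value w^T f(s0).
#' @param weights readout weights; default \code{NULL} uses
#'   \code{\link{optimal_weights}}.
#' @param seed integer seed; a fixed seed makes \code{\link{simulate_trials}}
#'   deterministic.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(enc = NULL, coherences = NULL,
                              trials_per_level = NULL, threshold = NULL,
                              weights = NULL, seed = 1L) {
  if (is.null(enc)) {
    n <- 20L
    f0 <- seq(5, 30, length.out = n)
    fprime0 <- rep(c(1, -1), length.out = n) * (0.06 + 0.004 * seq_len(n))
    enc <- population_encoding(f0, fprime0, sigma_g2 = 0.1)
  }
  if (is.null(coherences))
    coherences <- c(-25.6, -12.8, -6.4, -3.2, -1.6, 0, 1.6, 3.2, 6.4, 12.8, 25.6)
  if (is.null(trials_per_level))
    trials_per_level <- default_trials_per_level(coherences)
  trials_per_level <- rep_len(as.integer(trials_per_level), length(coherences))
  if (any(trials_per_level < 1L)) stop("each level needs at least one trial")
  structure(list(enc = enc, coherences = coherences,
                 trials_per_level = trials_per_level, threshold = threshold,
                 weights = weights, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a trial table from the generative model
#'
#' Per trial: draw the shared gain g ~ Gamma(mean 1, variance sigma_g2),
#' draw counts r_i ~ Poisson(g f_i(s)) (optionally coupled through a Gaussian
#' copula when the base covariance has off-diagonal structure), form the
#' decision variable d = w^T r and the choice D = +1 iff d > theta. The
#' population shares trials, so every neuron appears once per trial.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return A trial table: data.frame with columns \code{cell_id},
#'   \code{trial_id}, \code{coherence}, \code{choice}, \code{count}.
#'   Attributes \code{"decision"} (per-trial d), \code{"gain"} (per-trial g),
#'   \code{"weights"}, \code{"threshold"} and \code{"config"} expose the
#'   latent state.
#' @export
simulate_trials <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  enc <- cfg$enc
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  w <- if (is.null(cfg$weights)) optimal_weights(enc) else cfg$weights
  theta <- if (is.null(cfg$threshold)) sum(w * enc$f0) else cfg$threshold
  use_copula <- any(cfg$enc$sigma_base[upper.tri(cfg$enc$sigma_base)] != 0)
  R <- if (use_copula) stats::cov2cor(enc$sigma_base)
  n_lev <- length(cfg$coherences)
  counts_l <- vector("list", n_lev)
  d_l <- vector("list", n_lev)
  g_l <- vector("list", n_lev)
  trial0 <- 0L
  out <- vector("list", n_lev)
  for (l in seq_len(n_lev)) {
    s <- cfg$coherences[l]
    K <- cfg$trials_per_level[l]
    f <- pmax(tuning_at(enc, s), 1e-3)
    g <- if (enc$sigma_g2 > 0) {
      stats::rgamma(K, shape = 1 / enc$sigma_g2, rate = 1 / enc$sigma_g2)
    } else rep(1, K)
    lam <- outer(f, g)                       # n_neurons x K
    counts <- if (use_copula) {
      z <- t(MASS::mvrnorm(K, mu = rep(0, enc$n), Sigma = R))
      matrix(stats::qpois(stats::pnorm(z), lam), nrow = enc$n)
    } else {
      matrix(stats::rpois(enc$n * K, lam), nrow = enc$n)
    }
    d <- drop(crossprod(counts, w))
    choice <- ifelse(d > theta, 1L, -1L)
    out[[l]] <- data.frame(
      cell_id = rep(sprintf("cell%02d", seq_len(enc$n)), times = K),
      trial_id = rep(trial0 + seq_len(K), each = enc$n),
      coherence = s,
      choice = rep(choice, each = enc$n),
      count = as.integer(counts),
      stringsAsFactors = FALSE)
    d_l[[l]] <- d; g_l[[l]] <- g
    trial0 <- trial0 + K
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "decision") <- unlist(d_l)
  attr(tab, "gain") <- unlist(g_l)
  attr(tab, "weights") <- w
  attr(tab, "threshold") <- theta
  attr(tab, "config") <- cfg
  tab
}

#' Estimate the gain variance from spike counts across stimulus levels
#'
#' Fits the negative-binomial mean-variance relation var = mu + sigma_G^2 mu^2
#' across stimulus levels by least squares on the per-level sample moments
#' (mu_hat_l, var_hat_l); the estimate is clipped at zero. This is the moment
#' form of a shared-gain (Poisson-gamma) spiking model.
#'
#' @param counts_by_level a list of numeric vectors (spike counts per
#'   stimulus level for one cell), or a data.frame with columns \code{count}
#'   and \code{coherence} for one cell.
#' @param min_trials minimum trials per level for inclusion (default 10).
#' @return estimated sigma_G^2 (>= 0), with attribute \code{"n_levels"}.
#' @export
estimate_gain_variance <- function(counts_by_level, min_trials = 10L) {
  if (is.data.frame(counts_by_level))
    counts_by_level <- split(counts_by_level$count, counts_by_level$coherence)
  counts_by_level <- Filter(function(x) length(x) >= min_trials, counts_by_level)
  if (length(counts_by_level) < 2L)
    stop("need at least 2 stimulus levels with >= ", min_trials, " trials")
  mu <- vapply(counts_by_level, mean, numeric(1))
  v <- vapply(counts_by_level, stats::var, numeric(1))
  if (all(mu == 0)) stop("all mean counts are zero")
  est <- sum(mu^2 * (v - mu)) / sum(mu^4)
  structure(max(est, 0), n_levels = length(counts_by_level))
}
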