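# Feedforward encoding/decoding model with shared multiplicative gain
# fluctuations. A population with tuning f(s) and base covariance Sigma_bar
# acquires a rank-one, stimulus-dependent covariance component
# sigma_g2 * f(s) f(s)^T from trial-to-trial gain g (mean 1, variance
# sigma_g2). A linear readout d = w^T r thresholded at theta produces the
# choice; the model predicts cell-specific CP(pCR) profiles whose asymmetric
# component grows with the gain-variance fraction lambda_i.

#' Population encoding with shared gain fluctuations
#'
#' @param f0 tuning values f(s0) at the uninformative stimulus, all > 0
#'   (counts per trial).
#' @param fprime0 tuning derivatives f'(s0) (counts per unit stimulus).
#' @param sigma_base base covariance matrix (stimulus-independent, symmetric
#'   positive-definite). The default \code{NULL} uses Poisson-level variance
#'   \code{diag(f0)}.
#' @param sigma_g2 gain variance sigma_G^2 >= 0 (dimensionless).
#' @param s0 reference (uninformative) stimulus level; default 0.
#' @return An object of class \code{"population_encoding"}.
#' @export
population_encoding <- function(f0, fprime0, sigma_base = NULL, sigma_g2 = 0,
                                s0 = 0) {
  n <- length(f0)
  stopifnot(n >= 1, length(fprime0) == n, all(f0 > 0), sigma_g2 >= 0)
  if (is.null(sigma_base)) sigma_base <- diag(f0, n)
  sigma_base <- as.matrix(sigma_base)
  if (!isTRUE(all.equal(sigma_base, t(sigma_base), tolerance = 1e-8)))
    stop("'sigma_base' must be symmetric")
  ev <- eigen(sigma_base, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("'sigma_base' must be positive-definite")
  structure(list(f0 = as.numeric(f0), fprime0 = as.numeric(fprime0),
                 sigma_base = sigma_base, sigma_g2 = sigma_g2, s0 = s0,
                 n = n),
            class = "population_encoding")
}

# linearized tuning at stimulus s
tuning_at <- function(enc, s) enc$f0 + enc$fprime0 * (s - enc$s0)

#' Total response covariance at a stimulus level
#'
#' Sigma(s) = Sigma_bar + sigma_G^2 f(s) f(s)^T with linearized tuning
#' f(s) = f0 + f'(s0) (s - s0).
#'
#' @param enc a \code{\link{population_encoding}}.
#' @param s stimulus level.
#' @return covariance matrix (checked positive-definite).
#' @export
total_covariance <- function(enc, s = enc$s0) {
  f <- tuning_at(enc, s)
  sig <- enc$sigma_base + enc$sigma_g2 * tcrossprod(f)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("total covariance is not positive-definite at s = ", s)
  sig
}

#' Optimal linear readout weights
#'
#' w = Sigma^-1(s0) f'(s0) / (f'(s0)^T Sigma^-1(s0) f'(s0)), normalized so
#' that w^T f'(s0) = 1 (locally unbiased stimulus estimate).
#'
#' @param enc a \code{\link{population_encoding}}.
#' @return numeric weight vector.
#' @export
optimal_weights <- function(enc) {
  sig0 <- total_covariance(enc, enc$s0)
  w <- solve(sig0, enc$fprime0)
  denom <- sum(enc$fprime0 * w)
  if (abs(denom) < .Machine$double.eps)
    stop("degenerate tuning: f'(s0)^T Sigma^-1 f'(s0) is zero")
  w / denom
}

#' Choice correlations implied by a linear readout
#'
#' CC_i = (Sigma(s) w)_i / sqrt(Sigma_ii(s) w^T Sigma(s) w), the correlation
#' between each neuron's response and the decision variable d = w^T r.
#'
#' @param enc a \code{\link{population_encoding}}.
#' @param w readout weight vector (at least one nonzero entry).
#' @param s stimulus level (default s0).
#' @return per-neuron choice correlations, all in [-1, 1].
#' @export
cc_from_readout <- function(enc, w, s = enc$s0) {
  stopifnot(length(w) == enc$n)
  if (all(w == 0)) stop("'w' must have at least one nonzero weight")
  sig <- total_covariance(enc, s)
  sw <- drop(sig %*% w)
  var_d <- sum(w * sw)
  vr <- diag(sig)
  if (var_d <= 0 || any(vr <= 0)) stop("zero variance encountered")
  sw / sqrt(vr * var_d)
}

#' Gain-variance fraction lambda_i
#'
#' lambda_i^2 = sigma_G^2 f_i^2(s0) / Sigma_ii(s0): the fraction of neuron i's
#' variance at the reference stimulus caused by the shared gain fluctuations.
#'
#' @param enc a \code{\link{population_encoding}}.
#' @param i neuron index or vector of indices (default all).
#' @return lambda_i in [0, 1).
#' @export
lambda_fraction <- function(enc, i = seq_len(enc$n)) {
  vii <- diag(total_covariance(enc, enc$s0))[i]
  if (any(vii <= 0)) stop("zero variance encountered")
  sqrt(enc$sigma_g2 * enc$f0[i]^2 / vii)
}

#' Gain-induced choice-correlation profile
#'
#' First-order prediction under the optimal readout:
#' CC_i(ds) = CC_i(0.5) + sigma_G lambda_i (1 - CC_i(0.5)^2) ds / sd(d),
#' where CC_i(0.5) is the choice correlation at the reference stimulus and
#' sd(d) is evaluated at s0. The slope coefficient
#' beta_pCR = sigma_G lambda_i (1 - CC_i(0.5)^2) is non-negative whenever
#' sigma_G >= 0.
#'
#' @param enc a \code{\link{population_encoding}}.
#' @param i neuron index.
#' @param delta_s vector of stimulus offsets ds = s - s0 (linear regime).
#' @param w readout weights; default \code{optimal_weights(enc)}.
#' @return list with \code{cc} (per offset), \code{cc_half} = CC_i(0.5),
#'   \code{slope} = beta_pCR, and \code{sd_d}.
#' @export
cc_gain_profile <- function(enc, i, delta_s, w = optimal_weights(enc)) {
  sig0 <- total_covariance(enc, enc$s0)
  sd_d <- sqrt(drop(crossprod(w, sig0 %*% w)))
  cc0 <- cc_from_readout(enc, w, enc$s0)[i]
  lam <- lambda_fraction(enc, i)
  slope <- sqrt(enc$sigma_g2) * lam * (1 - cc0^2)
  cc <- cc0 + slope * delta_s / sd_d
  if (any(abs(cc) >= 1))
    stop("predicted |CC| >= 1: stimulus offsets outside the linear regime")
  list(cc = cc, cc_half = cc0, slope = slope, sd_d = sd_d)
}

#' Model-predicted CP(pCR) profile
#'
#' Composes the gain-induced choice-correlation profile with the
#' threshold-model CP at each choice rate. The mapping between choice rate
#' and stimulus offset defaults to the model-implied psychometric
#' pCR = Phi(ds / sd(d)) of the unbiased optimal readout.
#'
#' @param enc a \code{\link{population_encoding}}.
#' @param i neuron index.
#' @param pcr_grid choice rates, each in (0, 1).
#' @param w readout weights; default optimal.
#' @param psychometric_inv optional function mapping pCR to stimulus offset
#'   ds; default \code{function(p) sd_d * qnorm(p)}.
#' @param exact logical; use \code{\link{cp_exact}} (default) rather than
#'   \code{\link{cp_linear}} on the predicted CC.
#' @return list with \code{p_cr}, \code{delta_s}, \code{cc} and \code{cp}.
#' @export
cp_profile_prediction <- function(enc, i, pcr_grid, w = optimal_weights(enc),
                                  psychometric_inv = NULL, exact = TRUE) {
  if (any(pcr_grid <= 0) || any(pcr_grid >= 1))
    stop("'pcr_grid' values must be inside (0, 1)")
  sig0 <- total_covariance(enc, enc$s0)
  sd_d <- sqrt(drop(crossprod(w, sig0 %*% w)))
  if (is.null(psychometric_inv))
    psychometric_inv <- function(p) sd_d * stats::qnorm(p)
  ds <- vapply(pcr_grid, psychometric_inv, numeric(1))
  prof <- cc_gain_profile(enc, i, ds, w)
  cp <- if (exact) {
    vapply(seq_along(pcr_grid),
           function(k) cp_exact(threshold_params(prof$cc[k], pcr_grid[k])),
           numeric(1))
  } else {
    cp_linear(prof$cc, pcr_grid)
  }
  list(p_cr = pcr_grid, delta_s = ds, cc = prof$cc, cp = cp,
       cc_half = prof$cc_half, slope = prof$slope, sd_d = sd_d)
}
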