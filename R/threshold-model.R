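# Closed-form choice-probability theory under the bivariate-Gaussian
# decision-threshold model: a latent decision variable d is compared with a
# threshold theta (choice D = +1 iff d > theta), and the joint distribution of
# a neuron's response r and d is bivariate Gaussian with correlation rho
# (the "choice correlation"). The choice rate pCR = p(D = +1) carries the
# stimulus dependence.

#' Parameters of the decision-threshold model
#'
#' Sufficient statistics for the exact choice probability of one neuron:
#' the correlation \code{rho} between its response and the latent decision
#' variable, and the choice rate \code{p_cr} = p(D = +1).
#'
#' @param rho choice correlation, in (-1, 1).
#' @param p_cr choice rate, in (0, 1); values are accepted only within
#'   \code{[1e-6, 1 - 1e-6]} because the exact solution degenerates at the
#'   endpoints. Callers converting empirical rates should clip first.
#' @return An object of class \code{"threshold_params"}.
#' @export
threshold_params <- function(rho, p_cr) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(p_cr), length(p_cr) == 1L, is.finite(p_cr))
  if (abs(rho) >= 1)
    stop("'rho' must lie strictly inside (-1, 1)")
  if (p_cr < 1e-6 || p_cr > 1 - 1e-6)
    stop("'p_cr' must lie in [1e-6, 1 - 1e-6]")
  structure(list(rho = rho, p_cr = p_cr), class = "threshold_params")
}

#' Threshold-induced modulation factor h(pCR)
#'
#' Multiplicative factor by which an unbalanced choice rate amplifies the
#' separation between the choice-conditional distributions of the decision
#' variable. \code{h_factor(0.5) == 1} is its minimum, and the factor is
#' symmetric about 0.5, so CP deviates more from 0.5 the further the choice
#' rate is from 0.5 -- identically for all neurons.
#'
#' @param p_cr choice rate(s) in (0, 1). Vectorized.
#' @return h(pCR) >= 1.
#' @export
h_factor <- function(p_cr) {
  if (!is.numeric(p_cr) || any(!is.finite(p_cr)) ||
      any(p_cr <= 0) || any(p_cr >= 1))
    stop("'p_cr' must be numeric in (0, 1)")
  sqrt(2 * pi) * stats::dnorm(stats::qnorm(p_cr)) / (4 * p_cr * (1 - p_cr))
}

#' Choice rate implied by a Gaussian decision variable
#'
#' @param mean_d mean of the decision variable.
#' @param sd_d standard deviation of the decision variable (> 0).
#' @param threshold decision threshold theta (same units as d).
#' @return pCR = Phi((mean_d - threshold) / sd_d).
#' @export
choice_rate <- function(mean_d, sd_d, threshold) {
  if (!is.numeric(sd_d) || any(sd_d <= 0))
    stop("'sd_d' must be positive")
  stats::pnorm((mean_d - threshold) / sd_d)
}

#' Owen's T function
#'
#' T(h, a) = (1/2pi) int_0^a exp(-h^2 (1+x^2)/2) / (1+x^2) dx, the kernel of
#' the exact CP solution. Evaluated by 64-node Gauss-Legendre quadrature after
#' range reduction to |a| <= 1 via the standard identity
#' T(h, a) = Phi(h)/2 + Phi(ah)/2 - Phi(h) Phi(ah) - T(ah, 1/a) (h, a >= 0),
#' together with T(-h, a) = T(h, a) and T(h, -a) = -T(h, a). Absolute accuracy
#' is well below 1e-10 (the integrand is analytic on a unit interval).
#'
#' @param h scalar or vector.
#' @param a scalar or vector (recycled).
#' @return T(h, a).
#' @export
owens_t <- function(h, a) {
  if (!is.numeric(h) || !is.numeric(a) || any(!is.finite(h)) || any(!is.finite(a)))
    stop("'h' and 'a' must be finite numerics")
  n <- max(length(h), length(a))
  h <- rep_len(h, n); a <- rep_len(a, n)
  vapply(seq_len(n), function(i) .owens_t1(h[i], a[i]), numeric(1))
}

.owens_t_gl <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(64, 0, 1)
    cache
  }
})

# core: any h, any finite a, after symmetry + range reduction
.owens_t1 <- function(h, a) {
  if (a == 0) return(0)
  s <- sign(a); a <- abs(a); h <- abs(h)
  val <- if (a <= 1) {
    .owens_t_core(h, a)
  } else {
    # reduction to slope 1/a < 1; valid for h >= 0, a > 0
    ph <- stats::pnorm(h); pah <- stats::pnorm(a * h)
    0.5 * ph + 0.5 * pah - ph * pah - .owens_t_core(a * h, 1 / a)
  }
  s * val
}

.owens_t_core <- function(h, a) {
  gl <- .owens_t_gl()
  x <- gl$x * a          # nodes on [0, a]
  w <- gl$w * a
  sum(w * exp(-h^2 * (1 + x^2) / 2) / (2 * pi * (1 + x^2)))
}

#' Exact choice probability of the threshold model
#'
#' CP = 1/2 + T(Phi^-1(pCR), rho / sqrt(2 - rho^2)) / (pCR (1 - pCR)),
#' where T is Owen's T function. For rho = 0 this is exactly 0.5; it is
#' antisymmetric in rho about 0.5 and symmetric in pCR about 0.5. For
#' pCR = 0.5 it reduces to the arctangent closed form
#' 1/2 + (2/pi) asin(rho / sqrt(2)).
#'
#' @param params a \code{\link{threshold_params}} object, or the correlation
#'   \code{rho} if \code{p_cr} is also given.
#' @param p_cr optional choice rate, allowing \code{cp_exact(rho, p_cr)}.
#' @return the choice probability, in (0, 1).
#' @export
cp_exact <- function(params, p_cr = NULL) {
  if (!inherits(params, "threshold_params"))
    params <- threshold_params(params, p_cr)
  rho <- params$rho; p <- params$p_cr
  if (rho == 0) return(0.5)
  0.5 + owens_t(stats::qnorm(p), rho / sqrt(2 - rho^2)) / (p * (1 - p))
}

#' Linear approximation of the choice probability
#'
#' CP ~ 1/2 + (sqrt(2)/pi) h(pCR) CC, the first-order expansion of the exact
#' solution in the choice correlation. Accurate to better than 0.01 for
#' |CC| <= 0.3 and pCR in [0.1, 0.9], the empirically relevant regime.
#'
#' @param cc choice correlation, |cc| < 1.
#' @param p_cr choice rate in (0, 1).
#' @return approximate CP.
#' @export
cp_linear <- function(cc, p_cr) {
  if (any(abs(cc) >= 1)) stop("|cc| must be < 1")
  0.5 + (sqrt(2) / pi) * h_factor(p_cr) * cc
}

#' Choice probability from a choice-triggered average
#'
#' Gaussian linear approximation CP ~ 1/2 + CTA / (2 sqrt(pi) sd(r)),
#' i.e. Phi(CTA / (sqrt(2) sd(r))) linearized about 0.5. Consistent with
#' \code{\link{cp_linear}} composed with \code{\link{cta_from_model}}.
#'
#' @param cta choice-triggered average (spikes).
#' @param var_r response variance (> 0, spikes^2).
#' @return approximate CP.
#' @export
cp_from_cta <- function(cta, var_r) {
  if (any(var_r <= 0)) stop("'var_r' must be positive")
  0.5 + cta / (2 * sqrt(pi) * sqrt(var_r))
}

#' Choice-triggered average implied by the threshold model
#'
#' CTA = 4 h(pCR) / sqrt(2 pi) * rho * sd_r, the mean response difference
#' between the two choices. Equals cov(r, D) / (2 pCR (1 - pCR)) for choices
#' coded D = +/-1.
#'
#' @param params a \code{\link{threshold_params}} object (or rho with
#'   \code{p_cr} given).
#' @param sd_r response standard deviation (> 0).
#' @param p_cr optional choice rate when \code{params} is given as rho.
#' @return CTA in response units.
#' @export
cta_from_model <- function(params, sd_r, p_cr = NULL) {
  if (!inherits(params, "threshold_params"))
    params <- threshold_params(params, p_cr)
  if (any(sd_r <= 0)) stop("'sd_r' must be positive")
  4 * h_factor(params$p_cr) / sqrt(2 * pi) * params$rho * sd_r
}

#' Choice-conditional density of the z-scored response
#'
#' The density of z = (r - <r>)/sd(r) given D = +1, a skew-normal:
#' p(z | D = 1) = (1/pCR) phi(z) Phi(alpha z + c), with
#' alpha = rho / sqrt(1 - rho^2) and c = Phi^-1(pCR) / sqrt(1 - rho^2).
#' Integrates to one over the real line.
#'
#' @param z z-scored response value(s).
#' @param params a \code{\link{threshold_params}} object (or rho with
#'   \code{p_cr} given).
#' @param p_cr optional choice rate when \code{params} is given as rho.
#' @param choice which choice to condition on, +1 (default) or -1.
#' @return density values at \code{z}.
#' @export
conditional_zscore_density <- function(z, params, p_cr = NULL, choice = 1) {
  if (!inherits(params, "threshold_params"))
    params <- threshold_params(params, p_cr)
  if (!choice %in% c(-1, 1)) stop("'choice' must be +1 or -1")
  rho <- params$rho; p <- params$p_cr
  alpha <- rho / sqrt(1 - rho^2)
  cc <- stats::qnorm(p) / sqrt(1 - rho^2)
  if (choice == 1) {
    stats::dnorm(z) * stats::pnorm(alpha * z + cc) / p
  } else {
    stats::dnorm(z) * (1 - stats::pnorm(alpha * z + cc)) / (1 - p)
  }
}
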