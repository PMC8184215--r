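# Empirical CP estimation and within-cell CP(pCR) profiles. CPs are
# Mann-Whitney (ROC-area) statistics per stimulus level; levels are assigned
# to five choice-rate bins through the subject's psychometric function, and
# combined within and across cells by inverse-error weighting with
# unnormalized weights K * pCR * (1 - pCR).

# rank-based AUC with half credit for ties: P(x > y) + 0.5 P(x = y)
.cp_rank <- function(x, y) {
  nx <- as.numeric(length(x)); ny <- as.numeric(length(y))
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Choice probability of one stimulus level
#'
#' The rank-sum (Mann-Whitney / ROC-area) estimator
#' (#\{pairs r+ > r-\} + 0.5 #\{ties\}) / (n+ n-), where r+ are counts from
#' choice D = +1 trials and r- from D = -1 trials. Levels failing the
#' inclusion criteria (at least \code{min_total} trials in total and
#' \code{min_per_choice} per choice) yield an "excluded" sentinel rather
#' than an error.
#'
#' @param counts_pos spike counts on D = +1 trials.
#' @param counts_neg spike counts on D = -1 trials.
#' @param p_cr choice rate used for the SEM approximation
#'   1/sqrt(12 K pCR (1-pCR)); defaults to the empirical fraction but the
#'   psychometric-predicted value is preferred (stabler at high coherence).
#' @param min_total,min_per_choice inclusion thresholds (defaults 15 and 4).
#' @return An object of class \code{"cp_estimate"}: list with \code{cp},
#'   \code{sem}, \code{n_pos}, \code{n_neg}, \code{K}, \code{p_cr},
#'   \code{excluded} (logical) and, when excluded, \code{reason}.
#' @export
estimate_cp <- function(counts_pos, counts_neg, p_cr = NULL,
                        min_total = 15L, min_per_choice = 4L) {
  n_pos <- length(counts_pos); n_neg <- length(counts_neg)
  K <- n_pos + n_neg
  excl <- function(reason)
    structure(list(cp = NA_real_, sem = NA_real_, n_pos = n_pos,
                   n_neg = n_neg, K = K, p_cr = p_cr, excluded = TRUE,
                   reason = reason), class = "cp_estimate")
  if (n_pos < min_per_choice || n_neg < min_per_choice)
    return(excl(sprintf("fewer than %d trials for one choice", min_per_choice)))
  if (K < min_total)
    return(excl(sprintf("fewer than %d trials in total", min_total)))
  if (is.null(p_cr)) p_cr <- n_pos / K
  structure(list(cp = .cp_rank(counts_pos, counts_neg),
                 sem = cp_sem(K, p_cr), n_pos = n_pos, n_neg = n_neg,
                 K = K, p_cr = p_cr, excluded = FALSE),
            class = "cp_estimate")
}

#' Approximate standard error of a CP estimate
#'
#' SEM(CP) ~ 1 / sqrt(12 K pCR (1 - pCR)), valid for CP near 0.5. The error
#' grows as the choice rate departs from 0.5 because the minority choice is
#' poorly sampled: e.g. K = 30 trials at pCR = 0.9 give SEM ~ 0.18.
#'
#' @param K number of trials.
#' @param p_cr choice rate in (0, 1).
#' @return the SEM approximation.
#' @export
cp_sem <- function(K, p_cr) {
  if (any(K < 1)) stop("'K' must be >= 1")
  if (any(p_cr <= 0) || any(p_cr >= 1)) stop("'p_cr' must be inside (0, 1)")
  1 / sqrt(12 * K * p_cr * (1 - p_cr))
}

#' Fit a psychometric function
#'
#' Binomial maximum-likelihood fit of p(D = +1) as a monotone function of
#' signed coherence, with a free bias: a cumulative Gaussian
#' Phi((s - mu)/sigma) by default (probit link), or a logistic alternative.
#'
#' @param coherence per-trial signed coherence (%).
#' @param choice per-trial choices in \{-1, +1\}.
#' @param family \code{"probit"} (cumulative Gaussian, default) or
#'   \code{"logit"}.
#' @return An object of class \code{"psychometric_fit"} with coefficients,
#'   \code{mu} (bias) and \code{sigma} (slope scale, probit only).
#' @export
fit_psychometric <- function(coherence, choice, family = c("probit", "logit")) {
  family <- match.arg(family)
  stopifnot(length(coherence) == length(choice), all(choice %in% c(-1, 1)))
  if (length(unique(choice)) < 2L)
    stop("degenerate data: all trials have the same choice")
  if (length(unique(coherence)) < 3L)
    stop("need at least 3 coherence levels")
  y <- as.integer(choice == 1)
  fit <- stats::glm(y ~ coherence, family = stats::binomial(link = family))
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("psychometric fit is not increasing in coherence")
  structure(list(coef = b, family = family,
                 mu = unname(-b[1] / b[2]),
                 sigma = if (family == "probit") unname(1 / b[2]) else NA_real_),
            class = "psychometric_fit")
}

#' Predicted choice rate at given coherence levels
#'
#' @param object a \code{\link{fit_psychometric}} result.
#' @param coherence stimulus levels.
#' @param clip predictions are clipped to \code{[clip, 1 - clip]}
#'   (default 0.01) before use in SEM weights.
#' @param ... unused.
#' @return predicted pCR values.
#' @export
predict.psychometric_fit <- function(object, coherence, clip = 0.01, ...) {
  eta <- object$coef[1] + object$coef[2] * coherence
  p <- if (object$family == "probit") stats::pnorm(eta) else stats::plogis(eta)
  pmin(pmax(unname(p), clip), 1 - clip)
}

# bin index for each level: five pCR bins
# [0-0.3], [0.3-(0.5-eps)], central (zero coherence only), [(0.5+eps)-0.7], [0.7-1]
.assign_bins <- function(coherence, p_cr, epsilon) {
  ifelse(coherence == 0, 3L,
  ifelse(p_cr <= 0.3, 1L,
  ifelse(p_cr < 0.5 | (p_cr == 0.5 & coherence < 0), 2L,
  ifelse(p_cr <= 0.7, 4L, 5L))))
}

#' Build a within-cell CP(pCR) profile
#'
#' Estimates a CP per stimulus level, assigns levels to five pCR bins via the
#' psychometric function (the half-width \code{epsilon} of the central bin is
#' set so that only the zero-coherence level falls in it), and combines
#' levels within a bin as a weighted average with normalized weights
#' proportional to K_j pCR_j (1 - pCR_j). The bin SEM is
#' 1/sqrt(12 M_k <w_U>) where <w_U> averages the unnormalized weights.
#'
#' @param cell_trials trial-table slice for one cell (columns
#'   \code{coherence}, \code{choice}, \code{count}).
#' @param psych a \code{\link{fit_psychometric}} result.
#' @param epsilon central-bin half width; default: half the minimum
#'   |pCR(level) - 0.5| over informative (nonzero-coherence) levels.
#' @param min_total,min_per_choice level inclusion thresholds passed to
#'   \code{\link{estimate_cp}}.
#' @return An object of class \code{"cp_profile"}: \code{cell_id},
#'   \code{cp} and \code{sem} (length-5), \code{w_u} (summed unnormalized
#'   weights per bin), \code{n_levels} per bin, \code{bin_pcr}
#'   (weight-averaged pCR per bin), \code{mean_cp} (weighted over bins) and
#'   \code{complete}. Incompleteness is encoded in the flag, never an error.
#' @export
build_cell_profile <- function(cell_trials, psych, epsilon = NULL,
                               min_total = 15L, min_per_choice = 4L) {
  cell_id <- if ("cell_id" %in% names(cell_trials))
    as.character(cell_trials$cell_id[1]) else NA_character_
  levels <- sort(unique(cell_trials$coherence))
  p_lev <- predict(psych, levels)
  if (is.null(epsilon)) {
    inf_lev <- levels != 0
    epsilon <- if (any(inf_lev)) min(abs(p_lev[inf_lev] - 0.5)) / 2 else 0.05
  }
  bins <- .assign_bins(levels, p_lev, epsilon)
  cp_l <- sem_l <- wu_l <- rep(NA_real_, length(levels))
  for (j in seq_along(levels)) {
    tr <- cell_trials[cell_trials$coherence == levels[j], ]
    est <- estimate_cp(tr$count[tr$choice == 1], tr$count[tr$choice == -1],
                       p_cr = p_lev[j], min_total = min_total,
                       min_per_choice = min_per_choice)
    if (!est$excluded) {
      cp_l[j] <- est$cp; sem_l[j] <- est$sem
      wu_l[j] <- est$K * p_lev[j] * (1 - p_lev[j])
    }
  }
  cp <- sem <- wu <- bin_pcr <- rep(NA_real_, 5L)
  n_levels <- integer(5L)
  for (k in 1:5) {
    use <- which(bins == k & !is.na(cp_l))
    n_levels[k] <- length(use)
    if (length(use)) {
      w <- wu_l[use] / sum(wu_l[use])
      cp[k] <- sum(w * cp_l[use])
      wu[k] <- sum(wu_l[use])
      sem[k] <- 1 / sqrt(12 * wu[k])
      bin_pcr[k] <- sum(w * p_lev[use])
    }
  }
  complete <- !anyNA(cp)
  mean_cp <- if (any(!is.na(cp)))
    sum(cp * wu, na.rm = TRUE) / sum(wu, na.rm = TRUE) else NA_real_
  structure(list(cell_id = cell_id, cp = cp, sem = sem, w_u = wu,
                 n_levels = n_levels, bin_pcr = bin_pcr, mean_cp = mean_cp,
                 epsilon = epsilon, complete = complete),
            class = "cp_profile")
}

#' Average CP(pCR) profiles across cells
#'
#' Cells are grouped by the sign of their weighted mean CP relative to 0.5
#' (ties assigned to the "above" group) and averaged per bin with the same
#' inverse-error weighting used within cells (weights are the summed
#' unnormalized bin weights). Only complete profiles enter the average, so
#' the result is an average of within-cell profiles rather than a mixture of
#' cell subsets per bin.
#'
#' @param profiles list of \code{"cp_profile"} objects.
#' @param group \code{"above"} or \code{"below"} (mean CP vs 0.5).
#' @return a \code{"cp_profile"} for the group, with \code{n_cells} and the
#'   member \code{cell_ids}.
#' @export
average_profiles <- function(profiles, group = c("above", "below")) {
  group <- match.arg(group)
  profiles <- Filter(function(p) isTRUE(p$complete), profiles)
  sel <- vapply(profiles, function(p)
    if (group == "above") p$mean_cp >= 0.5 else p$mean_cp < 0.5, logical(1))
  profiles <- profiles[sel]
  if (!length(profiles)) stop("no complete profiles in group '", group, "'")
  cpm <- t(vapply(profiles, `[[`, numeric(5), "cp"))
  wum <- t(vapply(profiles, `[[`, numeric(5), "w_u"))
  pcm <- t(vapply(profiles, `[[`, numeric(5), "bin_pcr"))
  wu <- colSums(wum)
  cp <- colSums(cpm * wum) / wu
  structure(list(cell_id = sprintf("<average:%s>", group), cp = cp,
                 sem = 1 / sqrt(12 * wu), w_u = wu,
                 n_levels = colSums(!is.na(cpm)),
                 bin_pcr = colSums(pcm * wum) / wu,
                 mean_cp = sum(cp * wu) / sum(wu),
                 complete = TRUE, n_cells = length(profiles),
                 cell_ids = vapply(profiles, `[[`, character(1), "cell_id")),
            class = "cp_profile")
}

#' Extract the CP matrix from a list of profiles
#'
#' @param profiles list of complete \code{"cp_profile"} objects.
#' @param centered subtract 0.5 (default TRUE), the representation used for
#'   clustering.
#' @return numeric matrix, one row per cell, five columns.
#' @export
profile_matrix <- function(profiles, centered = TRUE) {
  profiles <- Filter(function(p) isTRUE(p$complete), profiles)
  m <- t(vapply(profiles, `[[`, numeric(5), "cp"))
  rownames(m) <- vapply(profiles, `[[`, character(1), "cell_id")
  if (centered) m - 0.5 else m
}

#' @export
print.cp_profile <- function(x, ...) {
  cat("CP(pCR) profile", if (!is.na(x$cell_id)) paste0("[", x$cell_id, "]"),
      if (!x$complete) "(incomplete)", "\n")
  print(round(rbind(pCR = x$bin_pcr, CP = x$cp, SEM = x$sem), 4))
  cat("weighted mean CP:", round(x$mean_cp, 4), "\n")
  invisible(x)
}
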