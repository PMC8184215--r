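# Surrogate-based test of the null hypothesis that a cell's CP does not
# depend on the choice rate. Responses from low-information stimulus levels
# are pooled after a choice-conditioned z-scoring (estimating each level's
# mean and SD from the two choice-conditional moments with equal weight, so
# that an unbalanced choice rate does not bias the normalization and the CP
# is not underestimated under a constant-CP null). Surrogate data sets
# preserve the per-level per-choice trial counts exactly and destroy any
# stimulus dependence, so any profile structure left in them reflects only
# the sampling design.

#' Choice-conditioned z-scoring of low-information levels
#'
#' Within the pooling window, each level's responses are normalized with a
#' balanced location/scale estimate: mean = (m+ + m-)/2 and variance
#' (v+ + v-)/2 + (m+ - m-)^2/4 (choice-conditional moments with denominator
#' n), which removes the choice-rate weighting of the ordinary sample
#' moments. For exactly balanced choices it reduces to ordinary per-level
#' z-scoring. Levels missing a choice (or with zero variance) are skipped
#' with a warning.
#'
#' @param cell_trials trial-table slice for one cell.
#' @param window symmetric coherence window (%), default \code{c(-1.6, 1.6)}.
#' @return list with \code{z_pos} and \code{z_neg} (pooled normalized
#'   responses labeled by choice) and \code{levels_used}.
#' @export
choice_conditioned_zscore <- function(cell_trials, window = c(-1.6, 1.6)) {
  if (window[1] > 0 || window[2] < 0 || abs(window[1] + window[2]) > 1e-9)
    stop("pooling window must be symmetric about 0")
  sel <- cell_trials$coherence >= window[1] & cell_trials$coherence <= window[2]
  tr <- cell_trials[sel, ]
  if (!nrow(tr)) stop("no trials inside the pooling window")
  z_pos <- list(); z_neg <- list(); used <- numeric(0)
  for (s in sort(unique(tr$coherence))) {
    xp <- tr$count[tr$coherence == s & tr$choice == 1]
    xn <- tr$count[tr$coherence == s & tr$choice == -1]
    if (!length(xp) || !length(xn)) {
      warning("level ", s, " skipped: one choice absent inside the window")
      next
    }
    mp <- mean(xp); mn <- mean(xn)
    vp <- mean((xp - mp)^2); vn <- mean((xn - mn)^2)
    m <- (mp + mn) / 2
    v <- (vp + vn) / 2 + (mp - mn)^2 / 4
    if (v <= 0) {
      warning("level ", s, " skipped: zero variance")
      next
    }
    z_pos[[length(z_pos) + 1L]] <- (xp - m) / sqrt(v)
    z_neg[[length(z_neg) + 1L]] <- (xn - m) / sqrt(v)
    used <- c(used, s)
  }
  if (!length(used)) stop("no usable level inside the pooling window")
  list(z_pos = unlist(z_pos), z_neg = unlist(z_neg), levels_used = used)
}

#' Generate one surrogate data set for a cell
#'
#' For every stimulus level of the cell, draws (with replacement) the
#' original number of D = +1 trials from the choice-positive pool and the
#' original number of D = -1 trials from the choice-negative pool, so the
#' per-level per-choice trial counts equal the original exactly while any
#' CP-stimulus dependence is destroyed.
#'
#' @param cell_trials trial-table slice for one cell.
#' @param pool result of \code{\link{choice_conditioned_zscore}}.
#' @return a data.frame with columns \code{coherence}, \code{choice},
#'   \code{count} (normalized responses; the CP is invariant under the
#'   monotone normalization).
#' @export
generate_surrogate <- function(cell_trials, pool) {
  if (!length(pool$z_pos) || !length(pool$z_neg))
    stop("empty pool for one of the choices")
  out <- lapply(sort(unique(cell_trials$coherence)), function(s) {
    np <- sum(cell_trials$coherence == s & cell_trials$choice == 1)
    nn <- sum(cell_trials$coherence == s & cell_trials$choice == -1)
    data.frame(
      coherence = s,
      choice = rep(c(1L, -1L), c(np, nn)),
      count = c(sample(pool$z_pos, np, replace = TRUE),
                sample(pool$z_neg, nn, replace = TRUE)))
  })
  do.call(rbind, out)
}

#' Delta-CP summary statistic of a profile
#'
#' From the bin differences dCP_k = CP(pCR_{k+1}) - CP(pCR_k), k = 1..4:
#' the \code{"asymmetric"} variant is their mean; the \code{"symmetric"}
#' variant flips the sign of the differences on the pCR < 0.5 side before
#' averaging; the \code{"threshold"} variant is the symmetric statistic
#' additionally inverted for cells/groups whose mean CP is below 0.5
#' (matching the inverted modulation the threshold model predicts for
#' negative choice correlations).
#'
#' @param profile a complete \code{"cp_profile"} or a numeric length-5 CP
#'   vector.
#' @param variant \code{"asymmetric"}, \code{"symmetric"} or
#'   \code{"threshold"}.
#' @param mean_cp mean CP used by the threshold variant; taken from the
#'   profile when available.
#' @return scalar statistic.
#' @export
delta_cp_statistic <- function(profile,
                               variant = c("asymmetric", "symmetric",
                                           "threshold"),
                               mean_cp = NULL) {
  variant <- match.arg(variant)
  if (inherits(profile, "cp_profile")) {
    if (!profile$complete) stop("profile is incomplete")
    if (is.null(mean_cp)) mean_cp <- profile$mean_cp
    cp <- profile$cp
  } else {
    cp <- as.numeric(profile)
    if (length(cp) != 5L || anyNA(cp)) stop("need a complete 5-bin profile")
  }
  d <- diff(cp)
  if (variant == "asymmetric") return(mean(d))
  s <- mean(c(-d[1:2], d[3:4]))
  if (variant == "threshold") {
    if (is.null(mean_cp)) stop("'mean_cp' required for the threshold variant")
    if (mean_cp < 0.5) s <- -s
  }
  s
}

#' One-sided surrogate p-value
#'
#' Fraction of surrogate statistics greater than or equal to the observed one
#' (ties counted as exceeding), the counting definition without add-one
#' smoothing. A smoothed variant (n+1 denominator) is available.
#'
#' @param observed observed statistic.
#' @param surrogate_stats vector of >= 100 surrogate statistics.
#' @param smoothed use (#exceed + 1)/(n + 1) instead of the raw fraction.
#' @return p-value in [0, 1].
#' @export
empirical_pvalue <- function(observed, surrogate_stats, smoothed = FALSE) {
  if (length(surrogate_stats) < 100L)
    stop("need at least 100 surrogate statistics")
  n_ge <- sum(surrogate_stats >= observed)
  if (smoothed) (n_ge + 1) / (length(surrogate_stats) + 1) else
    n_ge / length(surrogate_stats)
}

# ---- internal fast machinery shared by surrogate_test / cluster_significance

# per-cell structure: included levels only (those entering the observed
# profile), with per-level choice counts, weights, bins, and the z pools
.cell_structure <- function(cell_trials, psych, profile, window,
                            min_total, min_per_choice) {
  levels <- sort(unique(cell_trials$coherence))
  p_lev <- predict(psych, levels)
  bins <- .assign_bins(levels, p_lev, profile$epsilon)
  keep <- logical(length(levels))
  np <- nn <- integer(length(levels))
  for (j in seq_along(levels)) {
    np[j] <- sum(cell_trials$coherence == levels[j] & cell_trials$choice == 1)
    nn[j] <- sum(cell_trials$coherence == levels[j] & cell_trials$choice == -1)
    keep[j] <- np[j] >= min_per_choice && nn[j] >= min_per_choice &&
      (np[j] + nn[j]) >= min_total
  }
  pool <- choice_conditioned_zscore(cell_trials, window)
  list(n_pos = np[keep], n_neg = nn[keep], bins = bins[keep],
       wu = ((np + nn) * p_lev * (1 - p_lev))[keep],
       pool_pos = pool$z_pos, pool_neg = pool$z_neg)
}

# 5-bin weighted profile (cp, wu) from per-level CPs
.bin_profile <- function(cp_l, wu_l, bins) {
  cp <- wu <- rep(NA_real_, 5L)
  for (k in 1:5) {
    use <- bins == k
    if (any(use)) {
      wu[k] <- sum(wu_l[use])
      cp[k] <- sum(cp_l[use] * wu_l[use]) / wu[k]
    }
  }
  list(cp = cp, wu = wu)
}

# one surrogate 5-bin profile for one cell structure
.surrogate_profile <- function(st) {
  nl <- length(st$n_pos)
  cp_l <- numeric(nl)
  for (j in seq_len(nl)) {
    x <- st$pool_pos[sample.int(length(st$pool_pos), st$n_pos[j], replace = TRUE)]
    y <- st$pool_neg[sample.int(length(st$pool_neg), st$n_neg[j], replace = TRUE)]
    cp_l[j] <- .cp_rank(x, y)
  }
  .bin_profile(cp_l, st$wu, st$bins)
}

# weighted average of per-cell (cp, wu) profiles
.average_bin_profiles <- function(profs) {
  cpm <- t(vapply(profs, `[[`, numeric(5), "cp"))
  wum <- t(vapply(profs, `[[`, numeric(5), "wu"))
  wu <- colSums(wum)
  list(cp = colSums(cpm * wum) / wu, wu = wu)
}

#' Surrogate test of CP stimulus dependence
#'
#' Tests the observed (group-averaged) CP(pCR) profile against the null of a
#' pCR-independent CP. Cells with complete profiles are selected by CP sign
#' group, their low-information responses are pooled with choice-conditioned
#' z-scoring, and surrogate profiles preserving per-level per-choice trial
#' counts are generated; the delta-CP statistic of the observed average
#' profile is compared with the surrogate distribution.
#'
#' @param trials a trial table (one or several cells).
#' @param psych optional \code{\link{fit_psychometric}} result; by default
#'   fitted from the de-duplicated trials of the table.
#' @param variant statistic variant, see \code{\link{delta_cp_statistic}};
#'   default \code{"threshold"}.
#' @param group \code{"above"}, \code{"below"} or \code{"all"}: which CP-sign
#'   group of cells to test (default \code{"above"}).
#' @param n_surrogates number of surrogates (default 8000; >= 100 required).
#' @param window coherence pooling window, default \code{c(-1.6, 1.6)}.
#' @param seed optional integer seed for reproducible surrogates.
#' @param min_total,min_per_choice level inclusion thresholds.
#' @return list with \code{statistic}, \code{p_value}, \code{n_surrogates},
#'   \code{n_cells}, the observed averaged \code{profile} and the
#'   \code{surrogate_stats}.
#' @export
surrogate_test <- function(trials, psych = NULL, variant = "threshold",
                           group = c("above", "below", "all"),
                           n_surrogates = 8000L, window = c(-1.6, 1.6),
                           seed = NULL, min_total = 15L, min_per_choice = 4L) {
  group <- match.arg(group)
  if (n_surrogates < 100L) stop("'n_surrogates' must be >= 100")
  if (is.null(psych)) {
    uniq <- trials[!duplicated(trials$trial_id), ]
    psych <- fit_psychometric(uniq$coherence, uniq$choice)
  }
  cells <- split(trials, trials$cell_id)
  profiles <- lapply(cells, build_cell_profile, psych = psych,
                     min_total = min_total, min_per_choice = min_per_choice)
  keep <- vapply(profiles, function(p) {
    p$complete && switch(group, above = p$mean_cp >= 0.5,
                         below = p$mean_cp < 0.5, all = TRUE)
  }, logical(1))
  if (!any(keep)) stop("no complete profiles in group '", group, "'")
  cells <- cells[keep]; profiles <- profiles[keep]
  structs <- Map(.cell_structure, cells, profile = profiles,
                 MoreArgs = list(psych = psych, window = window,
                                 min_total = min_total,
                                 min_per_choice = min_per_choice))
  obs_bin <- .average_bin_profiles(
    lapply(profiles, function(p) list(cp = p$cp, wu = p$w_u)))
  mean_cp <- sum(obs_bin$cp * obs_bin$wu) / sum(obs_bin$wu)
  obs_stat <- delta_cp_statistic(obs_bin$cp, variant, mean_cp = mean_cp)
  if (!is.null(seed)) set.seed(seed)
  surr <- vapply(seq_len(n_surrogates), function(b) {
    avg <- .average_bin_profiles(lapply(structs, .surrogate_profile))
    delta_cp_statistic(avg$cp, variant, mean_cp = mean_cp)
  }, numeric(1))
  list(statistic = obs_stat,
       p_value = empirical_pvalue(obs_stat, surr),
       n_surrogates = n_surrogates, n_cells = length(cells),
       profile = obs_bin$cp, surrogate_stats = surr)
}
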