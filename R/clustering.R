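# Discovery of shared CP(pCR) shapes: spherical k-means under cosine
# distance on the centered profiles CP - 0.5, projection onto symmetric /
# asymmetric templates, a 2-D embedding spanned by cluster centers, the
# quadratic asymmetry-slope fit, and surrogate-based cluster significance.

#' k-means clustering of CP profiles under cosine distance
#'
#' Lloyd iterations on the 5-vectors CP - 0.5 with dissimilarity
#' 1 - cosine similarity (spherical k-means: rows are normalized, centers
#' are normalized means of their members). Multiple random restarts; the
#' solution with the smallest total within-cluster dissimilarity is kept.
#' Zero vectors (cosine undefined) are excluded with a warning.
#'
#' @param x numeric matrix (rows = cells, columns = 5 pCR bins of CP - 0.5),
#'   e.g. from \code{\link{profile_matrix}}.
#' @param k number of clusters.
#' @param nstart random restarts (default 100).
#' @param max_iter Lloyd iteration cap per restart.
#' @param seed optional seed; fixed seed gives a deterministic result.
#' @return list with \code{cluster} (assignments, named by rownames),
#'   \code{centers} (k x 5, unit norm), \code{objective} (total cosine
#'   dissimilarity) and \code{excluded} (rownames of zero vectors).
#' @export
kmeans_cosine <- function(x, k, nstart = 100L, max_iter = 100L, seed = NULL) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  excluded <- rownames(x)[nrm == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded), " zero profile(s): cosine undefined")
    x <- x[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  if (nrow(x) < k) stop("need at least k nonzero profiles")
  u <- x / nrm
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- u[sample.int(nrow(u), k), , drop = FALSE]
    assign_old <- rep(0L, nrow(u))
    for (it in seq_len(max_iter)) {
      sim <- u %*% t(centers)
      assign <- max.col(sim, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(assign == j)) {         # re-seed empty cluster at worst point
          worst <- which.min(sim[cbind(seq_len(nrow(u)), assign)])
          assign[worst] <- j
        }
        cm <- colMeans(u[assign == j, , drop = FALSE])
        cn <- sqrt(sum(cm^2))
        if (cn > 0) centers[j, ] <- cm / cn
      }
      if (identical(assign, assign_old)) break
      assign_old <- assign
    }
    obj <- sum(1 - (u %*% t(centers))[cbind(seq_len(nrow(u)), assign)])
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(cluster = stats::setNames(assign, rownames(u)),
                   centers = centers, objective = obj)
  }
  best$excluded <- excluded
  best
}

#' Symmetric / asymmetric template projections of a profile
#'
#' Inner products of CP - 0.5 with two unit-norm templates over the 5 bins:
#' a constant template (the magnitude of CP - 0.5) and a centered linear
#' slope-1 template (the monotone asymmetry). A flat profile has asymmetric
#' score 0; a pure linear profile with mean offset c has symmetric score
#' sqrt(5) c.
#'
#' @param profile a \code{"cp_profile"}, a length-5 CP vector (values around
#'   0.5), or a matrix of centered profiles (rows = cells).
#' @return named vector \code{c(symmetric, asymmetric)}, or a two-column
#'   matrix for matrix input.
#' @export
template_projection <- function(profile) {
  t_sym <- rep(1, 5) / sqrt(5)
  t_asym <- (-2:2) / sqrt(10)
  if (is.matrix(profile))
    return(cbind(symmetric = drop(profile %*% t_sym),
                 asymmetric = drop(profile %*% t_asym)))
  v <- if (inherits(profile, "cp_profile")) profile$cp - 0.5
       else as.numeric(profile) - 0.5
  if (length(v) != 5L) stop("need a 5-bin profile")
  c(symmetric = sum(v * t_sym), asymmetric = sum(v * t_asym))
}

#' Two-dimensional embedding of CP profiles
#'
#' The horizontal axis is the unit direction between the two main cluster
#' centers (closely aligned with CP - 0.5); the vertical axis, computed
#' separately within each main cluster that has subclusters, is the
#' component of its subcluster-center difference orthogonal to the
#' horizontal axis. Profiles are projected (plain inner products) onto both.
#'
#' @param x centered profile matrix (rows = cells).
#' @param main result of \code{\link{kmeans_cosine}} with k = 2 on \code{x}.
#' @param subs named list mapping a main cluster label ("1", "2") to a
#'   \code{\link{kmeans_cosine}} result with k = 2 on that cluster's rows;
#'   clusters without an entry get NA vertical coordinates.
#' @return list with \code{coords} (n x 2), \code{axis_h}, and
#'   \code{axis_v} (per main cluster).
#' @export
embed_2d <- function(x, main, subs = list()) {
  x <- as.matrix(x)
  dc <- main$centers[1, ] - main$centers[2, ]
  if (sqrt(sum(dc^2)) < 1e-12) stop("coincident main cluster centers")
  axis_h <- dc / sqrt(sum(dc^2))
  if (sum(axis_h * colMeans(main$centers)) < 0) axis_h <- -axis_h
  axis_v <- list()
  v_coord <- rep(NA_real_, nrow(x))
  for (lab in names(subs)) {
    sc <- subs[[lab]]$centers
    dv <- sc[1, ] - sc[2, ]
    dv <- dv - sum(dv * axis_h) * axis_h
    if (sqrt(sum(dv^2)) < 1e-12) stop("coincident subcluster centers")
    dv <- dv / sqrt(sum(dv^2))
    axis_v[[lab]] <- dv
    members <- names(main$cluster)[main$cluster == as.integer(lab)]
    idx <- match(members, rownames(x))
    v_coord[idx] <- x[idx, , drop = FALSE] %*% dv
  }
  coords <- cbind(h = drop(x %*% axis_h), v = v_coord)
  rownames(coords) <- rownames(x)
  list(coords = coords, axis_h = axis_h, axis_v = axis_v)
}

#' Quadratic fit of CP against stimulus level
#'
#' Least squares CP(s) = c0 + c1 s + c2 s^2; the linear coefficient c1 is
#' the observed asymmetry slope of the profile (per unit stimulus), the
#' empirical counterpart of the gain-model slope beta_pCR.
#'
#' @param s stimulus levels (>= 4 distinct points).
#' @param cp CP values at those levels.
#' @return the linear coefficient c1, with the full fit as attribute
#'   \code{"coefficients"}.
#' @export
fit_cp_quadratic <- function(s, cp) {
  ok <- !is.na(cp) & !is.na(s)
  s <- s[ok]; cp <- cp[ok]
  if (length(s) < 4L) stop("need at least 4 points")
  X <- cbind(1, s, s^2)
  if (qr(X)$rank < 3L) stop("rank-deficient design (too few distinct levels)")
  beta <- qr.solve(X, cp)
  structure(beta[2], coefficients = stats::setNames(beta, c("c0", "c1", "c2")))
}

#' Surrogate significance of clustered CP(pCR) patterns
#'
#' Repeats the full clustering on surrogate profiles (per cell, preserving
#' per-level per-choice trial counts, see \code{\link{generate_surrogate}}),
#' matches surrogate clusters to the original ones by the sign of their mean
#' CP - 0.5 and center correlation, and compares the delta-CP statistic of
#' each original cluster's average profile with its surrogate distribution.
#'
#' @param trials trial table (several cells).
#' @param psych optional psychometric fit (default: fitted from the table).
#' @param k number of main clusters (default 2).
#' @param variant statistic variant (default "threshold").
#' @param n_surrogates number of surrogate clusterings (default 1000).
#' @param nstart restarts for the observed clustering; surrogate
#'   clusterings use \code{surrogate_nstart} (default 10).
#' @param surrogate_nstart restarts per surrogate clustering.
#' @param window pooling window for the z-scored pools.
#' @param seed optional seed.
#' @param min_total,min_per_choice level inclusion thresholds.
#' @return list with per-cluster \code{statistic}, \code{p_value},
#'   \code{centers}, \code{cluster} assignments and \code{n_surrogates}.
#' @export
cluster_significance <- function(trials, psych = NULL, k = 2L,
                                 variant = "threshold",
                                 n_surrogates = 1000L, nstart = 100L,
                                 surrogate_nstart = 10L,
                                 window = c(-1.6, 1.6), seed = NULL,
                                 min_total = 15L, min_per_choice = 4L) {
  if (is.null(psych)) {
    uniq <- trials[!duplicated(trials$trial_id), ]
    psych <- fit_psychometric(uniq$coherence, uniq$choice)
  }
  cells <- split(trials, trials$cell_id)
  profiles <- lapply(cells, build_cell_profile, psych = psych,
                     min_total = min_total, min_per_choice = min_per_choice)
  keep <- vapply(profiles, function(p) p$complete, logical(1))
  cells <- cells[keep]; profiles <- profiles[keep]
  if (length(cells) < k) stop("need at least k cells with complete profiles")
  if (!is.null(seed)) set.seed(seed)
  X <- profile_matrix(profiles)
  obs <- kmeans_cosine(X, k, nstart = nstart)
  structs <- Map(.cell_structure, cells, profile = profiles,
                 MoreArgs = list(psych = psych, window = window,
                                 min_total = min_total,
                                 min_per_choice = min_per_choice))
  cluster_stat <- function(cp_rows, wu_rows, members) {
    avg <- .average_bin_profiles(Map(function(cp, wu) list(cp = cp, wu = wu),
                                     cp_rows[members], wu_rows[members]))
    m <- sum(avg$cp * avg$wu) / sum(avg$wu)
    delta_cp_statistic(avg$cp, variant, mean_cp = m)
  }
  cp_rows <- lapply(profiles, `[[`, "cp")
  wu_rows <- lapply(profiles, `[[`, "w_u")
  obs_stats <- vapply(seq_len(k), function(j)
    cluster_stat(cp_rows, wu_rows, which(obs$cluster == j)), numeric(1))
  surr_stats <- matrix(NA_real_, n_surrogates, k)
  for (b in seq_len(n_surrogates)) {
    sp <- lapply(structs, .surrogate_profile)
    sx <- t(vapply(sp, `[[`, numeric(5), "cp")) - 0.5
    rownames(sx) <- rownames(X)
    scl <- kmeans_cosine(sx, k, nstart = surrogate_nstart)
    scp <- lapply(sp, `[[`, "cp"); swu <- lapply(sp, `[[`, "wu")
    used <- rep(FALSE, k)
    for (j in seq_len(k)) {
      sgn <- sign(mean(obs$centers[j, ]))
      cand <- which(!used & sign(rowMeans(scl$centers)) == sgn)
      if (!length(cand)) cand <- which(!used)
      m <- cand[which.max(drop(scl$centers[cand, , drop = FALSE] %*%
                                 obs$centers[j, ]))]
      used[m] <- TRUE
      memb <- which(scl$cluster == m)
      if (length(memb))
        surr_stats[b, j] <- cluster_stat(scp, swu, memb)
    }
  }
  p <- vapply(seq_len(k), function(j)
    empirical_pvalue(obs_stats[j], surr_stats[!is.na(surr_stats[, j]), j]),
    numeric(1))
  list(statistic = obs_stats, p_value = p, centers = obs$centers,
       cluster = obs$cluster, n_surrogates = n_surrogates)
}
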