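# Poisson GLMs of spike counts with stimulus-choice interaction terms:
# log mu = sum_{j=0..4} a_j s^j + sum_{j=1..Nc} I_{Pj}(pCR) b_j D, with the
# stimulus entering as a fourth-order polynomial of signed coherence and the
# choice D = +/-1 entering through Nc choice coefficients tied to subsets of
# pCR bins. Models are compared by the cross-validated relative increase in
# likelihood RIL = (L(choice,stimulus) - L(stimulus)) / (L(stimulus) - L0).

#' Partition pCR bins into choice-coefficient levels
#'
#' One-dimensional k-means (exact, by enumeration of contiguous splits in
#' sorted order) on the five bin CPs: bins in the same cluster share a
#' choice coefficient. Groupings need not be contiguous in pCR -- a
#' symmetric profile puts the two extreme bins together -- which is why
#' plain pCR tiling is not used.
#'
#' @param profile a complete \code{"cp_profile"} or a length-5 CP vector.
#' @param n_levels number of choice levels Nc (1, 2 or 3).
#' @return integer vector of length 5 mapping each pCR bin to a choice level
#'   in 1..Nc (labels ordered by increasing group mean CP).
#' @export
partition_choice_levels <- function(profile, n_levels) {
  cp <- if (inherits(profile, "cp_profile")) {
    if (!profile$complete) stop("profile is incomplete")
    profile$cp
  } else as.numeric(profile)
  if (length(cp) != 5L || anyNA(cp)) stop("need a complete 5-bin profile")
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L || n_levels > 5L) stop("'n_levels' must be in 1..5")
  if (n_levels == 1L) return(rep(1L, 5L))
  if (length(unique(cp)) < n_levels)
    stop("fewer distinct CP values than choice levels")
  ord <- order(cp)
  splits <- utils::combn(4L, n_levels - 1L)   # split points in sorted order
  best <- NULL
  for (c in seq_len(ncol(splits))) {
    bounds <- c(0L, splits[, c], 5L)
    ss <- 0; lab <- integer(5L)
    for (j in seq_len(n_levels)) {
      idx <- ord[(bounds[j] + 1L):bounds[j + 1L]]
      ss <- ss + sum((cp[idx] - mean(cp[idx]))^2)
      lab[idx] <- j
    }
    if (is.null(best) || ss < best$ss - 1e-15) best <- list(ss = ss, lab = lab)
  }
  best$lab
}

# design matrix: intercept + s..s^4 (s scaled by its max abs for
# conditioning) and, per model, choice columns I_{Pj} * D
.glm_design <- function(s, choice, group, model, s_scale, n_levels) {
  ss <- s / s_scale
  X <- cbind(1, ss, ss^2, ss^3, ss^4)
  colnames(X) <- paste0("a", 0:4)
  if (model == "stim-indep-choice") {
    X <- cbind(X, b1 = choice)
  } else if (model == "stim-dep-choice") {
    for (j in seq_len(n_levels))
      X <- cbind(X, (group == j) * choice)
    colnames(X)[5L + seq_len(n_levels)] <- paste0("b", seq_len(n_levels))
  } else if (model == "null") {
    X <- X[, 1, drop = FALSE]
  }
  X
}

.poisson_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(stats::dpois(y, exp(eta), log = TRUE))
}

#' Fit a Poisson GLM with optional stimulus-choice interactions
#'
#' Fits one of four nested Poisson log-link models by iteratively
#' reweighted least squares: \code{"null"} (constant rate),
#' \code{"stimulus"} (fourth-order polynomial in signed coherence),
#' \code{"stim-indep-choice"} (adds one choice coefficient), or
#' \code{"stim-dep-choice"} (adds Nc choice coefficients tied to pCR-bin
#' subsets). The stimulus is standardized internally by its maximum absolute
#' level; polynomial coefficients are reported on the raw scale.
#'
#' @param trials data.frame with columns \code{coherence}, \code{choice}
#'   (D in \{-1, +1\}) and \code{count}.
#' @param model model type, see above.
#' @param choice_group integer vector (per trial) mapping each trial to its
#'   choice-coefficient level; required for \code{"stim-dep-choice"}.
#' @param n_levels number of choice levels Nc for the stimulus-dependent
#'   model; default \code{max(choice_group)}.
#' @return An object of class \code{"cp_glm_fit"}: raw-scale stimulus
#'   coefficients \code{a}, choice coefficients \code{b}, \code{loglik}
#'   (training), \code{converged}, and the internal scale, usable with
#'   \code{\link{glm_loglik}}.
#' @export
fit_poisson_glm <- function(trials, model = c("stimulus", "stim-indep-choice",
                                              "stim-dep-choice", "null"),
                            choice_group = NULL, n_levels = NULL) {
  model <- match.arg(model)
  stopifnot(all(trials$choice %in% c(-1, 1)))
  if (model == "stim-dep-choice") {
    if (is.null(choice_group)) stop("'choice_group' required for this model")
    if (is.null(n_levels)) n_levels <- max(choice_group)
  }
  s_scale <- max(abs(trials$coherence), 1e-12)
  X <- .glm_design(trials$coherence, trials$choice, choice_group, model,
                   s_scale, n_levels)
  y <- trials$count
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(),
                   control = list(epsilon = 1e-10, maxit = 100)))
  beta <- stats::setNames(fit$coefficients, colnames(X))
  a_std <- if (model == "null") c(beta[1], rep(0, 4)) else beta[1:5]
  structure(list(
    model = model,
    coefficients = beta,
    a = stats::setNames(a_std / s_scale^(0:4), paste0("a", 0:4)),
    b = beta[grep("^b", names(beta))],
    loglik = .poisson_loglik(beta, X, y),
    converged = fit$converged && all(is.finite(beta)),
    s_scale = s_scale, n_levels = n_levels),
    class = "cp_glm_fit")
}

#' Held-out Poisson log-likelihood of a fitted GLM
#'
#' @param fit a \code{\link{fit_poisson_glm}} result.
#' @param trials evaluation trials (same columns as for fitting).
#' @param choice_group per-trial choice levels (stimulus-dependent model).
#' @return total log-likelihood of \code{trials} under \code{fit}.
#' @export
glm_loglik <- function(fit, trials, choice_group = NULL) {
  X <- .glm_design(trials$coherence, trials$choice, choice_group, fit$model,
                   fit$s_scale, fit$n_levels)
  .poisson_loglik(fit$coefficients, X, trials$count)
}

#' Cross-validated relative increase in likelihood (RIL)
#'
#' Compares the stimulus-only, stimulus-independent-choice and
#' stimulus-dependent-choice GLMs for one cell with choice-balanced
#' cross-validation. Trials are pooled per (choice level, choice) across the
#' stimulus levels sharing a choice coefficient; each repeat draws a
#' training set of 80% of the smaller choice pool from both pools (so the
#' training set is exactly choice-balanced within every level), fits all
#' models on the common training set and evaluates held-out log-likelihood
#' on the common test set. Test log-likelihoods are averaged over repeats
#' and RIL = (L(choice, stimulus) - L(stimulus)) / (L(stimulus) - L0) is
#' computed against the constant-rate null. The stimulus-dependent model is
#' the better of Nc = 2 and Nc = 3 by held-out likelihood; the
#' stimulus-independent RIL is reported from the same split scheme.
#'
#' @param cell_trials trial-table slice for one cell.
#' @param psych a psychometric fit used to bin levels (default: fitted from
#'   the slice).
#' @param profile optional \code{"cp_profile"} of the cell; built if absent.
#'   Must be complete (the Nc partition is derived from it, once per cell).
#' @param n_repeats cross-validation repeats (default 50).
#' @param seed optional master seed; each repeat uses a derived sub-seed.
#' @param min_per_choice minimum trials per choice for a level to enter the
#'   GLM (default 4).
#' @return list with \code{ril_stim_dep}, \code{ril_stim_indep},
#'   \code{nc_selected}, the average held-out log-likelihoods
#'   (\code{L0, L_stim, L_choice_indep, L_choice_dep}), \code{n_repeats}
#'   and \code{partition} (bin to choice level, selected Nc).
#' @export
crossval_ril <- function(cell_trials, psych = NULL, profile = NULL,
                         n_repeats = 50L, seed = NULL, min_per_choice = 4L) {
  if (is.null(psych))
    psych <- fit_psychometric(cell_trials$coherence, cell_trials$choice)
  if (is.null(profile))
    profile <- build_cell_profile(cell_trials, psych)
  if (!profile$complete) stop("complete CP(pCR) profile required")
  levels <- sort(unique(cell_trials$coherence))
  p_lev <- predict(psych, levels)
  bins <- .assign_bins(levels, p_lev, profile$epsilon)
  # drop levels with too few trials per choice
  keep_lev <- vapply(levels, function(s) {
    min(sum(cell_trials$coherence == s & cell_trials$choice == 1),
        sum(cell_trials$coherence == s & cell_trials$choice == -1)) >=
      min_per_choice
  }, logical(1))
  tr <- cell_trials[cell_trials$coherence %in% levels[keep_lev], ]
  bin_of <- stats::setNames(bins, levels)
  if (!is.null(seed)) set.seed(seed)
  eval_nc <- function(nc) {
    part <- partition_choice_levels(profile, nc)
    grp <- part[bin_of[as.character(tr$coherence)]]
    pools <- lapply(seq_len(nc), function(j)
      list(pos = which(grp == j & tr$choice == 1),
           neg = which(grp == j & tr$choice == -1)))
    if (any(vapply(pools, function(p)
      min(length(p$pos), length(p$neg)), numeric(1)) < 5))
      return(NULL)
    ll <- matrix(0, n_repeats, 4,
                 dimnames = list(NULL, c("null", "stim", "indep", "dep")))
    n_test <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      train_idx <- unlist(lapply(pools, function(p) {
        n_tr <- floor(0.8 * min(length(p$pos), length(p$neg)))
        c(sample(p$pos, n_tr), sample(p$neg, n_tr))
      }))
      test_idx <- setdiff(seq_len(nrow(tr)), train_idx)
      if (!length(test_idx)) { ll[r, ] <- NA; next }
      trn <- tr[train_idx, ]; tst <- tr[test_idx, ]
      for (m in c("null", "stimulus", "stim-indep-choice", "stim-dep-choice")) {
        f <- fit_poisson_glm(trn, m, choice_group = grp[train_idx],
                             n_levels = nc)
        col <- switch(m, null = "null", stimulus = "stim",
                      `stim-indep-choice` = "indep", `stim-dep-choice` = "dep")
        ll[r, col] <- glm_loglik(f, tst, choice_group = grp[test_idx])
      }
      n_test[r] <- length(test_idx)
    }
    # per-trial average held-out log-likelihood over repeats
    ok <- stats::complete.cases(ll)
    list(part = part,
         L = colSums(ll[ok, , drop = FALSE]) / sum(n_test[ok]))
  }
  res <- list(`2` = eval_nc(2L), `3` = eval_nc(3L))
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    stop("every choice-level group needs at least 5 trials per choice")
  pick <- which.max(vapply(res, function(x) x$L["dep"], numeric(1)))
  L <- res[[pick]]$L
  denom <- L["stim"] - L["null"]
  ril <- function(num) if (denom > 0) unname(num / denom) else NA_real_
  list(ril_stim_dep = ril(L["dep"] - L["stim"]),
       ril_stim_indep = ril(L["indep"] - L["stim"]),
       nc_selected = as.integer(names(res)[pick]),
       L0 = unname(L["null"]), L_stim = unname(L["stim"]),
       L_choice_indep = unname(L["indep"]), L_choice_dep = unname(L["dep"]),
       n_repeats = n_repeats, partition = res[[pick]]$part)
}

#' Summarize RIL values per group
#'
#' @param ril numeric vector of per-cell RIL values.
#' @param group optional grouping factor (e.g. cluster labels).
#' @param threshold RIL threshold for the exceedance proportion
#'   (default 0.1).
#' @return data.frame with one row per group: \code{n}, \code{mean_ril},
#'   \code{prop_above}. Empty groups are omitted.
#' @export
ril_summary <- function(ril, group = NULL, threshold = 0.1) {
  if (is.null(group)) group <- rep("all", length(ril))
  out <- do.call(rbind, lapply(split(ril, group), function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    data.frame(n = length(x), mean_ril = mean(x),
               prop_above = mean(x > threshold))
  }))
  cbind(group = rownames(out), out, row.names = NULL)
}
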