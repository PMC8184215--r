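# Trial-table I/O, JSON run configuration, and the end-to-end pipeline.
# The native data format is tab-delimited text with header
# cell_id, trial_id, coherence, choice, count; configs and summary outputs
# are JSON sidecars.

.trial_cols <- c("cell_id", "trial_id", "coherence", "choice", "count")

#' Read a trial table
#'
#' @param path path to a delimited text file with header columns
#'   \code{cell_id, trial_id, coherence, choice, count}.
#' @param sep field separator (default tab).
#' @return validated trial-table data.frame.
#' @export
read_trial_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty trial table: ", path)
  if (!all(.trial_cols %in% names(tab)))
    stop("header must contain: ", paste(.trial_cols, collapse = ", "))
  tab <- tab[, .trial_cols]
  bad <- which(!tab$choice %in% c(-1, 1))
  if (length(bad))
    stop("invalid choice value (must be -1 or +1) at data line ", bad[1])
  if (any(!is.finite(tab$count)))
    stop("non-finite count at data line ", which(!is.finite(tab$count))[1])
  bad <- which(tab$count < 0 | abs(tab$count - round(tab$count)) > 1e-8)
  if (length(bad))
    stop("count must be a non-negative integer at data line ", bad[1])
  tab$count <- as.integer(round(tab$count))
  tab$choice <- as.integer(tab$choice)
  tab
}

#' Write a trial table
#'
#' @param trials trial-table data.frame.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_trial_table <- function(trials, path, sep = "\t") {
  utils::write.table(trials[, .trial_cols], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' @param path JSON file; see \code{\link{run_pipeline}} for the recognized
#'   blocks.
#' @return config list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> psychometric fit -> per-cell CP(pCR) profiles ->
#' surrogate significance tests per CP-sign group -> cosine k-means
#' clustering with template projections and quadratic slopes -> GLM RIL per
#' cell. All outputs are plain text (TSV/JSON) under \code{out_dir}; a
#' provenance record (config, seed, package version) accompanies them. A run
#' is reproducible from config + seed alone.
#'
#' @param config a config list or path to a JSON file. Recognized blocks
#'   (all optional): \code{seed}; \code{input} (path to a trial table;
#'   absent means simulate); \code{simulate} (\code{sigma_g2},
#'   \code{coherences}, \code{trials_per_level}); \code{profiles}
#'   (\code{min_total}, \code{min_per_choice}); \code{test}
#'   (\code{variant}, \code{n_surrogates}, \code{window}); \code{cluster}
#'   (\code{k}, \code{nstart}); \code{glm} (\code{enabled},
#'   \code{n_repeats}, \code{max_cells}).
#' @param out_dir output directory (created if missing); \code{NULL}
#'   disables file output.
#' @return (invisibly) a list with the trial table, profiles, test results,
#'   clustering and GLM summaries.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  set.seed(seed)
  blk <- function(name) if (is.null(config[[name]])) list() else config[[name]]
  # --- data
  if (!is.null(config$input)) {
    trials <- read_trial_table(config$input)
  } else {
    sim <- blk("simulate")
    enc <- NULL
    if (!is.null(sim$sigma_g2)) {
      cfg0 <- simulation_config()
      enc <- population_encoding(cfg0$enc$f0, cfg0$enc$fprime0,
                                 sigma_g2 = sim$sigma_g2)
    }
    cfg <- simulation_config(
      enc = enc,
      coherences = sim$coherences,
      trials_per_level = sim$trials_per_level,
      seed = seed)
    trials <- simulate_trials(cfg)
  }
  uniq <- trials[!duplicated(trials$trial_id), ]
  psych <- fit_psychometric(uniq$coherence, uniq$choice)
  # --- profiles
  pb <- blk("profiles")
  min_total <- if (is.null(pb$min_total)) 15L else pb$min_total
  min_pc <- if (is.null(pb$min_per_choice)) 4L else pb$min_per_choice
  cells <- split(trials, trials$cell_id)
  profiles <- lapply(cells, build_cell_profile, psych = psych,
                     min_total = min_total, min_per_choice = min_pc)
  complete <- vapply(profiles, `[[`, logical(1), "complete")
  # --- surrogate tests per group
  tb <- blk("test")
  n_surr <- if (is.null(tb$n_surrogates)) 1000L else tb$n_surrogates
  variant <- if (is.null(tb$variant)) "threshold" else tb$variant
  window <- if (is.null(tb$window)) c(-1.6, 1.6) else tb$window
  tests <- list()
  for (g in c("above", "below")) {
    in_group <- vapply(profiles, function(p)
      p$complete && ((p$mean_cp >= 0.5) == (g == "above")), logical(1))
    if (any(in_group)) {
      tests[[g]] <- surrogate_test(
        trials[trials$cell_id %in% names(profiles)[in_group], ],
        psych = psych, variant = variant, group = g,
        n_surrogates = n_surr, window = window,
        min_total = min_total, min_per_choice = min_pc)
      tests[[g]]$surrogate_stats <- NULL
    }
  }
  # --- clustering
  cb <- blk("cluster")
  k <- if (is.null(cb$k)) 2L else cb$k
  nstart <- if (is.null(cb$nstart)) 100L else cb$nstart
  clustering <- NULL
  if (sum(complete) >= k) {
    X <- profile_matrix(profiles[complete])
    clustering <- kmeans_cosine(X, k, nstart = nstart)
    clustering$templates <- template_projection(X)
    slopes <- vapply(names(cells)[complete], function(id) {
      tr <- cells[[id]]
      lev <- sort(unique(tr$coherence))
      cp_l <- vapply(lev, function(s) {
        e <- estimate_cp(tr$count[tr$coherence == s & tr$choice == 1],
                         tr$count[tr$coherence == s & tr$choice == -1],
                         p_cr = predict(psych, s),
                         min_total = min_total, min_per_choice = min_pc)
        if (e$excluded) NA_real_ else e$cp
      }, numeric(1))
      if (sum(!is.na(cp_l)) >= 4) unname(fit_cp_quadratic(lev, cp_l))
      else NA_real_
    }, numeric(1))
    clustering$quadratic_slope <- slopes
  }
  # --- GLM
  gb <- blk("glm")
  glm_res <- NULL
  if (is.null(gb$enabled) || isTRUE(gb$enabled)) {
    n_rep <- if (is.null(gb$n_repeats)) 50L else gb$n_repeats
    ids <- names(cells)[complete]
    if (!is.null(gb$max_cells)) ids <- utils::head(ids, gb$max_cells)
    glm_res <- lapply(ids, function(id) {
      r <- tryCatch(
        crossval_ril(cells[[id]], psych = psych, profile = profiles[[id]],
                     n_repeats = n_rep),
        error = function(e) NULL)
      if (is.null(r)) return(NULL)
      list(cell_id = id, ril_stim_dep = r$ril_stim_dep,
           ril_stim_indep = r$ril_stim_indep, nc = r$nc_selected)
    })
    glm_res <- Filter(Negate(is.null), glm_res)
  }
  bundle <- list(trials = trials, psych = psych, profiles = profiles,
                 tests = tests, clustering = clustering, glm = glm_res,
                 seed = seed)
  # --- outputs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(trials, file.path(out_dir, "trials.tsv"))
    prof_rows <- do.call(rbind, lapply(profiles[complete], function(p)
      data.frame(cell_id = p$cell_id, bin = 1:5, bin_pcr = p$bin_pcr,
                 cp = p$cp, sem = p$sem)))
    utils::write.table(prof_rows, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(tests, function(t) t[c("statistic", "p_value", "n_surrogates",
                                    "n_cells")]),
      file.path(out_dir, "test.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(clustering)) {
      cl_rows <- data.frame(cell_id = names(clustering$cluster),
                            cluster = clustering$cluster,
                            symmetric = clustering$templates[, "symmetric"],
                            asymmetric = clustering$templates[, "asymmetric"],
                            quadratic_slope = clustering$quadratic_slope)
      utils::write.table(cl_rows, file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(glm_res))
      jsonlite::write_json(glm_res, file.path(out_dir, "glm.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = seed, config = config,
           package = as.character(utils::packageVersion("cpstim")),
           r_version = R.version.string),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  invisible(bundle)
}
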