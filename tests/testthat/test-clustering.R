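test_that("cosine k-means separates CP-sign groups and noise-free shape fixtures", {
  set.seed(83)
  up <- matrix(rep(c(0.10, 0.05, 0.03, 0.05, 0.10), 6), 6, byrow = TRUE) +
    rnorm(30, 0, 0.004)
  dn <- matrix(rep(c(-0.08, -0.04, -0.02, -0.04, -0.08), 5), 5, byrow = TRUE) +
    rnorm(25, 0, 0.004)
  X <- rbind(up, dn); rownames(X) <- paste0("c", 1:11)
  km <- kmeans_cosine(X, 2, nstart = 30, seed = 1)
  expect_equal(length(unique(km$cluster[1:6])), 1L)
  expect_equal(length(unique(km$cluster[7:11])), 1L)
  expect_false(km$cluster[1] == km$cluster[11])
  # symmetric vs asymmetric noise-free shapes separate perfectly
  sym <- (h_factor(c(0.15, 0.4, 0.5, 0.6, 0.85)) - 1) + 0.02
  asym <- 0.02 * (-2:2) + 0.02
  Y <- rbind(t(replicate(4, sym)), t(replicate(4, asym)))
  rownames(Y) <- paste0("y", 1:8)
  km2 <- kmeans_cosine(Y, 2, nstart = 30, seed = 2)
  expect_equal(length(unique(km2$cluster[1:4])), 1L)
  expect_equal(length(unique(km2$cluster[5:8])), 1L)
  expect_false(km2$cluster[1] == km2$cluster[8])
  # duplicated profiles always share a cluster, whatever the seed
  for (s in c(10, 20)) {
    km3 <- kmeans_cosine(Y, 2, nstart = 10, seed = s)
    expect_equal(unname(km3$cluster[1]), unname(km3$cluster[2]))
  }
  # zero rows are excluded with a warning
  Z <- rbind(Y, y9 = rep(0, 5))
  expect_warning(km4 <- kmeans_cosine(Z, 2, nstart = 5, seed = 1), "zero")
  expect_equal(km4$excluded, "y9")
})

test_that("cosine k-means objective is optimal for the fixtures and deterministic", {
  set.seed(89)
  X <- rbind(t(replicate(5, c(0.1, 0.05, 0.02, 0.05, 0.1))),
             t(replicate(5, c(-0.02, 0, 0.02, 0.04, 0.06)))) +
    rnorm(50, 0, 0.003)
  rownames(X) <- paste0("p", 1:10)
  a <- kmeans_cosine(X, 2, nstart = 50, seed = 7)
  b <- kmeans_cosine(X, 2, nstart = 50, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_equal(a$objective, b$objective)
  # centers are unit vectors
  expect_equal(unname(rowSums(a$centers^2)), c(1, 1), tolerance = 1e-10)
})

test_that("template projections: orthogonality and hand-computed scores", {
  expect_equal(unname(template_projection(rep(0.57, 5))["asymmetric"]), 0,
               tolerance = 1e-12)
  # pure linear profile: symmetric score is sqrt(5) times the mean offset
  lin <- 0.55 + 0.01 * (-2:2)
  expect_equal(unname(template_projection(lin)["symmetric"]), sqrt(5) * 0.05,
               tolerance = 1e-12)
  expect_equal(unname(template_projection(lin)["asymmetric"]),
               0.01 * sqrt(10), tolerance = 1e-12)
  # an h-shaped symmetric profile has (near-)zero asymmetric score
  hprof <- 0.5 + 0.05 * h_factor(c(0.15, 0.4, 0.5, 0.6, 0.85))
  expect_lt(abs(template_projection(hprof)["asymmetric"]), 1e-10)
  # scores are linear in the profile
  a <- template_projection(lin); b <- template_projection(hprof)
  expect_equal(template_projection((lin - 0.5) + (hprof - 0.5) + 0.5), a + b,
               tolerance = 1e-12)
})

test_that("template scores order the gain-model predictions as expected", {
  grid <- c(0.12, 0.35, 0.5, 0.65, 0.88)
  enc_hi <- population_encoding(10, 0.25, sigma_base = diag(10, 1),
                                sigma_g2 = 0.1)
  enc_lo <- population_encoding(10, 0.25, sigma_base = diag(10, 1),
                                sigma_g2 = 0.01)
  # single-neuron readout: CC = 1 is out of the linear regime, so use a
  # population context with one high-gain member
  mk <- function(sg2) {
    enc <- population_encoding(c(10, 12, 11, 13), c(0.3, -0.3, 0.28, -0.28),
                               sigma_g2 = sg2)
    cp_profile_prediction(enc, 1, grid)$cp
  }
  t_hi <- template_projection(mk(0.1))
  t_lo <- template_projection(mk(0.01))
  expect_gt(t_hi["asymmetric"], t_lo["asymmetric"])
  # larger CC -> larger symmetric score (no gain, scaled tuning)
  mk_cc <- function(fp) {
    enc <- population_encoding(c(10, 12, 11, 13), c(fp, -0.3, 0.28, -0.28),
                               sigma_g2 = 0)
    cp_profile_prediction(enc, 1, grid)$cp
  }
  expect_gt(template_projection(mk_cc(0.5))["symmetric"],
            template_projection(mk_cc(0.2))["symmetric"])
})

test_that("2-D embedding recovers constructed axes and preserves inner products", {
  set.seed(97)
  dir_main <- c(1, 1, 1, 1, 1) / sqrt(5)
  dir_sub <- (-2:2) / sqrt(10)
  mk_rows <- function(center, n, eps = 0.001)
    t(replicate(n, center + rnorm(5, 0, eps)))
  X <- rbind(mk_rows(0.1 * dir_main + 0.02 * dir_sub, 5),
             mk_rows(0.1 * dir_main - 0.02 * dir_sub, 5),
             mk_rows(-0.1 * dir_main, 6))
  rownames(X) <- paste0("e", 1:16)
  main <- kmeans_cosine(X, 2, nstart = 30, seed = 3)
  lab_up <- unname(main$cluster[1])
  sub <- kmeans_cosine(X[main$cluster == lab_up, , drop = FALSE], 2,
                       nstart = 30, seed = 4)
  emb <- embed_2d(X, main, stats::setNames(list(sub), lab_up))
  # horizontal axis within 5 degrees of the constructed main direction
  ang_h <- acos(min(abs(sum(emb$axis_h * dir_main)), 1)) * 180 / pi
  expect_lt(ang_h, 5)
  ang_v <- acos(min(abs(sum(emb$axis_v[[as.character(lab_up)]] * dir_sub)), 1)) *
    180 / pi
  expect_lt(ang_v, 5)
  # projections are plain inner products with the axis vectors
  expect_equal(emb$coords[, "h"], drop(X %*% emb$axis_h), tolerance = 1e-10)
  idx <- which(main$cluster == lab_up)
  expect_equal(emb$coords[idx, "v"],
               drop(X[idx, ] %*% emb$axis_v[[as.character(lab_up)]]),
               tolerance = 1e-10)
})

test_that("quadratic CP regression extracts the linear asymmetry coefficient", {
  s <- c(-6.4, -3.2, -1.6, 0, 1.6, 3.2, 6.4)
  expect_equal(as.numeric(fit_cp_quadratic(s, 0.5 + 0.001 * s^2)), 0,
               tolerance = 1e-10)
  expect_equal(as.numeric(fit_cp_quadratic(s, 0.5 + 0.01 * s)), 0.01,
               tolerance = 1e-12)
  expect_equal(as.numeric(fit_cp_quadratic(s, 0.52 + 0.007 * s - 0.002 * s^2)),
               0.007, tolerance = 1e-10)
  expect_error(fit_cp_quadratic(s[1:3], c(0.5, 0.5, 0.5)), "at least 4")
  expect_error(fit_cp_quadratic(rep(1, 5), rep(0.5, 5)), "rank")
})

test_that("cluster significance is invariant to label permutations and flags a real effect", {
  set.seed(103)
  lev_pcr <- c(0.12, 0.3, 0.42, 0.5, 0.58, 0.7, 0.88)
  lev <- qnorm(lev_pcr) * 8
  mk_cell <- function(id, rho) {
    rows <- lapply(seq_along(lev), function(i) {
      sim <- sim_bvn_threshold(rho, lev_pcr[i], 250)
      data.frame(cell_id = id, trial_id = paste(id, i, seq_len(250)),
                 coherence = lev[i], choice = sim$D, count = sim$r)
    })
    do.call(rbind, rows)
  }
  tab <- rbind(do.call(rbind, lapply(sprintf("p%02d", 1:6), mk_cell, rho = 0.45)),
               do.call(rbind, lapply(sprintf("n%02d", 1:4), mk_cell, rho = -0.45)))
  ps <- fit_psychometric(tab$coherence[tab$cell_id == "p01"],
                         tab$choice[tab$cell_id == "p01"])
  res <- cluster_significance(tab, psych = ps, k = 2, n_surrogates = 200,
                              nstart = 20, surrogate_nstart = 5, seed = 9)
  expect_length(res$p_value, 2L)
  # the k = 2 split recovers the CP-sign groups
  signs <- sign(rowMeans(res$centers))
  expect_setequal(signs, c(-1, 1))
  memb_sign <- signs[res$cluster]
  is_pos_cell <- startsWith(names(res$cluster), "p")
  expect_true(all(memb_sign[is_pos_cell] == 1))
  expect_true(all(memb_sign[!is_pos_cell] == -1))
  # the threshold-induced modulation is strong enough to reject for the
  # larger positive-CP cluster
  pos_cl <- which(signs == 1)
  expect_lt(res$p_value[pos_cl], 0.05)
})
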