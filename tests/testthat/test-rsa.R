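test_that("RSA Spearman correlation matches a rank-then-Pearson oracle", {
  set.seed(1)
  m <- as_rsm(tcrossprod(matrix(rnorm(20), 4, 5)) / 5)
  expect_equal(rsa_correlation(m, m), 1)
  expect_equal(rsa_correlation(m, as_rsm(-as.matrix(m))), -1)
  model <- as_rsm(tcrossprod(matrix(rnorm(20), 4, 5)) / 5)
  a <- as.matrix(m)[upper.tri(diag(4), diag = TRUE)]
  b <- as.matrix(model)[upper.tri(diag(4), diag = TRUE)]
  expect_equal(rsa_correlation(m, model), cor(rank(a), rank(b)),
               tolerance = 1e-12)
  # diagonal exclusion changes the support
  a2 <- as.matrix(m)[upper.tri(diag(4))]
  b2 <- as.matrix(model)[upper.tri(diag(4))]
  expect_equal(rsa_correlation(m, model, include_diagonal = FALSE),
               cor(rank(a2), rank(b2)), tolerance = 1e-12)
  expect_error(rsa_correlation(as_rsm(matrix(1, 3, 3)), model[1:3, 1:3]),
               "constant")
})

test_that("partial RSA equals plain RSA with no covariates and matches its oracle", {
  set.seed(2)
  m <- as_rsm(tcrossprod(matrix(rnorm(30), 5, 6)) / 6)
  model <- as_rsm(tcrossprod(matrix(rnorm(30), 5, 6)) / 6)
  expect_equal(partial_rsa(m, model), rsa_correlation(m, model),
               tolerance = 1e-12)
  cov1 <- as_rsm(tcrossprod(matrix(rnorm(30), 5, 6)) / 6)
  cov2 <- as_rsm(tcrossprod(matrix(rnorm(30), 5, 6)) / 6)
  got <- partial_rsa(m, model, list(cov1, cov2))
  # explicit residual-regression oracle on ranks
  sel <- upper.tri(diag(5), diag = TRUE)
  ra <- rank(as.matrix(m)[sel]); rb <- rank(as.matrix(model)[sel])
  Z <- cbind(1, rank(as.matrix(cov1)[sel]), rank(as.matrix(cov2)[sel]))
  res_a <- ra - Z %*% solve(t(Z) %*% Z, t(Z) %*% ra)
  res_b <- rb - Z %*% solve(t(Z) %*% Z, t(Z) %*% rb)
  expect_equal(got, cor(res_a, res_b)[1, 1], tolerance = 1e-8)
  # degenerate covariates are dropped with a warning
  expect_warning(p2 <- partial_rsa(m, model, list(as_rsm(matrix(1, 5, 5)))),
                 "degenerate")
  expect_equal(p2, rsa_correlation(m, model), tolerance = 1e-12)
})

test_that("partial semantic correlation vanishes when only perceptual signal exists", {
  perc <- perceptual_rsms(render_stimulus_images(default_set, seed = 3)$features)
  catm <- categorical_rsms(default_set)
  mx <- ground_truth_mixture(list(as.matrix(perc$size),
                                  as.matrix(perc$elongation)),
                             c(1, 1), individual_sd = 0.3,
                             session_sd = 0.2, noise_sd = 0.5)
  # diagonal excluded: the same-condition diagonal is constant within every
  # model (perceptual 1, semantic 0) so it carries no model contrast, and
  # its reliability signal cannot be residualized away by any covariate
  rhos <- vapply(1:4, function(k) {
    co <- simulate_patterns(default_set, mx, 20, 1, 300, seed = 30 + k)
    g <- as.matrix(group_rsm(cohort_pair_rsms(co)$rsms))
    partial_rsa(g, as.matrix(catm$category), lapply(perc, as.matrix),
                include_diagonal = FALSE)
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.06)
})

test_that("importance weights implement the binned density-ratio rule", {
  src <- c(rep(0.1, 10), rep(1.0, 10))
  # target identical to source: uniform weights
  iw <- importance_weights(src, src, n_bins = 2)
  expect_equal(iw$weights, rep(1 / 20, 20))
  # a bin with twice the source density of the target gets half weight
  src2 <- c(rep(0.1, 20), rep(1.0, 10))
  tgt2 <- c(rep(0.1, 10), rep(1.0, 10))
  iw2 <- importance_weights(src2, tgt2, edges = 0.5)
  w_low <- iw2$weights[1]; w_high <- iw2$weights[21]
  expect_equal(w_low / w_high, 0.5, tolerance = 1e-12)
  # source units in bins absent from the target get zero weight
  src3 <- c(rep(0.1, 10), rep(10, 5))
  tgt3 <- rep(0.1, 10)
  iw3 <- importance_weights(src3, tgt3, edges = 5)
  expect_true(all(iw3$weights[11:15] == 0))
  expect_error(importance_weights(numeric(0), tgt3), "non-empty")
  expect_error(importance_weights(rep(10, 5), rep(0.001, 5), n_bins = 2),
               "overlap")
})

test_that("reweighted resampling matches the target motion distribution", {
  set.seed(7)
  src <- rlnorm(400, log(0.912) - 0.32, 0.8)   # infant-like motion
  tgt <- rlnorm(400, log(0.177) - 0.32, 0.8)   # adult-like target
  tgt <- tgt[tgt <= max(src)]
  iw <- importance_weights(src, tgt)
  wmean <- sum(iw$weights * src)
  expect_lt(abs(wmean - mean(tgt)) / mean(tgt), 0.1)
})

test_that("bootstrap machinery: distribution shape, degenerate and weighted cases", {
  set.seed(8)
  v <- as.vector(tcrossprod(matrix(rnorm(20), 4, 5)) / 5)
  rsms_same <- matrix(v, 16, 10)   # all units identical
  M <- matrix(rnorm(16), 4, 4); M <- M + t(M)
  stat <- function(m) rsa_correlation(m, M)
  br <- bootstrap_statistic(rsms_same, stat, n_boot = 50, seed = 1)
  expect_equal(br$ci[1], br$ci[2])
  expect_equal(br$ci[1], br$point)
  expect_equal(length(br$dist), 50)
  # uniform explicit weights reproduce the unweighted draws exactly
  rsms <- rsms_same + matrix(rnorm(160, sd = 0.1), 16, 10)
  b1 <- bootstrap_statistic(rsms, stat, n_boot = 40, seed = 2)
  b2 <- bootstrap_statistic(rsms, stat, n_boot = 40, seed = 2,
                            weights = rep(0.1, 10))
  expect_identical(b1$dist, b2$dist)
  # excluded units never enter
  rsms_flag <- cbind(rsms, matrix(99, 16, 2))
  b3 <- bootstrap_statistic(rsms_flag, stat, n_boot = 40, seed = 2,
                            exclude = c(rep(FALSE, 10), TRUE, TRUE))
  expect_identical(b3$dist, b1$dist)
  expect_error(bootstrap_statistic(rsms[, 1, drop = FALSE], stat), "2 sampling")
})

test_that("group differences flag disjoint but not identical distributions", {
  a <- structure(list(point = 0.5, dist = rnorm(200, 0.5, 0.01)),
                 class = "bootstrap_result")
  same <- group_difference(a, a)
  expect_false(same$significant)
  b <- structure(list(point = 0.2, dist = rnorm(200, 0.2, 0.01)),
                 class = "bootstrap_result")
  diff_ab <- group_difference(a, b)
  expect_true(diff_ab$significant)
  expect_gt(diff_ab$ci[1], 0)
})

test_that("age-dependent animacy weights produce a significant group contrast", {
  catm <- categorical_rsms(default_set)
  mk <- function(w_anim, seed, group)
    simulate_patterns(default_set, ground_truth_mixture(
      list(as.matrix(catm$category), as.matrix(catm$animacy_tripartite)),
      c(0.6, w_anim), noise_sd = 1), 14, 1, 250, seed = seed, group = group)
  co_young <- mk(0.2, 41, "infant2mo")
  co_old <- mk(0.55, 42, "adult")
  M <- as.matrix(catm$animacy_tripartite)
  stat <- function(m) rsa_correlation(m, M)
  ps_y <- cohort_pair_rsms(co_young); ps_o <- cohort_pair_rsms(co_old)
  b_y <- bootstrap_statistic(ps_y$rsms, stat, n_boot = 200, seed = 1,
                             pair_subjects = pair_subject_frame(ps_y))
  b_o <- bootstrap_statistic(ps_o$rsms, stat, n_boot = 200, seed = 2,
                             pair_subjects = pair_subject_frame(ps_o))
  d <- group_difference(b_o, b_y)
  expect_true(d$significant)
  expect_gt(d$point, 0)
})

test_that("ceiling normalization divides when valid and passes through when not", {
  nz <- normalize_by_ceiling(0.3, 0.6)
  expect_equal(nz$value, 0.5)
  expect_true(nz$normalized)
  expect_equal(normalize_by_ceiling(0.42, 1)$value, 0.42)
  low <- normalize_by_ceiling(0.05, 0.03)
  expect_equal(low$value, 0.05)
  expect_false(low$normalized)
  nc <- structure(list(corrected = 0.5, valid = TRUE), class = "noise_ceiling")
  expect_equal(normalize_by_ceiling(0.25, nc)$value, 0.5)
})

test_that("maturity correlation tracks shared structure monotonically", {
  # two realizable (PSD) representational geometries: one shared with the
  # adult reference, one idiosyncratic
  set.seed(49)
  R_adult <- cor(matrix(rnorm(12 * 36), 12, 36))
  R_other <- cor(matrix(rnorm(12 * 36), 12, 36))
  rho <- vapply(c(0, 0.5, 2), function(w) {
    mx <- ground_truth_mixture(list(R_adult, R_other), c(w, 1),
                               individual_sd = 0.3, session_sd = 0.2,
                               noise_sd = 0.7)
    co <- simulate_patterns(default_set, mx, 10, 1, 250, seed = 50 + w * 10)
    ps <- cohort_pair_rsms(co)
    maturity_correlation(ps$rsms, R_adult, n_boot = 50, seed = 3)$point
  }, numeric(1))
  expect_lt(abs(rho[1]), 0.15)
  expect_true(all(diff(rho) > 0))
  expect_gt(rho[3], 0.6)
})

test_that("longitudinal permutation test detects identity and respects add-one", {
  lg <- simulate_longitudinal_rsms(10, 12, self_weight = 10, seed = 60)
  lg$t2 <- lg$t1   # exact copies: maximal self-consistency
  out <- longitudinal_permutation_test(lg$t1, lg$t2, n_perm = 1000, seed = 4)
  expect_lte(out$p_value, 0.01)
  expect_gte(out$p_value, 1 / 1001)
  expect_error(longitudinal_permutation_test(lg$t1, lg$t2,
                                             links = c(1, 1, 2:9),
                                             n_perm = 10), "duplicate")
  expect_error(longitudinal_permutation_test(lg$t1[1:3], lg$t2[1:3],
                                             n_perm = 10), "5 linked")
})

test_that("regression RSA recovers mixture weight ordering", {
  catm <- categorical_rsms(default_set)
  mods <- list(category = as.matrix(catm$category),
               animacy = as.matrix(catm$animacy_tripartite))
  mx <- ground_truth_mixture(mods, c(1, 0.5), noise_sd = 1)
  co <- simulate_patterns(default_set, mx, 16, 1, 300, seed = 70)
  en <- enumerate_pairs(co, "run")
  covs <- lapply(seq_len(nrow(en$pairs)), function(i)
    as.matrix(covariance_rsm(
      devrsa:::unit_patterns(co, en$units[en$pairs$a[i], ]),
      devrsa:::unit_patterns(co, en$units[en$pairs$b[i], ]))))
  gcov <- Reduce(`+`, covs) / length(covs)
  w <- recover_mixture_weights(gcov, mods)
  expect_gt(w["category"], w["animacy"])
  expect_gt(w["animacy"], 0)
})
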