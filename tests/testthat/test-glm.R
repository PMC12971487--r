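test_that("motion censoring and run QC apply the thresholds", {
  qc <- censor_and_qc(c(0.1, 2.0, 0.3), fwd_threshold = 1.5)
  expect_equal(qc$n_censored, 1)
  expect_true(qc$accepted)
  expect_equal(qc$censor_mask, c(FALSE, TRUE, FALSE))
  expect_false(censor_and_qc(rep(2, 50))$accepted)
  qc0 <- censor_and_qc(rep(0, 50))
  expect_equal(qc0$n_censored, 0)
  expect_true(qc0$accepted)
  # boundary: exactly half censored is still accepted
  expect_true(censor_and_qc(rep(c(0, 9), 10))$accepted)
  expect_error(censor_and_qc(numeric(0)), "empty")
  expect_error(censor_and_qc(c(1, 2), fwd_threshold = 0), "positive")
})

test_that("design matrices have the right columns and roles", {
  ev <- make_events(default_set, 2, seed = 2)
  dm <- build_design_matrix(ev, tr = 0.61, n_frames = 510)
  expect_equal(sum(dm$roles == "condition"), 36)
  expect_equal(sum(dm$roles == "spike"), 0)
  expect_equal(sum(dm$roles == "intercept"), 1)
  expect_equal(sum(dm$roles == "trend"), 1)
  # 0.01 Hz cutoff over a 311 s run spans 6 cosine regressors
  expect_equal(sum(dm$roles == "cosine"), floor(2 * 510 * 0.61 * 0.01))
  cm <- rep(FALSE, 510); cm[c(5, 100, 101)] <- TRUE
  mp <- matrix(rnorm(510 * 6), 510, 6)
  dm2 <- build_design_matrix(ev, tr = 0.61, n_frames = 510,
                             censor_mask = cm, motion_params = mp)
  expect_equal(sum(dm2$roles == "spike"), 3)
  expect_equal(sum(dm2$roles == "motion"), 6)
  spikes <- dm2$X[, dm2$roles == "spike", drop = FALSE]
  expect_true(all(colSums(spikes) == 1))
  expect_true(all(spikes[cm, ] == diag(3)))
  expect_error(build_design_matrix(ev, tr = 0.1, n_frames = 100),
               "mismatch|exceed")
})

test_that("a stimulus at t=0 drives a response peaking near six seconds", {
  ev1 <- data.frame(onset = 0, duration = 3, trial_type = "a", run = 1L)
  class(ev1) <- c("event_table", "data.frame")
  d1 <- build_design_matrix(ev1, tr = 0.61, n_frames = 100,
                            conditions = "a")
  peak_s <- (which.max(d1$X[, 1]) - 1) * 0.61
  expect_gt(peak_s, 4.5)
  expect_lt(peak_s, 8)
})

test_that("OLS matches the brute-force normal-equations oracle", {
  set.seed(31)
  ev <- make_events(make_stimulus_set(1, 1, 4), n_repetitions = 3,
                    soa_range = c(3.5, 4.5), seed = 3)
  n_frames <- 60; tr <- 1
  dm <- build_design_matrix(ev, tr = tr, n_frames = n_frames)
  Y <- matrix(rnorm(n_frames * 7), n_frames)
  fit <- fit_glm(Y, dm)
  # independent oracle: explicit normal equations
  X <- dm$X
  beta_ref <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(unname(fit$betas),
               unname(beta_ref[dm$roles == "condition", , drop = FALSE]),
               tolerance = 1e-8)
  sig_ref <- colSums((Y - X %*% beta_ref)^2) / (n_frames - ncol(X))
  expect_equal(unname(fit$sigma2), unname(sig_ref), tolerance = 1e-8)
  disp_ref <- max(diag(solve(t(X) %*% X))[dm$roles == "condition"]) * sig_ref
  expect_equal(unname(fit$dispersion), unname(disp_ref), tolerance = 1e-8)
})

test_that("noiseless forward model is inverted exactly", {
  ss <- tiny_set
  ev <- make_events(ss, 3, seed = 5)
  set.seed(6)
  pat <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(ss$condition, NULL))
  run <- simulate_bold_run(ev, pat, tr = 1, n_frames = 150, noise_sd = 0,
                           fwd = rep(0.1, 150), seed = 6)
  dm <- build_design_matrix(ev, tr = 1, n_frames = 150)
  fit <- fit_glm(run$timeseries, dm)
  cc <- diag(cor(t(fit$betas[rownames(pat), ]), t(pat)))
  expect_true(all(cc > 0.99))
})

test_that("pure-noise voxels give beta values centered on zero", {
  ev <- make_events(tiny_set, 3, seed = 8)
  set.seed(9)
  Y <- matrix(rnorm(150 * 500), 150, 500)
  dm <- build_design_matrix(ev, tr = 1, n_frames = 150)
  fit <- fit_glm(Y, dm)
  expect_lt(abs(mean(fit$betas)), 0.05)
})

test_that("spike-regressor censoring equals row deletion for the betas", {
  ev <- make_events(tiny_set, 2, seed = 12)
  set.seed(13)
  Y <- matrix(rnorm(100 * 5), 100, 5)
  cm <- rep(FALSE, 100); cm[37] <- TRUE
  dm_spike <- build_design_matrix(ev, tr = 1, n_frames = 100,
                                  censor_mask = cm)
  fit_spike <- fit_glm(Y, dm_spike)
  dm_full <- build_design_matrix(ev, tr = 1, n_frames = 100)
  X_del <- dm_full$X[!cm, ]
  beta_del <- solve(t(X_del) %*% X_del, t(X_del) %*% Y[!cm, ])
  expect_equal(unname(fit_spike$betas),
               unname(beta_del[dm_full$roles == "condition", ]),
               tolerance = 1e-8)
})

test_that("heavy censoring inflates the dispersion estimate", {
  ev <- make_events(tiny_set, 3, seed = 14)
  set.seed(15)
  Y <- matrix(rnorm(160 * 5, sd = 1), 160, 5)
  cm <- rep(FALSE, 160)
  cm[sample(160, 78)] <- TRUE  # ~49% censored
  fit_cens <- fit_glm(Y, build_design_matrix(ev, tr = 1, n_frames = 160,
                                             censor_mask = cm))
  fit_free <- fit_glm(Y, build_design_matrix(ev, tr = 1, n_frames = 160))
  X <- build_design_matrix(ev, tr = 1, n_frames = 160)$X
  expect_gt(mean(fit_cens$dispersion), mean(fit_free$dispersion))
})

test_that("rank-deficient designs raise an error naming the columns", {
  ev <- make_events(tiny_set, 2, seed = 16)
  dm <- build_design_matrix(ev, tr = 1, n_frames = 100)
  dm$X <- cbind(dm$X, dup = dm$X[, 1])
  dm$roles <- c(dm$roles, "condition")
  expect_error(fit_glm(matrix(rnorm(500), 100, 5), dm), "collinear")
})

test_that("dispersion filtering is thresholded, monotone, and identity at Inf", {
  b <- structure(list(betas = matrix(0, 2, 3), dispersion = c(1, 11, 5),
                      valid = rep(TRUE, 3)), class = "beta_patterns")
  f10 <- filter_voxels_by_dispersion(b, 10)
  expect_equal(f10$valid, c(TRUE, FALSE, TRUE))
  expect_equal(f10$excluded_proportion, 1 / 3)
  expect_true(all(filter_voxels_by_dispersion(b, Inf)$valid))
  b0 <- b; b0$dispersion <- rep(0, 3)
  expect_true(all(filter_voxels_by_dispersion(b0, 10)$valid))
  # excluded proportion non-decreasing as the threshold decreases
  props <- vapply(c(20, 10, 4, 0.5),
                  function(th) filter_voxels_by_dispersion(b, th)$excluded_proportion,
                  numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("run-level mean centering zeroes voxel means and is idempotent", {
  m <- matrix(c(1, 2, 3), 3, 4)
  expect_equal(mean_center_runs(m), matrix(c(-1, 0, 1), 3, 4))
  expect_equal(mean_center_runs(mean_center_runs(m)), mean_center_runs(m))
  const <- matrix(5, 36, 3)
  expect_true(all(mean_center_runs(const) == 0))
  expect_lt(max(abs(colMeans(mean_center_runs(matrix(rnorm(72), 36, 2))))),
            1e-10)
  expect_error(mean_center_runs(matrix(1, 1, 3)), "2 conditions")
})

test_that("tSNR is mean over sd, scale-invariant, and guards degenerate input", {
  set.seed(20)
  base <- scale(matrix(rnorm(200 * 10), 200, 10))  # unit sd, zero mean
  Y <- 100 + 10 * base
  expect_equal(compute_tsnr(Y, detrend = FALSE), 10, tolerance = 1e-6)
  expect_equal(compute_tsnr(2 * Y, detrend = FALSE),
               compute_tsnr(Y, detrend = FALSE), tolerance = 1e-10)
  # white-noise voxels with zero mean give tSNR near zero
  expect_lt(abs(compute_tsnr(matrix(rnorm(5000), 500, 10))), 0.3)
  expect_error(compute_tsnr(matrix(1, 10, 3)), "constant")
  expect_warning(compute_tsnr(cbind(Y, 7), detrend = FALSE),
                 "zero-variance")
  expect_error(compute_tsnr(matrix(1, 1, 3)), "frames")
  # detrending removes drift that would deflate tSNR
  drift <- Y + 50 * seq_len(200)
  expect_gt(compute_tsnr(drift, detrend = TRUE),
            compute_tsnr(drift, detrend = FALSE))
})
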