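test_that("stimulus set enumerates the nested class/category/exemplar design", {
  expect_equal(nrow(default_set), 36)
  expect_equal(nrow(make_stimulus_set(1, 1, 1)), 1)
  ss <- make_stimulus_set(2, 2, 2)
  expect_equal(nrow(ss), 8)
  expect_equal(as.vector(table(ss$category)), rep(2L, 4))
  # every condition id maps to exactly one (class, category, exemplar)
  expect_false(anyDuplicated(default_set$condition) > 0)
  # deterministic ordering: class varies slowest
  expect_equal(default_set$class[1:12], rep("animate", 12))
  expect_error(make_stimulus_set(0, 4, 3), "positive")
  expect_error(make_stimulus_set(3, -1, 3), "positive")
})

test_that("event tables honor counts, SOA jitter and determinism", {
  ev <- make_events(default_set, n_repetitions = 2, seed = 42)
  expect_equal(nrow(ev), 72)
  expect_equal(as.vector(table(ev$trial_type)), rep(2L, 36))
  # onsets strictly increasing with gaps inside the jitter window
  gaps <- diff(ev$onset)
  expect_true(all(gaps >= 3.5 & gaps <= 4.5))
  expect_true(all(ev$duration == 3))
  expect_identical(ev, make_events(default_set, n_repetitions = 2, seed = 42))
  expect_false(identical(ev$trial_type,
                         make_events(default_set, 2, seed = 43)$trial_type))
  expect_error(make_events(default_set, n_repetitions = 0), "n_repetitions")
})

test_that("single-category designs are trivially valid", {
  ss1 <- make_stimulus_set(1, 1, 1)
  ev <- make_events(ss1, n_repetitions = 3, seed = 1)
  expect_equal(nrow(ev), 3)
  expect_true(check_event_constraint(ev, ss1))
})

test_that("category ordering constraint holds at every prefix for many seeds", {
  for (seed in 1:8) {
    ev <- make_events(default_set, n_repetitions = 2, seed = seed)
    expect_true(check_event_constraint(ev, default_set))
    # cumulative per-category counts never differ by more than 1
    cat_of <- setNames(default_set$category, default_set$condition)
    counts <- table(factor(cat_of[ev$trial_type[1:18]],
                           levels = unique(default_set$category)))
    expect_lte(max(counts) - min(counts), 1)
  }
  # the checker detects violations
  bad <- make_events(default_set, 2, seed = 1)
  bad$trial_type[2] <- bad$trial_type[1]
  expect_false(check_event_constraint(bad, default_set))
})

test_that("framewise displacement traces are non-negative with the requested mean", {
  fwd <- simulate_fwd(20000, mean_fwd = 0.912, sdlog = 0.8)
  expect_true(all(fwd >= 0))
  expect_equal(mean(fwd), 0.912, tolerance = 0.05)
  expect_error(simulate_fwd(0, 0.5), "n_frames")
  expect_error(simulate_fwd(10, -1), "mean_fwd")
  # age-group defaults follow the motion gradient
  expect_gt(default_fwd_mean("infant2mo"), default_fwd_mean("infant9mo"))
  expect_gt(default_fwd_mean("infant9mo"), default_fwd_mean("adult"))
})

test_that("synthetic cohorts are seed-deterministic with unique identifiers", {
  co1 <- make_test_cohort(n_subjects = 4, runs_per_subject = 2, seed = 5)
  co2 <- make_test_cohort(n_subjects = 4, runs_per_subject = 2, seed = 5)
  expect_identical(co1$subjects[[3]]$runs[[2]]$patterns,
                   co2$subjects[[3]]$runs[[2]]$patterns)
  ids <- vapply(co1$subjects, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  co3 <- make_test_cohort(n_subjects = 4, runs_per_subject = 2, seed = 6)
  expect_false(identical(co1$subjects[[1]]$runs[[1]]$patterns,
                         co3$subjects[[1]]$runs[[1]]$patterns))
})

test_that("generative identifiability: noiseless one-component cohort matches its model", {
  # realizable (positive semidefinite) model: a correlation matrix
  set.seed(2)
  R <- cor(matrix(rnorm(10 * 36), 10, 36))
  mx <- ground_truth_mixture(list(R), 1, group_sd = 1, individual_sd = 0,
                             session_sd = 0, noise_sd = 0)
  co <- simulate_patterns(default_set, mx, 4, 1, 4000, seed = 2)
  g <- group_rsm(cohort_pair_rsms(co)$rsms)
  # in the noiseless limit the pair RSMs rank-correlate ~1 with the model
  expect_gt(rsa_correlation(g, R), 0.97)
  # contrast models are not PSD; only their off-diagonal structure can be
  # realized, via the diagonal-raising floor of the mixture covariance
  catm <- categorical_rsms(default_set)
  mx2 <- ground_truth_mixture(list(as.matrix(catm$category)), 1,
                              group_sd = 1, individual_sd = 0,
                              session_sd = 0, noise_sd = 0)
  C <- devrsa:::mixture_covariance(mx2, 36)
  off <- upper.tri(C)
  expect_gt(cor(C[off], as.matrix(catm$category)[off]), 0.999)
  co2 <- simulate_patterns(default_set, mx2, 4, 1, 8000, seed = 3)
  emp <- tcrossprod(co2$truth$group_component) / 8000
  expect_gt(cor(emp[off], C[off]), 0.7)
})

test_that("pure-noise cohorts give near-zero group RSMs", {
  mx <- ground_truth_mixture(group_sd = 0, individual_sd = 0,
                             session_sd = 0, noise_sd = 1)
  co <- simulate_patterns(default_set, mx, 12, 1, 200, seed = 3)
  g <- group_rsm(cohort_pair_rsms(co)$rsms)
  expect_lt(max(abs(as.matrix(g))), 0.1)
  expect_lt(abs(mean(as.matrix(g))), 0.01)
})

test_that("invalid mixtures are rejected", {
  expect_error(ground_truth_mixture(noise_sd = -1), "standard deviations")
  expect_error(ground_truth_mixture(list(diag(3)), numeric(0)), "weight")
  expect_error(ground_truth_mixture(list(diag(3)), NaN), "finite")
})

test_that("simulated BOLD runs respect events, seeds and spike injection", {
  ss <- tiny_set
  ev <- make_events(ss, 2, seed = 1)
  pat <- matrix(rnorm(8 * 20), 8, 20, dimnames = list(ss$condition, NULL))
  r1 <- simulate_bold_run(ev, pat, tr = 1, n_frames = 120, seed = 9)
  r2 <- simulate_bold_run(ev, pat, tr = 1, n_frames = 120, seed = 9)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_error(simulate_bold_run(ev, pat, tr = -1), "tr")
  expect_error(simulate_bold_run(ev, pat, tr = 0.1, n_frames = 10),
               "exceed")
  # forcing most frames above threshold trips downstream QC
  fwd_high <- rep(2, 120); fwd_high[1:40] <- 0.1
  r3 <- simulate_bold_run(ev, pat, tr = 1, n_frames = 120, fwd = fwd_high,
                          seed = 9)
  expect_false(censor_and_qc(r3$fwd)$accepted)
})
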