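# Shared fixtures, built in code at test time.

default_set <- make_stimulus_set()

tiny_set <- make_stimulus_set(2, 2, 2)

# Small cohort with category + animacy structure, used across suites.
make_test_cohort <- function(n_subjects = 8, runs_per_subject = 1,
                             n_voxels = 150, seed = 11,
                             weights = c(1, 0.5), noise_sd = 1,
                             individual_sd = 0.5, session_sd = 0.25,
                             group_sd = 1, group = "group1") {
  catm <- categorical_rsms(default_set)
  mx <- ground_truth_mixture(
    list(as.matrix(catm$category), as.matrix(catm$animacy_tripartite)),
    weights, group_sd = group_sd, individual_sd = individual_sd,
    session_sd = session_sd, noise_sd = noise_sd)
  simulate_patterns(default_set, mx, n_subjects, runs_per_subject,
                    n_voxels, seed = seed, group = group)
}

pair_subject_frame <- function(pair_set) {
  data.frame(a = pair_set$units$subject[pair_set$pairs$a],
             b = pair_set$units$subject[pair_set$pairs$b])
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(as.matrix(m) - t(as.matrix(m)))), tol)
}
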