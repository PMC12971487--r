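#' Ground-truth generative mixture for synthetic cohorts
#'
#' Describes the generative model behind \code{\link{simulate_patterns}}:
#' condition patterns are the sum of a group-shared component (common to
#' all subjects, with cross-condition covariance proportional to the
#' weighted mixture of the supplied model RSMs), an individual component
#' (common to one subject's runs), a session component (common within a
#' run's repetitions) and i.i.d. measurement noise.
#'
#' @param models list of model RSMs (square matrices); empty for an
#'   unstructured (white) group component.
#' @param weights numeric mixture weights, one per model.
#' @param group_sd,individual_sd,session_sd,noise_sd standard deviations of
#'   the four additive components (all >= 0), in pattern units.
#' @return object of class \code{ground_truth_mixture} carrying the
#'   normalized target covariance.
#' @export
ground_truth_mixture <- function(models = list(), weights = numeric(0),
                                 group_sd = 1, individual_sd = 0.5,
                                 session_sd = 0.25, noise_sd = 1) {
  sds <- c(group_sd, individual_sd, session_sd, noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all component standard deviations must be finite and >= 0")
  if (length(models) != length(weights))
    stop("need one weight per model")
  if (length(weights) && any(!is.finite(weights)))
    stop("weights must be finite")
  structure(list(models = lapply(models, as.matrix), weights = weights,
                 group_sd = group_sd, individual_sd = individual_sd,
                 session_sd = session_sd, noise_sd = noise_sd),
            class = "ground_truth_mixture")
}

# Target covariance of the group-shared component: the weighted model sum,
# floored to positive semidefinite by raising the diagonal (adding white
# variance), which preserves the off-diagonal mixture structure exactly —
# the property the weight-recovery analyses rely on — then normalized to
# unit mean diagonal so group_sd^2 sets the scale. With no models, the
# identity.
mixture_covariance <- function(mixture, n_conditions) {
  if (length(mixture$models) == 0) return(diag(n_conditions))
  C <- Reduce(`+`, Map(`*`, mixture$models, mixture$weights))
  if (nrow(C) != n_conditions) stop("model RSMs do not match condition count")
  C <- (C + t(C)) / 2
  e_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (e_min < 1e-8) C <- C + diag(abs(e_min) + 1e-8, n_conditions)
  md <- mean(diag(C))
  if (md <= 0) stop("mixture covariance has non-positive mean diagonal")
  C / md
}

#' Simulate a cohort of condition patterns with known structure
#'
#' Generates per-subject, per-run condition x voxel pattern matrices as
#' the additive mixture described in \code{\link{ground_truth_mixture}}.
#' The group-shared component is built by coloring white voxel loadings
#' with the matrix square root of the target covariance, so its expected
#' cross-pattern covariance equals \code{group_sd^2} times the normalized
#' weighted model mixture. Each run also carries two repetition-half
#' patterns (sharing the run's group/individual/session signal, differing
#' in measurement noise) and a framewise-displacement trace.
#'
#' @param stimulus_set a \code{\link{make_stimulus_set}} object.
#' @param mixture a \code{\link{ground_truth_mixture}}.
#' @param n_subjects number of subjects.
#' @param runs_per_subject integer, or vector of per-subject run counts.
#' @param n_voxels voxels per pattern (>= n_conditions recommended).
#' @param seed RNG seed.
#' @param group group label stored on every subject.
#' @param fwd_mean mean framewise displacement (mm) of the simulated
#'   lognormal FWD traces; age-group defaults via
#'   \code{\link{default_fwd_mean}}.
#' @param fwd_sdlog lognormal log-scale s.d. of the within-run frame
#'   variation.
#' @param fwd_between_sdlog lognormal log-scale s.d. of the between-run
#'   mean-motion variation (runs differ in how restless the session was).
#'   The default gives the infant groups enough low-motion mass that the
#'   adult motion distribution is nested within theirs, which is the
#'   support the importance reweighting relies on.
#' @param n_frames frames per run for the FWD traces (default 510).
#' @param nicu_fraction fraction of subjects flagged as NICU graduates.
#' @return object of class \code{synthetic_cohort}: list with
#'   \code{subjects} (each with \code{id}, \code{group}, \code{nicu},
#'   \code{runs}: \code{run}, \code{patterns}, \code{halves}, \code{fwd}),
#'   the \code{stimulus_set}, the \code{mixture} and \code{truth} (the
#'   realized group component and component s.d.s).
#' @export
simulate_patterns <- function(stimulus_set, mixture, n_subjects,
                              runs_per_subject = 1, n_voxels = 200,
                              seed = 1L, group = "group1",
                              fwd_mean = NULL, fwd_sdlog = 0.8,
                              fwd_between_sdlog = 1,
                              n_frames = 510, nicu_fraction = 0) {
  stopifnot(inherits(stimulus_set, "stimulus_set"),
            inherits(mixture, "ground_truth_mixture"))
  if (n_subjects < 1) stop("need at least one subject")
  n <- nrow(stimulus_set)
  runs <- rep_len(runs_per_subject, n_subjects)
  if (is.null(fwd_mean)) fwd_mean <- default_fwd_mean(group)
  local_rng(seed)
  C <- mixture_covariance(mixture, n)
  Chalf <- mat_sqrt(C)
  G <- mixture$group_sd * (Chalf %*% matrix(stats::rnorm(n * n_voxels),
                                            n, n_voxels))
  rownames(G) <- stimulus_set$condition
  nicu <- rep(FALSE, n_subjects)
  if (nicu_fraction > 0)
    nicu[sample(n_subjects, round(nicu_fraction * n_subjects))] <- TRUE
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    I_i <- mixture$individual_sd * matrix(stats::rnorm(n * n_voxels),
                                          n, n_voxels)
    run_list <- vector("list", runs[i])
    for (r in seq_len(runs[i])) {
      S_r <- mixture$session_sd * matrix(stats::rnorm(n * n_voxels),
                                         n, n_voxels)
      base <- G + I_i + S_r
      h1 <- base + sqrt(2) * mixture$noise_sd *
        matrix(stats::rnorm(n * n_voxels), n, n_voxels)
      h2 <- base + sqrt(2) * mixture$noise_sd *
        matrix(stats::rnorm(n * n_voxels), n, n_voxels)
      pat <- (h1 + h2) / 2
      rownames(pat) <- rownames(h1) <- rownames(h2) <- stimulus_set$condition
      run_mean <- fwd_mean * stats::rlnorm(1, -fwd_between_sdlog^2 / 2,
                                           fwd_between_sdlog)
      fwd <- simulate_fwd(n_frames, run_mean, fwd_sdlog)
      run_list[[r]] <- list(run = as.integer(r), patterns = pat,
                            halves = list(h1, h2), fwd = fwd)
    }
    subjects[[i]] <- list(id = sprintf("%s.s%03d", group, i), group = group,
                          nicu = nicu[i], runs = run_list)
  }
  structure(list(subjects = subjects, stimulus_set = stimulus_set,
                 mixture = mixture,
                 truth = list(group_component = G)),
            class = "synthetic_cohort")
}

#' Age-group default mean framewise displacement
#'
#' Mean FWD levels (mm) typical of awake scanning at each developmental
#' stage: 0.912 for 2-month-olds, 0.532 for 9-month-olds, 0.177 for
#' adults. Unrecognized labels fall back to the adult level.
#'
#' @param group group label; matched against "2mo"/"two", "9mo"/"nine",
#'   "adult".
#' @return mean FWD in mm.
#' @export
default_fwd_mean <- function(group) {
  g <- tolower(group)
  if (grepl("2mo|two|infant2", g)) 0.912
  else if (grepl("9mo|nine|infant9", g)) 0.532
  else 0.177
}

#' Simulate a framewise-displacement trace
#'
#' Draws per-frame FWD from a lognormal with the requested arithmetic mean,
#' reproducing the heavy-tailed motion profiles of awake developmental
#' scanning.
#'
#' @param n_frames number of frames.
#' @param mean_fwd target arithmetic mean (mm).
#' @param sdlog log-scale standard deviation.
#' @return non-negative numeric vector of length \code{n_frames}.
#' @export
simulate_fwd <- function(n_frames, mean_fwd = 0.5, sdlog = 0.8) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (mean_fwd <= 0) stop("mean_fwd must be positive")
  meanlog <- log(mean_fwd) - sdlog^2 / 2
  stats::rlnorm(n_frames, meanlog, sdlog)
}

# Symmetric PSD matrix square root.
mat_sqrt <- function(C) {
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  eig$vectors %*% (sqrt(vals) * t(eig$vectors))
}

#' Expected cross-subject pair RSM of a synthetic cohort
#'
#' The large-sample limit of the cross-subject group RSM given the cohort's
#' realized group-shared component: entry (p, q) is the voxel covariance of
#' group-component rows p and q, attenuated by the independent individual,
#' session and measurement variance in the denominator. Used as the
#' per-cohort population value in recovery and coverage checks.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @return an \code{rsm} (Pearson metric).
#' @export
expected_pair_rsm <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  G <- cohort$truth$group_component
  mx <- cohort$mixture
  v <- mx$individual_sd^2 + mx$session_sd^2 + mx$noise_sd^2
  Gc <- G - rowMeans(G)
  cv <- tcrossprod(Gc) / (ncol(G) - 1)
  sds <- sqrt(diag(cv) + v)
  m <- cv / outer(sds, sds)
  as_rsm((m + t(m)) / 2, metric = "pearson", labels = rownames(G))
}

#' Simulate a BOLD run from an event table and condition patterns
#'
#' Forward model for the first-level GLM: condition boxcars are convolved
#' with the double-gamma HRF and multiplied onto the condition patterns,
#' plus a slow drift, white measurement noise, and spike artifacts injected
#' at frames whose simulated FWD exceeds the motion threshold.
#'
#' @param events an \code{event_table}.
#' @param patterns condition x voxel matrix; rows must cover the event
#'   trial types.
#' @param tr repetition time in seconds.
#' @param n_frames number of frames.
#' @param noise_sd white-noise s.d. in BOLD units.
#' @param drift_amplitude amplitude of the slow sinusoidal drift.
#' @param fwd optional FWD trace (length \code{n_frames}); simulated from
#'   \code{motion_mean} when missing.
#' @param motion_mean mean FWD for the simulated trace.
#' @param spike_threshold FWD above which a frame receives a spike
#'   artifact (default 1.5 mm).
#' @param spike_sd artifact s.d. at spiking frames.
#' @param hrf_params passed to \code{\link{glover_hrf}}.
#' @param seed RNG seed.
#' @return list with \code{timeseries} (frames x voxels), \code{fwd},
#'   \code{events}, \code{tr}.
#' @export
simulate_bold_run <- function(events, patterns, tr = 0.61, n_frames = 510,
                              noise_sd = 0, drift_amplitude = 0,
                              fwd = NULL, motion_mean = 0.2,
                              spike_threshold = 1.5, spike_sd = 50,
                              hrf_params = list(), seed = 1L) {
  if (tr <= 0) stop("tr must be positive")
  if (max(events$onset + events$duration) > n_frames * tr)
    stop("events exceed run duration")
  local_rng(seed)
  if (is.null(fwd)) fwd <- simulate_fwd(n_frames, motion_mean, 0.8)
  X <- condition_design(events, rownames(patterns), tr, n_frames, hrf_params)
  Y <- X %*% patterns
  if (drift_amplitude > 0) {
    t <- seq_len(n_frames) * tr
    Y <- Y + drift_amplitude * sin(2 * pi * t / (n_frames * tr)) %o%
      rep(1, ncol(patterns))
  }
  if (noise_sd > 0)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y))
  spikes <- fwd > spike_threshold
  if (any(spikes))
    Y[spikes, ] <- Y[spikes, , drop = FALSE] +
      matrix(stats::rnorm(sum(spikes) * ncol(Y), sd = spike_sd), sum(spikes))
  list(timeseries = Y, fwd = fwd, events = events, tr = tr)
}

#' Per-subject longitudinal RSM pairs with a controllable self-link
#'
#' Generates paired per-subject RSMs at two timepoints whose shared
#' structure is governed by \code{self_weight}: each subject's two RSMs mix
#' a subject-specific latent matrix (weight \code{self_weight}) with
#' independent noise. At \code{self_weight = 0} the pairing carries no
#' information (the null of the longitudinal permutation test).
#'
#' @param n_subjects number of linked subjects.
#' @param n_conditions RSM size.
#' @param self_weight weight of the subject-specific latent structure.
#' @param seed RNG seed.
#' @return list with \code{t1}, \code{t2} (lists of \code{rsm}) and
#'   \code{links} (identity permutation).
#' @export
simulate_longitudinal_rsms <- function(n_subjects, n_conditions = 12,
                                       self_weight = 0.5, seed = 1L) {
  local_rng(seed)
  rand_rsm <- function() {
    m <- matrix(stats::rnorm(n_conditions^2), n_conditions)
    (m + t(m)) / 2
  }
  t1 <- vector("list", n_subjects); t2 <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    latent <- rand_rsm()
    t1[[i]] <- as_rsm(self_weight * latent + rand_rsm())
    t2[[i]] <- as_rsm(self_weight * latent + rand_rsm())
  }
  list(t1 = t1, t2 = t2, links = seq_len(n_subjects))
}
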