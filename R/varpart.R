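#' Covariance-metric RSM between two pattern sets
#'
#' Cross-voxel covariance of the two measurements' condition patterns,
#' symmetrized. Covariance (rather than correlation) is additive over
#' independent signal components, which is what makes the variance
#' partitioning traces interpretable. Patterns are first centered per
#' voxel across conditions, so a voxel-wise constant added to all
#' conditions leaves the result unchanged.
#'
#' @param patterns_u,patterns_v condition x voxel matrices over the same
#'   conditions and voxel mask.
#' @param center perform the per-voxel centering (default TRUE).
#' @return an \code{rsm} with metric \code{"covariance"}.
#' @export
covariance_rsm <- function(patterns_u, patterns_v, center = TRUE) {
  if (!all(dim(patterns_u) == dim(patterns_v)))
    stop("pattern matrices must be conformable")
  if (ncol(patterns_u) < 2) stop("need at least 2 voxels")
  if (center) {
    patterns_u <- sweep(patterns_u, 2, colMeans(patterns_u))
    patterns_v <- sweep(patterns_v, 2, colMeans(patterns_v))
  }
  cc <- stats::cov(t(patterns_u), t(patterns_v))
  as_rsm((cc + t(cc)) / 2, metric = "covariance",
         labels = rownames(patterns_u))
}

#' Split a run's events into repetition halves at the category level
#'
#' For the category-level GLM (12 categories x 6 repetitions per run),
#' each category's events are split by occurrence parity (odd / even) and
#' a design with one regressor per category-half (24 columns of interest)
#' is fitted, yielding two category x voxel pattern sets per run.
#'
#' @param events an \code{event_table} for the run.
#' @param timeseries frames x voxels matrix.
#' @param stimulus_set the stimulus set (maps conditions to categories).
#' @param tr,n_frames,censor_mask,motion_params,hrf_params passed to
#'   \code{\link{build_design_matrix}}.
#' @return list with \code{half1}, \code{half2} (category x voxel
#'   matrices, mean-centered per voxel) and the fitted
#'   \code{beta_patterns}.
#' @export
repetition_split_patterns <- function(events, timeseries, stimulus_set,
                                      tr, n_frames, censor_mask = NULL,
                                      motion_params = NULL,
                                      hrf_params = list()) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  cat_of <- stats::setNames(stimulus_set$category, stimulus_set$condition)
  ev <- events[order(events$onset), ]
  ev$category <- unname(cat_of[ev$trial_type])
  cats <- unique(stimulus_set$category)
  counts <- table(ev$category)
  if (any(!(cats %in% names(counts))) || any(counts < 2))
    stop("every category needs at least 2 events per run")
  occ <- stats::ave(seq_len(nrow(ev)), ev$category, FUN = seq_along)
  ev$trial_type <- paste0(ev$category, ifelse(occ %% 2 == 1, ".h1", ".h2"))
  conds <- c(paste0(cats, ".h1"), paste0(cats, ".h2"))
  design <- build_design_matrix(ev, tr = tr, n_frames = n_frames,
                                censor_mask = censor_mask,
                                motion_params = motion_params,
                                conditions = conds,
                                hrf_params = hrf_params)
  fit <- fit_glm(timeseries, design)
  b <- fit$betas
  h1 <- b[paste0(cats, ".h1"), , drop = FALSE]
  h2 <- b[paste0(cats, ".h2"), , drop = FALSE]
  rownames(h1) <- rownames(h2) <- cats
  list(half1 = mean_center_runs(h1), half2 = mean_center_runs(h2),
       fit = fit)
}

# Mean diagonal of the covariance RSM between two pattern sets.
cov_trace <- function(u, v) mean(diag(as.matrix(covariance_rsm(u, v))))

#' Partition pattern variance into group, individual and session components
#'
#' Computes mean covariance-RSM traces over three tiers of comparisons:
#' across subjects (\code{T_group}), within subject across runs
#' (\code{T_indiv}) and within run across repetition halves
#' (\code{T_sess}). Under the additive generative model their expectations
#' nest, and the components are recovered as differences: group =
#' \code{T_group}; individual = \code{T_indiv - T_group}; session =
#' \code{T_sess - T_indiv}. Components may be negative by sampling noise
#' and are reported unclipped. Bootstrap CIs resample subjects.
#'
#' @param cohort a cohort whose runs carry \code{patterns} and
#'   \code{halves} (as produced by \code{\link{simulate_patterns}}, or
#'   assembled from \code{\link{repetition_split_patterns}}).
#' @param n_boot bootstrap resamples over subjects (default 200; 0 skips
#'   CIs).
#' @param seed RNG seed for the bootstrap.
#' @return object of class \code{variance_components}: \code{components}
#'   (group, individual, session), \code{traces}, and \code{ci} (2 x 3
#'   matrix) when bootstrapped. Tiers without data (e.g. all single-run
#'   subjects) give \code{NA} with a message in \code{undefined}.
#' @export
partition_variance <- function(cohort, n_boot = 200, seed = 1L) {
  subs <- cohort_subjects(cohort)
  if (length(subs) < 2) stop("need at least 2 subjects")
  est <- function(sub_idx) {
    ss <- subs[sub_idx]
    # group tier: across-subject run pairs (first run of each, all cross pairs)
    t_group <- c()
    for (i in seq_along(ss)) for (j in seq_along(ss)) {
      # pairs duplicated by the bootstrap stay cross-subject only
      if (i < j && sub_idx[i] != sub_idx[j])
        t_group <- c(t_group, cov_trace(ss[[i]]$runs[[1]]$patterns,
                                        ss[[j]]$runs[[1]]$patterns))
    }
    t_indiv <- c()
    for (s in ss) {
      nr <- length(s$runs)
      if (nr >= 2)
        for (i in seq_len(nr - 1)) for (j in (i + 1):nr)
          t_indiv <- c(t_indiv, cov_trace(s$runs[[i]]$patterns,
                                          s$runs[[j]]$patterns))
    }
    t_sess <- c()
    for (s in ss) for (r in s$runs) {
      if (!is.null(r$halves))
        t_sess <- c(t_sess, cov_trace(r$halves[[1]], r$halves[[2]]))
    }
    c(group = mean(t_group),
      indiv = if (length(t_indiv)) mean(t_indiv) else NA_real_,
      sess = if (length(t_sess)) mean(t_sess) else NA_real_)
  }
  tr <- est(seq_along(subs))
  comp <- c(group = unname(tr["group"]),
            individual = unname(tr["indiv"] - tr["group"]),
            session = unname(tr["sess"] - tr["indiv"]))
  undefined <- names(comp)[is.na(comp)]
  ci <- NULL
  if (n_boot > 0) {
    local_rng(seed)
    bs <- replicate(n_boot, {
      t_b <- est(sample(seq_along(subs), replace = TRUE))
      c(t_b["group"], t_b["indiv"] - t_b["group"], t_b["sess"] - t_b["indiv"])
    })
    ci <- apply(bs, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    colnames(ci) <- names(comp)
  }
  structure(list(components = comp, traces = tr, ci = ci,
                 undefined = undefined),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (covariance-trace units):\n")
  print(round(x$components, 4))
  invisible(x)
}
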