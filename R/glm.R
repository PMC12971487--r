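#' Canonical double-gamma (Glover) hemodynamic response function
#'
#' Evaluates the canonical double-gamma HRF: a gamma density for the
#' positive lobe (response delay \code{peak}) minus an undershoot gamma
#' (delay \code{undershoot}) scaled by \code{ratio}, normalized to unit
#' peak. Uses the standard shape/rate parameterization (shape =
#' delay, rate = 1), so the positive lobe peaks just under \code{peak}
#' seconds.
#'
#' @param t time in seconds (vector).
#' @param peak response-delay parameter of the positive lobe (default 6).
#' @param undershoot delay parameter of the undershoot (default 16).
#' @param ratio undershoot amplitude ratio (default 1/6).
#' @return HRF values at \code{t}.
#' @export
glover_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  h / max(h)
}

# Condition-of-interest design: per-condition boxcars on an oversampled
# grid, convolved with the HRF, sampled at frame acquisition times.
condition_design <- function(events, conditions, tr, n_frames,
                             hrf_params = list()) {
  os <- 16
  dt <- tr / os
  grid_n <- n_frames * os + ceiling(40 / dt)
  hrf <- do.call(glover_hrf, c(list(t = seq(0, 32, by = dt)), hrf_params))
  X <- matrix(0, n_frames, length(conditions),
              dimnames = list(NULL, conditions))
  frame_idx <- seq_len(n_frames)
  for (j in seq_along(conditions)) {
    ev <- events[events$trial_type == conditions[j], , drop = FALSE]
    if (nrow(ev) == 0) next
    box <- numeric(grid_n)
    for (k in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset[k] / dt) + 1
      i1 <- min(grid_n, floor((ev$onset[k] + ev$duration[k]) / dt))
      box[i0:i1] <- box[i0:i1] + 1   # overlapping same-condition events sum
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(grid_n)]
    X[, j] <- conv[(frame_idx - 1) * os + 1]
  }
  X * dt
}

#' Motion censoring and run-level quality control
#'
#' Flags frames whose framewise displacement exceeds the motion threshold
#' (censored via spike regressors downstream) and rejects the run outright
#' when more than \code{max_censored_fraction} of its frames are flagged.
#'
#' @param fwd numeric FWD trace (mm, one value per frame).
#' @param fwd_threshold censoring threshold in mm (default 1.5).
#' @param max_censored_fraction run-rejection threshold on the censored
#'   fraction (default 0.5).
#' @return list of class \code{qc_report}: \code{censor_mask} (logical,
#'   TRUE = censored), \code{n_frames}, \code{n_censored},
#'   \code{censored_fraction}, \code{accepted}, \code{median_fwd}.
#' @export
censor_and_qc <- function(fwd, fwd_threshold = 1.5,
                          max_censored_fraction = 0.5) {
  if (length(fwd) == 0) stop("empty motion trace")
  if (fwd_threshold <= 0) stop("fwd_threshold must be positive")
  mask <- fwd > fwd_threshold
  frac <- mean(mask)
  out <- list(censor_mask = mask, n_frames = length(fwd),
              n_censored = sum(mask), censored_fraction = frac,
              accepted = frac <= max_censored_fraction,
              median_fwd = stats::median(fwd))
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d frames censored (%.1f%%); run %s; median FWD %.3f mm\n",
              x$n_censored, x$n_frames, 100 * x$censored_fraction,
              if (x$accepted) "accepted" else "REJECTED", x$median_fwd))
  invisible(x)
}

#' Build a first-level design matrix
#'
#' Condition-of-interest columns are event boxcars convolved with the
#' canonical double-gamma HRF sampled at the TR. One spike column (single
#' 1) is appended per censored frame, followed by optional motion
#' covariates, a linear trend, a cosine drift basis spanning frequencies
#' below the high-pass cutoff, and an intercept.
#'
#' @param events an \code{event_table} for the run.
#' @param tr repetition time (s).
#' @param n_frames number of frames.
#' @param censor_mask optional logical vector (TRUE = censored frame).
#' @param motion_params optional frames x k matrix of motion covariates
#'   (e.g. three translations + three rotations).
#' @param conditions condition names; defaults to the sorted unique trial
#'   types.
#' @param hrf_params passed to \code{\link{glover_hrf}}.
#' @param highpass_hz high-pass cutoff for the cosine drift set (default
#'   0.01 Hz).
#' @return list of class \code{design_matrix}: \code{X} (frames x columns),
#'   \code{roles} (per-column role: condition / spike / motion / trend /
#'   cosine / intercept), \code{conditions}, \code{tr}.
#' @export
build_design_matrix <- function(events, tr, n_frames, censor_mask = NULL,
                                motion_params = NULL, conditions = NULL,
                                hrf_params = list(), highpass_hz = 0.01) {
  if (max(events$onset) > n_frames * tr)
    stop("events exceed run duration; n_frames mismatch")
  if (is.null(conditions)) conditions <- sort(unique(events$trial_type))
  Xc <- condition_design(events, conditions, tr, n_frames, hrf_params)
  roles <- rep("condition", ncol(Xc))
  X <- Xc
  if (!is.null(censor_mask)) {
    if (length(censor_mask) != n_frames) stop("censor_mask length mismatch")
    ci <- which(censor_mask)
    if (length(ci)) {
      S <- matrix(0, n_frames, length(ci),
                  dimnames = list(NULL, paste0("spike", ci)))
      S[cbind(ci, seq_along(ci))] <- 1
      X <- cbind(X, S)
      roles <- c(roles, rep("spike", length(ci)))
    }
  }
  if (!is.null(motion_params)) {
    motion_params <- as.matrix(motion_params)
    if (nrow(motion_params) != n_frames) stop("motion_params length mismatch")
    colnames(motion_params) <- paste0("motion", seq_len(ncol(motion_params)))
    X <- cbind(X, motion_params)
    roles <- c(roles, rep("motion", ncol(motion_params)))
  }
  t_sec <- (seq_len(n_frames) - 1) * tr
  trend <- scale(t_sec, center = TRUE, scale = FALSE)[, 1]
  X <- cbind(X, trend = trend)
  roles <- c(roles, "trend")
  K <- floor(2 * n_frames * tr * highpass_hz)
  if (K >= 1) {
    fr <- seq_len(n_frames) - 0.5
    D <- sapply(seq_len(K), function(k) cos(pi * k * fr / n_frames))
    colnames(D) <- paste0("cosine", seq_len(K))
    X <- cbind(X, D)
    roles <- c(roles, rep("cosine", K))
  }
  X <- cbind(X, intercept = 1)
  roles <- c(roles, "intercept")
  structure(list(X = X, roles = roles, conditions = conditions, tr = tr),
            class = "design_matrix")
}

#' Fit a run-level GLM and estimate condition patterns
#'
#' Ordinary least squares per voxel. The per-voxel dispersion proxy is the
#' maximum over the condition regressors of their estimator variance,
#' \code{diag((X'X)^-1)} times the voxel residual mean square, with degrees
#' of freedom reduced by the spike-regressor count.
#'
#' @param timeseries frames x voxels matrix.
#' @param design a \code{design_matrix}.
#' @param subject,run identifiers stored on the result.
#' @return object of class \code{beta_patterns}: \code{betas} (condition x
#'   voxel), \code{dispersion} (per voxel), \code{valid} (per-voxel mask,
#'   initially all TRUE), \code{sigma2}, \code{df}, ids.
#' @export
fit_glm <- function(timeseries, design, subject = "s1", run = 1L) {
  X <- design$X
  if (nrow(X) != nrow(timeseries)) stop("design / timeseries frame mismatch")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  beta_all <- qr.coef(qrX, timeseries)
  resid <- qr.resid(qrX, timeseries)
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- colSums(resid^2) / df
  unpiv <- order(qrX$pivot)
  XtXinv <- chol2inv(qr.R(qrX))[unpiv, unpiv, drop = FALSE]
  cond_idx <- which(design$roles == "condition")
  var_scale <- diag(XtXinv)[cond_idx]
  dispersion <- max(var_scale) * sigma2
  betas <- beta_all[cond_idx, , drop = FALSE]
  rownames(betas) <- design$conditions
  structure(list(betas = betas, dispersion = dispersion,
                 valid = rep(TRUE, ncol(timeseries)),
                 sigma2 = sigma2, df = df, subject = subject,
                 run = as.integer(run)),
            class = "beta_patterns")
}

#' Exclude voxels with unstable estimates
#'
#' Falsifies the validity mask wherever the per-voxel vcov dispersion
#' exceeds \code{max_dispersion} (default 10), recording the excluded
#' proportion.
#'
#' @param betas a \code{beta_patterns}.
#' @param max_dispersion exclusion threshold.
#' @return the updated \code{beta_patterns}, with an
#'   \code{excluded_proportion} field.
#' @export
filter_voxels_by_dispersion <- function(betas, max_dispersion = 10) {
  stopifnot(inherits(betas, "beta_patterns"))
  bad <- betas$dispersion > max_dispersion
  betas$valid <- betas$valid & !bad
  betas$excluded_proportion <- mean(bad)
  betas
}

#' Run-level mean centering of condition estimates
#'
#' Subtracts each voxel's mean across conditions, removing run-specific
#' baseline differences; idempotent.
#'
#' @param betas a \code{beta_patterns}, or a plain condition x voxel
#'   matrix.
#' @return same type as the input, centered so each voxel's mean over
#'   conditions is 0.
#' @export
mean_center_runs <- function(betas) {
  center <- function(m) sweep(m, 2, colMeans(m))
  if (inherits(betas, "beta_patterns")) {
    if (nrow(betas$betas) < 2) stop("need >= 2 conditions to center")
    betas$betas <- center(betas$betas)
    betas
  } else {
    if (nrow(betas) < 2) stop("need >= 2 conditions to center")
    center(betas)
  }
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel temporal mean over temporal standard deviation (after an
#' optional linear detrend), averaged over ROI voxels. Zero-variance
#' voxels are excluded with a warning count.
#'
#' @param timeseries frames x voxels matrix.
#' @param roi_mask optional logical voxel mask.
#' @param detrend remove a linear trend (and keep the mean) before the
#'   s.d. (default TRUE).
#' @return scalar mean tSNR.
#' @export
compute_tsnr <- function(timeseries, roi_mask = NULL, detrend = TRUE) {
  if (nrow(timeseries) < 2) stop("need at least 2 frames")
  Y <- if (is.null(roi_mask)) timeseries
       else timeseries[, roi_mask, drop = FALSE]
  mu <- colMeans(Y)
  if (detrend) {
    t <- seq_len(nrow(Y))
    Y <- stats::lm.fit(cbind(1, t), Y)$residuals
    sdv <- apply(Y, 2, stats::sd)
  } else {
    sdv <- apply(Y, 2, stats::sd)
  }
  keep <- sdv > 1e-8 * pmax(abs(mu), 1)
  if (!any(keep)) stop("tSNR undefined: all ROI voxels are constant")
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    warning(n_excluded, " zero-variance voxel(s) excluded from tSNR")
  mean(mu[keep] / sdv[keep])
}
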