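#' Spearman correlation between brain and model RSMs
#'
#' Rank correlation of the vectorized upper triangles of two conformable
#' RSMs. The leading diagonal is included for the perceptual/categorical
#' feature comparisons and excluded for DNN-layer and maturity comparisons;
#' choose with \code{include_diagonal}.
#'
#' @param brain_rsm,model_rsm conformable square matrices / \code{rsm}s.
#' @param include_diagonal include the leading diagonal (default TRUE).
#' @return Spearman's rho.
#' @export
rsa_correlation <- function(brain_rsm, model_rsm, include_diagonal = TRUE) {
  a <- upper_tri_vec(brain_rsm, include_diagonal)
  b <- upper_tri_vec(model_rsm, include_diagonal)
  if (length(a) != length(b)) stop("RSMs are not conformable")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Spearman correlation undefined for a constant RSM vector")
  stats::cor(a, b, method = "spearman")
}

#' Partial Spearman correlation controlling for covariate models
#'
#' All RSM vectors are rank-transformed; the brain and target-model ranks
#' are residualized on the covariate ranks (plus an intercept) by least
#' squares, and the Pearson correlation of the residuals is returned.
#' Degenerate (constant) covariates are dropped with a warning. With an
#' empty covariate set this equals \code{\link{rsa_correlation}}.
#'
#' @param brain_rsm,model_rsm conformable RSMs.
#' @param covariates list of covariate RSMs (e.g. the four perceptual
#'   models).
#' @param include_diagonal include the leading diagonal.
#' @return partial Spearman's rho.
#' @export
partial_rsa <- function(brain_rsm, model_rsm, covariates = list(),
                        include_diagonal = TRUE) {
  a <- rank(upper_tri_vec(brain_rsm, include_diagonal))
  b <- rank(upper_tri_vec(model_rsm, include_diagonal))
  if (length(covariates) == 0) return(stats::cor(a, b))
  Z <- vapply(covariates, function(m)
    upper_tri_vec(m, include_diagonal), numeric(length(a)))
  keep <- apply(Z, 2, function(z) stats::sd(z) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " degenerate covariate model(s) dropped")
    Z <- Z[, keep, drop = FALSE]
  }
  if (ncol(Z) == 0) return(stats::cor(a, b))
  Z <- apply(Z, 2, rank)
  X <- cbind(1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) warning("collinear covariate ranks")
  ra <- qr.resid(qx, a)
  rb <- qr.resid(qx, b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("target collinear with covariates; partial correlation undefined")
  stats::cor(ra, rb)
}

#' Importance weights matching a motion distribution
#'
#' Bins the pooled source + target FWD samples into quantile bins and
#' weights each source unit proportionally to the target-to-source count
#' ratio of its bin, so that resampling the source with these
#' probabilities reproduces the target motion distribution. Source units
#' falling in bins empty of target mass get weight 0.
#'
#' @param source_fwd per-unit FWD of the group being resampled.
#' @param target_fwd FWD sample of the distribution to match.
#' @param n_bins number of quantile bins (default 10, deciles).
#' @param edges optional explicit interior bin boundaries, overriding the
#'   quantile binning.
#' @return list of class \code{importance_weights}: \code{weights}
#'   (normalized, one per source unit), \code{bin_edges}, \code{bins}.
#' @export
importance_weights <- function(source_fwd, target_fwd, n_bins = 10,
                               edges = NULL) {
  if (length(source_fwd) == 0 || length(target_fwd) == 0)
    stop("source and target samples must be non-empty")
  if (is.null(edges)) {
    pooled <- c(source_fwd, target_fwd)
    edges <- unique(stats::quantile(pooled,
                                    probs = seq(0, 1, length.out = n_bins + 1)))
  } else {
    edges <- c(min(c(source_fwd, target_fwd)) - 1, sort(edges),
               max(c(source_fwd, target_fwd)) + 1)
  }
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  sb <- cut(source_fwd, edges, labels = FALSE)
  tb <- cut(target_fwd, edges, labels = FALSE)
  n_eff <- length(edges) - 1
  s_count <- tabulate(sb, n_eff)
  t_count <- tabulate(tb, n_eff)
  ratio <- ifelse(s_count > 0, t_count / pmax(s_count, 1), 0)
  w <- ratio[sb]
  if (sum(w) == 0)
    stop("no overlap between source and target motion distributions")
  structure(list(weights = w / sum(w), bin_edges = edges, bins = sb),
            class = "importance_weights")
}

#' Bootstrap a statistic of the group RSM over sampling pairs
#'
#' Resamples the sampling units (subject/run pair RSMs) with replacement —
#' optionally with importance weights as sampling probabilities and with
#' NICU-flagged units excluded first — averages each resample into a group
#' RSM, and applies the statistic. Returns the point estimate (statistic of
#' the full weighted mean), the resample distribution and the percentile
#' 95\% CI.
#'
#' @param rsms n_conditions^2 x n_units matrix of vectorized pair RSMs
#'   (e.g. \code{$rsms} from \code{\link{cohort_pair_rsms}}), or a list of
#'   \code{rsm}s.
#' @param statistic function taking a square group-RSM matrix and
#'   returning a scalar.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param weights optional per-unit sampling weights
#'   (\code{\link{importance_weights}} object or numeric vector).
#' @param exclude optional logical per-unit exclusion flags (e.g. NICU
#'   membership), applied before resampling.
#' @param pair_subjects optional data frame with columns \code{a} and
#'   \code{b} giving the two subject labels behind each pair RSM. When
#'   supplied, resampling is at the subject level: each resample draws
#'   subjects with replacement and averages the pair RSMs of all distinct
#'   drawn subject pairs (with multiplicities). This respects the
#'   dependence among pair RSMs sharing a subject, which unit-level
#'   resampling understates.
#' @param conf confidence level (default 0.95).
#' @return object of class \code{bootstrap_result}: \code{point},
#'   \code{dist}, \code{ci}, \code{n_boot}, \code{seed},
#'   \code{weighting}, \code{n_failed}.
#' @export
bootstrap_statistic <- function(rsms, statistic, n_boot = 1000, seed = 1L,
                                weights = NULL, exclude = NULL,
                                pair_subjects = NULL, conf = 0.95) {
  if (is.list(rsms)) {
    n <- nrow(rsms[[1]])
    rsms <- vapply(rsms, as.vector, numeric(n * n))
  }
  if (inherits(weights, "importance_weights")) weights <- weights$weights
  if (!is.null(exclude)) {
    rsms <- rsms[, !exclude, drop = FALSE]
    if (!is.null(weights)) weights <- weights[!exclude]
    if (!is.null(pair_subjects))
      pair_subjects <- pair_subjects[!exclude, , drop = FALSE]
  }
  n_units <- ncol(rsms)
  if (n_units < 2) stop("need at least 2 sampling units")
  w <- if (is.null(weights)) rep(1 / n_units, n_units)
       else weights / sum(weights)
  n_cond <- as.integer(sqrt(nrow(rsms)))
  stat_of <- function(v) statistic(matrix(v, n_cond, n_cond))
  point <- stat_of(as.vector(rsms %*% w))
  if (!is.null(pair_subjects)) {
    subs <- unique(c(pair_subjects$a, pair_subjects$b))
    ns <- length(subs)
    ia <- match(pair_subjects$a, subs)
    ib <- match(pair_subjects$b, subs)
    # per-subject resampling probability from the unit weights
    ws <- vapply(seq_len(ns), function(s) sum(w[ia == s | ib == s]),
                 numeric(1))
    ws <- ws / sum(ws)
    # uniform weights reproduce the unweighted sampler exactly
    ws_arg <- if (max(ws) - min(ws) < 1e-15) NULL else ws
    draw <- function() {
      mult <- tabulate(sample.int(ns, ns, replace = TRUE, prob = ws_arg), ns)
      pw <- mult[ia] * mult[ib]
      if (sum(pw) == 0) return(NULL)
      as.vector(rsms %*% (pw / sum(pw)))
    }
  } else {
    w_arg <- if (max(w) - min(w) < 1e-15) NULL else w
    draw <- function() {
      idx <- sample.int(n_units, n_units, replace = TRUE, prob = w_arg)
      rowMeans(rsms[, idx, drop = FALSE])
    }
  }
  local_rng(seed)
  dist <- numeric(n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      v <- draw()
      val <- if (is.null(v)) NA_real_
        else tryCatch(stat_of(v), error = function(e) NA_real_)
      if (!is.na(val)) break
      n_failed <- n_failed + 1L
      if (n_failed > 10 * n_boot) stop("statistic failed on most resamples")
    }
    dist[b] <- val
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(dist, c(alpha, 1 - alpha)))
  structure(list(point = point, dist = dist, ci = ci, n_boot = n_boot,
                 seed = seed,
                 weighting = if (is.null(weights)) "uniform" else "importance",
                 resampling = if (is.null(pair_subjects)) "unit" else "subject",
                 n_failed = n_failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap estimate %.4f, 95%% CI [%.4f, %.4f] (%d resamples, %s weights)\n",
              x$point, x$ci[1], x$ci[2], x$n_boot, x$weighting))
  invisible(x)
}

#' Difference between two bootstrap distributions
#'
#' Element-wise difference of the two resample distributions; the contrast
#' is significant when the percentile 95\% CI of the difference excludes
#' zero.
#'
#' @param result_a,result_b \code{bootstrap_result}s. Unequal lengths are
#'   equalized by resampling the longer distribution.
#' @param conf confidence level.
#' @return list: \code{point}, \code{ci}, \code{significant}, \code{dist}.
#' @export
group_difference <- function(result_a, result_b, conf = 0.95) {
  da <- result_a$dist; db <- result_b$dist
  n <- min(length(da), length(db))
  if (length(da) != length(db)) {
    da <- da[seq_len(n)]; db <- db[seq_len(n)]
  }
  d <- da - db
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(d, c(alpha, 1 - alpha)))
  list(point = result_a$point - result_b$point, ci = ci,
       significant = ci[1] > 0 || ci[2] < 0, dist = d)
}

#' Express a correlation as a proportion of the noise ceiling
#'
#' Divides by the corrected split-half ceiling when it is at or above the
#' validity floor; unreliable ceilings (e.g. regions with no consistent
#' signal) leave the raw value, flagged as un-normalized.
#'
#' @param rho correlation value(s).
#' @param ceiling a \code{\link{split_half_noise_ceiling}} result, or a
#'   number.
#' @param floor validity floor when \code{ceiling} is numeric.
#' @return list: \code{value}, \code{normalized} (logical).
#' @export
normalize_by_ceiling <- function(rho, ceiling, floor = 0.1) {
  if (inherits(ceiling, "noise_ceiling")) {
    ok <- ceiling$valid
    cval <- ceiling$corrected
  } else {
    cval <- ceiling
    ok <- cval >= floor
  }
  if (ok) list(value = rho / cval, normalized = TRUE)
  else list(value = rho, normalized = FALSE)
}

#' Maturity: correlation of infant group RSMs to a fixed adult RSM
#'
#' Bootstraps the Spearman correlation between the resampled infant group
#' RSM and the (fixed, never resampled) adult group RSM; the diagonal is
#' excluded by default.
#'
#' @param infant_rsms vectorized infant pair RSM matrix or list of
#'   \code{rsm}s.
#' @param adult_rsm fixed adult group RSM.
#' @param n_boot,seed,weights,exclude,pair_subjects as
#'   \code{\link{bootstrap_statistic}} (supply \code{pair_subjects} to
#'   resample across infants rather than pairs).
#' @param include_diagonal include the diagonal (default FALSE).
#' @return a \code{bootstrap_result}.
#' @export
maturity_correlation <- function(infant_rsms, adult_rsm, n_boot = 1000,
                                 seed = 1L, weights = NULL, exclude = NULL,
                                 pair_subjects = NULL,
                                 include_diagonal = FALSE) {
  adult_m <- as.matrix(adult_rsm)
  bootstrap_statistic(infant_rsms,
                      function(m) rsa_correlation(m, adult_m,
                                                  include_diagonal),
                      n_boot = n_boot, seed = seed, weights = weights,
                      exclude = exclude, pair_subjects = pair_subjects)
}

#' Recover mixture weights by multiple-regression RSA
#'
#' Regresses the off-diagonal entries of a brain RSM (covariance metric
#' preferred, for additivity) on the off-diagonal entries of the candidate
#' model RSMs plus an intercept. Each coefficient is the partial
#' contribution of that model controlling for the others; under the
#' additive generative mixture the coefficients are proportional to the
#' generative weights, so their rank order recovers the weight order.
#'
#' Both sides are double-centered (row and column means removed) first:
#' voxel-wise pattern centering double-centers an empirical covariance
#' RSM, so projecting the models through the same transform keeps the
#' regression consistent for models with non-uniform row sums.
#'
#' @param brain_rsm square matrix (group covariance or correlation RSM).
#' @param models named list of model RSMs.
#' @return named numeric vector of regression weights.
#' @export
recover_mixture_weights <- function(brain_rsm, models) {
  dc <- function(m) {
    m <- as.matrix(m)
    m - outer(rowMeans(m), rep(1, ncol(m))) -
      outer(rep(1, nrow(m)), colMeans(m)) + mean(m)
  }
  y <- upper_tri_vec(dc(brain_rsm), include_diagonal = FALSE)
  X <- vapply(models, function(m)
    upper_tri_vec(dc(m), include_diagonal = FALSE), numeric(length(y)))
  fit <- stats::lm.fit(cbind(`(intercept)` = 1, X), y)
  fit$coefficients[-1]
}

#' Longitudinal permutation test of representational self-consistency
#'
#' Tests whether subjects' RSMs at the first timepoint are more similar to
#' their own RSMs at the second timepoint than to a random subject's. The
#' observed statistic is the mean over linked subjects of the Spearman
#' correlation between own-timepoint RSMs (upper triangle, diagonal
#' excluded); the null is built from random relinkings, and the p-value
#' uses the add-one correction p = (1 + #(null >= observed)) / (1 +
#' n_perm).
#'
#' @param rsms_t1,rsms_t2 lists of per-subject RSMs.
#' @param links integer vector: subject i at t1 links to
#'   \code{links[i]} at t2 (default identity). Must be a permutation
#'   without duplicates.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list: \code{p_value}, \code{observed}, \code{null} (the
#'   permutation distribution), \code{n_perm}.
#' @export
longitudinal_permutation_test <- function(rsms_t1, rsms_t2, links = NULL,
                                          n_perm = 1000, seed = 1L) {
  n <- length(rsms_t1)
  if (n < 5) stop("need at least 5 linked subjects")
  if (is.null(links)) links <- seq_len(n)
  if (anyDuplicated(links)) stop("duplicate longitudinal links")
  v1 <- lapply(rsms_t1, upper_tri_vec, include_diagonal = FALSE)
  v2 <- lapply(rsms_t2, upper_tri_vec, include_diagonal = FALSE)
  pair_stat <- function(map) mean(vapply(seq_len(n), function(i)
    stats::cor(v1[[i]], v2[[map[i]]], method = "spearman"), numeric(1)))
  observed <- pair_stat(links)
  local_rng(seed)
  null <- vapply(seq_len(n_perm), function(k) pair_stat(sample(links)),
                 numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(p_value = p, observed = observed, null = null, n_perm = n_perm)
}
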