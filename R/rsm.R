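#' Representational similarity matrix container
#'
#' Wraps a square numeric matrix as an \code{rsm} object carrying its metric
#' tag (\code{"pearson"}, \code{"covariance"} or \code{"model"}), condition
#' labels and provenance (which subject/run pairs produced it).
#'
#' @param m square numeric matrix.
#' @param metric metric tag.
#' @param labels optional condition labels.
#' @param provenance optional list/data frame of contributing pairs.
#' @param symmetric logical; when TRUE the matrix must be symmetric to
#'   1e-10.
#' @return an \code{rsm} object (a classed matrix).
#' @export
as_rsm <- function(m, metric = "pearson", labels = NULL, provenance = NULL,
                   symmetric = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("RSM must be square")
  if (symmetric && max(abs(m - t(m))) >= 1e-10)
    stop("RSM not symmetric")
  if (!is.null(labels)) {
    if (length(labels) != nrow(m)) stop("labels length mismatch")
    dimnames(m) <- list(labels, labels)
  }
  attr(m, "metric") <- metric
  attr(m, "provenance") <- provenance
  attr(m, "symmetric") <- symmetric
  class(m) <- c("rsm", class(m))
  m
}

rsm_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  m
}

#' @export
as.matrix.rsm <- function(x, ...) rsm_matrix(x)

#' Vectorize the upper triangle of an RSM
#'
#' @param rsm an \code{rsm} or square matrix.
#' @param include_diagonal include the leading diagonal in the vector.
#' @return numeric vector of upper-triangle entries (column-major order).
#' @export
upper_tri_vec <- function(rsm, include_diagonal = FALSE) {
  m <- as.matrix(rsm)
  m[upper.tri(m, diag = include_diagonal)]
}

#' Enumerate cross-subject sampling pairs
#'
#' Lists all unordered pairs of sampling units with the two members drawn
#' from different subjects. At \code{level = "run"} every (subject, run) is
#' a unit, so subjects contribute each of their runs and within-subject
#' cross-run pairs are excluded. At \code{level = "subject"} runs are first
#' aggregated (averaged) into one unit per subject, giving
#' \code{choose(n_subjects, 2)} pairs.
#'
#' @param cohort a cohort (see \code{\link{simulate_patterns}}) or any list
#'   of subjects each with a \code{runs} list.
#' @param level \code{"run"} or \code{"subject"}.
#' @return list with \code{units} (data frame: unit id, subject, run) and
#'   \code{pairs} (data frame of unit index pairs \code{a}, \code{b}), in
#'   deterministic order.
#' @export
enumerate_pairs <- function(cohort, level = c("run", "subject")) {
  level <- match.arg(level)
  subs <- cohort_subjects(cohort)
  if (length(subs) < 2) stop("need at least 2 subjects")
  units <- do.call(rbind, lapply(seq_along(subs), function(i) {
    s <- subs[[i]]
    if (level == "subject") {
      data.frame(subject = s$id, run = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(subject = s$id,
                 run = vapply(s$runs, function(r) r$run, integer(1)),
                 stringsAsFactors = FALSE)
    }
  }))
  units$unit <- seq_len(nrow(units))
  idx <- utils::combn(nrow(units), 2)
  keep <- units$subject[idx[1, ]] != units$subject[idx[2, ]]
  pairs <- data.frame(a = idx[1, keep], b = idx[2, keep])
  list(units = units, pairs = pairs)
}

cohort_subjects <- function(cohort) {
  if (!is.null(cohort$subjects)) cohort$subjects else cohort
}

# Pattern matrix for a unit: run-level pattern or subject average.
unit_patterns <- function(cohort, units_row) {
  subs <- cohort_subjects(cohort)
  sid <- units_row$subject
  s <- subs[[which(vapply(subs, function(x) x$id, character(1)) == sid)]]
  if (is.na(units_row$run)) {
    mats <- lapply(s$runs, `[[`, "patterns")
    Reduce(`+`, mats) / length(mats)
  } else {
    rid <- vapply(s$runs, function(r) r$run, integer(1))
    s$runs[[which(rid == units_row$run)]]$patterns
  }
}

#' Cross-measurement pair RSM
#'
#' Correlates two condition x voxel pattern matrices across voxels. Entry
#' (p, q) is the average of corr(A_p, B_q) and corr(A_q, B_p), so the
#' result is symmetric; the diagonal is the cross-measurement
#' same-condition correlation, not forced to 1.
#'
#' @param patterns_a,patterns_b condition x voxel matrices with the same
#'   condition set.
#' @param voxel_mask optional logical vector of voxels valid in both
#'   measurements.
#' @return an \code{rsm} with metric \code{"pearson"}.
#' @export
pair_rsm <- function(patterns_a, patterns_b, voxel_mask = NULL) {
  if (!all(dim(patterns_a) == dim(patterns_b)))
    stop("pattern matrices must be conformable")
  if (!is.null(voxel_mask)) {
    patterns_a <- patterns_a[, voxel_mask, drop = FALSE]
    patterns_b <- patterns_b[, voxel_mask, drop = FALSE]
  }
  if (ncol(patterns_a) < 3) stop("need at least 3 shared valid voxels")
  cc <- stats::cor(t(patterns_a), t(patterns_b))
  m <- (cc + t(cc)) / 2
  as_rsm(m, metric = "pearson", labels = rownames(patterns_a))
}

#' All cross-subject pair RSMs of a cohort
#'
#' @param cohort cohort object.
#' @param level aggregation level passed to \code{\link{enumerate_pairs}}.
#' @param voxel_mask optional shared voxel mask.
#' @return list with \code{rsms} (n_cond^2 x n_pairs matrix of vectorized
#'   pair RSMs), \code{pairs}, \code{units}, \code{fwd} (per-pair mean FWD
#'   when the cohort carries motion traces) and \code{n_conditions}.
#' @export
cohort_pair_rsms <- function(cohort, level = "run", voxel_mask = NULL) {
  en <- enumerate_pairs(cohort, level)
  pats <- lapply(seq_len(nrow(en$units)), function(i)
    unit_patterns(cohort, en$units[i, ]))
  n <- nrow(pats[[1]])
  rsms <- vapply(seq_len(nrow(en$pairs)), function(k) {
    a <- en$pairs$a[k]; b <- en$pairs$b[k]
    as.vector(pair_rsm(pats[[a]], pats[[b]], voxel_mask))
  }, numeric(n * n))
  fwd_u <- unit_fwd(cohort, en$units)
  fwd <- if (all(is.na(fwd_u))) rep(NA_real_, nrow(en$pairs))
    else (fwd_u[en$pairs$a] + fwd_u[en$pairs$b]) / 2
  list(rsms = rsms, pairs = en$pairs, units = en$units, fwd = fwd,
       n_conditions = n,
       labels = rownames(pats[[1]]))
}

unit_fwd <- function(cohort, units) {
  subs <- cohort_subjects(cohort)
  ids <- vapply(subs, function(s) s$id, character(1))
  vapply(seq_len(nrow(units)), function(i) {
    s <- subs[[which(ids == units$subject[i])]]
    fw <- vapply(s$runs, function(r)
      if (is.null(r$fwd)) NA_real_ else mean(r$fwd), numeric(1))
    if (is.na(units$run[i])) mean(fw)
    else fw[vapply(s$runs, function(r) r$run, integer(1)) == units$run[i]]
  }, numeric(1))
}

#' Average pair RSMs into a group RSM
#'
#' @param rsms list of conformable \code{rsm} objects, or a matrix of
#'   vectorized RSMs (one column per pair, as from
#'   \code{\link{cohort_pair_rsms}}).
#' @param weights optional non-negative weights, normalized internally.
#' @param labels optional condition labels for the result.
#' @return the element-wise (weighted) mean as an \code{rsm}.
#' @export
group_rsm <- function(rsms, weights = NULL, labels = NULL) {
  if (is.list(rsms)) {
    if (length(rsms) == 0) stop("empty RSM list")
    labels <- labels %||% rownames(rsms[[1]])
    n <- nrow(rsms[[1]])
    rsms <- vapply(rsms, as.vector, numeric(n * n))
    if (is.null(dim(rsms))) rsms <- matrix(rsms, ncol = 1)
  }
  if (ncol(rsms) == 0) stop("empty RSM list")
  n <- as.integer(sqrt(nrow(rsms)))
  if (is.null(weights)) weights <- rep(1, ncol(rsms))
  if (any(weights < 0)) stop("weights must be non-negative")
  weights <- weights / sum(weights)
  v <- as.vector(rsms %*% weights)
  as_rsm(matrix(v, n, n), metric = "pearson", labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' z-score an RSM for display
#'
#' Standardizes the selected entries (upper triangle, optionally including
#' the diagonal) to mean 0, s.d. 1, mirroring the result to keep symmetry.
#' Used for plotting representational content independent of signal
#' strength.
#'
#' @param rsm an \code{rsm}.
#' @param include_diagonal standardize the diagonal along with the
#'   off-diagonal entries.
#' @return z-scored \code{rsm}.
#' @export
zscore_rsm <- function(rsm, include_diagonal = TRUE) {
  m <- as.matrix(rsm)
  sel <- upper.tri(m, diag = include_diagonal)
  v <- m[sel]
  if (stats::sd(v) == 0) stop("constant RSM cannot be z-scored")
  z <- (m - mean(v)) / stats::sd(v)
  if (!include_diagonal) diag(z) <- diag(as.matrix(rsm))
  out <- (z + t(z)) / 2
  as_rsm(out, metric = attr(rsm, "metric") %||% "pearson",
         labels = rownames(m))
}

#' Spearman-Brown prophecy correction
#'
#' Corrects a split-half reliability for test length: doubling the test
#' gives reliability 2r / (1 + r).
#'
#' @param r raw split-half correlation, in (-1, 1].
#' @return corrected reliability.
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1 | r > 1)) stop("r must lie in (-1, 1]")
  2 * r / (1 + r)
}

#' Split-half noise ceiling of a cohort's group RSM
#'
#' Subjects are randomly partitioned into halves (runs travel with their
#' subject), a group RSM is built per half, and the Spearman correlation of
#' their upper triangles is computed. The raw correlation is averaged over
#' \code{n_splits} random partitions and corrected for test length with the
#' Spearman-Brown prophecy formula. Ceilings below \code{floor} are flagged
#' invalid (downstream normalization is then skipped).
#'
#' @param cohort cohort object with >= 4 subjects.
#' @param level aggregation level for pair RSMs within each half.
#' @param n_splits number of random splits averaged (default 100).
#' @param seed RNG seed.
#' @param floor validity floor on the corrected ceiling (default 0.1).
#' @param pair_set optional precomputed \code{\link{cohort_pair_rsms}}
#'   result to avoid recomputation.
#' @return list of class \code{noise_ceiling}: \code{corrected},
#'   \code{raw} (mean split correlation), \code{n_splits}, \code{valid}.
#' @export
split_half_noise_ceiling <- function(cohort, level = "run", n_splits = 100,
                                     seed = 1L, floor = 0.1,
                                     pair_set = NULL) {
  subs <- cohort_subjects(cohort)
  ns <- length(subs)
  if (ns < 4) stop("need at least 4 subjects (2 per half)")
  if (is.null(pair_set)) pair_set <- cohort_pair_rsms(cohort, level)
  sub_of_pair_a <- pair_set$units$subject[pair_set$pairs$a]
  sub_of_pair_b <- pair_set$units$subject[pair_set$pairs$b]
  ids <- vapply(subs, function(s) s$id, character(1))
  local_rng(seed)
  n <- pair_set$n_conditions
  ut <- upper.tri(matrix(0, n, n))
  raws <- vapply(seq_len(n_splits), function(k) {
    half <- sample(ids, floor(ns / 2))
    in1 <- sub_of_pair_a %in% half & sub_of_pair_b %in% half
    in2 <- !(sub_of_pair_a %in% half) & !(sub_of_pair_b %in% half)
    if (!any(in1) || !any(in2)) return(NA_real_)
    g1 <- rowMeans(pair_set$rsms[, in1, drop = FALSE])
    g2 <- rowMeans(pair_set$rsms[, in2, drop = FALSE])
    stats::cor(g1[ut], g2[ut], method = "spearman")
  }, numeric(1))
  raw <- mean(raws, na.rm = TRUE)
  corrected <- spearman_brown(max(raw, -0.999))
  out <- list(corrected = corrected, raw = raw, n_splits = n_splits,
              valid = corrected >= floor, floor = floor)
  class(out) <- "noise_ceiling"
  out
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("Split-half noise ceiling: %.3f (raw %.3f over %d splits)%s\n",
              x$corrected, x$raw, x$n_splits,
              if (x$valid) "" else " [below floor; not used for normalization]"))
  invisible(x)
}
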