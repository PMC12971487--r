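#' Convert a similarity RSM to a dissimilarity matrix
#'
#' Max-minus transform: \code{d = max(M) - M}, diagonal forced to zero,
#' symmetrized. Rank order of the similarities is preserved.
#'
#' @param rsm symmetric similarity RSM.
#' @return non-negative symmetric dissimilarity matrix with zero diagonal.
#' @export
rsm_to_dissimilarity <- function(rsm) {
  m <- as.matrix(rsm)
  if (max(abs(m - t(m))) >= 1e-8) stop("RSM must be symmetric")
  d <- max(m) - m
  d <- (d + t(d)) / 2
  diag(d) <- 0
  pmax(d, 0)
}

# Raw stress and normalized stress-1 of a configuration.
smacof_stress <- function(delta, X) {
  d <- as.matrix(stats::dist(X))
  ut <- upper.tri(delta)
  raw <- sum((delta[ut] - d[ut])^2)
  list(raw = raw, stress1 = sqrt(raw / sum(delta[ut]^2)))
}

#' Stress-minimizing MDS via the SMACOF algorithm
#'
#' Metric multidimensional scaling by stress majorization: repeated
#' Guttman transforms from a random (seeded) or supplied initial
#' configuration, stopping when the raw-stress decrease falls below
#' \code{tol} or at \code{max_iter}. Stress is guaranteed non-increasing
#' across iterations.
#'
#' @param dissimilarity symmetric non-negative matrix, zero diagonal.
#' @param n_dim embedding dimension (default 2); must be < n.
#' @param init optional n x n_dim starting configuration (warm start);
#'   when missing, the classical-scaling (Torgerson) solution is used,
#'   which is deterministic and avoids the local minima of random starts.
#' @param max_iter iteration cap (default 300).
#' @param tol convergence tolerance on the raw-stress decrease.
#' @param seed seed for the random jitter applied only when the
#'   initialization is degenerate.
#' @return object of class \code{embedding}: \code{coords} (n x n_dim),
#'   \code{stress} (normalized stress-1), \code{stress_trace} (raw stress
#'   per iteration), \code{n_iter}.
#' @export
smacof_embed <- function(dissimilarity, n_dim = 2, init = NULL,
                         max_iter = 300, tol = 1e-10, seed = 1L) {
  delta <- as.matrix(dissimilarity)
  n <- nrow(delta)
  if (n_dim >= n) stop("n_dim must be smaller than the number of points")
  if (any(delta < 0) || any(abs(diag(delta)) > 1e-12))
    stop("invalid dissimilarity matrix")
  if (is.null(init)) {
    # classical scaling (Torgerson) start
    J <- diag(n) - 1 / n
    B <- -0.5 * J %*% (delta^2) %*% J
    eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
    vals <- pmax(eig$values[seq_len(n_dim)], 0)
    X <- eig$vectors[, seq_len(n_dim), drop = FALSE] %*% diag(sqrt(vals),
                                                              n_dim)
    if (max(stats::dist(X)) == 0) {
      local_rng(seed)
      X <- matrix(stats::rnorm(n * n_dim), n, n_dim)
    }
  } else {
    X <- as.matrix(init)
    if (!all(dim(X) == c(n, n_dim))) stop("init has wrong dimensions")
    # a degenerate (zero-spread) warm start cannot move; jitter it
    if (max(stats::dist(X)) == 0) {
      local_rng(seed)
      X <- X + matrix(stats::rnorm(n * n_dim, sd = 1e-6), n, n_dim)
    }
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  trace <- numeric(0)
  s_old <- smacof_stress(delta, X)$raw
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    D <- as.matrix(stats::dist(X))
    B <- matrix(0, n, n)
    nz <- D > 0
    B[nz] <- -delta[nz] / D[nz]
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    s_new <- smacof_stress(delta, X)$raw
    trace <- c(trace, s_new)
    n_iter <- it
    if (s_old - s_new < tol) break
    s_old <- s_new
  }
  structure(list(coords = X, stress = smacof_stress(delta, X)$stress1,
                 stress_trace = trace, n_iter = n_iter,
                 dissimilarity = delta),
            class = "embedding")
}

#' Procrustes distance between two configurations
#'
#' Root-mean-square discrepancy after optimal translation, uniform
#' scaling and rotation/reflection of \code{Y} onto \code{X}; used to
#' compare embeddings up to rigid motion.
#'
#' @param X,Y n x d coordinate matrices.
#' @return non-negative scalar (0 = identical up to similarity transform).
#' @export
procrustes_distance <- function(X, Y) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  nx <- sqrt(sum(X^2)); ny <- sqrt(sum(Y^2))
  if (nx == 0 || ny == 0) return(sqrt(sum((X - Y)^2) / nrow(X)))
  X <- X / nx; Y <- Y / ny
  s <- svd(crossprod(Y, X))
  Yr <- Y %*% (s$u %*% t(s$v))
  sqrt(sum((X - Yr)^2) / nrow(X))
}

#' Hierarchically aligned embeddings across regions and age groups
#'
#' Three-stage alignment mirroring the display convention for comparing
#' representational spaces across groups: (1) one global SMACOF fit on the
#' mean dissimilarity over all (region, age) cells; (2) per-region fits on
#' the age-averaged dissimilarity, warm-started from the global
#' configuration; (3) per-(region, age) fits warm-started from the
#' region's stage-2 configuration. Warm starts keep the plots mutually
#' comparable; majorization guarantees each refinement's stress does not
#' exceed that of evaluating its initialization.
#'
#' @param rsms named list of RSMs; names of the form
#'   \code{"<roi>.<age>"}, or supply \code{keys}.
#' @param keys optional data frame with columns \code{roi}, \code{age}
#'   (one row per RSM).
#' @param n_dim,max_iter,tol,seed passed to \code{\link{smacof_embed}}.
#' @return list with \code{global} (stage-1 \code{embedding}),
#'   \code{by_roi} (stage 2), \code{by_cell} (stage 3, keyed like
#'   \code{rsms}).
#' @export
hierarchical_embed <- function(rsms, keys = NULL, n_dim = 2,
                               max_iter = 300, tol = 1e-10, seed = 1L) {
  if (length(rsms) == 0) stop("no RSMs supplied")
  if (is.null(keys)) {
    parts <- strsplit(names(rsms), ".", fixed = TRUE)
    keys <- data.frame(roi = vapply(parts, `[`, "", 1),
                       age = vapply(parts, function(p)
                         paste(p[-1], collapse = "."), ""))
  }
  diss <- lapply(rsms, rsm_to_dissimilarity)
  mean_diss <- function(ds) Reduce(`+`, ds) / length(ds)
  global <- smacof_embed(mean_diss(diss), n_dim = n_dim,
                         max_iter = max_iter, tol = tol, seed = seed)
  rois <- unique(keys$roi)
  by_roi <- lapply(rois, function(rr) {
    smacof_embed(mean_diss(diss[keys$roi == rr]), n_dim = n_dim,
                 init = global$coords, max_iter = max_iter, tol = tol)
  })
  names(by_roi) <- rois
  by_cell <- lapply(seq_along(diss), function(i) {
    smacof_embed(diss[[i]], n_dim = n_dim,
                 init = by_roi[[keys$roi[i]]]$coords,
                 max_iter = max_iter, tol = tol)
  })
  names(by_cell) <- names(rsms)
  list(global = global, by_roi = by_roi, by_cell = by_cell, keys = keys)
}
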