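#' Extract perceptual features from a stimulus image
#'
#' Computes the four image features used to build the perceptual model RSMs:
#' \describe{
#'   \item{size}{number of foreground pixels minus number of background
#'     pixels (over the full canvas).}
#'   \item{elongation}{max of height/width and width/height of the
#'     foreground bounding box (dimensionless, >= 1).}
#'   \item{color}{mean of the three color-channel means over the full image
#'     (0-255 scale).}
#'   \item{compactness}{isoperimetric quotient 4*pi*A/P^2 — the ratio of the
#'     shape's area to the area of the disc with the same perimeter. The
#'     perimeter is measured as the marching-squares contour length of the
#'     (lightly smoothed) mask.}
#' }
#'
#' @param image height x width x 3 numeric array (0-255 scale), or a matrix
#'   for grayscale.
#' @param mask logical height x width foreground mask.
#' @return list of class \code{feature_vector} with fields \code{size},
#'   \code{elongation}, \code{color}, \code{compactness}.
#' @export
extract_perceptual_features <- function(image, mask) {
  if (is.matrix(image)) image <- array(rep(image, 3),
                                       dim = c(dim(image), 3))
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask and image dimensions differ")
  mask <- mask > 0
  n_fg <- sum(mask)
  if (n_fg == 0) stop("empty foreground mask")
  n_bg <- length(mask) - n_fg
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  h <- diff(rows) + 1; w <- diff(cols) + 1
  A <- n_fg
  P <- mask_perimeter(mask)
  out <- list(
    size = n_fg - n_bg,
    elongation = max(h / w, w / h),
    color = mean(apply(image, 3, mean)),
    compactness = 4 * pi * A / P^2
  )
  class(out) <- "feature_vector"
  out
}

# Marching-squares contour length of a binary mask. The mask is upsampled
# 2x (nearest neighbour) and smoothed with a 4x4 box filter so the 0.5
# level set interpolates the true boundary at subpixel resolution instead
# of tracing pixel staircases. The smoothing radius (2 fine-grid pixels =
# 1 original pixel) balances the staircase overestimate on curved/oblique
# edges against corner rounding on polygonal shapes; both stay within a
# few percent for shapes tens of pixels across.
mask_perimeter <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask))
  up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  pad <- 6
  f <- matrix(0, nrow(up) + 2 * pad, ncol(up) + 2 * pad)
  f[pad + seq_len(nrow(up)), pad + seq_len(ncol(up))] <- up
  f <- box_blur(f, 4)
  cl <- grDevices::contourLines(x = seq_len(nrow(f)), y = seq_len(ncol(f)),
                                z = f, levels = 0.5)
  if (length(cl) == 0) return(0)
  sum(vapply(cl, function(s)
    sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), numeric(1))) / 2
}

# Separable k x k box blur (zero-padded edges).
box_blur <- function(m, k) {
  kern <- rep(1 / k, k)
  f <- apply(m, 2, function(col) stats::filter(col, kern, sides = 2))
  f[is.na(f)] <- 0
  f <- t(apply(f, 1, function(row) stats::filter(row, kern, sides = 2)))
  f[is.na(f)] <- 0
  f
}

#' Build a perceptual feature model RSM from per-condition scalar values
#'
#' Pairwise absolute differences between the feature values are scaled by
#' their maximum to [0, 1]; similarity is 1 minus the scaled distance, with
#' diagonal exactly 1. When all values are equal the model carries no
#' information and is flagged degenerate.
#'
#' @param values numeric vector, one scalar feature value per condition.
#' @param name model name stored on the RSM.
#' @return a \code{model_rsm} (see \code{\link{as_rsm}}) with family
#'   \code{"perceptual"} and a \code{degenerate} attribute.
#' @export
feature_rsm <- function(values, name = "feature") {
  n <- length(values)
  if (n < 2) stop("need at least two conditions")
  d <- abs(outer(values, values, `-`))
  degenerate <- max(d) == 0
  if (!degenerate) d <- d / max(d)
  m <- 1 - d
  diag(m) <- 1
  out <- as_rsm(m, metric = "model", labels = names(values))
  attr(out, "model_name") <- name
  attr(out, "family") <- "perceptual"
  attr(out, "degenerate") <- degenerate
  class(out) <- c("model_rsm", class(out))
  out
}

#' Categorical hypothesis model RSMs
#'
#' Builds the five categorical models for a stimulus set:
#' \describe{
#'   \item{identity}{within versus between image — the identity matrix.}
#'   \item{category}{generalization across exemplars within a basic-level
#'     category: within-exemplar (diagonal) 0, within-category across
#'     exemplars +1, across categories -1.}
#'   \item{animacy_tripartite}{the animate / inanimate-small /
#'     inanimate-large distinction: same class +1, different class -1,
#'     diagonal 0.}
#'   \item{animate_vs_inanimate}{animate versus both inanimate classes,
#'     same +1 / different -1 coding, diagonal 0.}
#'   \item{small_vs_large_inanimate}{inanimate-small versus inanimate-large
#'     restricted to inanimate conditions; pairs involving animate
#'     conditions are neutral 0.}
#' }
#'
#' @param stimulus_set a \code{\link{make_stimulus_set}} object.
#' @return named list of \code{model_rsm} objects, family
#'   \code{"categorical"}.
#' @export
categorical_rsms <- function(stimulus_set) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  n <- nrow(stimulus_set)
  labs <- stimulus_set$condition
  cat_eq <- outer(stimulus_set$category, stimulus_set$category, `==`)
  cls <- stimulus_set$class
  cls_eq <- outer(cls, cls, `==`)
  mk <- function(m, nm) {
    out <- as_rsm(m, metric = "model", labels = labs)
    attr(out, "model_name") <- nm
    attr(out, "family") <- "categorical"
    class(out) <- c("model_rsm", class(out))
    out
  }
  identity_m <- diag(n)
  category_m <- ifelse(cat_eq, 1, -1)
  diag(category_m) <- 0
  tri_m <- ifelse(cls_eq, 1, -1)
  diag(tri_m) <- 0
  animate <- cls == "animate"
  an_eq <- outer(animate, animate, `==`)
  an_m <- ifelse(an_eq, 1, -1)
  diag(an_m) <- 0
  inan <- !animate
  small <- cls == "inanimate-small"
  sl_m <- matrix(0, n, n)
  both_inan <- outer(inan, inan, `&`)
  sl_m[both_inan] <- ifelse(outer(small, small, `==`)[both_inan], 1, -1)
  diag(sl_m) <- 0
  list(identity = mk(identity_m, "identity"),
       category = mk(category_m, "category"),
       animacy_tripartite = mk(tri_m, "animacy_tripartite"),
       animate_vs_inanimate = mk(an_m, "animate_vs_inanimate"),
       small_vs_large_inanimate = mk(sl_m, "small_vs_large_inanimate"))
}

#' Perceptual model RSMs for a rendered stimulus set
#'
#' Convenience wrapper: extracts the four perceptual features from rendered
#' images (or uses a supplied feature table) and returns one
#' \code{\link{feature_rsm}} per feature.
#'
#' @param features data frame with columns \code{size}, \code{elongation},
#'   \code{color}, \code{compactness} (e.g. from
#'   \code{\link{render_stimulus_images}} or measured by
#'   \code{\link{extract_perceptual_features}}).
#' @return named list of four \code{model_rsm} objects.
#' @export
perceptual_rsms <- function(features) {
  needed <- c("size", "elongation", "color", "compactness")
  if (!all(needed %in% names(features)))
    stop("features must contain columns: ", paste(needed, collapse = ", "))
  stats::setNames(lapply(needed, function(f)
    feature_rsm(features[[f]], name = f)), needed)
}
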