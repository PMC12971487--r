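#' @name stimulus-images
#' @title Parametric stimulus images with analytic feature ground truth
#'
#' @description Stimuli are rendered from a parametric shape family
#' (ellipses, axis-aligned rectangles, convex polygons) on a black canvas,
#' so that the perceptual features used by the feature models — size,
#' elongation, mean color and compactness — have closed-form ground-truth
#' values against which pixel-based extraction can be validated.
NULL

# Shape geometry: analytic area / perimeter / bounding box -------------------

shape_area <- function(shape) {
  switch(shape$type,
    ellipse = pi * shape$rx * shape$ry,
    rect = shape$w * shape$h,
    polygon = {
      x <- shape$x; y <- shape$y; n <- length(x)
      j <- c(n, seq_len(n - 1))
      abs(sum(x[j] * y - x * y[j])) / 2
    },
    stop("unknown shape type: ", shape$type))
}

shape_perimeter <- function(shape) {
  switch(shape$type,
    ellipse = {
      # Ramanujan's second approximation; error < 1e-6 for aspect <= 10
      a <- shape$rx; b <- shape$ry
      h <- ((a - b) / (a + b))^2
      pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    },
    rect = 2 * (shape$w + shape$h),
    polygon = {
      x <- shape$x; y <- shape$y; n <- length(x)
      j <- c(2:n, 1)
      sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
    },
    stop("unknown shape type: ", shape$type))
}

shape_bbox <- function(shape) {
  switch(shape$type,
    ellipse = c(w = 2 * shape$rx, h = 2 * shape$ry),
    rect = c(w = shape$w, h = shape$h),
    polygon = c(w = diff(range(shape$x)), h = diff(range(shape$y))),
    stop("unknown shape type: ", shape$type))
}

shape_inside <- function(shape, px, py) {
  switch(shape$type,
    ellipse = ((px - shape$cx) / shape$rx)^2 +
      ((py - shape$cy) / shape$ry)^2 <= 1,
    rect = abs(px - shape$cx) <= shape$w / 2 &
      abs(py - shape$cy) <= shape$h / 2,
    polygon = point_in_polygon(px, py, shape$x, shape$y),
    stop("unknown shape type: ", shape$type))
}

point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Render a single parametric shape
#'
#' @param shape a list describing the shape. Common fields: \code{type}
#'   (\code{"ellipse"}, \code{"rect"} or \code{"polygon"}), \code{fill}
#'   (RGB triple on the 0-255 scale). Ellipses take \code{cx, cy, rx, ry};
#'   rectangles \code{cx, cy, w, h}; polygons vertex vectors \code{x, y}.
#' @param image_size canvas size as \code{c(width, height)} in pixels.
#' @return list with \code{image} (height x width x 3 array, 0-255),
#'   \code{mask} (logical height x width matrix) and \code{truth}: the
#'   analytic \code{area}, \code{perimeter}, \code{size}, \code{elongation},
#'   \code{color} and \code{compactness} of the rendered shape.
#' @export
render_shape <- function(shape, image_size = c(640, 360)) {
  W <- image_size[1]; H <- image_size[2]
  if (W < 1 || H < 1) stop("image_size must be positive")
  bb <- shape_bbox(shape)
  ctr <- switch(shape$type,
                polygon = c(mean(range(shape$x)), mean(range(shape$y))),
                c(shape$cx, shape$cy))
  if (ctr[1] - bb["w"] / 2 < 0 || ctr[1] + bb["w"] / 2 > W ||
      ctr[2] - bb["h"] / 2 < 0 || ctr[2] + bb["h"] / 2 > H)
    stop("shape exceeds canvas")
  px <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
  py <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H)
  mask <- matrix(shape_inside(shape, as.vector(px), as.vector(py)), nrow = H)
  fill <- shape$fill
  if (is.null(fill)) fill <- c(200, 200, 200)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    plane[mask] <- fill[ch]
    img[, , ch] <- plane
  }
  A <- shape_area(shape)
  P <- shape_perimeter(shape)
  truth <- list(
    area = A,
    perimeter = P,
    size = 2 * A - W * H,
    elongation = max(bb["w"] / bb["h"], bb["h"] / bb["w"]),
    color = mean(fill) * A / (W * H),
    compactness = 4 * pi * A / P^2
  )
  list(image = img, mask = mask, truth = truth, shape = shape)
}

random_shape <- function(image_size) {
  W <- image_size[1]; H <- image_size[2]
  type <- sample(c("ellipse", "rect", "polygon"), 1)
  scale <- stats::runif(1, 0.12, 0.38) * min(W, H)
  aspect <- exp(stats::runif(1, 0, log(3)))
  fill <- stats::runif(3, 40, 255)
  cx <- W / 2; cy <- H / 2
  if (type == "ellipse") {
    ry <- scale / sqrt(aspect); rx <- scale * sqrt(aspect)
    rx <- min(rx, W / 2 - 1); ry <- min(ry, H / 2 - 1)
    list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry, fill = fill)
  } else if (type == "rect") {
    h <- 2 * scale / sqrt(aspect); w <- 2 * scale * sqrt(aspect)
    w <- min(w, W - 2); h <- min(h, H - 2)
    list(type = "rect", cx = cx, cy = cy, w = w, h = h, fill = fill)
  } else {
    n <- sample(5:9, 1)
    ang <- sort(stats::runif(n, 0, 2 * pi))
    rad <- stats::runif(n, 0.5, 1) * scale
    x <- cx + rad * cos(ang) * sqrt(aspect)
    y <- cy + rad * sin(ang) / sqrt(aspect)
    x <- pmin(pmax(x, 1), W - 1); y <- pmin(pmax(y, 1), H - 1)
    list(type = "polygon", x = x, y = y, fill = fill)
  }
}

#' Render one stimulus image per condition
#'
#' Draws a random parametric shape per condition (seeded), returning the
#' rendered images, foreground masks and a ground-truth feature table whose
#' values are analytic properties of the shapes, independent of the
#' rasterization.
#'
#' @param stimulus_set a \code{\link{make_stimulus_set}} object.
#' @param image_size canvas \code{c(width, height)}; default the 640 x 360
#'   presentation canvas.
#' @param seed integer seed for the shape draws.
#' @param shapes optional list of shape descriptions (one per condition)
#'   overriding the random draws.
#' @return list with \code{images}, \code{masks} (lists keyed by condition)
#'   and \code{features}: a data frame of analytic ground-truth
#'   \code{size}, \code{elongation}, \code{color}, \code{compactness} per
#'   condition.
#' @export
render_stimulus_images <- function(stimulus_set, image_size = c(640, 360),
                                   seed = 1L, shapes = NULL) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  n <- nrow(stimulus_set)
  local_rng(seed)
  if (is.null(shapes)) shapes <- replicate(n, random_shape(image_size),
                                           simplify = FALSE)
  if (length(shapes) != n) stop("need one shape per condition")
  rendered <- lapply(shapes, render_shape, image_size = image_size)
  feats <- do.call(rbind, lapply(rendered, function(r)
    as.data.frame(r$truth[c("size", "elongation", "color", "compactness")])))
  feats <- cbind(condition = stimulus_set$condition, feats)
  rownames(feats) <- NULL
  list(images = stats::setNames(lapply(rendered, `[[`, "image"),
                                stimulus_set$condition),
       masks = stats::setNames(lapply(rendered, `[[`, "mask"),
                               stimulus_set$condition),
       features = feats)
}
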