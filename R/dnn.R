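#' @name dnn-alignment
#' @title Layerwise alignment between brain RSMs and network activations
#' @description The package compares brain representational geometry with
#' the layer hierarchy of a convolutional network. Activations can come
#' from the built-in untrained (Glorot-initialized) eight-stage
#' convolutional stack, or be supplied externally (e.g. exported from a
#' pretrained model) as one images x features matrix per layer.
NULL

resize_bilinear <- function(img, out_h, out_w) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  ys <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, C))
  for (ch in seq_len(C)) {
    p <- img[, , ch]
    out[, , ch] <- (1 - wy) * ((p[y0, x0] * rep((1 - wx), each = out_h)) +
                                 (p[y0, x1] * rep(wx, each = out_h))) +
      wy * ((p[y1, x0] * rep((1 - wx), each = out_h)) +
              (p[y1, x1] * rep(wx, each = out_h)))
  }
  out
}

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# 3x3 same-padding convolution via im2col; x is H x W x C_in.
conv3x3 <- function(x, weights) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, dim = c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  k <- 1
  for (dw in 0:2) for (dh in 0:2) {
    sl <- xp[dh + seq_len(H), dw + seq_len(W), , drop = FALSE]
    cols[, (k - 1) * C + seq_len(C)] <- matrix(sl, H * W, C)
    k <- k + 1
  }
  out <- cols %*% weights
  array(out, dim = c(H, W, ncol(weights)))
}

maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  a <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  b <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  c_ <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  d <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  pmax(a, b, c_, d)
}

relu <- function(x) pmax(x, 0)

#' Activations from an untrained Glorot-initialized convolutional stack
#'
#' Runs each stimulus image through a deterministic (seeded) convolutional
#' network with the canonical five convolutional and three fully connected
#' stages; weights are drawn once with Glorot (uniform) initialization and
#' never updated. Activations are recorded post-ReLU and flattened at each
#' of the 8 capture points (\code{conv1 ... conv5, fc6, fc7, output}; the
#' output stage is linear). Images are composited onto a mid-gray
#' background using their foreground masks and resized to the network
#' input resolution.
#'
#' @param images list of height x width x 3 arrays (0-255 scale).
#' @param masks optional list of logical foreground masks; background
#'   pixels are set to gray (128).
#' @param seed RNG seed for the weight draw.
#' @param input_size network input resolution (default 64).
#' @param n_output output-layer width (default 12, the category count).
#' @return object of class \code{layer_activations}: named list of
#'   images x features matrices, one per layer, plus a \code{layers}
#'   attribute giving the capture order.
#' @export
default_activation_provider <- function(images, masks = NULL, seed = 1L,
                                        input_size = 64, n_output = 12) {
  dims <- vapply(images, function(im) dim(im)[1:2], numeric(2))
  if (any(dims != dims[, 1])) stop("inconsistent image sizes")
  local_rng(seed)
  channels <- c(3, 16, 32, 48, 64, 64)
  conv_w <- lapply(seq_len(5), function(l)
    matrix(glorot_uniform(9 * channels[l], 9 * channels[l + 1],
                          9 * channels[l] * channels[l + 1]),
           9 * channels[l], channels[l + 1]))
  flat_dim <- (input_size / 2^5)^2 * channels[6]
  fc_dims <- c(flat_dim, 128, 64, n_output)
  fc_w <- lapply(seq_len(3), function(l)
    matrix(glorot_uniform(fc_dims[l], fc_dims[l + 1],
                          fc_dims[l] * fc_dims[l + 1]),
           fc_dims[l], fc_dims[l + 1]))
  layer_names <- c(paste0("conv", 1:5), "fc6", "fc7", "output")
  acts <- lapply(layer_names, function(x) NULL)
  names(acts) <- layer_names
  for (i in seq_along(images)) {
    im <- images[[i]] / 255
    if (!is.null(masks)) {
      for (ch in 1:3) {
        p <- im[, , ch]
        p[!masks[[i]]] <- 128 / 255
        im[, , ch] <- p
      }
    }
    x <- resize_bilinear(im, input_size, input_size)
    feats <- vector("list", 8)
    for (l in seq_len(5)) {
      x <- maxpool2(relu(conv3x3(x, conv_w[[l]])))
      feats[[l]] <- as.vector(x)
    }
    v <- as.vector(x)
    v <- relu(as.vector(v %*% fc_w[[1]])); feats[[6]] <- v
    v <- relu(as.vector(v %*% fc_w[[2]])); feats[[7]] <- v
    feats[[8]] <- as.vector(v %*% fc_w[[3]])
    for (l in seq_len(8))
      acts[[l]] <- rbind(acts[[l]], feats[[l]])
  }
  for (l in seq_len(8)) rownames(acts[[l]]) <- names(images)
  attr(acts, "layers") <- layer_names
  class(acts) <- "layer_activations"
  acts
}

#' Layer RSMs from network activations
#'
#' One Pearson-correlation RSM per layer, computed between the images'
#' flattened activation vectors; symmetric with unit diagonal.
#'
#' @param activations a \code{layer_activations} object or named list of
#'   images x features matrices.
#' @return named list of \code{model_rsm} objects, family
#'   \code{"dnn-layer"}.
#' @export
layer_rsms <- function(activations) {
  lapply(unclass_activations(activations), function(a) {
    sds <- apply(a, 1, stats::sd)
    if (any(sds == 0))
      stop("constant activation row(s): ",
           paste(rownames(a)[sds == 0], collapse = ", "))
    m <- stats::cor(t(a))
    m <- (m + t(m)) / 2
    diag(m) <- 1
    out <- as_rsm(m, metric = "pearson", labels = rownames(a))
    attr(out, "family") <- "dnn-layer"
    class(out) <- c("model_rsm", class(out))
    out
  })
}

unclass_activations <- function(a) {
  if (inherits(a, "layer_activations")) {
    nm <- attr(a, "layers")
    a <- unclass(a)
    attr(a, "layers") <- NULL
    a[nm]
  } else a
}

#' Layer-resolved RSA profile of brain RSMs
#'
#' For each network layer, bootstraps the Spearman correlation (diagonal
#' excluded) between the resampled brain group RSM and the layer RSM,
#' normalized by the group/ROI noise ceiling.
#'
#' @param brain_rsms vectorized pair RSM matrix (e.g. \code{$rsms} from
#'   \code{\link{cohort_pair_rsms}}) or list of \code{rsm}s.
#' @param layers named list of layer \code{model_rsm}s (from
#'   \code{\link{layer_rsms}}).
#' @param ceiling optional noise ceiling for normalization.
#' @param n_boot,seed,weights as \code{\link{bootstrap_statistic}}.
#' @return list with \code{profile} (data frame: layer, rho, rho_norm,
#'   ci_lo, ci_hi, normalized) and \code{results} (per-layer
#'   \code{bootstrap_result}s).
#' @export
layerwise_rsa <- function(brain_rsms, layers, ceiling = NULL,
                          n_boot = 1000, seed = 1L, weights = NULL) {
  results <- lapply(seq_along(layers), function(l) {
    lm_ <- as.matrix(layers[[l]])
    bootstrap_statistic(brain_rsms,
                        function(m) rsa_correlation(m, lm_,
                                                    include_diagonal = FALSE),
                        n_boot = n_boot, seed = seed + l, weights = weights)
  })
  names(results) <- names(layers)
  rho <- vapply(results, `[[`, numeric(1), "point")
  if (!is.null(ceiling)) {
    nz <- normalize_by_ceiling(rho, ceiling)
    rho_norm <- nz$value; normalized <- nz$normalized
  } else {
    rho_norm <- rho; normalized <- FALSE
  }
  profile <- data.frame(layer = names(layers), rho = rho,
                        rho_norm = rho_norm,
                        ci_lo = vapply(results, function(r) r$ci[1],
                                       numeric(1)),
                        ci_hi = vapply(results, function(r) r$ci[2],
                                       numeric(1)),
                        normalized = normalized,
                        row.names = NULL)
  list(profile = profile, results = results)
}
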