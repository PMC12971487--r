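#' Construct a nested stimulus set
#'
#' Builds the condition labelling used throughout the package: animacy
#' classes, each holding a fixed number of basic-level categories, each
#' holding a fixed number of exemplars. The default (3 classes x 4
#' categories x 3 exemplars) gives the canonical 36-condition design.
#' Conditions are ordered class -> category -> exemplar, deterministically
#' given the labels.
#'
#' @param n_classes number of animacy classes (default 3: animate,
#'   inanimate-small, inanimate-large).
#' @param n_categories_per_class number of basic-level categories per class.
#' @param n_exemplars number of exemplars per category.
#' @param class_labels optional character vector of class labels; defaults to
#'   the canonical three (recycled/extended as \code{class<k>} if more are
#'   requested).
#' @return An object of class \code{stimulus_set}: a data frame with one row
#'   per condition and columns \code{condition} (id string), \code{class},
#'   \code{category}, \code{exemplar}, plus attributes recording the design
#'   counts.
#' @examples
#' ss <- make_stimulus_set()
#' nrow(ss)         # 36
#' @export
make_stimulus_set <- function(n_classes = 3, n_categories_per_class = 4,
                              n_exemplars = 3, class_labels = NULL) {
  counts <- c(n_classes, n_categories_per_class, n_exemplars)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be positive integers")
  canonical <- c("animate", "inanimate-small", "inanimate-large")
  if (is.null(class_labels)) {
    class_labels <- if (n_classes <= 3) canonical[seq_len(n_classes)]
      else c(canonical, paste0("class", seq_len(n_classes - 3) + 3))
  }
  if (length(class_labels) != n_classes)
    stop("class_labels must have length n_classes")
  grid <- expand.grid(exemplar = seq_len(n_exemplars),
                      category_in_class = seq_len(n_categories_per_class),
                      class_idx = seq_len(n_classes))
  # expand.grid varies the first column fastest; reorder so class varies slowest
  grid <- grid[order(grid$class_idx, grid$category_in_class, grid$exemplar), ]
  cls <- class_labels[grid$class_idx]
  category <- sprintf("%s.cat%02d",
                      cls,
                      (grid$class_idx - 1) * n_categories_per_class +
                        grid$category_in_class)
  out <- data.frame(
    condition = sprintf("%s.ex%d", category, grid$exemplar),
    class = cls,
    category = category,
    exemplar = grid$exemplar,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_classes") <- n_classes
  attr(out, "n_categories_per_class") <- n_categories_per_class
  attr(out, "n_exemplars") <- n_exemplars
  class(out) <- c("stimulus_set", "data.frame")
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d classes x %d categories x %d exemplars = %d conditions\n",
              attr(x, "n_classes"), attr(x, "n_categories_per_class"),
              attr(x, "n_exemplars"), nrow(x)))
  invisible(x)
}

#' Number of conditions in a stimulus set
#' @param stimulus_set a \code{stimulus_set}.
#' @return integer count of conditions.
#' @export
n_conditions <- function(stimulus_set) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  nrow(stimulus_set)
}
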