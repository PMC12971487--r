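#' @name formats
#' @title Readers and writers for the pipeline's exchange formats
#' @description Event tables and confounds travel as BIDS-style TSV;
#' RSMs and pattern matrices as TSV with a JSON sidecar carrying labels,
#' metric and provenance; stimulus images as PNG plus a mask PNG. Numeric
#' payloads round-trip losslessly (full double precision).
NULL

#' Write / read a BIDS-style events TSV
#'
#' @param events an \code{event_table} (columns onset, duration,
#'   trial_type, and optionally run).
#' @param path file path.
#' @return \code{read_events_tsv} returns an \code{event_table}.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("events file ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$run)) df$run <- 1L
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write / read a confounds TSV with a framewise_displacement column
#'
#' @param fwd numeric FWD trace; extra confound columns may be supplied
#'   via \code{extra}.
#' @param path file path.
#' @param extra optional data frame of additional per-frame confounds.
#' @return \code{read_confounds_tsv} returns a data frame; the FWD trace
#'   is in \code{$framewise_displacement}.
#' @export
write_confounds_tsv <- function(fwd, path, extra = NULL) {
  df <- data.frame(framewise_displacement = fwd)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confounds_tsv
#' @export
read_confounds_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(df$framewise_displacement))
    stop("confounds file ", path, " missing column: framewise_displacement")
  df
}

#' Write / read an RSM as TSV plus JSON sidecar
#'
#' The matrix goes into a TSV (full precision); the sidecar records the
#' metric tag, condition labels and provenance.
#'
#' @param rsm an \code{rsm}.
#' @param path TSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{read_rsm} returns the \code{rsm}.
#' @export
write_rsm <- function(rsm, path) {
  m <- as.matrix(rsm)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  side <- list(metric = attr(rsm, "metric"),
               labels = rownames(m),
               provenance = attr(rsm, "provenance"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rsm
#' @export
read_rsm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  side_path <- paste0(path, ".json")
  metric <- "pearson"; labels <- NULL; provenance <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    metric <- side$metric %||% "pearson"
    labels <- side$labels
    provenance <- side$provenance
  }
  as_rsm(m, metric = metric, labels = labels, provenance = provenance,
         symmetric = max(abs(m - t(m))) < 1e-10)
}

#' Write / read a condition x voxel pattern matrix with labels
#'
#' @param patterns condition x voxel matrix (condition labels as row
#'   names).
#' @param path TSV path; labels go into \code{<path>.json}.
#' @return \code{read_patterns} returns the labeled matrix.
#' @export
write_patterns <- function(patterns, path) {
  utils::write.table(format(patterns, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(conditions = rownames(patterns),
                            n_voxels = ncol(patterns)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    rownames(m) <- side$conditions
  }
  m
}

#' Write a stimulus image and its foreground mask as PNG
#'
#' @param image height x width x 3 array on the 0-255 scale.
#' @param mask logical foreground mask.
#' @param path image path; the mask is written as
#'   \code{<path>_mask.png}.
#' @return invisibly, the two paths.
#' @export
write_stimulus_png <- function(image, mask, path) {
  png::writePNG(image / 255, path)
  mask_path <- sub("\\.png$", "_mask.png", path)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), mask_path)
  invisible(c(path, mask_path))
}

#' Read a stimulus image and mask written by \code{write_stimulus_png}
#'
#' @param path image path.
#' @return list with \code{image} (0-255 array) and \code{mask}
#'   (logical).
#' @export
read_stimulus_png <- function(path) {
  img <- png::readPNG(path) * 255
  mask_path <- sub("\\.png$", "_mask.png", path)
  mask <- png::readPNG(mask_path) > 0.5
  if (length(dim(mask)) == 3) mask <- mask[, , 1]
  list(image = img, mask = mask)
}

#' Write / read pattern volumes as NIfTI (one volume per condition)
#'
#' Requires the optional RNifti package. Patterns are stored as a 4D
#' volume (x, y, z, condition) with the condition labels in a JSON
#' sidecar; the voxel axis is packed into x.
#'
#' @param patterns condition x voxel matrix.
#' @param path NIfTI path (.nii or .nii.gz).
#' @return \code{read_patterns_nifti} returns the labeled matrix.
#' @export
write_patterns_nifti <- function(patterns, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  arr <- array(t(patterns), dim = c(ncol(patterns), 1, 1, nrow(patterns)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(list(conditions = rownames(patterns)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patterns_nifti
#' @export
read_patterns_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input")
  arr <- RNifti::readNifti(path)
  m <- t(matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4]))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path))
    rownames(m) <- jsonlite::read_json(side_path,
                                       simplifyVector = TRUE)$conditions
  m
}
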