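#' Construct a labeled segmentation volume
#'
#' A `labeled_volume` wraps a 3D array of non-negative integer cell labels
#' together with its voxel spacing (micrometres per voxel, `(dz, dy, dx)`
#' order matching the array dimensions) and a set of background labels that
#' are treated as exterior (walls, air, unsegmented space) and never become
#' cells in downstream complexes.
#'
#' @param labels 3D array (or a matrix, promoted to a single-slice 3D array)
#'   of non-negative integers; each distinct non-background value is one cell.
#' @param spacing Numeric length-3, strictly positive, µm per voxel along each
#'   array dimension.
#' @param background Integer vector of label values treated as exterior.
#'   Defaults to `0`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, spacing = c(1, 1, 1), background = 0L) {
  if (is.matrix(labels)) {
    labels <- array(labels, dim = c(dim(labels), 1L))
  }
  if (is.null(dim(labels)) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array (or a matrix for a single slice)",
         call. = FALSE)
  }
  if (anyNA(labels)) stop("`labels` must not contain NA", call. = FALSE)
  if (any(labels < 0)) stop("`labels` must be non-negative", call. = FALSE)
  if (any(labels != round(labels))) {
    stop("`labels` must be integer-valued", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = spacing,
         background = as.integer(sort(unique(background)))),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing (%s) um\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = ", ")))
  cat(sprintf("  %d cells (background labels: %s)\n",
              length(cell_labels(x)), paste(x$background, collapse = ", ")))
  invisible(x)
}

#' Cell labels present in a volume
#'
#' @param vol A [labeled_volume()].
#' @return Sorted integer vector of the non-background labels present.
#' @export
cell_labels <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  setdiff(sort(unique(as.vector(vol$labels))), vol$background)
}

#' Read a labeled segmentation volume
#'
#' Reads a multi-page unsigned-integer TIFF into a [labeled_volume()]. Pages
#' become the third array dimension. Label values are preserved bit-exactly.
#'
#' @param path File to read.
#' @param format Only `"tiff"` is supported.
#' @param spacing,background Passed to [labeled_volume()].
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, format = c("tiff", "hdf5"),
                                spacing = c(1, 1, 1), background = 0L) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 volumes are not supported; convert to multi-page TIFF",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("TIFF pages must be single-channel integer images", call. = FALSE)
  }
  labels <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1]]), length(pages)))
  labeled_volume(labels, spacing = spacing, background = background)
}

#' Write a labeled segmentation volume
#'
#' Writes the label array as a 16-bit unsigned multi-page TIFF, one page per
#' slice of the third dimension. Round-trips through [read_labeled_volume()]
#' are bit-exact for labels up to 65535.
#'
#' @param vol A [labeled_volume()].
#' @param path Output file.
#' @param format Only `"tiff"` is supported.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path, format = c("tiff", "hdf5")) {
  stopifnot(inherits(vol, "labeled_volume"))
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 volumes are not supported; use format = \"tiff\"",
         call. = FALSE)
  }
  mx <- max(vol$labels)
  if (mx > 65535L) {
    stop("labels exceed 65535; 16-bit TIFF cannot store them", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(vol$labels)[3]),
                  function(k) vol$labels[, , k] / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) {
                   stop("cannot write TIFF to ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  invisible(path)
}

#' Restrict a volume to selected tissues
#'
#' Remaps the voxels of all cells outside the selected tissues to the first
#' background label, so that nerves built from the result cover only the cells
#' of the chosen tissue(s). Retained labels are unchanged and no new labels
#' are introduced.
#'
#' @param vol A [labeled_volume()].
#' @param table A cell table (see [read_cell_table()]) with `cell_id` and
#'   `tissue_id` columns covering the cells of `vol`.
#' @param tissues Tissue identifiers to keep (must select at least one cell).
#' @return A [labeled_volume()] with non-selected cells set to background.
#' @export
restrict_to_tissue <- function(vol, table, tissues) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (length(tissues) == 0) {
    stop("`tissues` must select at least one tissue", call. = FALSE)
  }
  keep <- unique(table$cell_id[table$tissue_id %in% tissues])
  if (length(keep) == 0) {
    stop("selected tissues (", paste(tissues, collapse = ", "),
         ") match no cells in `table`", call. = FALSE)
  }
  labs <- vol$labels
  bg <- vol$background[1]
  drop <- !(labs %in% c(keep, vol$background))
  labs[drop] <- bg
  labeled_volume(labs, spacing = vol$spacing, background = vol$background)
}
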