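#' Enumerate the face-vector alphabet of a set of nerves
#'
#' Feature vectors of different samples are only comparable over a common
#' enumeration of face-vectors, so the alphabet must be built from the union
#' of all nerves under comparison. The canonical order pads every face-vector
#' with zeros to the maximum length in the set and sorts lexicographically;
#' entries are displayed trimmed.
#'
#' @param nerves A list of `nerve` objects (one suffices).
#' @return An object of class `fv_alphabet`: a list with `vectors` (list of
#'   integer face-vectors) and `keys` (canonical strings like `"1-6-6"`).
#' @export
enumerate_face_vectors <- function(nerves) {
  if (inherits(nerves, "nerve")) nerves <- list(nerves)
  if (length(nerves) == 0) stop("need at least one nerve", call. = FALSE)
  fvs <- unlist(lapply(nerves, function(n) face_vectors(n)$face_vector),
                recursive = FALSE)
  keys <- vapply(fvs, simplex_key, character(1))
  fvs <- fvs[!duplicated(keys)]
  maxlen <- max(lengths(fvs))
  padded <- do.call(rbind, lapply(fvs, function(v) {
    c(v, rep(0L, maxlen - length(v)))
  }))
  ord <- do.call(order, as.data.frame(padded))
  fvs <- fvs[ord]
  structure(list(vectors = fvs,
                 keys = vapply(fvs, simplex_key, character(1))),
            class = "fv_alphabet")
}

#' @export
print.fv_alphabet <- function(x, ...) {
  cat("<fv_alphabet> ", length(x$keys), " face-vectors: ",
      paste(utils::head(x$keys, 8), collapse = ", "),
      if (length(x$keys) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Feature vector of a nerve over an alphabet
#'
#' Component i is the proportion of cells of the nerve whose face-vector
#' equals the i-th alphabet entry; the components sum to 1.
#'
#' @param nerve A `nerve`.
#' @param alphabet An [enumerate_face_vectors()] result covering every
#'   face-vector occurring in `nerve`.
#' @return Numeric vector of proportions named by alphabet key.
#' @export
feature_vector <- function(nerve, alphabet) {
  stopifnot(inherits(alphabet, "fv_alphabet"))
  fv <- face_vectors(nerve)
  missing <- setdiff(unique(fv$fv_key), alphabet$keys)
  if (length(missing) > 0) {
    stop("face-vector(s) ", paste(missing, collapse = ", "),
         " absent from the alphabet; build the alphabet from the full ",
         "comparison set", call. = FALSE)
  }
  counts <- table(factor(fv$fv_key, levels = alphabet$keys))
  out <- as.numeric(counts) / nrow(fv)
  names(out) <- alphabet$keys
  out
}

#' Feature matrix of labeled cohorts of nerves
#'
#' Builds one shared face-vector alphabet across all cohorts, then one
#' proportion row per nerve, tagged with cohort metadata. Rows sum to 1.
#'
#' @param cohorts Named list of cohorts; each cohort is a list of `nerve`
#'   objects. At least one nerve per cohort.
#' @param sample_ids Optional list (parallel to `cohorts`) of sample id
#'   character vectors; defaults to `<cohort>_<i>`.
#' @param alphabet Optionally, a pre-built alphabet (e.g. a global one across
#'   stages); by default the alphabet is the union over the given cohorts.
#' @return A tibble with columns `sample_id`, `cohort` and one `fv_<key>`
#'   column per alphabet entry; the alphabet is attached as attribute
#'   `"alphabet"`.
#' @export
feature_matrix <- function(cohorts, sample_ids = NULL, alphabet = NULL) {
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    stop("`cohorts` must be a named list", call. = FALSE)
  }
  if (any(lengths(cohorts) == 0)) {
    stop("every cohort needs at least one nerve", call. = FALSE)
  }
  all_nerves <- unlist(unname(cohorts), recursive = FALSE)
  if (is.null(alphabet)) alphabet <- enumerate_face_vectors(all_nerves)
  rows <- purrr::imap(cohorts, function(nerves, label) {
    ids <- if (!is.null(sample_ids)) sample_ids[[label]] else {
      paste0(label, "_", seq_along(nerves))
    }
    mat <- do.call(rbind, lapply(nerves, feature_vector, alphabet = alphabet))
    colnames(mat) <- paste0("fv_", gsub("-", "_", alphabet$keys))
    dplyr::bind_cols(tibble::tibble(sample_id = ids, cohort = label),
                     tibble::as_tibble(mat))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alphabet") <- alphabet
  out
}

#' @keywords internal
fv_columns <- function(matrix) grep("^fv_", names(matrix), value = TRUE)

#' Spread of a set of feature vectors
#'
#' The mean of the pairwise Euclidean distances between the vectors (over the
#' n(n-1)/2 unordered pairs); a scalar measure of cohort heterogeneity.
#'
#' @param vectors A list of equal-length numeric vectors, or a numeric matrix
#'   / feature-matrix tibble with one vector per row.
#' @return Non-negative scalar.
#' @export
spread <- function(vectors) {
  if (is.data.frame(vectors)) {
    vectors <- as.matrix(vectors[fv_columns(vectors)])
  }
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (nrow(vectors) < 2) {
    stop("need at least 2 vectors", call. = FALSE)
  }
  mean(stats::dist(vectors))
}

#' PCA projection of a feature matrix
#'
#' Column-centred (unscaled) principal component scores of the proportion
#' columns, with a deterministic sign convention: each component is flipped so
#' that its largest-magnitude loading is positive.
#'
#' @param matrix A [feature_matrix()] tibble (or plain numeric matrix).
#' @param k Number of components (default 2); must be at most
#'   `min(nrow - 1, ncol)`.
#' @return A tibble with the metadata columns of `matrix` plus `PC1..PCk`;
#'   the proportion of variance explained is attached as attribute
#'   `"var_explained"`.
#' @export
pca_project <- function(matrix, k = 2) {
  meta <- NULL
  if (is.data.frame(matrix)) {
    cols <- fv_columns(matrix)
    if (length(cols) == 0) cols <- names(matrix)[vapply(matrix, is.numeric, logical(1))]
    meta <- matrix[setdiff(names(matrix), cols)]
    x <- as.matrix(matrix[cols])
  } else {
    x <- as.matrix(matrix)
  }
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  if (k > min(nrow(x) - 1, ncol(x))) {
    stop("`k` must be at most min(rows - 1, columns)", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- if (!is.null(meta) && ncol(meta) > 0) {
    dplyr::bind_cols(tibble::as_tibble(meta), tibble::as_tibble(scores))
  } else {
    tibble::as_tibble(scores)
  }
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  attr(out, "var_explained") <- ve
  out
}

#' Scatter plot of PCA-projected feature vectors
#'
#' @param matrix A [feature_matrix()] tibble.
#' @param colour Column to colour points by (default `cohort`).
#' @return A ggplot object.
#' @export
plot_feature_pca <- function(matrix, colour = "cohort") {
  scores <- pca_project(matrix, k = 2)
  ve <- attr(scores, "var_explained")
  ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data[[colour]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}
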