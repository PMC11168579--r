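#' @keywords internal
simplex_key <- function(cells) paste(cells, collapse = "-")

new_nerve <- function(simplices) {
  # simplices: list of sorted integer vectors, assumed already deduplicated
  len <- lengths(simplices)
  L <- max(len)
  pad <- t(vapply(simplices, function(s) c(s, rep.int(0L, L - length(s))),
                  integer(L)))
  if (is.null(dim(pad))) pad <- matrix(pad, ncol = L)
  ord <- do.call(order, c(list(len), asplit(pad, 2)))
  structure(list(simplices = simplices[ord]), class = "nerve")
}

#' @export
print.nerve <- function(x, ...) {
  cts <- simplex_counts(x)
  cat("<nerve> ", length(x$simplices), " simplices (",
      paste(sprintf("%d %d-simplices", cts, seq_along(cts) - 1L),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Vertices (cell labels) of a nerve
#' @param nerve A [build_nerve()] result.
#' @return Sorted integer vector of cell labels.
#' @export
nerve_vertices <- function(nerve) {
  stopifnot(inherits(nerve, "nerve"))
  sort(unlist(nerve$simplices[lengths(nerve$simplices) == 1L]))
}

# Cache of subset index patterns: .subset_idx[[n]] is the list of all
# non-empty index subsets of 1..n. Sets here have at most 8 elements
# (one 2x2x2 block).
.subset_idx <- local({
  cache <- vector("list", 8)
  for (n in 1:8) {
    cache[[n]] <- unlist(lapply(seq_len(n), function(k) {
      asplit(utils::combn(n, k), 2)
    }), recursive = FALSE)
  }
  cache
})

# All non-empty subsets of a sorted integer vector.
all_subsets <- function(s) {
  lapply(.subset_idx[[length(s)]], function(i) s[i])
}

#' Build the nerve complex of a labeled volume
#'
#' The nerve encodes how a segmented object is assembled from its cells: each
#' cell is a vertex, and every set of k+1 cells whose closures meet contributes
#' a k-simplex (an edge for two cells, a triangle for three, a tetrahedron for
#' four, ...). In a hard voxel segmentation each voxel carries one label, so
#' "cells that meet" is read on the dual grid: under the default `block2`
#' scheme every 2x2x2 block of voxels (2x2 in a single-slice volume)
#' contributes a simplex on the distinct non-background labels it contains,
#' plus all sub-simplices, which makes the complex downward closed by
#' construction. For a Voronoi tessellation of generic seed points this
#' reproduces the Delaunay triangulation away from the image border. The
#' `pairwise_face` scheme keeps only vertices and the edges between cells
#' sharing a voxel face (6-connectivity) — the unweighted region adjacency
#' graph.
#'
#' Voxel spacing does not affect the result: the nerve is an abstract complex
#' and anisotropy changes geometry, not incidence. Cells touching the image
#' border are retained; only their stars are incomplete.
#'
#' @param vol A [labeled_volume()] with at least one non-background cell.
#' @param scheme `"block2"` (default) or `"pairwise_face"`.
#' @return A `nerve` object: a downward-closed list of simplices, each a
#'   sorted integer vector of cell labels, ordered by dimension then
#'   lexicographically.
#' @export
build_nerve <- function(vol, scheme = c("block2", "pairwise_face")) {
  stopifnot(inherits(vol, "labeled_volume"))
  scheme <- match.arg(scheme)
  a <- vol$labels
  d <- dim(a)
  if (sum(d > 1L) < 2L) {
    stop("volume must extend over at least two dimensions", call. = FALSE)
  }
  bg <- vol$background
  verts <- cell_labels(vol)
  if (length(verts) == 0) {
    stop("volume is entirely background", call. = FALSE)
  }
  if (scheme == "pairwise_face") {
    edges <- face_adjacent_pairs(a, bg)
    simp <- c(lapply(verts, identity),
              lapply(seq_len(nrow(edges)), function(i) edges[i, ]))
    return(new_nerve(simp))
  }

  # block2: gather the labels of every 2x2x2 (or 2x2x1) voxel block
  rng <- lapply(d, function(n) if (n > 1L) seq_len(n - 1L) else 1L)
  off <- lapply(d, function(n) if (n > 1L) 0:1 else 0L)
  cols <- list()
  for (o3 in off[[3]]) for (o2 in off[[2]]) for (o1 in off[[1]]) {
    cols[[length(cols) + 1L]] <-
      as.vector(a[rng[[1]] + o1, rng[[2]] + o2, rng[[3]] + o3])
  }
  mn <- Reduce(pmin, cols)
  mx <- Reduce(pmax, cols)
  uniform <- mn == mx

  key_sets <- new.env(parent = emptyenv())
  for (v in setdiff(unique(mn[uniform]), bg)) {
    assign(as.character(v), v, envir = key_sets)
  }
  if (any(!uniform)) {
    mixed <- vapply(cols, function(cc) cc[!uniform], integer(sum(!uniform)))
    if (is.null(dim(mixed))) mixed <- matrix(mixed, nrow = 1L)
    pat_key <- do.call(paste, c(as.data.frame(mixed), sep = ","))
    first <- !duplicated(pat_key)
    patterns <- mixed[first, , drop = FALSE]
    for (i in seq_len(nrow(patterns))) {
      s <- setdiff(sort(unique(patterns[i, ])), bg)
      if (length(s) > 0) assign(simplex_key(s), s, envir = key_sets)
    }
  }
  # every voxel lies in at least one block, so all cells appear as vertices
  sets <- as.list(key_sets)
  subs <- unlist(lapply(sets, all_subsets), recursive = FALSE)
  keys <- vapply(subs, simplex_key, character(1))
  new_nerve(unname(subs[!duplicated(keys)]))
}

# Pairs of distinct non-background labels sharing a voxel face.
face_adjacent_pairs <- function(a, bg) {
  d <- dim(a)
  pairs <- list()
  shift_pairs <- function(x, y) {
    keep <- x != y & !(x %in% bg) & !(y %in% bg)
    if (!any(keep)) return(NULL)
    cbind(pmin(x[keep], y[keep]), pmax(x[keep], y[keep]))
  }
  if (d[1] > 1L) pairs <- c(pairs, list(shift_pairs(
    as.vector(a[-d[1], , , drop = FALSE]), as.vector(a[-1, , , drop = FALSE]))))
  if (d[2] > 1L) pairs <- c(pairs, list(shift_pairs(
    as.vector(a[, -d[2], , drop = FALSE]), as.vector(a[, -1, , drop = FALSE]))))
  if (d[3] > 1L) pairs <- c(pairs, list(shift_pairs(
    as.vector(a[, , -d[3], drop = FALSE]), as.vector(a[, , -1, drop = FALSE]))))
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  unique(pairs)
}

#' Region adjacency graph of a nerve
#'
#' @param nerve A `nerve`.
#' @return Two-column integer matrix of edges (the 1-simplices), each row
#'   sorted, rows in deterministic order.
#' @export
adjacency_graph <- function(nerve) {
  stopifnot(inherits(nerve, "nerve"))
  e <- nerve$simplices[lengths(nerve$simplices) == 2L]
  if (length(e) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  m <- do.call(rbind, e)
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

#' Vertex star of a cell
#'
#' All simplices of the nerve that contain the given cell, including the
#' 0-simplex of the cell itself.
#'
#' @param nerve A `nerve`.
#' @param cell A cell label that is a vertex of `nerve`.
#' @return List of simplices (sorted integer vectors).
#' @export
vertex_star <- function(nerve, cell) {
  stopifnot(inherits(nerve, "nerve"))
  cell <- as.integer(cell)
  if (!cell %in% nerve_vertices(nerve)) {
    stop("cell ", cell, " is not a vertex of the nerve", call. = FALSE)
  }
  nerve$simplices[vapply(nerve$simplices, function(s) cell %in% s, logical(1))]
}

#' Face-vector of a cell
#'
#' The face-vector of a cell is the integer tuple `(c0, c1, c2, ...)` whose
#' k-th entry counts the k-simplices in the cell's vertex star; `c0` is always
#' 1, `c1` is the number of neighbours. For a simple polyhedral cell with
#' face-vector `(1, x2, x3, x4)`, `x2`/`x3`/`x4` are its polyhedral faces,
#' edges and vertices, so interior cells of a generic tessellation satisfy the
#' Euler relation `x2 - x3 + x4 = 2`.
#'
#' @param nerve A `nerve`.
#' @param cell A vertex label.
#' @return Integer vector, trailing zeros trimmed.
#' @export
face_vector <- function(nerve, cell) {
  star <- vertex_star(nerve, cell)
  dims <- lengths(star) - 1L
  counts <- tabulate(dims + 1L)
  counts
}

#' Face-vectors of all cells of a nerve
#'
#' @param nerve A `nerve`.
#' @return A tibble with columns `cell` (label) and `face_vector` (list of
#'   integer vectors) and `fv_key` (canonical string, e.g. `"1-6-6"`).
#' @export
face_vectors <- function(nerve) {
  stopifnot(inherits(nerve, "nerve"))
  verts <- nerve_vertices(nerve)
  vidx <- seq_along(verts)
  names(vidx) <- as.character(verts)
  maxdim <- max(lengths(nerve$simplices))
  counts <- matrix(0L, nrow = length(verts), ncol = maxdim)
  for (s in nerve$simplices) {
    k <- length(s)
    counts[vidx[as.character(s)], k] <- counts[vidx[as.character(s)], k] + 1L
  }
  fv <- lapply(unname(vidx), function(i) {
    row <- counts[i, ]
    last <- max(which(row != 0L))
    row[seq_len(last)]
  })
  tibble::tibble(
    cell = verts,
    face_vector = fv,
    fv_key = vapply(fv, simplex_key, character(1))
  )
}

#' Number of simplices per dimension
#'
#' @param nerve A `nerve`.
#' @return Integer vector: counts of 0-, 1-, 2-, ... simplices.
#' @export
simplex_counts <- function(nerve) {
  stopifnot(inherits(nerve, "nerve"))
  tabulate(lengths(nerve$simplices))
}

#' Serialize a nerve to JSON
#'
#' Writes the simplices as a JSON array of sorted integer arrays, ordered by
#' dimension then lexicographically, so that serialized nerves diff cleanly.
#'
#' @param nerve A `nerve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nerve <- function(nerve, path) {
  stopifnot(inherits(nerve, "nerve"))
  jsonlite::write_json(nerve$simplices, path)
  invisible(path)
}

#' Read a serialized nerve
#' @param path JSON file written by [write_nerve()].
#' @return A `nerve`.
#' @export
read_nerve <- function(path) {
  simp <- jsonlite::read_json(path, simplifyVector = FALSE)
  new_nerve(lapply(simp, function(s) as.integer(unlist(s))))
}
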