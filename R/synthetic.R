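#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Child seeds derived from a master seed; kept below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Specification of a synthetic tessellation generator
#'
#' Bundles the parameters of one synthetic "digital tissue" so cohorts can be
#' generated reproducibly. `voronoi_bulk` places seeds uniformly (with a
#' minimum-separation heuristic) in the interior of the box and labels each
#' voxel by its nearest seed; `weighted_voronoi` additionally draws additive
#' power weights, whose dispersion inflates the realized cell-volume CV;
#' `layered_sheet` arranges seeds on jittered 2D grids stacked in `n_layers`
#' parallel sheets, emulating the regular layered architecture of
#' epidermis-like tissues.
#'
#' @param kind One of `"voronoi_bulk"`, `"weighted_voronoi"`,
#'   `"layered_sheet"`.
#' @param n_cells Number of cells (seeds). For `layered_sheet` this is rounded
#'   to `n_layers` equal grids.
#' @param dim Voxel grid dimensions, default `c(24, 24, 24)`.
#' @param spacing µm per voxel, default isotropic 1 µm.
#' @param margin Fraction of each box extent kept free of seeds near the
#'   walls, default 0.15.
#' @param weight_sd Power-weight standard deviation (µm^2 scale), only used by
#'   `weighted_voronoi`.
#' @param n_layers Number of sheets for `layered_sheet`, default 2.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(kind = c("voronoi_bulk", "weighted_voronoi",
                                    "layered_sheet"),
                           n_cells = 40, dim = c(24, 24, 24),
                           spacing = c(1, 1, 1), margin = 0.15,
                           weight_sd = 0, n_layers = 2) {
  kind <- match.arg(kind)
  stopifnot(n_cells >= 1, length(dim) == 3, all(dim >= 2),
            margin >= 0, margin < 0.5, weight_sd >= 0, n_layers >= 1)
  structure(list(kind = kind, n_cells = as.integer(n_cells),
                 dim = as.integer(dim), spacing = as.numeric(spacing),
                 margin = margin, weight_sd = weight_sd,
                 n_layers = as.integer(n_layers)),
            class = "generator_spec")
}

# Best-candidate (Mitchell) sampling: spreads n points in the margin box.
sample_seeds <- function(n, extent, margin, candidates = 24L) {
  lo <- margin * extent
  hi <- (1 - margin) * extent
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- stats::runif(3, lo, hi)
  if (n > 1) for (i in 2:n) {
    cand <- cbind(stats::runif(candidates, lo[1], hi[1]),
                  stats::runif(candidates, lo[2], hi[2]),
                  stats::runif(candidates, lo[3], hi[3]))
    dmin <- apply(cand, 1, function(p) {
      min(colSums((t(pts[seq_len(i - 1), , drop = FALSE]) - p)^2))
    })
    pts[i, ] <- cand[which.max(dmin), ]
  }
  pts
}

#' Generate a (possibly weighted) Voronoi-labeled volume
#'
#' Labels each voxel by the seed minimizing the squared Euclidean distance
#' (minus the seed's power weight, if any) from the voxel centre, in physical
#' (spacing-aware) coordinates. Seeds are drawn away from the walls and
#' checked for genericity (no d+2 points near-cospherical, tolerance 1e-9
#' relative); degenerate draws are retried.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed; fully determines the output.
#' @param seeds Optional matrix of seed positions as fractions of the box
#'   extent (n x 3, values in (0,1)); overrides random placement so the same
#'   tessellation can be rendered at several resolutions.
#' @param max_retries Retries on a degenerate seed configuration.
#' @param ensure_generic Run the O(n^4) cosphericality screen on the seeds.
#'   Defaults to `TRUE` for at most 25 seeds at oracle-grade resolution
#'   (every box dimension at least 32 voxels) — the regime where exact
#'   Delaunay comparison applies — and `FALSE` otherwise: above 25 seeds the
#'   screen would dominate runtime, and in smaller boxes the vertex
#'   separation it demands is geometrically infeasible.
#' @param feature_sep_voxels Minimum separation between Voronoi vertices in
#'   voxel units (default 2.5), enforced together with `ensure_generic`:
#'   tessellation features smaller than a voxel block cannot be resolved on
#'   the grid, so closer vertices would make the nerve resolution-dependent.
#' @return A list with `volume` (a [labeled_volume()]; label i is seed i),
#'   `seeds` (physical µm coordinates), `seeds_rel` (box fractions),
#'   `weights`, `spec`, `seed`.
#' @export
make_voronoi_volume <- function(spec = generator_spec(), seed = 1,
                                seeds = NULL, max_retries = 200,
                                ensure_generic = spec$n_cells <= 25 &&
                                  min(spec$dim) >= 32,
                                feature_sep_voxels = 2.5) {
  stopifnot(inherits(spec, "generator_spec"))
  extent <- spec$dim * spec$spacing
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      if (!is.null(seeds)) {
        pts <- sweep(as.matrix(seeds), 2, extent, `*`)
      } else if (spec$kind == "layered_sheet") {
        pts <- sheet_seeds(spec, extent)
      } else {
        pts <- sample_seeds(spec$n_cells, extent, spec$margin)
      }
      w <- if (spec$kind == "weighted_voronoi") {
        stats::rnorm(nrow(pts), 0, spec$weight_sd)
      } else rep(0, nrow(pts))
      deg <- if (ensure_generic) {
        check_generic(pts, feature_sep = feature_sep_voxels * max(spec$spacing))
      } else NULL
      if (is.null(deg)) break
      if (!is.null(seeds) || attempt == max_retries) {
        stop("degenerate seed configuration (",
             if (length(deg)) paste("near-cospherical subset:",
                                    paste(deg, collapse = ", "))
             else "Voronoi vertices closer than the resolvable feature size",
             ")", call. = FALSE)
      }
    }
    labels <- label_nearest_seed(pts, w, spec$dim, spec$spacing)
    list(volume = labeled_volume(labels, spacing = spec$spacing),
         seeds = pts, seeds_rel = sweep(pts, 2, extent, `/`),
         weights = w, spec = spec, seed = seed)
  })
}

sheet_seeds <- function(spec, extent) {
  per_layer <- max(1L, round(spec$n_cells / spec$n_layers))
  nx <- max(1L, round(sqrt(per_layer)))
  ny <- max(1L, ceiling(per_layer / nx))
  lo <- spec$margin; hi <- 1 - spec$margin
  gx <- (seq_len(nx) - 0.5) / nx * (hi - lo) + lo
  gy <- (seq_len(ny) - 0.5) / ny * (hi - lo) + lo
  gz <- (seq_len(spec$n_layers) - 0.5) / spec$n_layers * (hi - lo) + lo
  grid <- expand.grid(x = gx, y = gy, z = gz)
  # mild positional noise (10% of cell pitch): epithelial sheets are regular
  jit <- c((hi - lo) / nx, (hi - lo) / ny, (hi - lo) / spec$n_layers) * 0.1
  pts <- as.matrix(grid) +
    cbind(stats::runif(nrow(grid), -jit[1], jit[1]),
          stats::runif(nrow(grid), -jit[2], jit[2]),
          stats::runif(nrow(grid), -jit[3], jit[3]))
  sweep(pts, 2, extent, `*`)
}

label_nearest_seed <- function(pts, w, dim, spacing) {
  ax <- lapply(1:3, function(k) (seq_len(dim[k]) - 0.5) * spacing[k])
  best <- array(Inf, dim = dim)
  labels <- array(0L, dim = dim)
  for (i in seq_len(nrow(pts))) {
    d2 <- outer(outer((ax[[1]] - pts[i, 1])^2, (ax[[2]] - pts[i, 2])^2, `+`),
                (ax[[3]] - pts[i, 3])^2, `+`) - w[i]
    upd <- d2 < best
    best[upd] <- d2[upd]
    labels[upd] <- i
  }
  labels
}

# Circumsphere of d+1 points in d dimensions: centre, squared radius.
circumsphere <- function(p) {
  d <- ncol(p)
  A <- 2 * sweep(p[-1, , drop = FALSE], 2, p[1, ], `-`)
  b <- rowSums(p[-1, , drop = FALSE]^2) - sum(p[1, ]^2)
  if (abs(det(A)) < 1e-12 * max(abs(A))^d) return(NULL)
  centre <- solve(A, b)
  list(centre = centre, r2 = sum((centre - p[1, ])^2))
}

# Returns indices of a near-degenerate subset (cospherical within tolerance),
# or NULL when the configuration is generic. When `feature_sep > 0` the
# screen additionally requires all Voronoi vertices (circumcentres of empty
# circumspheres) to be at least `feature_sep` apart: features smaller than a
# voxel block cannot be resolved on the grid, so tessellations violating this
# would not be refinement-stable at the target resolution.
check_generic <- function(pts, tol = 1e-9, feature_sep = 0) {
  n <- nrow(pts); d <- ncol(pts)
  if (n < d + 2) return(NULL)
  subs <- utils::combn(n, d + 1)
  centres <- list()
  for (j in seq_len(ncol(subs))) {
    s <- subs[, j]
    cs <- circumsphere(pts[s, , drop = FALSE])
    if (is.null(cs)) return(s)
    others <- setdiff(seq_len(n), s)
    rel <- (rowSums(sweep(pts[others, , drop = FALSE], 2, cs$centre, `-`)^2) -
              cs$r2) / cs$r2
    if (any(abs(rel) < tol)) return(c(s, others[which.min(abs(rel))]))
    if (all(rel > 0)) centres[[length(centres) + 1L]] <- cs$centre
  }
  if (feature_sep > 0 && length(centres) > 1) {
    cm <- do.call(rbind, centres)
    if (min(stats::dist(cm)) < feature_sep) {
      return(integer(0))  # too-close Voronoi vertices; no single subset
    }
  }
  NULL
}

#' Brute-force Delaunay complex by the empty-circumsphere test
#'
#' Independent geometric oracle for the nerve of a Voronoi tessellation: a set
#' of d+1 generic points spans a Delaunay simplex exactly when its unique
#' circumsphere contains no other point strictly inside. The full complex is
#' the downward closure of those top simplices. Exhaustive enumeration, so
#' intended for small point sets (<= 25).
#'
#' @param points n x d numeric matrix (d = 2 or 3) of point coordinates in
#'   physical units.
#' @param tol Relative cosphericality tolerance; a point this close to a
#'   circumsphere raises a degeneracy error naming the offending subset.
#' @return A `nerve` object over the point indices `1..n`.
#' @export
brute_force_delaunay <- function(points, tol = 1e-9) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (!d %in% c(2, 3)) stop("points must be 2D or 3D", call. = FALSE)
  if (n < d + 1) stop("need at least d + 1 points", call. = FALSE)
  if (n > 25) stop("brute-force oracle limited to 25 points", call. = FALSE)
  subs <- utils::combn(n, d + 1)
  seen <- new.env(parent = emptyenv())
  for (v in seq_len(n)) assign(as.character(v), v, envir = seen)
  for (j in seq_len(ncol(subs))) {
    s <- subs[, j]
    cs <- circumsphere(points[s, , drop = FALSE])
    if (is.null(cs)) {
      stop("degenerate (affinely dependent) subset: ",
           paste(s, collapse = ", "), call. = FALSE)
    }
    others <- setdiff(seq_len(n), s)
    rel <- if (length(others)) {
      (rowSums(sweep(points[others, , drop = FALSE], 2, cs$centre, `-`)^2) -
         cs$r2) / cs$r2
    } else numeric(0)
    if (any(abs(rel) < tol)) {
      stop("near-cospherical subset: ",
           paste(c(s, others[which.min(abs(rel))]), collapse = ", "),
           call. = FALSE)
    }
    if (all(rel > 0)) {
      for (sub in all_subsets(s)) {
        assign(simplex_key(sub), sub, envir = seen)
      }
    }
  }
  new_nerve(unname(as.list(seen)))
}

#' Cell labels touching the volume border
#'
#' Cells whose voxels reach any face of the array; their Voronoi regions are
#' clipped by the box, so their stars are incomplete and they are excluded
#' when comparing a nerve against the Delaunay oracle.
#'
#' @param vol A [labeled_volume()].
#' @return Integer vector of border cell labels.
#' @export
border_labels <- function(vol) {
  a <- vol$labels
  d <- dim(a)
  lab <- c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ], a[, , 1], a[, , d[3]])
  setdiff(sort(unique(lab)), vol$background)
}

#' Restrict a nerve to a subset of cells
#'
#' Keeps exactly the simplices all of whose vertices lie in `cells`; the
#' result is again downward closed.
#'
#' @param nerve A `nerve`.
#' @param cells Integer vector of cell labels to keep.
#' @return A `nerve`.
#' @export
restrict_nerve <- function(nerve, cells) {
  stopifnot(inherits(nerve, "nerve"))
  keep <- vapply(nerve$simplices, function(s) all(s %in% cells), logical(1))
  if (!any(keep)) stop("no simplices left after restriction", call. = FALSE)
  new_nerve(nerve$simplices[keep])
}

#' Hexagonal worked-example fixture
#'
#' A single-slice labeled volume of one central hexagonal cell (label 1)
#' surrounded by a closed ring of six cells (labels 2-7), each ring cell
#' adjacent to the centre and to its two ring neighbours, non-consecutive ring
#' cells not adjacent. The centre's vertex star therefore has one vertex, six
#' edges and six triangles — face-vector (1, 6, 6) — and each ring cell has
#' face-vector (1, 3, 2).
#'
#' @param size Grid side length in pixels (default 60).
#' @return A [labeled_volume()] with 7 cells.
#' @export
make_hex_fixture <- function(size = 60) {
  ctr <- (size + 1) / 2
  r <- 0.30 * size
  ang <- (0:5) * pi / 3 + 0.12  # small rotation avoids grid-aligned vertices
  seeds <- rbind(c(ctr, ctr),
                 cbind(ctr + r * cos(ang), ctr + r * sin(ang)))
  xi <- seq_len(size)
  labels <- matrix(0L, size, size)
  best <- matrix(Inf, size, size)
  for (i in seq_len(nrow(seeds))) {
    d2 <- outer((xi - seeds[i, 1])^2, (xi - seeds[i, 2])^2, `+`)
    upd <- d2 < best
    best[upd] <- d2[upd]
    labels[upd] <- i
  }
  labeled_volume(labels)
}

#' Generate paired synthetic cohorts
#'
#' Draws `n_samples` independent tessellations from each generator spec,
#' deriving one child seed per sample from the master seed. With
#' `spec_a = spec_b` this is a null configuration: both cohorts come from the
#' same architecture and differ only by their random streams.
#'
#' @param spec_a,spec_b [generator_spec()]s for the two cohorts.
#' @param n_samples Samples per cohort (>= 2).
#' @param seed Master seed.
#' @return Named list with `a` and `b`, each a list of [make_voronoi_volume()]
#'   results, plus `seed`.
#' @export
make_cohort_pair <- function(spec_a, spec_b, n_samples = 10, seed = 1) {
  stopifnot(n_samples >= 2)
  ks <- child_seeds(seed, 2 * n_samples)
  # cohort statistics never feed the Delaunay oracle, so the genericity
  # screen (meant for oracle-scale single volumes) is skipped here
  list(a = lapply(seq_len(n_samples),
                  function(i) make_voronoi_volume(spec_a, seed = ks[i],
                                                  ensure_generic = FALSE)),
       b = lapply(seq_len(n_samples),
                  function(i) make_voronoi_volume(spec_b, seed = ks[n_samples + i],
                                                  ensure_generic = FALSE)),
       seed = seed)
}

#' Generate a synthetic stage-resolved cell table
#'
#' Draws per-cell volumes for each (stage, tissue, sample) from a lognormal
#' law with the requested mean and coefficient of variation, producing a cell
#' table with known ground truth: with `cv = 0` all cells equal the tissue
#' mean and [growth_table()] recovers the input increments exactly.
#'
#' @param stage_means Tibble with columns `stage`, `tissue_id`, `mean_volume`
#'   (µm^3, positive).
#' @param n_samples Samples per stage (default 3).
#' @param cells_per_tissue Cells drawn per (sample, stage, tissue), default 30.
#' @param cv Target coefficient of variation of cell volume (>= 0).
#' @param seed Integer seed.
#' @param stage_order Ordered stage labels; default [default_stage_order()].
#' @return A cell table tibble (same schema as [read_cell_table()]).
#' @export
make_growth_series <- function(stage_means, n_samples = 3,
                               cells_per_tissue = 30, cv = 0.3, seed = 1,
                               stage_order = default_stage_order()) {
  if (any(stage_means$mean_volume <= 0)) {
    stop("`mean_volume` must be positive", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  sigma <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    rows <- purrr::pmap(stage_means, function(stage, tissue_id, mean_volume) {
      purrr::map(seq_len(n_samples), function(s) {
        vol <- if (cv == 0) rep(mean_volume, cells_per_tissue) else {
          stats::rlnorm(cells_per_tissue,
                        meanlog = log(mean_volume) - sigma^2 / 2,
                        sdlog = sigma)
        }
        tibble::tibble(
          sample_id = paste0(stage, "_s", s),
          species_or_condition = "synthetic",
          stage = factor(stage, levels = stage_order, ordered = TRUE),
          tissue_id = as.character(tissue_id),
          volume = vol
        )
      })
    })
    out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
    out |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(cell_id = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::relocate("sample_id", "species_or_condition", "stage",
                      "cell_id", "tissue_id", "volume")
  })
}
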