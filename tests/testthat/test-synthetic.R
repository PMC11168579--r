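test_that("generators are pure functions of their seed", {
  spec <- generator_spec("voronoi_bulk", n_cells = 10, dim = c(16, 16, 16))
  g1 <- make_voronoi_volume(spec, seed = 5, ensure_generic = FALSE)
  g2 <- make_voronoi_volume(spec, seed = 5, ensure_generic = FALSE)
  expect_identical(g1$volume$labels, g2$volume$labels)
  expect_identical(g1$seeds, g2$seeds)
  g3 <- make_voronoi_volume(spec, seed = 6, ensure_generic = FALSE)
  expect_false(identical(g1$volume$labels, g3$volume$labels))

  cp1 <- make_cohort_pair(spec, spec, n_samples = 2, seed = 9)
  cp2 <- make_cohort_pair(spec, spec, n_samples = 2, seed = 9)
  expect_identical(lapply(cp1$a, function(g) g$volume$labels),
                   lapply(cp2$a, function(g) g$volume$labels))
})

test_that("Voronoi volumes have one label per seed", {
  g2 <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 2, dim = c(12, 12, 12)), seed = 1)
  expect_setequal(cell_labels(g2$volume), 1:2)
  g20 <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 20, dim = c(24, 24, 24)),
    seed = 2, ensure_generic = FALSE)
  expect_setequal(cell_labels(g20$volume), 1:20)
  # spacing-aware labeling: anisotropic spacing changes geometry only
  ga <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 5, dim = c(12, 12, 12),
                   spacing = c(2, 1, 1)), seed = 3, ensure_generic = FALSE)
  expect_setequal(cell_labels(ga$volume), 1:5)
})

test_that("the hexagonal fixture has seven cells in a closed ring", {
  vol <- make_hex_fixture()
  expect_length(cell_labels(vol), 7)
  nv <- build_nerve(vol)
  edges <- adjacency_graph(nv)
  # centre adjacent to every ring cell
  expect_equal(sum(edges[, 1] == 1), 6)
  # each ring cell has exactly two ring neighbours
  ring_edges <- edges[edges[, 1] != 1, , drop = FALSE]
  expect_equal(nrow(ring_edges), 6)
})

test_that("growth series hit the requested means and coefficient of variation", {
  means <- tibble::tibble(stage = c("2-III", "2-IV"), tissue_id = "t",
                          mean_volume = c(50, 80))
  noiseless <- make_growth_series(means, n_samples = 2, cells_per_tissue = 5,
                                  cv = 0, seed = 1)
  expect_true(all(noiseless$volume %in% c(50, 80)))
  gt <- growth_table(noiseless, "tissue_volume")
  expect_equal(gt$relative_increase[!is.na(gt$relative_increase)], 0.6)

  noisy <- make_growth_series(
    tibble::tibble(stage = "2-III", tissue_id = "t", mean_volume = 100),
    n_samples = 1, cells_per_tissue = 500, cv = 0.3, seed = 8)
  expect_equal(cvcv(noisy$volume), 0.3, tolerance = 0.1)
  expect_lt(abs(cvcv(noisy$volume) - 0.3), 0.03)

  expect_identical(make_growth_series(means, seed = 4),
                   make_growth_series(means, seed = 4))
  expect_error(make_growth_series(
    tibble::tibble(stage = "1-I", tissue_id = "t", mean_volume = -1)),
    "positive")
})

test_that("the Delaunay oracle handles minimal configurations", {
  # 3 non-collinear points in 2D: one triangle plus its faces
  tri <- matrix(c(0, 0, 1, 0.1, 0.4, 1.2), 3, 2, byrow = TRUE)
  d2 <- brute_force_delaunay(tri)
  expect_equal(nerve_keys(d2), c("1", "1-2", "1-2-3", "1-3", "2", "2-3", "3"))

  # 4 generic points in 3D: one tetrahedron plus all faces (15 simplices)
  tet <- matrix(c(0, 0, 0, 1, 0.1, 0, 0.2, 1.1, 0, 0.3, 0.4, 1.2),
                4, 3, byrow = TRUE)
  d3 <- brute_force_delaunay(tet)
  expect_equal(simplex_counts(d3), c(4L, 6L, 4L, 1L))

  # jittered square with centre point in 2D: centre joins every triangle
  sq <- matrix(c(0, 0, 1, 0.02, 1.03, 1.01, -0.01, 1.02, 0.51, 0.48),
               5, 2, byrow = TRUE)
  d5 <- brute_force_delaunay(sq)
  tris <- d5$simplices[lengths(d5$simplices) == 3]
  expect_equal(length(tris), 4)
  expect_true(all(vapply(tris, function(s) 5 %in% s, logical(1))))

  # an exactly cospherical square is flagged as degenerate
  exact_sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_error(brute_force_delaunay(exact_sq), "cospherical")
  expect_error(brute_force_delaunay(matrix(runif(60), 30, 2)), "25 points")
})

test_that("weight dispersion inflates realized cell-volume variation", {
  realized_cv <- function(weight_sd, sd) {
    g <- make_voronoi_volume(
      generator_spec("weighted_voronoi", n_cells = 15, dim = c(20, 20, 20),
                     weight_sd = weight_sd),
      seed = sd, ensure_generic = FALSE)
    counts <- table(g$volume$labels[g$volume$labels > 0])
    stats::sd(counts) / mean(counts)
  }
  cv_flat <- mean(vapply(1:4, function(sd) realized_cv(0, sd), numeric(1)))
  cv_disp <- mean(vapply(1:4, function(sd) realized_cv(30, sd), numeric(1)))
  expect_gt(cv_disp, cv_flat)
})

test_that("layered sheets stack the requested number of layers", {
  g <- make_voronoi_volume(
    generator_spec("layered_sheet", n_cells = 18, dim = c(20, 20, 20),
                   n_layers = 2),
    seed = 5, ensure_generic = FALSE)
  expect_equal(length(cell_labels(g$volume)), nrow(g$seeds))
  z <- g$seeds[, 3]
  expect_equal(length(unique(round(z / 5))), 2)
})
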