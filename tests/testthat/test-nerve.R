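test_that("trivial volumes give trivial nerves", {
  n1 <- build_nerve(one_cell_volume())
  expect_equal(n1$simplices, list(1L))
  expect_equal(simplex_counts(n1), 1L)

  n2 <- build_nerve(two_cell_volume())
  expect_equal(nerve_keys(n2), c("1", "1-2", "2"))
  expect_equal(simplex_counts(n2), c(2L, 1L))
  expect_equal(adjacency_graph(n2), cbind(from = 1L, to = 2L))

  expect_error(build_nerve(labeled_volume(array(0L, dim = c(3, 3, 3)))),
               "background")
  expect_error(build_nerve(labeled_volume(array(1L, dim = c(9, 1, 1)))),
               "two dimensions")
})

test_that("the hexagonal fixture reproduces the worked example", {
  nv <- build_nerve(make_hex_fixture())
  expect_equal(simplex_counts(nv), c(7L, 12L, 6L))
  # centre: one vertex, six edges, six triangles
  expect_length(vertex_star(nv, 1), 13)
  expect_equal(face_vector(nv, 1), c(1L, 6L, 6L))
  # each ring cell: three neighbours, two triangles with the centre
  for (cell in 2:7) expect_equal(face_vector(nv, cell), c(1L, 3L, 2L))
  # 6 spoke + 6 ring edges
  expect_equal(nrow(adjacency_graph(nv)), 12)
  expect_lte(nrow(adjacency_graph(nv)), choose(7, 2))
  expect_error(vertex_star(nv, 99), "not a vertex")
})

test_that("nerves are downward closed and consistent with double counting", {
  gen <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 12, dim = c(24, 24, 24)),
    seed = 5, ensure_generic = FALSE)
  nv <- build_nerve(gen$volume)
  keys <- nerve_keys(nv)
  for (s in nv$simplices) {
    if (length(s) > 1) {
      for (drop in seq_along(s)) {
        expect_true(paste(s[-drop], collapse = "-") %in% keys)
      }
    }
  }
  # sum of star sizes counts each simplex once per vertex
  star_total <- sum(vapply(nerve_vertices(nv),
                           function(v) length(vertex_star(nv, v)), numeric(1)))
  expect_equal(star_total, sum(lengths(nv$simplices)))
})

test_that("the nerve is invariant under relabeling of cells", {
  gen <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 8, dim = c(16, 16, 16)),
    seed = 9, ensure_generic = FALSE)
  vol <- gen$volume
  perm <- c(5L, 3L, 8L, 1L, 7L, 2L, 6L, 4L)  # label i -> perm[i]
  relabeled <- labeled_volume(
    array(ifelse(vol$labels == 0L, 0L, perm[vol$labels]), dim = dim(vol$labels)))
  n0 <- build_nerve(vol)
  n1 <- build_nerve(relabeled)
  mapped <- lapply(n0$simplices, function(s) sort(perm[s]))
  expect_setequal(nerve_keys(n1),
                  vapply(mapped, function(s) paste(s, collapse = "-"),
                         character(1)))
})

test_that("face-vectors are invariant under relabeling", {
  gen <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 8, dim = c(16, 16, 16)),
    seed = 2, ensure_generic = FALSE)
  vol <- gen$volume
  perm <- sample(8)
  relabeled <- labeled_volume(
    array(ifelse(vol$labels == 0L, 0L, perm[vol$labels]), dim = dim(vol$labels)))
  fv0 <- face_vectors(build_nerve(vol))
  fv1 <- face_vectors(build_nerve(relabeled))
  for (i in 1:8) {
    expect_identical(fv1$fv_key[fv1$cell == perm[i]], fv0$fv_key[fv0$cell == i])
  }
})

test_that("the Voronoi nerve matches the Delaunay oracle on interior cells", {
  gen <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 12, dim = c(48, 48, 48)),
    seed = 4)
  nv <- build_nerve(gen$volume)
  del <- brute_force_delaunay(gen$seeds)
  interior <- setdiff(cell_labels(gen$volume), border_labels(gen$volume))
  expect_identical(nerve_keys(nv, interior), nerve_keys(del, interior))
  # full Delaunay contains every nerve simplex among interior cells
  expect_true(all(nerve_keys(nv, interior) %in% nerve_keys(del)))
})

test_that("doubling the voxel resolution leaves the nerve unchanged", {
  spec1 <- generator_spec("voronoi_bulk", n_cells = 10, dim = c(32, 32, 32))
  gen <- make_voronoi_volume(spec1, seed = 6)
  spec2 <- generator_spec("voronoi_bulk", n_cells = 10, dim = c(64, 64, 64))
  gen2 <- make_voronoi_volume(spec2, seed = 6, seeds = gen$seeds_rel)
  expect_identical(nerve_keys(build_nerve(gen$volume)),
                   nerve_keys(build_nerve(gen2$volume)))
})

test_that("pairwise_face gives the region adjacency graph", {
  vol <- two_cell_volume()
  nf <- build_nerve(vol, scheme = "pairwise_face")
  expect_equal(nerve_keys(nf), c("1", "1-2", "2"))
  # on the hex fixture the face-adjacency edges equal the block2 1-skeleton
  hexv <- make_hex_fixture()
  e_face <- adjacency_graph(build_nerve(hexv, scheme = "pairwise_face"))
  e_block <- adjacency_graph(build_nerve(hexv))
  expect_identical(e_face, e_block)
})

test_that("nerves serialize deterministically and round-trip", {
  nv <- build_nerve(make_hex_fixture())
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_nerve(nv, p1)
  write_nerve(build_nerve(make_hex_fixture()), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(nerve_keys(read_nerve(p1)), nerve_keys(nv))
})
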