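test_that("TIFF round-trips preserve labels bit-exactly", {
  vol <- two_cell_volume()
  path <- withr::local_tempfile(fileext = ".tif")
  write_labeled_volume(vol, path)
  back <- read_labeled_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_identical(max(back$labels), max(vol$labels))

  gen <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 20, dim = c(16, 16, 16)),
    seed = 7, ensure_generic = FALSE)
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_labeled_volume(gen$volume, path2)
  back2 <- read_labeled_volume(path2)
  expect_identical(back2$labels, gen$volume$labels)
  expect_identical(table(back2$labels), table(gen$volume$labels))
})

test_that("an all-background volume reads back with zero cells", {
  vol <- labeled_volume(array(0L, dim = c(4, 4, 4)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_labeled_volume(vol, path)
  expect_length(cell_labels(read_labeled_volume(path)), 0)
})

test_that("labeled_volume validates its invariants", {
  expect_error(labeled_volume(array(-1L, dim = c(2, 2, 2))), "non-negative")
  expect_error(labeled_volume(array(1.5, dim = c(2, 2, 2))), "integer")
  expect_error(labeled_volume(array(1L, dim = c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(labeled_volume(1:8), "3D")
  expect_error(read_labeled_volume("x.tif", format = "hdf5"), "not supported")
})

test_that("cell tables parse, validate stages and partition by sample", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,stage,label,parent,volume",
               "s1,2-III,1,A,40.5",
               "s1,2-III,2,A,55",
               "s2,2-IV,1,B,70"), path)
  tb <- read_cell_table(path)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$volume, c(40.5, 55, 70))
  expect_s3_class(tb$stage, "ordered")
  expect_equal(as.vector(table(tb$sample_id)), c(2, 1))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,stage,label,parent,volume",
               "s1,9-IX,1,A,40"), bad)
  expect_error(read_cell_table(bad), "9-IX")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,stage,parent,volume", "s1,2-III,A,40"), nocol)
  expect_error(read_cell_table(nocol), "cell id")
})

test_that("the schema mapping supports custom column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ovule,phase,CellID,Tissue,Vol_um3",
               "o1,3-I,12,oi2,101.5"), path)
  tb <- read_cell_table(path, schema = list(sample_id = "ovule",
                                            stage = "phase",
                                            cell_id = "CellID",
                                            tissue_id = "Tissue",
                                            volume = "Vol_um3"))
  expect_equal(tb$cell_id, 12L)
  expect_equal(tb$tissue_id, "oi2")
  expect_equal(tb$volume, 101.5)

  # the same mapping can come from a YAML config, with its own stage order
  cfg <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    columns = list(sample_id = "ovule", stage = "phase", cell_id = "CellID",
                   tissue_id = "Tissue", volume = "Vol_um3"),
    stage_order = c("3-I", "3-II")), cfg)
  tb2 <- read_cell_table(path, schema = cfg)
  expect_identical(tb2$cell_id, tb$cell_id)
  expect_equal(levels(tb2$stage), c("3-I", "3-II"))
})

test_that("the small-cell filter keeps the boundary value and is monotone", {
  tb <- tibble::tibble(cell_id = 1:3, volume = c(10, 30, 45))
  kept <- filter_small_cells(tb)
  expect_equal(kept$volume, c(30, 45))
  # idempotent
  expect_identical(filter_small_cells(kept), kept)
  # identity when everything passes
  big <- tibble::tibble(cell_id = 1:2, volume = c(31, 60))
  expect_identical(filter_small_cells(big), big)
  # monotone in the threshold: higher threshold keeps a subset
  set.seed(11)
  rnd <- tibble::tibble(cell_id = 1:100, volume = rlnorm(100, log(40), 0.6))
  k30 <- filter_small_cells(rnd, 30)
  k50 <- filter_small_cells(rnd, 50)
  expect_true(all(k50$cell_id %in% k30$cell_id))
  # brute-force recount
  expect_equal(nrow(k30), sum(rnd$volume >= 30))
  expect_error(filter_small_cells(rnd, -1), "non-negative")
})

test_that("tissue restriction keeps exactly the selected cells", {
  gen <- make_voronoi_volume(
    generator_spec("voronoi_bulk", n_cells = 12, dim = c(16, 16, 16)),
    seed = 3, ensure_generic = FALSE)
  vol <- gen$volume
  tab <- tibble::tibble(cell_id = 1:12,
                        tissue_id = rep(c("A", "B"), each = 6))
  ra <- restrict_to_tissue(vol, tab, "A")
  expect_setequal(cell_labels(ra), 1:6)
  # no new labels anywhere
  expect_true(all(unique(as.vector(ra$labels)) %in% c(0L, 1:6)))
  # selecting every tissue is the identity
  expect_identical(restrict_to_tissue(vol, tab, c("A", "B"))$labels,
                   vol$labels)
  # restriction to disjoint sets commutes (both orders give all-background)
  rab <- restrict_to_tissue(ra, tab, "B")
  expect_error(restrict_to_tissue(vol, tab, character(0)), "at least one")
  expect_error(restrict_to_tissue(vol, tab, "C"), "no cells")
  expect_length(cell_labels(rab), 0)
  rb <- restrict_to_tissue(vol, tab, "B")
  expect_identical(rab$labels, restrict_to_tissue(rb, tab, "A")$labels)
})
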