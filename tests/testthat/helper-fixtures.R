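# Small fixtures built in code, shared across test files.

# Volume split into two face-adjacent halves labeled 1 | 2.
two_cell_volume <- function(n = 4) {
  a <- array(1L, dim = c(n, n, n))
  a[(n / 2 + 1):n, , ] <- 2L
  labeled_volume(a)
}

# Single-cell volume.
one_cell_volume <- function(n = 3) {
  labeled_volume(array(1L, dim = c(n, n, n)))
}

# Toy long-format cell table.
toy_cell_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    species_or_condition = "toy",
    stage = factor("2-III", levels = default_stage_order(), ordered = TRUE),
    cell_id = c(1L, 2L, 3L, 1L, 2L),
    tissue_id = c("A", "A", "B", "A", "B"),
    volume = c(40, 55, 70, 35, 90)
  )
}

# Simplices of a nerve as canonical "a-b-c" keys, optionally restricted to a
# cell subset.
nerve_keys <- function(nv, cells = NULL) {
  simp <- nv$simplices
  if (!is.null(cells)) {
    simp <- simp[vapply(simp, function(s) all(s %in% cells), logical(1))]
  }
  sort(vapply(simp, function(s) paste(s, collapse = "-"), character(1)))
}
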