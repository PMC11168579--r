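#' Default developmental stage order
#'
#' The ordered stage labels used when no stage order is supplied: two stage-1
#' substages, five stage-2 substages and six stage-3 substages of ovule
#' development.
#'
#' @return Character vector of 13 ordered stage labels.
#' @export
default_stage_order <- function() {
  c("1-I", "1-II", "2-I", "2-II", "2-III", "2-IV", "2-V",
    "3-I", "3-II", "3-III", "3-IV", "3-V", "3-VI")
}

#' Read a long-format per-cell attribute table
#'
#' Reads a CSV export of per-cell attributes (one row per cell) into a tidy
#' cell table. Column names in the file are mapped onto the canonical schema
#' via `schema`; the default mapping matches common segmentation exports where
#' the cell label column is `label`, the tissue annotation is `parent` and the
#' cell volume is `volume`.
#'
#' @param path CSV file with a header row.
#' @param schema Named list mapping canonical fields (`sample_id`,
#'   `species_or_condition`, `stage`, `cell_id`, `tissue_id`, `volume`) to
#'   column names in the file, or the path of a YAML config with a `columns`
#'   mapping (and optionally `stage_order`). Fields absent from the list fall
#'   back to the canonical name itself; `cell_id`, `tissue_id` and `volume`
#'   also fall back to `label`/`parent`/`volume`.
#' @param stage_order Ordered character vector of valid stage labels; stages
#'   in the file must be drawn from it. Defaults to [default_stage_order()],
#'   overridden by a `stage_order` entry of a YAML schema config.
#' @return A tibble with columns `sample_id`, `species_or_condition`, `stage`
#'   (ordered factor), `cell_id` (integer), `tissue_id` (character), `volume`
#'   (double, µm^3).
#' @export
read_cell_table <- function(path, schema = list(),
                            stage_order = default_stage_order()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1) {
    cfg <- yaml::read_yaml(schema)
    if (!is.null(cfg$stage_order)) stage_order <- unlist(cfg$stage_order)
    schema <- cfg$columns %||% list()
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  defaults <- list(sample_id = "sample_id",
                   species_or_condition = "species_or_condition",
                   stage = "stage",
                   cell_id = "label",
                   tissue_id = "parent",
                   volume = "volume")
  map <- utils::modifyList(defaults, as.list(schema))
  pick <- function(field, alternatives = character()) {
    for (col in unique(c(map[[field]], field, alternatives))) {
      if (col %in% names(raw)) return(raw[[col]])
    }
    NULL
  }
  cell_id <- pick("cell_id")
  volume <- pick("volume")
  if (is.null(cell_id)) {
    stop("no cell id column found (looked for '", map$cell_id,
         "' and 'cell_id')", call. = FALSE)
  }
  if (is.null(volume)) {
    stop("no volume column found (looked for '", map$volume, "')",
         call. = FALSE)
  }
  volume <- suppressWarnings(as.numeric(volume))
  if (anyNA(volume)) stop("non-numeric cell volumes in ", path, call. = FALSE)

  stage <- pick("stage")
  if (!is.null(stage)) {
    stage <- as.character(stage)
    bad <- setdiff(unique(stage), stage_order)
    if (length(bad) > 0) {
      stop("unknown stage label(s): ", paste(bad, collapse = ", "),
           " (declared order: ", paste(stage_order, collapse = " < "), ")",
           call. = FALSE)
    }
    stage <- factor(stage, levels = stage_order, ordered = TRUE)
  }
  out <- tibble::tibble(
    sample_id = as.character(pick("sample_id") %||% "sample_1"),
    species_or_condition = as.character(pick("species_or_condition") %||% NA),
    stage = stage %||% factor(rep(NA_character_, nrow(raw)),
                              levels = stage_order, ordered = TRUE),
    cell_id = as.integer(cell_id),
    tissue_id = as.character(pick("tissue_id") %||% "all"),
    volume = volume
  )
  dup <- duplicated(out[c("sample_id", "cell_id")])
  if (any(dup)) {
    stop("duplicated (sample_id, cell_id) pairs, e.g. cell ",
         out$cell_id[which(dup)[1]], call. = FALSE)
  }
  if (any(out$volume <= 0)) {
    stop("cell volumes must be positive", call. = FALSE)
  }
  out
}

#' Drop cells below a volume threshold
#'
#' Removes records whose cell volume is strictly less than `threshold` µm^3;
#' tiny segments at this scale are segmentation artifacts (mislabeled empty
#' space), not cells. A cell exactly at the threshold is retained. Row order
#' is preserved and the operation is idempotent.
#'
#' @param table A cell table with a `volume` column (µm^3).
#' @param threshold Minimum retained volume in µm^3; default 30.
#' @return The filtered table.
#' @export
filter_small_cells <- function(table, threshold = 30) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  dplyr::filter(table, .data$volume >= threshold)
}
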