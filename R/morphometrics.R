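#' Coefficient of variation of cell volume
#'
#' Standard deviation over mean of a set of cell volumes; a scale-free measure
#' of cell-size heterogeneity within a (cohort, stage, tissue) group. Uses the
#' sample standard deviation (n-1 denominator) by default.
#'
#' @param volumes Numeric vector of cell volumes (µm^3), at least two values,
#'   positive mean. Apply [filter_small_cells()] upstream.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return Non-negative scalar.
#' @export
cvcv <- function(volumes, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(volumes) < 2) stop("need at least 2 volumes", call. = FALSE)
  m <- mean(volumes)
  if (m <= 0) stop("mean volume must be positive", call. = FALSE)
  s <- stats::sd(volumes)
  if (sd_denominator == "n") {
    s <- s * sqrt((length(volumes) - 1) / length(volumes))
  }
  s / m
}

#' Relative increase between consecutive stages
#'
#' The stage-wise growth estimate `(y(n+1) - y(n)) / y(n)` computed from
#' cohort means, since fixed samples cannot be followed through time.
#'
#' @param y_n Mean parameter at the earlier stage; must be positive.
#' @param y_n1 Mean parameter at the later stage.
#' @return The relative increase (0.5 means +50%).
#' @export
relative_increase <- function(y_n, y_n1) {
  if (any(y_n <= 0)) stop("`y_n` must be positive", call. = FALSE)
  (y_n1 - y_n) / y_n
}

#' Stage-wise relative growth table
#'
#' For each tissue and consecutive stage pair, the relative increase of the
#' stage-wise mean of the chosen measure: mean total tissue volume per sample
#' (`tissue_volume`) or mean cell count per sample (`cell_count`). Tissues
#' absent at a stage yield an `NA` increment for the pairs involving that
#' stage (flagged, never silently dropped).
#'
#' @param table A cell table (see [read_cell_table()]); group also by
#'   `species_or_condition` if several cohorts are present.
#' @param measure `"tissue_volume"` or `"cell_count"`.
#' @return A tibble with columns `species_or_condition`, `tissue_id`,
#'   `stage_from`, `stage_to`, `mean_from`, `mean_to`, `relative_increase`,
#'   `percent_change`.
#' @export
growth_table <- function(table, measure = c("tissue_volume", "cell_count")) {
  measure <- match.arg(measure)
  stages <- levels(table$stage)
  present <- stages[stages %in% as.character(unique(table$stage))]
  if (length(present) < 2) stop("need at least 2 stages", call. = FALSE)

  per_sample <- table |>
    dplyr::group_by(.data$species_or_condition, .data$tissue_id,
                    .data$stage, .data$sample_id) |>
    dplyr::summarise(
      value = if (measure == "tissue_volume") sum(.data$volume) else dplyr::n(),
      .groups = "drop"
    )
  means <- per_sample |>
    dplyr::group_by(.data$species_or_condition, .data$tissue_id, .data$stage) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")

  grid <- tidyr::expand_grid(
    dplyr::distinct(means, .data$species_or_condition, .data$tissue_id),
    stage_from = factor(present[-length(present)], levels = stages, ordered = TRUE)
  ) |>
    dplyr::mutate(stage_to = factor(
      present[match(as.character(.data$stage_from), present) + 1L],
      levels = stages, ordered = TRUE))

  grid |>
    dplyr::left_join(means, by = c("species_or_condition", "tissue_id",
                                   stage_from = "stage")) |>
    dplyr::rename(mean_from = "mean_value") |>
    dplyr::left_join(means, by = c("species_or_condition", "tissue_id",
                                   stage_to = "stage")) |>
    dplyr::rename(mean_to = "mean_value") |>
    dplyr::mutate(
      relative_increase = dplyr::if_else(
        !is.na(.data$mean_from) & !is.na(.data$mean_to) & .data$mean_from > 0,
        (.data$mean_to - .data$mean_from) / .data$mean_from,
        NA_real_),
      percent_change = 100 * .data$relative_increase
    )
}

#' Per-sample tissue proportion shares
#'
#' The relative contribution of each tissue to a sample, either by total
#' volume or by cell count; shares sum to 1 within each sample.
#'
#' @param table A cell table.
#' @param measure `"tissue_volume"` or `"cell_count"`.
#' @return A tibble with `sample_id`, `stage`, `tissue_id`, `value`, `share`.
#' @export
tissue_proportions <- function(table, measure = c("tissue_volume", "cell_count")) {
  measure <- match.arg(measure)
  if (nrow(table) == 0) stop("empty cell table", call. = FALSE)
  table |>
    dplyr::group_by(.data$sample_id, .data$stage, .data$tissue_id) |>
    dplyr::summarise(
      value = if (measure == "tissue_volume") sum(.data$volume) else dplyr::n(),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(share = .data$value / sum(.data$value)) |>
    dplyr::ungroup()
}

#' Extrapolate a staging threshold between species
#'
#' Transfers the lower limit of a developmental stage from a reference
#' species to a target species by scaling: the reference min-to-max ratio is
#' applied to the target maximum,
#' `min_target = (min_ref / max_ref) * max_target`.
#'
#' @param min_ref,max_ref Reference-species stage minimum and maximum
#'   (volume or cell count); `max_ref` must be positive.
#' @param max_target Target-species stage maximum.
#' @return The extrapolated target-species minimum.
#' @export
stage_threshold_extrapolation <- function(min_ref, max_ref, max_target) {
  if (any(max_ref <= 0)) stop("`max_ref` must be positive", call. = FALSE)
  (min_ref / max_ref) * max_target
}

#' Summarise a mitotic-division classification tally
#'
#' Totals and percentages of classified cell divisions (e.g. periclinal vs
#' anticlinal), overall and within optional groupings such as stage or layer.
#' Percentages are reported both raw and rounded to the nearest integer for
#' display.
#'
#' @param tally A tibble with one row per scored division and a `class`
#'   column; optional grouping columns (`stage`, `layer`, ...).
#' @param groupings Character vector of additional columns to group by
#'   (default none: overall summary).
#' @return A tibble with `class`, grouping columns, `count`, `total`,
#'   `percent`, `percent_rounded`.
#' @export
division_summary <- function(tally, groupings = character()) {
  if (nrow(tally) == 0) stop("empty division tally", call. = FALSE)
  if (!"class" %in% names(tally)) {
    stop("`tally` needs a `class` column", call. = FALSE)
  }
  tally |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groupings))) |>
    dplyr::mutate(total = dplyr::n()) |>
    dplyr::group_by(.data$class,
                    dplyr::across(dplyr::all_of(c(groupings, "total")))) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(percent = 100 * .data$count / .data$total,
                  percent_rounded = round(.data$percent)) |>
    dplyr::relocate("class", dplyr::all_of(groupings),
                    "count", "total", "percent", "percent_rounded")
}
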