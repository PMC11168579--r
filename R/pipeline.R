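#' Define a two-cohort comparison plan
#'
#' A plan names two cohorts of samples and fixes everything the comparison
#' depends on: the nerve scheme, the bootstrap settings and the optional
#' per-stage/per-tissue structure. Volumes may be given as `labeled_volume`
#' objects or as TIFF paths (read lazily at run time); every referenced path
#' must exist when the plan is built.
#'
#' @param cohort_a,cohort_b Tibbles with one row per sample: columns
#'   `sample_id`, optionally `stage`, and either a `volume` list-column of
#'   [labeled_volume()]s or a `path` column of TIFF files. An optional
#'   `cell_table` list-column plus the `tissues` argument restrict each volume
#'   to a tissue before the nerve is built.
#' @param labels Length-2 character vector naming the cohorts.
#' @param tissues Optional named list `tissue label -> tissue_id vector`; each
#'   entry yields one comparison per (stage, tissue).
#' @param scheme Nerve scheme, see [build_nerve()].
#' @param B,seed,resampling Bootstrap settings, see [cramer_test()].
#' @return A `comparison_plan` object.
#' @export
comparison_plan <- function(cohort_a, cohort_b, labels = c("A", "B"),
                            tissues = NULL, scheme = "block2",
                            B = 1000, seed = 1,
                            resampling = "permutation") {
  stopifnot(length(labels) == 2, labels[1] != labels[2])
  check_cohort <- function(tb, lab) {
    if (!is.data.frame(tb) || nrow(tb) == 0) {
      stop("cohort ", lab, " must be a non-empty tibble", call. = FALSE)
    }
    if (!"sample_id" %in% names(tb)) {
      tb$sample_id <- paste0(lab, "_", seq_len(nrow(tb)))
    }
    if (!"volume" %in% names(tb)) {
      if (!"path" %in% names(tb)) {
        stop("cohort ", lab, " needs a `volume` or `path` column",
             call. = FALSE)
      }
      missing <- tb$path[!file.exists(tb$path)]
      if (length(missing) > 0) {
        stop("missing volume file(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
    }
    if (!"stage" %in% names(tb)) tb$stage <- "all"
    tb
  }
  structure(
    list(cohorts = stats::setNames(
           list(check_cohort(cohort_a, labels[1]),
                check_cohort(cohort_b, labels[2])), labels),
         tissues = tissues, scheme = scheme, B = as.integer(B),
         seed = as.integer(seed), resampling = resampling),
    class = "comparison_plan"
  )
}

#' Read a comparison plan from a YAML config
#'
#' The config declares two cohorts (label -> list of volume paths), and
#' optionally `scheme`, `B`, `seed`, `resampling`, `spacing`, `background`.
#'
#' @param path YAML file.
#' @return A `comparison_plan`.
#' @export
read_comparison_plan <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohorts) || length(cfg$cohorts) != 2) {
    stop("config must declare exactly two cohorts", call. = FALSE)
  }
  labs <- names(cfg$cohorts)
  mk <- function(paths) tibble::tibble(path = unlist(paths))
  comparison_plan(mk(cfg$cohorts[[1]]), mk(cfg$cohorts[[2]]),
                  labels = labs,
                  scheme = cfg$scheme %||% "block2",
                  B = cfg$B %||% 1000, seed = cfg$seed %||% 1,
                  resampling = cfg$resampling %||% "permutation")
}

plan_volume <- function(row) {
  if ("volume" %in% names(row) && !is.null(row$volume[[1]])) {
    v <- row$volume[[1]]
    if (inherits(v, "labeled_volume")) return(v)
    if (is.list(v) && inherits(v$volume, "labeled_volume")) return(v$volume)
  }
  read_labeled_volume(row$path)
}

#' Run a two-cohort topological comparison
#'
#' For every (stage, tissue) combination of the plan: restrict each sample's
#' volume to the tissue, build nerves under the plan's scheme, enumerate one
#' shared face-vector alphabet over both cohorts, assemble the feature matrix
#' and run the bootstrap Cramer test. Combinations with fewer than two
#' samples in a cohort are kept in the output flagged as skipped, never
#' silently dropped.
#'
#' @param plan A [comparison_plan()].
#' @param out_dir Optional directory: results, feature matrices, PCA scores
#'   and a reproducibility manifest (seed, settings, package version) are
#'   written there as CSV/JSON.
#' @return A list with `results` (tibble: stage, tissue, statistic, p_value,
#'   m, n, B, seed, spread per cohort, skipped flag) and `feature_matrices`
#'   (named list of [feature_matrix()] tibbles).
#' @export
run_comparison <- function(plan, out_dir = NULL) {
  stopifnot(inherits(plan, "comparison_plan"))
  labs <- names(plan$cohorts)
  stages <- sort(unique(c(as.character(plan$cohorts[[1]]$stage),
                          as.character(plan$cohorts[[2]]$stage))))
  tissue_sets <- plan$tissues %||% list(all = NULL)
  seeds <- child_seeds(plan$seed, length(stages) * length(tissue_sets))
  results <- list(); fms <- list(); k <- 0L
  for (st in stages) for (ti in names(tissue_sets)) {
    k <- k + 1L
    sub <- lapply(plan$cohorts, function(tb) tb[tb$stage == st, , drop = FALSE])
    mn <- vapply(sub, nrow, integer(1))
    if (any(mn < 2)) {
      warning("skipping stage ", st, " / tissue ", ti,
              ": fewer than 2 samples in a cohort", call. = FALSE)
      results[[k]] <- tibble::tibble(
        stage = st, tissue = ti, statistic = NA_real_, p_value = NA_real_,
        m = mn[1], n = mn[2], B = plan$B, seed = seeds[k],
        spread_a = NA_real_, spread_b = NA_real_, skipped = TRUE)
      next
    }
    nerves <- lapply(sub, function(tb) {
      lapply(seq_len(nrow(tb)), function(i) {
        row <- tb[i, , drop = FALSE]
        vol <- plan_volume(row)
        sel <- tissue_sets[[ti]]
        if (!is.null(sel)) {
          vol <- restrict_to_tissue(vol, row$cell_table[[1]], sel)
        }
        build_nerve(vol, scheme = plan$scheme)
      })
    })
    fm <- feature_matrix(nerves,
                         sample_ids = lapply(sub, function(tb) tb$sample_id))
    res <- compare_feature_cohorts(fm, B = plan$B, seed = seeds[k],
                                   resampling = plan$resampling)
    results[[k]] <- tibble::tibble(
      stage = st, tissue = ti, statistic = res$statistic,
      p_value = res$p_value, m = res$m, n = res$n, B = res$B,
      seed = seeds[k],
      spread_a = spread(fm[fm$cohort == labs[1], ]),
      spread_b = spread(fm[fm$cohort == labs[2], ]),
      skipped = FALSE)
    fms[[paste(st, ti, sep = "_")]] <- fm
  }
  out <- list(results = dplyr::bind_rows(results), feature_matrices = fms)
  if (!is.null(out_dir)) write_comparison_outputs(out, plan, out_dir)
  out
}

write_comparison_outputs <- function(out, plan, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out$results, file.path(out_dir, "comparison_results.csv"))
  for (nm in names(out$feature_matrices)) {
    fm <- out$feature_matrices[[nm]]
    readr::write_csv(fm, file.path(out_dir, paste0("features_", nm, ".csv")))
    if (nrow(fm) >= 3) {
      readr::write_csv(pca_project(fm, k = 2),
                       file.path(out_dir, paste0("pca_", nm, ".csv")))
    }
  }
  manifest <- list(
    package = "nervetopo",
    version = as.character(utils::packageVersion("nervetopo")),
    seed = plan$seed, B = plan$B, scheme = plan$scheme,
    resampling = plan$resampling,
    n_tests = sum(!out$results$skipped),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the morphometric report on a cell table
#'
#' Applies the small-cell volume filter, then computes the coefficient of
#' variation of cell volume per (cohort, stage, tissue), the stage-wise
#' relative growth of tissue volume and cell number, and per-sample tissue
#' proportion shares.
#'
#' @param table A cell table (see [read_cell_table()]).
#' @param volume_threshold Minimum cell volume in µm^3 (default 30).
#' @param cvcv_mode `"pooled"` (default): pool cells across samples of a
#'   (cohort, stage, tissue); `"per_sample"`: CV per sample, then averaged.
#' @param out_dir Optional output directory for tidy CSVs.
#' @return A list of tibbles: `cvcv`, `growth_volume`, `growth_cell_count`,
#'   `proportions_volume`, `proportions_cell_count`.
#' @export
run_morphometrics <- function(table, volume_threshold = 30,
                              cvcv_mode = c("pooled", "per_sample"),
                              out_dir = NULL) {
  cvcv_mode <- match.arg(cvcv_mode)
  tb <- filter_small_cells(table, volume_threshold)
  cv_tbl <- if (cvcv_mode == "pooled") {
    tb |>
      dplyr::group_by(.data$species_or_condition, .data$stage, .data$tissue_id) |>
      dplyr::summarise(n_cells = dplyr::n(),
                       cvcv = cvcv(.data$volume), .groups = "drop")
  } else {
    tb |>
      dplyr::group_by(.data$species_or_condition, .data$stage,
                      .data$tissue_id, .data$sample_id) |>
      dplyr::summarise(cv_sample = cvcv(.data$volume), n = dplyr::n(),
                       .groups = "drop_last") |>
      dplyr::summarise(n_cells = sum(.data$n), cvcv = mean(.data$cv_sample),
                       .groups = "drop")
  }
  out <- list(
    cvcv = cv_tbl,
    growth_volume = growth_table(tb, "tissue_volume"),
    growth_cell_count = growth_table(tb, "cell_count"),
    proportions_volume = tissue_proportions(tb, "tissue_volume"),
    proportions_cell_count = tissue_proportions(tb, "cell_count")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  out
}

#' P-value profile across stages
#'
#' Plots the per-stage bootstrap p-values of a comparison against the 0.05
#' reference line, one panel per tissue.
#'
#' @param results The `results` tibble of [run_comparison()].
#' @return A ggplot object.
#' @export
plot_pvalue_profile <- function(results) {
  ggplot2::ggplot(results[!results$skipped, ],
                  ggplot2::aes(.data$stage, .data$p_value, group = 1)) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "stage", y = "bootstrap p-value") +
    ggplot2::theme_minimal()
}
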