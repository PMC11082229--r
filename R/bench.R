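#' Run a workflow grid over a dataset collection
#'
#' Executes every workflow of the grid on every dataset contrast (here
#' each simulated dataset has one A-vs-B contrast), computes the
#' five-metric vector against ground truth, averages per workflow, and
#' attaches the aggregated ranking. Per-cell failures are recorded, not
#' fatal: brute-force grids inevitably contain degenerate combinations,
#' and failed cells are excluded from the means. Each cell's randomness is
#' derived solely from the master seed, workflow id and dataset id, so
#' execution order (or parallelism) cannot change results.
#'
#' @param datasets Named list of datasets as from [simulate_collection()]
#'   (each a list with `views`, `truth`, `design`).
#' @param grid Workflow tibble (rows from [workflow()]).
#' @param seed Integer master seed.
#' @param logfc_thresh,q_thresh DE-calling thresholds for the
#'   confusion-based metrics.
#' @return A `benchmark_run` list with elements `cells` (per workflow x
#'   dataset metrics, `error` column for failed cells), `mean_metrics`,
#'   `ranking` (a `ranking_table`), and `seed`.
#' @export
run_grid <- function(datasets, grid, seed = 1L,
                     logfc_thresh = log2(1.5), q_thresh = 0.05) {
  grid <- tibble::as_tibble(grid)
  if (is.null(names(datasets))) {
    names(datasets) <- sprintf("dataset%02d", seq_along(datasets))
  }
  for (i in seq_len(nrow(grid))) {
    bad <- validate_workflow(grid[i, ])
    if (length(bad) > 0L) {
      abort(paste0("grid row ", i, " invalid: ", paste(bad, collapse = "; ")))
    }
  }
  ids <- workflow_id(grid)
  cells <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    purrr::imap_dfr(datasets, function(ds, dname) {
      cell_seed <- derive_seed(seed, paste(ids[i], dname, sep = "@"))
      base <- dplyr::bind_cols(
        tibble::tibble(dataset = dname), grid[i, ]
      )
      res <- tryCatch(
        {
          r <- run_workflow(ds$views, grid[i, ], ds$design, seed = cell_seed)
          dplyr::bind_cols(
            metric_vector(r, ds$truth, logfc_thresh, q_thresh),
            tibble::tibble(error = NA_character_)
          )
        },
        error = function(e) {
          tibble::tibble(
            pauc001 = NA_real_, pauc005 = NA_real_, pauc01 = NA_real_,
            nmcc = NA_real_, gmean = NA_real_,
            error = conditionMessage(e)
          )
        }
      )
      dplyr::bind_cols(base, res)
    })
  })
  mean_metrics <- cells |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$setting, .data$matrix_type, .data$normalization,
                    .data$imputation, .data$dea) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(.metric_cols), mean),
      n_cells = dplyr::n(), .groups = "drop"
    )
  structure(
    list(
      cells = cells,
      mean_metrics = mean_metrics,
      ranking = aggregate_ranks(mean_metrics),
      seed = seed,
      datasets = names(datasets)
    ),
    class = "benchmark_run"
  )
}

#' @export
print.benchmark_run <- function(x, ...) {
  failed <- sum(!is.na(x$cells$error))
  cat(sprintf(
    "# benchmark_run: %d workflows x %d datasets (%d failed cells), seed %d\n",
    nrow(x$ranking), length(x$datasets), failed, x$seed
  ))
  print(utils::head(tibble::as_tibble(x$ranking), 5))
  invisible(x)
}

#' Write the benchmark report artifacts
#'
#' Emits `ranking.tsv` (workflow columns, five metrics, five ranks, final
#' rank, position, ranking score, level), `patterns_H.tsv` and
#' `patterns_L.tsv` (frequent option patterns at `min_sr`), and -- when
#' per-dataset metrics for at least three datasets are available --
#' `lodocv.tsv`. Re-running on the same `benchmark_run` reproduces the
#' files byte-identically.
#'
#' @param run A `benchmark_run`.
#' @param dir Output directory (created if needed).
#' @param min_sr Support-ratio threshold for pattern mining.
#' @return Character vector of the files written, invisibly.
#' @export
report <- function(run, dir, min_sr = 0.1) {
  stopifnot(inherits(run, "benchmark_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, path)
  }
  ranking <- tibble::as_tibble(run$ranking)
  ranking$level <- as.character(ranking$level)
  emit(ranking, "ranking.tsv")
  for (lev in c("H", "L")) {
    pat <- tryCatch(
      mine_levels(run$ranking, lev, min_sr = min_sr),
      error = function(e) NULL
    )
    if (!is.null(pat)) {
      emit(dplyr::select(pat, "pattern", "support", "sr"),
           paste0("patterns_", lev, ".tsv"))
    }
  }
  per_ds <- dplyr::filter(run$cells, is.na(.data$error))
  if (length(unique(per_ds$dataset)) >= 3L) {
    cv <- tryCatch(lodocv(per_ds), error = function(e) NULL)
    if (!is.null(cv)) emit(cv, "lodocv.tsv")
  }
  invisible(written)
}
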