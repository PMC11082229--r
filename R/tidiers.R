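#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize DEA results
#'
#' `tidy()` returns the per-protein table; `glance()` a one-row summary
#' with the protein count, DE calls at the default thresholds, and the
#' contrast.
#'
#' @param x A `dea_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dea_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.dea_result
#' @export
glance.dea_result <- function(x, ...) {
  called <- call_de(x)
  ctr <- attr(x, "contrast") %||% c(NA_character_, NA_character_)
  tibble::tibble(
    n_proteins = nrow(x),
    n_de = sum(called$de),
    n_flagged = sum(x$flag %||% FALSE),
    contrast = paste(ctr, collapse = " vs ")
  )
}

#' Tidy and summarize benchmark runs
#'
#' `tidy()` returns the workflow ranking table; `glance()` a one-row
#' summary with workflow, dataset and failed-cell counts and the best
#' workflow id.
#'
#' @param x A `benchmark_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.benchmark_run <- function(x, ...) {
  tibble::as_tibble(x$ranking)
}

#' @rdname tidy.benchmark_run
#' @export
glance.benchmark_run <- function(x, ...) {
  best <- x$ranking[x$ranking$position == 1L, ]
  tibble::tibble(
    n_workflows = nrow(x$ranking),
    n_datasets = length(x$datasets),
    n_failed_cells = sum(!is.na(x$cells$error)),
    best_workflow = workflow_id(best),
    best_rank_final = best$rank_final
  )
}

#' Volcano plot of a DEA result
#'
#' @param object A `dea_result`.
#' @param logfc_thresh,q_thresh DE-calling thresholds drawn as guides.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dea_result <- function(object, logfc_thresh = log2(1.5),
                                q_thresh = 0.05, ...) {
  df <- call_de(object, logfc_thresh, q_thresh)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(pmax(.data$qvalue, 1e-300)),
    colour = .data$de
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * logfc_thresh,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(q_thresh),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value",
                  colour = "DE call")
}

#' Plot a workflow ranking
#'
#' Final rank against each of the five benchmark metrics, coloured by
#' performance level.
#'
#' @param object A `ranking_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ranking_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(.metric_cols),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$value, colour = .data$level
  )) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "ranking position (1 = best)", y = "metric value",
                  colour = "level")
}

#' Plot per-cell metric distributions of a benchmark run
#'
#' @param object A `benchmark_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_run <- function(object, ...) {
  df <- object$cells |>
    dplyr::filter(is.na(.data$error)) |>
    tidyr::pivot_longer(dplyr::all_of(.metric_cols),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dea, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "DEA statistic", y = "metric value") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
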