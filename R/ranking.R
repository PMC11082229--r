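#' Aggregate per-metric ranks into a final workflow ranking
#'
#' Each of the five benchmark metrics is converted to a
#' descending-performance rank (average-tie convention); the final rank is
#' the arithmetic mean of the five. Workflows are ordered by final rank,
#' ties broken lexicographically by workflow spec, assigned positions
#' `1..N`, a ranking score `N - position`, and a performance level from
#' [label_levels()].
#'
#' @param metrics A tibble with one row per workflow: the workflow columns
#'   (`setting`, `matrix_type`, `normalization`, `imputation`, `dea`, or a
#'   single `workflow` id column) plus the five metric columns `pauc001`,
#'   `pauc005`, `pauc01`, `nmcc`, `gmean` (cross-dataset means).
#' @return A `ranking_table` tibble: the input columns plus
#'   `rank_pauc001` .. `rank_gmean`, `rank_final`, `position`,
#'   `ranking_score` and `level`.
#' @export
aggregate_ranks <- function(metrics) {
  metrics <- tibble::as_tibble(metrics)
  stopifnot(all(.metric_cols %in% names(metrics)))
  if (nrow(metrics) < 2L) {
    if (nrow(metrics) == 0L) abort("no workflows to rank")
  }
  out <- metrics
  for (m in .metric_cols) {
    out[[paste0("rank_", m)]] <- rank(-metrics[[m]], ties.method = "average")
  }
  out$rank_final <- rowMeans(out[paste0("rank_", .metric_cols)])
  id <- if ("workflow" %in% names(out)) {
    out$workflow
  } else {
    paste(out$setting, workflow_id(out), sep = "|")
  }
  ord <- order(out$rank_final, id)
  out <- out[ord, ]
  n <- nrow(out)
  out$position <- seq_len(n)
  out$ranking_score <- n - out$position
  out$level <- label_levels(n, out$position)
  structure(out, class = c("ranking_table", class(tibble::tibble())))
}

#' Performance-level labels from ranking positions
#'
#' Workflows are labeled high `H` (top 5%), relatively high `RH` (5-25%),
#' relatively low `RL` (25-50%) and low `L` (bottom 50%). Bin boundaries
#' use the ceiling rule: position `<= ceiling(0.05 N)` is `H`,
#' `<= ceiling(0.25 N)` is at least `RH`, `<= ceiling(0.5 N)` at least
#' `RL`.
#'
#' @param n Total number of ranked workflows.
#' @param positions Integer ranking positions in `1..n`.
#' @return A factor with levels `H`, `RH`, `RL`, `L`.
#' @examples
#' table(label_levels(100, 1:100)) # 5 H, 20 RH, 25 RL, 50 L
#' @export
label_levels <- function(n, positions = seq_len(n)) {
  stopifnot(all(positions >= 1), all(positions <= n))
  lev <- ifelse(positions <= ceiling(0.05 * n), "H",
    ifelse(positions <= ceiling(0.25 * n), "RH",
      ifelse(positions <= ceiling(0.5 * n), "RL", "L")
    )
  )
  factor(lev, levels = c("H", "RH", "RL", "L"))
}

#' Spearman correlation between two rank vectors
#'
#' Pearson correlation of average-tie ranks; errors on vectors shorter
#' than 3 or constant vectors (where the correlation is undefined).
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return A number in `[-1, 1]`.
#' @export
spearman_cor <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    abort("need two vectors of equal length >= 3")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Spearman correlation is undefined for a constant vector")
  }
  cor(a, b, method = "spearman")
}

#' Leave-one-dataset-out cross-validation of workflow rankings
#'
#' For each dataset, workflows are ranked by their mean metrics over all
#' other datasets and by the held-out dataset alone; the Spearman
#' correlation of the two final-rank vectors measures how well the pooled
#' benchmark predicts rankings on unseen data.
#'
#' @param metrics A tibble with columns `dataset`, workflow identifier
#'   columns, and the five metric columns (one row per workflow x
#'   dataset).
#' @return A tibble with columns `dataset`, `spearman`.
#' @export
lodocv <- function(metrics) {
  metrics <- tibble::as_tibble(metrics)
  stopifnot("dataset" %in% names(metrics))
  datasets <- sort(unique(metrics$dataset))
  if (length(datasets) < 3L) abort("LODOCV needs at least 3 datasets")
  wf_cols <- intersect(
    c("workflow", "setting", "matrix_type", "normalization", "imputation",
      "dea"),
    names(metrics)
  )
  mean_metrics <- function(df) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(wf_cols))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(.metric_cols), \(x) mean(x, na.rm = TRUE)),
        .groups = "drop"
      )
  }
  purrr::map_dfr(datasets, function(d) {
    train <- aggregate_ranks(mean_metrics(metrics[metrics$dataset != d, ]))
    test <- aggregate_ranks(mean_metrics(metrics[metrics$dataset == d, ]))
    key <- do.call(paste, c(train[wf_cols], sep = "|"))
    key_test <- do.call(paste, c(test[wf_cols], sep = "|"))
    m <- match(key, key_test)
    if (anyNA(m)) abort("workflow sets differ across datasets")
    tibble::tibble(
      dataset = d,
      spearman = spearman_cor(train$rank_final, test$rank_final[m])
    )
  })
}

#' Kruskal-Wallis test on per-contrast workflow ranks
#'
#' Tests whether a workflow's ranks computed from different groups of
#' contrasts (e.g. grouped by instrument type) share a common median,
#' using the tie-corrected H statistic with a chi-squared approximation.
#' Groups smaller than `min_n` are rejected, mirroring the practice of
#' skipping platforms that cannot form large-enough instrument groups.
#'
#' @param ranks Numeric vector of ranks (one per contrast).
#' @param groups Group labels, same length.
#' @param min_n Minimum group size (default 5).
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_ranks <- function(ranks, groups, min_n = 5L) {
  stopifnot(length(ranks) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) abort("need at least two groups")
  if (any(tab < min_n)) {
    abort(paste0("group(s) smaller than min_n = ", min_n, ": ",
                 paste(names(tab)[tab < min_n], collapse = ", ")))
  }
  kt <- kruskal.test(ranks, factor(groups))
  tibble::tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' Matched-pair comparison of options within one workflow step
#'
#' For a chosen step, every pair of options is compared over matched
#' workflow pairs -- workflows identical in all other steps. For each
#' metric, an option wins a pairwise comparison when the mean metric
#' difference over matched pairs is positive; options are ordered per
#' metric by win count (ties broken by the option's median performance),
#' and the final option rank is the average of its five per-metric ranks.
#'
#' @param metrics Per-workflow mean metrics: a tibble with the workflow
#'   option columns and the five metric columns.
#' @param step One of `"matrix_type"`, `"normalization"`, `"imputation"`,
#'   `"dea"`.
#' @return A list with `comparisons` (tibble: `metric`, `option_a`,
#'   `option_b`, `n_pairs`, `mean_diff`, `median_diff`) and `option_ranks`
#'   (tibble: `option`, per-metric ranks, `rank_final`). Option pairs with
#'   no matched workflows are reported with `n_pairs = 0` and skipped in
#'   the ranking.
#' @export
pairwise_option_compare <- function(metrics, step) {
  step <- match.arg(step, .step_names)
  metrics <- tibble::as_tibble(metrics)
  others <- setdiff(intersect(c("setting", .step_names), names(metrics)), step)
  key <- do.call(paste, c(metrics[others], sep = "|"))
  options <- sort(unique(metrics[[step]]))
  if (length(options) < 2L) abort("step has fewer than two options")
  pairs <- utils::combn(options, 2L)

  comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    ma <- metrics[metrics[[step]] == a, ]
    mb <- metrics[metrics[[step]] == b, ]
    m <- match(key[metrics[[step]] == a], key[metrics[[step]] == b])
    ok <- !is.na(m)
    purrr::map_dfr(.metric_cols, function(met) {
      d <- ma[[met]][ok] - mb[[met]][m[ok]]
      tibble::tibble(
        metric = met, option_a = a, option_b = b, n_pairs = sum(ok),
        mean_diff = if (sum(ok) > 0) mean(d) else NA_real_,
        median_diff = if (sum(ok) > 0) median(d) else NA_real_
      )
    })
  })

  option_ranks <- purrr::map_dfc(.metric_cols, function(met) {
    wins <- setNames(numeric(length(options)), options)
    cc <- comparisons[comparisons$metric == met & comparisons$n_pairs > 0, ]
    for (i in seq_len(nrow(cc))) {
      if (cc$mean_diff[i] > 0) {
        wins[cc$option_a[i]] <- wins[cc$option_a[i]] + 1
      } else if (cc$mean_diff[i] < 0) {
        wins[cc$option_b[i]] <- wins[cc$option_b[i]] + 1
      }
    }
    med <- vapply(options, function(o) {
      median(metrics[[met]][metrics[[step]] == o], na.rm = TRUE)
    }, numeric(1))
    # order: more wins first, ties by higher median performance
    r <- rank(-(wins * 1e6 + rank(med, ties.method = "average")),
              ties.method = "average")
    tibble::tibble(!!paste0("rank_", met) := r)
  })
  option_ranks <- dplyr::bind_cols(tibble::tibble(option = options),
                                   option_ranks)
  option_ranks$rank_final <- rowMeans(
    option_ranks[paste0("rank_", .metric_cols)]
  )
  option_ranks <- dplyr::arrange(option_ranks, .data$rank_final,
                                 .data$option)
  list(comparisons = comparisons, option_ranks = option_ranks)
}

#' Cross-setting comparison over a merged protein list
#'
#' To compare DEA results obtained under different quantification settings
#' fairly, all proteins are merged into a union list; protein groups
#' containing more than one protein (detected by the delimiter) are
#' removed; a protein absent from a setting is padded with `log2fc = 0`
#' and `qvalue = 1` (never called DE, so a truly DE protein missed by a
#' setting counts as its false negative); confusion counts are then taken
#' per setting over the common list.
#'
#' @param results Named list mapping setting to `dea_result`.
#' @param truth Ground-truth data frame covering the merged protein list.
#' @param delim Multi-protein-group delimiter (default `";"`).
#' @inheritParams confusion_counts
#' @return A tibble with one row per setting: `setting`, `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
cross_setting_compare <- function(results, truth, delim = ";",
                                  logfc_thresh = log2(1.5),
                                  q_thresh = 0.05) {
  if (length(results) < 2L) abort("need results from at least two settings")
  truth <- tibble::as_tibble(truth)
  proteins <- sort(unique(unlist(purrr::map(results, "protein"))))
  proteins <- proteins[!grepl(delim, proteins, fixed = TRUE)]
  if (length(proteins) == 0L) {
    abort("no single-protein groups shared across settings")
  }
  purrr::imap_dfr(results, function(res, setting) {
    m <- match(proteins, res$protein)
    padded <- tibble::tibble(
      protein = proteins,
      log2fc = ifelse(is.na(m), 0, res$log2fc[m]),
      qvalue = ifelse(is.na(m), 1, res$qvalue[m])
    )
    dplyr::bind_cols(
      tibble::tibble(setting = setting),
      confusion_counts(padded, truth, logfc_thresh, q_thresh)
    )
  })
}
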