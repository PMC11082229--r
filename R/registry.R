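#' Option registry for quantification settings
#'
#' A DEA workflow is the categorical 4-tuple (expression matrix type,
#' normalization, imputation, DEA statistic) inside a quantification
#' setting -- the pairing of quantification platform and acquisition type
#' (e.g. `FG_DDA` = FragPipe on label-free DDA data). The registry is
#' declarative: which matrix types each setting provides, which
#' normalization/imputation/DEA options are built in, which are plugin
#' slots, and which DEA statistics require spectral counts.
#'
#' @name registry
NULL

.registry <- local({
  lf_dda <- c("counts", "top0", "top3", "LFQ", "dlfq")
  dia <- c("top1", "top3", "LFQ", "dlfq")
  list(
    matrix = list(
      FG_DDA = lf_dda, MQ_DDA = lf_dda,
      DIANN_DIA = dia, spt_DIA = dia,
      FG_TMT = c("abd", "ratio", "phi"),
      MQ_TMT = "reporter",
      generic = unique(c(lf_dda, dia, "abd", "ratio", "phi", "reporter"))
    ),
    normalization = list(
      builtin = c(
        "none", "center.mean", "center.median", "div.mean", "div.median",
        "total", "max", "quantiles", "quantiles.robust", "MBQN", "Rlr",
        "lossf"
      ),
      plugin = "vsn"
    ),
    imputation = list(
      builtin = c("none", "zero", "min", "MinDet", "MinProb", "knn",
                  "SeqKNN", "Impseq"),
      plugin = c("bpca", "mice", "missForest", "GMS", "QRILC", "MLE",
                 "nbavg", "Impseqrob")
    ),
    dea = list(
      builtin = c("ttest", "anova", "moderated_t"),
      plugin = c("limma", "ROTS", "DEqMS", "proDA", "DEP", "MSstats",
                 "SAM", "plgem", "edgeR", "beta_binomial")
    ),
    count_based_dea = c("plgem", "edgeR", "beta_binomial")
  )
})

# user-registered plugin implementations, keyed "<step>:<name>"
.plugins <- new.env(parent = emptyenv())

#' Register a plugin implementation for a registry slot
#'
#' Plugin slots expose third-party normalization, imputation or DEA methods
#' behind a stable contract. A normalization or imputation plugin maps an
#' [expr_matrix()] to an [expr_matrix()] with unchanged dimensions; a DEA
#' plugin maps `(matrix, design, contrast)` to a data frame with columns
#' `protein`, `log2fc`, `pvalue` (q-values are added by the framework if
#' absent).
#'
#' @param step `"normalization"`, `"imputation"` or `"dea"`.
#' @param name Registered plugin option name (see [registry_options()]).
#' @param fn The implementation function.
#' @return `name`, invisibly.
#' @export
register_plugin <- function(step, name, fn) {
  step <- match.arg(step, c("normalization", "imputation", "dea"))
  slot <- .registry[[step]]
  if (!name %in% c(slot$builtin, slot$plugin)) {
    abort(paste0("'", name, "' is not a registered ", step, " option"))
  }
  stopifnot(is.function(fn))
  assign(paste0(step, ":", name), fn, envir = .plugins)
  invisible(name)
}

plugin_fn <- function(step, name) {
  key <- paste0(step, ":", name)
  if (exists(key, envir = .plugins)) get(key, envir = .plugins) else NULL
}

#' List registered options for a workflow step
#'
#' @param setting One of `FG_DDA`, `MQ_DDA`, `DIANN_DIA`, `spt_DIA`,
#'   `FG_TMT`, `MQ_TMT`, or `generic`.
#' @param step `"matrix"`, `"normalization"`, `"imputation"` or `"dea"`.
#' @return A tibble with columns `option`, `builtin` and `available`
#'   (built-ins are always available; plugin slots only once an
#'   implementation has been registered with [register_plugin()]).
#' @examples
#' registry_options("FG_DDA", "matrix")$option
#' @export
registry_options <- function(setting, step) {
  step <- match.arg(step, c("matrix", "normalization", "imputation", "dea"))
  if (!setting %in% names(.registry$matrix)) {
    abort(paste0("unknown setting '", setting, "'"))
  }
  if (step == "matrix") {
    opts <- .registry$matrix[[setting]]
    return(tibble::tibble(option = opts, builtin = TRUE, available = TRUE))
  }
  slot <- .registry[[step]]
  tibble::tibble(
    option = c(slot$builtin, slot$plugin),
    builtin = rep(c(TRUE, FALSE), c(length(slot$builtin), length(slot$plugin)))
  ) |>
    dplyr::mutate(available = .data$builtin |
      purrr::map_lgl(.data$option, \(o) !is.null(plugin_fn(step, o))))
}

#' Construct a workflow specification
#'
#' @param setting Quantification setting.
#' @param matrix_type,normalization,imputation,dea Option names for the four
#'   variable steps.
#' @return A one-row tibble with the five columns, ready to be stacked into
#'   a workflow grid.
#' @export
workflow <- function(setting, matrix_type, normalization, imputation, dea) {
  tibble::tibble(
    setting = setting, matrix_type = matrix_type,
    normalization = normalization, imputation = imputation, dea = dea
  )
}

#' Workflow identifier string
#'
#' @param spec A workflow tibble (one or more rows).
#' @return `"matrix|normalization|imputation|dea"` per row (the setting is
#'   carried separately).
#' @export
workflow_id <- function(spec) {
  paste(spec$matrix_type, spec$normalization, spec$imputation, spec$dea,
    sep = "|"
  )
}

#' Validate a workflow against the registry and compatibility rules
#'
#' Checks that every option is registered for the setting and that the
#' (matrix type, DEA statistic) pair is compatible: count-based statistics
#' require the spectral `counts` matrix, intensity statistics require an
#' intensity matrix.
#'
#' @param spec A one-row workflow tibble from [workflow()].
#' @return A character vector of violations; `character(0)` means valid.
#' @export
validate_workflow <- function(spec) {
  stopifnot(nrow(spec) == 1L)
  out <- character()
  if (!spec$setting %in% names(.registry$matrix)) {
    return(paste0("unknown setting '", spec$setting, "'"))
  }
  if (!spec$matrix_type %in% .registry$matrix[[spec$setting]]) {
    out <- c(out, paste0(
      "matrix type '", spec$matrix_type, "' not registered for setting '",
      spec$setting, "'"
    ))
  }
  for (step in c("normalization", "imputation", "dea")) {
    slot <- .registry[[step]]
    if (!spec[[step]] %in% c(slot$builtin, slot$plugin)) {
      out <- c(out, paste0(
        "'", spec[[step]], "' is not a registered ", step, " option"
      ))
    }
  }
  count_dea <- spec$dea %in% .registry$count_based_dea
  if (count_dea && spec$matrix_type != "counts") {
    out <- c(out, paste0(
      "count-based statistic '", spec$dea,
      "' requires the counts matrix, not '", spec$matrix_type, "'"
    ))
  }
  if (!count_dea && spec$matrix_type == "counts" &&
    spec$dea %in% c(.registry$dea$builtin, .registry$dea$plugin)) {
    out <- c(out, paste0(
      "intensity statistic '", spec$dea, "' is incompatible with counts"
    ))
  }
  out
}

#' Enumerate the built-in workflow grid for a setting
#'
#' The cartesian product of registered matrix types, built-in (and, if
#' `available_only = FALSE`, plugin) normalization, imputation and DEA
#' options, minus combinations rejected by [validate_workflow()].
#'
#' @param setting Quantification setting.
#' @param available_only Keep only options whose implementation is
#'   available (default `TRUE`).
#' @return A workflow tibble, lexicographically ordered.
#' @export
workflow_grid <- function(setting, available_only = TRUE) {
  pick <- function(step) {
    o <- registry_options(setting, step)
    if (available_only) o <- dplyr::filter(o, .data$available)
    sort(o$option)
  }
  grid <- tidyr::expand_grid(
    setting = setting,
    matrix_type = sort(registry_options(setting, "matrix")$option),
    normalization = pick("normalization"),
    imputation = pick("imputation"),
    dea = pick("dea")
  )
  keep <- purrr::map_lgl(
    seq_len(nrow(grid)),
    \(i) length(validate_workflow(grid[i, ])) == 0L
  )
  grid[keep, ]
}

#' Enumerate pairwise contrasts among group labels
#'
#' A contrast is one two-group expression comparison; `n` distinct groups
#' (e.g. spike-in concentration levels) yield `n (n - 1) / 2` unordered
#' pairs.
#'
#' @param groups Character vector of at least two distinct group labels.
#' @return A tibble with columns `group_a`, `group_b`, lexicographically
#'   ordered with `group_a < group_b`.
#' @examples
#' nrow(enumerate_contrasts(letters[1:5])) # choose(5, 2) = 10
#' @export
enumerate_contrasts <- function(groups) {
  groups <- as.character(groups)
  if (anyDuplicated(groups)) abort("group labels must be distinct")
  if (length(groups) < 2L) abort("need at least two groups")
  g <- sort(groups)
  pairs <- utils::combn(g, 2L)
  tibble::tibble(group_a = pairs[1L, ], group_b = pairs[2L, ]) |>
    dplyr::arrange(.data$group_a, .data$group_b)
}

#' Validate a sample design against a contrast
#'
#' @param design A data frame with columns `sample` and `group`.
#' @param contrast Length-2 character vector `(group_a, group_b)`.
#' @return The design tibble, invisibly; errors if a contrast group is
#'   absent or has fewer than two samples.
#' @export
check_design <- function(design, contrast) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample", "group") %in% names(design)))
  if (length(contrast) != 2L || contrast[1L] == contrast[2L]) {
    abort("contrast must name two distinct groups")
  }
  for (g in contrast) {
    n <- sum(design$group == g)
    if (n < 2L) {
      abort(paste0("contrast group '", g, "' has ", n, " sample(s); need >= 2"))
    }
  }
  invisible(design)
}

#' Benchmark dataset registry
#'
#' The gold-standard spike-in datasets commonly used to benchmark DEA
#' workflows: 12 label-free DDA, 7 label-free DIA and 5 TMT datasets, with
#' the number of contrasts each contributes (22, 17 and 15 in total) and
#' the published per-setting workflow-grid sizes. These describe public
#' repository accessions; no raw data ships with the package.
#'
#' @return A tibble with columns `dataset`, `id`, `technique`, `contrasts`,
#'   `instrument`.
#' @export
benchmark_datasets <- function() {
  tibble::tribble(
    ~dataset, ~id, ~technique, ~contrasts, ~instrument,
    "HYE5600735_LFQ", "PXD028735", "DDA", 1L, "SCIEX Triple TOF5600",
    "HYE6600735_LFQ", "PXD028735", "DDA", 1L, "SCIEX Triple TOF6600",
    "HYEqe735_LFQ", "PXD028735", "DDA", 1L, "Orbitrap QE-HFX",
    "HYEtims735_LFQ", "PXD028735", "DDA", 1L, "TimsToF pro",
    "HYtims134_LFQ", "PXD036134", "DDA", 3L, "TimsToF pro",
    "HEtims425_LFQ", "PXD021425", "DDA", 3L, "TimsToF pro",
    "YUltq006_LFQ", "PDC000006", "DDA", 2L, "LTQ-Orbitrap",
    "YUltq099_LFQ", "PXD002099", "DDA", 2L, "LTQ Orbitrap Velos",
    "YUltq819_LFQ", "PXD001819", "DDA", 3L, "LTQ Orbitrap Velos",
    "HEqe408_LFQ", "PXD018408", "DDA", 1L, "Q Exactive",
    "HYqfl683_LFQ", "PXD007683", "DDA", 3L, "Orbitrap Fusion Lumos",
    "HYEtims777_LFQ", "PXD014777", "DDA", 1L, "TimsToF pro",
    "HYEtims735_DIA", "PXD028735", "DIA", 1L, "TimsToF pro",
    "MYtims709_DIA", "PXD034709", "DIA", 3L, "TimsToF pro",
    "HEof_n600_DIA", "PXD026600", "DIA", 3L, "Orbitrap Fusion ETD",
    "HEof_w600_DIA", "PXD026600", "DIA", 3L, "Orbitrap Fusion ETD",
    "HYtims134_DIA", "PXD036134", "DIA", 3L, "TimsToF pro",
    "HEqe777_DIA", "PXD019777", "DIA", 3L, "Q Exactive HF",
    "HEqe408_DIA", "PXD018408", "DIA", 1L, "Q Exactive",
    "HEqe277_TMT10", "PXD013277", "TMT", 3L, "Q Exactive",
    "HYqfl683_TMT11", "PXD007683", "TMT", 3L, "Orbitrap Fusion Lumos",
    "HYms2faims815_TMT16", "PXD020815", "TMT", 3L, "Orbitrap Fusion Lumos",
    "HYsps2815_TMT16", "PXD020815", "TMT", 3L, "Orbitrap Fusion Lumos",
    "HYms2815_TMT16", "PXD020815", "TMT", 3L, "Orbitrap Fusion Lumos"
  )
}

#' Published per-setting workflow-grid sizes
#'
#' The full combinatoric workflow spaces benchmarked per quantification
#' setting (they depend on a compatibility matrix wider than the built-in
#' registry, which covers plugin tools as well).
#'
#' @return A named integer vector, one entry per setting.
#' @export
published_grid_sizes <- function() {
  c(
    FG_DDA = 7852L, MQ_DDA = 7852L, DIANN_DIA = 6284L, spt_DIA = 6284L,
    FG_TMT = 4720L, MQ_TMT = 1584L
  )
}
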