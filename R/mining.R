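#' Encode workflows as option itemsets
#'
#' Each workflow becomes a transaction of `step=option` items
#' (`matrix=dlfq`, `norm=none`, `mvi=SeqKNN`, `dea=limma`). The matrix
#' item is omitted when the workflow's setting registers a single matrix
#' type (as with MQ reporter-intensity TMT), since a constant item carries
#' no pattern information.
#'
#' @param specs A workflow tibble (rows from [workflow()] or a
#'   [aggregate_ranks()] table).
#' @return A list of character vectors, one transaction per workflow.
#' @export
encode_workflow_items <- function(specs) {
  specs <- tibble::as_tibble(specs)
  if (nrow(specs) == 0L) return(list())
  purrr::map(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    items <- c(
      paste0("matrix=", s$matrix_type),
      paste0("norm=", s$normalization),
      paste0("mvi=", s$imputation),
      paste0("dea=", s$dea)
    )
    if (s$setting %in% names(.registry$matrix) &&
        length(.registry$matrix[[s$setting]]) == 1L) {
      items <- items[-1L]
    }
    items
  })
}

# ---- FP-tree machinery -----------------------------------------------------
# Nodes are environments (mutable): item, count, parent, children (named
# list). The header table maps item -> list of tree nodes, ordered by
# support descending then item name ascending.

fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item
  e$count <- 0
  e$parent <- parent
  e$children <- list()
  e
}

fp_insert <- function(root, items, count, header) {
  node <- root
  for (it in items) {
    child <- node$children[[it]]
    if (is.null(child)) {
      child <- fp_node(it, node)
      node$children[[it]] <- child
      header$links[[it]] <- c(header$links[[it]], child)
    }
    child$count <- child$count + count
    node <- child
  }
}

fp_build <- function(transactions, counts, min_count) {
  support <- list()
  for (i in seq_along(transactions)) {
    for (it in transactions[[i]]) {
      support[[it]] <- (support[[it]] %||% 0) + counts[i]
    }
  }
  support <- unlist(support)
  if (is.null(support)) return(NULL)
  keep <- support[support >= min_count]
  if (length(keep) == 0L) return(NULL)
  # header order: support descending, item name ascending
  ord <- order(-keep, names(keep))
  item_order <- names(keep)[ord]
  header <- new.env(parent = emptyenv())
  header$links <- list()
  root <- fp_node(NA_character_, NULL)
  for (i in seq_along(transactions)) {
    items <- intersect(item_order, transactions[[i]])
    if (length(items) > 0L) fp_insert(root, items, counts[i], header)
  }
  list(root = root, header = header, item_order = item_order,
       support = keep[ord])
}

fp_mine <- function(tree, suffix, min_count, out) {
  # visit items in ascending support (reverse header order)
  for (it in rev(tree$item_order)) {
    pattern <- c(it, suffix)
    sup <- sum(vapply(tree$header$links[[it]], function(n) n$count,
                      numeric(1)))
    out$patterns[[length(out$patterns) + 1L]] <- list(
      items = pattern, support = sup
    )
    # conditional pattern base: prefix paths of every node carrying `it`
    base <- list()
    base_counts <- numeric()
    for (node in tree$header$links[[it]]) {
      path <- character()
      p <- node$parent
      while (!is.null(p) && !is.na(p$item)) {
        path <- c(p$item, path)
        p <- p$parent
      }
      if (length(path) > 0L) {
        base[[length(base) + 1L]] <- path
        base_counts <- c(base_counts, node$count)
      }
    }
    if (length(base) > 0L) {
      cond <- fp_build(base, base_counts, min_count)
      if (!is.null(cond)) fp_mine(cond, pattern, min_count, out)
    }
  }
  invisible(out)
}

#' Mine frequent option patterns with FP-growth
#'
#' Recursive frequent-pattern-tree mining: items are ordered by support in
#' a header table, transactions are compressed into an FP-tree, and
#' patterns grow by mining each item's conditional tree. Returns exactly
#' the itemsets whose support ratio (fraction of transactions containing
#' the itemset) reaches `min_sr`; singletons are included, the empty
#' itemset is not.
#'
#' @param transactions List of character vectors (e.g. from
#'   [encode_workflow_items()]).
#' @param min_sr Minimum support ratio in `(0, 1]`; default 0.1.
#' @return A tibble with columns `items` (list column, each itemset sorted
#'   alphabetically), `pattern` (collapsed label), `support` (transaction
#'   count) and `sr`, ordered by `sr` descending with lexicographic
#'   tie-break on the pattern label.
#' @examples
#' fp_growth(list(c("A", "B"), c("A", "B"), c("A", "C"), "B"), min_sr = 0.5)
#' @export
fp_growth <- function(transactions, min_sr = 0.1) {
  if (length(transactions) == 0L) abort("empty transaction list")
  if (min_sr <= 0 || min_sr > 1) abort("min_sr must lie in (0, 1]")
  n <- length(transactions)
  transactions <- purrr::map(transactions, unique)
  min_count <- min_sr * n - 1e-9
  tree <- fp_build(transactions, rep(1, n), min_count)
  out <- new.env(parent = emptyenv())
  out$patterns <- list()
  if (!is.null(tree)) fp_mine(tree, character(), min_count, out)
  if (length(out$patterns) == 0L) {
    return(tibble::tibble(
      items = list(), pattern = character(), support = integer(),
      sr = numeric()
    ))
  }
  tbl <- tibble::tibble(
    items = purrr::map(out$patterns, \(p) sort(p$items)),
    support = purrr::map_dbl(out$patterns, "support")
  )
  tbl$pattern <- purrr::map_chr(tbl$items, paste, collapse = ",")
  tbl$sr <- tbl$support / n
  tbl <- tbl[order(-tbl$sr, tbl$pattern), ]
  tbl$support <- as.integer(round(tbl$support))
  tbl[, c("items", "pattern", "support", "sr")]
}

#' Mine patterns from one performance level of a ranking
#'
#' Restricts FP-growth to the workflows labeled with the requested
#' performance level (typically `H`, the top 5%, or `L`, the bottom 50%);
#' support ratios are computed within that level's workflows.
#'
#' @param ranking A `ranking_table` from [aggregate_ranks()].
#' @param level `"H"`, `"RH"`, `"RL"` or `"L"`.
#' @param min_sr Minimum support ratio; default 0.1.
#' @return As [fp_growth()].
#' @export
mine_levels <- function(ranking, level = c("H", "L", "RH", "RL"),
                        min_sr = 0.1) {
  level <- match.arg(level)
  sub <- ranking[ranking$level == level, ]
  if (nrow(sub) == 0L) abort(paste0("no workflows at level ", level))
  fp_growth(encode_workflow_items(sub), min_sr = min_sr)
}
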