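#' P-value combination for ensemble inference
#'
#' Combines the per-protein p-values of several member workflows into one.
#' Missing members (`NA`) are allowed: with `t` of `K` sub-p-values
#' present, the hurdle statistic uses `t` degrees of freedom, Fisher uses
#' `2t`, and the voting modes take order statistics of the present values.
#'
#' * `combine_pvalues_hurdle()`: transform each present p-value to a
#'   z-value \eqn{z_i = \Phi^{-1}(1 - p_i)} (standard normal under the
#'   null) and refer \eqn{\sum z_i^2} to the upper tail of
#'   \eqn{\chi^2_t}. With `t = 1` the combined p-value equals the single
#'   existing one (exactly); with `t = 0` it is 1.
#' * `combine_pvalues_fisher()`: refer \eqn{-2 \sum \ln p_i} to the upper
#'   tail of \eqn{\chi^2_{2t}}.
#' * `combine_pvalues_vote()`: the minimum, maximum or median (midpoint
#'   for an even count) of the present p-values.
#'
#' p-values of exactly 0 are clipped to `1e-300` with a warning.
#'
#' @param p Numeric vector of sub-p-values in `(0, 1]`; `NA` marks an
#'   absent member.
#' @return The combined p-value.
#' @export
combine_pvalues_hurdle <- function(p) {
  p <- clip_pvalues(p[!is.na(p)])
  t <- length(p)
  if (t == 0L) return(1)
  if (t == 1L) return(p)
  z <- qnorm(p, lower.tail = FALSE) # = Phi^-1(1 - p), accurate for small p
  z <- pmin(pmax(z, qnorm(1e-300)), -qnorm(1e-300))
  pchisq(sum(z^2), df = t, lower.tail = FALSE)
}

#' @rdname combine_pvalues_hurdle
#' @export
combine_pvalues_fisher <- function(p) {
  p <- clip_pvalues(p[!is.na(p)])
  t <- length(p)
  if (t == 0L) return(1)
  pchisq(-2 * sum(log(p)), df = 2 * t, lower.tail = FALSE)
}

#' @rdname combine_pvalues_hurdle
#' @param mode `"min"`, `"max"` or `"median"`.
#' @export
combine_pvalues_vote <- function(p, mode = c("min", "max", "median")) {
  mode <- match.arg(mode)
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(1)
  switch(mode, min = min(p), max = max(p), median = median(p))
}

clip_pvalues <- function(p) {
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn("p-value of 0 clipped to 1e-300")
    p[p == 0] <- 1e-300
  }
  p
}

#' Integrate log2 fold changes across ensemble members
#'
#' The ensembled log2FC is the sub-log2FC with the biggest absolute value;
#' an exact magnitude tie is broken toward the earlier member, so the
#' result depends on member order in that (measure-zero) case.
#'
#' @param log2fc Numeric vector of sub-log2FCs; `NA` marks an absent
#'   member.
#' @return The selected log2FC (0 if no member is present).
#' @export
combine_logfc <- function(log2fc) {
  x <- log2fc[!is.na(log2fc)]
  if (length(x) == 0L) return(0)
  x[which.max(abs(x))]
}

combiner_fn <- function(method) {
  method <- match.arg(method, c("hurdle", "fisher", "min", "max", "median"))
  switch(method,
    hurdle = combine_pvalues_hurdle,
    fisher = combine_pvalues_fisher,
    function(p) combine_pvalues_vote(p, mode = method)
  )
}

combine_results <- function(members, method) {
  combine <- combiner_fn(method)
  proteins <- sort(unique(unlist(purrr::map(members, "protein"))))
  if (length(proteins) == 0L) abort("ensemble members contain no proteins")
  pv <- matrix(NA_real_, length(proteins), length(members))
  fc <- matrix(NA_real_, length(proteins), length(members))
  for (j in seq_along(members)) {
    m <- match(members[[j]]$protein, proteins)
    pv[m, j] <- members[[j]]$pvalue
    fc[m, j] <- members[[j]]$log2fc
  }
  p_comb <- apply(pv, 1, combine)
  fc_comb <- apply(fc, 1, combine_logfc)
  new_dea_result(
    protein = proteins, log2fc = fc_comb, pvalue = p_comb,
    flag = rowSums(!is.na(pv)) == 0,
    contrast = attr(members[[1L]], "contrast")
  )
}

#' Multi-quantification ensemble inference
#'
#' Integrates the DEA results of the best workflow per expression-matrix
#' type (e.g. spectral counts, topN, MaxLFQ and directLFQ views of the
#' same samples) into a single result: per protein, the present
#' sub-p-values are combined by the chosen method and the sub-log2FCs by
#' maximum magnitude; q-values are recomputed by Benjamini-Hochberg over
#' the combined p-values. A protein present in only one member keeps that
#' member's p-value (the hurdle `t = 1` rule).
#'
#' @param results Named list mapping matrix type to the top-ranked
#'   workflow's `dea_result` for that view; at least two distinct views.
#' @param method `"hurdle"` (default), `"fisher"`, `"min"`, `"max"` or
#'   `"median"`.
#' @return A `dea_result` tibble over the union protein list.
#' @export
ens_multi_quant <- function(results, method = "hurdle") {
  if (length(results) < 2L) abort("need at least two member views")
  if (anyDuplicated(names(results))) {
    abort("member views must have distinct matrix types")
  }
  out <- combine_results(results, method)
  attr(out, "ensemble") <- list(
    strategy = "multi_quant", method = method, members = names(results)
  )
  out
}

#' Top-k ensemble inference
#'
#' Integrates the results of the globally top-`k` workflows of a ranking
#' (by final rank position), with the same combination rules as
#' [ens_multi_quant()].
#'
#' @param ranking A `ranking_table` from [aggregate_ranks()].
#' @param results Named list of `dea_result` objects keyed by workflow id
#'   (`"matrix|normalization|imputation|dea"`, see [workflow_id()]).
#' @param k Number of top workflows to integrate (`>= 2`).
#' @inheritParams ens_multi_quant
#' @return A `dea_result` tibble.
#' @export
ens_topk <- function(ranking, results, k = 5L, method = "hurdle") {
  if (k < 2L) abort("k must be at least 2")
  if (k > nrow(ranking)) abort("k exceeds the number of ranked workflows")
  top <- ranking[order(ranking$position), ][seq_len(k), ]
  ids <- workflow_id(top)
  missing <- setdiff(ids, names(results))
  if (length(missing) > 0L) {
    abort(paste0("no result supplied for top workflow(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- combine_results(results[ids], method)
  attr(out, "ensemble") <- list(
    strategy = "topk", method = method, members = ids, k = k
  )
  out
}
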