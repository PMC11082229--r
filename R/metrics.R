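#' Confusion counts for DE calls against ground truth
#'
#' Counts true/false positives/negatives at the DE-calling thresholds: a
#' positive call is `|log2fc| >= logfc_thresh` and `qvalue < q_thresh`;
#' truth is the `is_de` flag of the spike-in ground truth.
#'
#' @param result A `dea_result` (or data frame with `protein`, `log2fc`,
#'   `qvalue`).
#' @param truth Data frame with columns `protein`, `is_de` (and optionally
#'   `true_log2fc`). Must cover every protein in `result`.
#' @param logfc_thresh,q_thresh DE-calling thresholds; defaults
#'   `log2(1.5)` and 0.05.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(result, truth, logfc_thresh = log2(1.5),
                             q_thresh = 0.05) {
  truth <- tibble::as_tibble(truth)
  absent <- setdiff(result$protein, truth$protein)
  if (length(absent) > 0L) {
    abort(paste0("proteins absent from ground truth: ",
                 paste(head(absent, 5L), collapse = ", ")))
  }
  called <- call_de(result, logfc_thresh, q_thresh)
  is_de <- truth$is_de[match(called$protein, truth$protein)]
  tibble::tibble(
    tp = sum(called$de & is_de),
    fp = sum(called$de & !is_de),
    tn = sum(!called$de & !is_de),
    fn = sum(!called$de & is_de)
  )
}

#' Confusion-matrix metrics
#'
#' `nmcc()` is the normalized Matthews correlation coefficient
#' \eqn{(MCC + 1) / 2 \in [0, 1]}; `gmean()` the geometric mean of
#' specificity and recall; `f1_mcc()` returns precision, recall, F1 and MCC
#' together (the classifier-evaluation pair). Any zero denominator factor
#' contributes 0 by convention.
#'
#' @param counts A one-row data frame with `tp`, `fp`, `tn`, `fn` (from
#'   [confusion_counts()]).
#' @return `nmcc()` and `gmean()` return a number in `[0, 1]`; `f1_mcc()` a
#'   one-row tibble with `precision`, `recall`, `f1`, `mcc`.
#' @export
nmcc <- function(counts) (mcc(counts) + 1) / 2

mcc <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  tn <- counts$tn
  fn <- counts$fn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' @rdname nmcc
#' @export
gmean <- function(counts) {
  spec <- if (counts$fp + counts$tn == 0) 0 else counts$tn / (counts$fp + counts$tn)
  rec <- if (counts$tp + counts$fn == 0) 0 else counts$tp / (counts$tp + counts$fn)
  sqrt(spec * rec)
}

#' @rdname nmcc
#' @export
f1_mcc <- function(counts) {
  prec <- if (counts$tp + counts$fp == 0) 0 else counts$tp / (counts$tp + counts$fp)
  rec <- if (counts$tp + counts$fn == 0) 0 else counts$tp / (counts$tp + counts$fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  tibble::tibble(precision = prec, recall = rec, f1 = f1, mcc = mcc(counts))
}

#' Partial area under the ROC curve
#'
#' Raw (unstandardized) trapezoidal area under the ROC over
#' \eqn{FPR \in [0, fpr\_max]}, so a perfect classifier scores `fpr_max`
#' and a random one `fpr_max^2 / 2`. The confidence that a protein is
#' truly DE is `1 - qvalue`. Tied confidences traverse the ROC diagonally
#' (simultaneous step).
#'
#' @param confidence Numeric vector of per-protein confidences.
#' @param is_de Logical vector of ground-truth labels (same order).
#' @param fpr_max False-positive-rate cap, conventionally 0.01, 0.05 or
#'   0.1.
#' @return The partial area, in `[0, fpr_max]`.
#' @export
pauc <- function(confidence, is_de, fpr_max = 0.1) {
  stopifnot(length(confidence) == length(is_de))
  npos <- sum(is_de)
  nneg <- sum(!is_de)
  if (npos == 0L || nneg == 0L) {
    abort("pAUC needs at least one positive and one negative in the truth")
  }
  ord <- order(confidence, decreasing = TRUE)
  conf <- confidence[ord]
  lab <- is_de[ord]
  # one ROC vertex per distinct confidence value (ties step simultaneously)
  idx <- which(!duplicated(conf, fromLast = TRUE))
  tpr <- cumsum(lab)[idx] / npos
  fpr <- cumsum(!lab)[idx] / nneg
  xs <- c(0, fpr)
  ys <- c(0, tpr)
  area <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x1 <- xs[i]
    x2 <- xs[i + 1L]
    y1 <- ys[i]
    y2 <- ys[i + 1L]
    if (x1 >= fpr_max) break
    if (x2 > fpr_max) {
      # clip the segment at the cap
      y2 <- y1 + (y2 - y1) * (fpr_max - x1) / (x2 - x1)
      x2 <- fpr_max
    }
    area <- area + (x2 - x1) * (y1 + y2) / 2
  }
  area
}

#' The five-metric benchmark vector
#'
#' Composes the three partial AUCs (FPR caps 0.01, 0.05, 0.1, on the
#' `1 - qvalue` confidence), nMCC and G-mean for one DEA result against
#' ground truth.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble with columns `pauc001`, `pauc005`, `pauc01`,
#'   `nmcc`, `gmean`.
#' @export
metric_vector <- function(result, truth, logfc_thresh = log2(1.5),
                          q_thresh = 0.05) {
  truth <- tibble::as_tibble(truth)
  counts <- confusion_counts(result, truth, logfc_thresh, q_thresh)
  is_de <- truth$is_de[match(result$protein, truth$protein)]
  conf <- 1 - result$qvalue
  tibble::tibble(
    pauc001 = pauc(conf, is_de, 0.01),
    pauc005 = pauc(conf, is_de, 0.05),
    pauc01 = pauc(conf, is_de, 0.1),
    nmcc = nmcc(counts),
    gmean = gmean(counts)
  )
}

.metric_cols <- c("pauc001", "pauc005", "pauc01", "nmcc", "gmean")
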