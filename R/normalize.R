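#' Normalize an expression matrix
#'
#' Column-wise (per-sample) normalization operators. Centering and
#' regression-based methods operate on log2 intensities; ratio-type
#' scalings (`div.*`, `total`, `max`) operate on raw intensities. All
#' operators touch observed cells only -- the missingness pattern is never
#' changed.
#'
#' Contracts per method:
#' * `none`: identity.
#' * `center.mean` / `center.median`: subtract each sample's observed
#'   mean / median (log2 scale).
#' * `div.mean` / `div.median`: divide each sample by its observed
#'   mean / median (raw scale).
#' * `total`: total-ion-current style -- divide each sample by its observed
#'   sum, then multiply by the grand mean of sample sums (raw scale).
#' * `max`: divide each sample by its observed maximum (raw scale).
#' * `quantiles` / `quantiles.robust`: quantile normalization to the mean /
#'   median reference distribution; missing entries are skipped and values
#'   are mapped through rank interpolation.
#' * `MBQN`: quantile normalization followed by restoring each sample's
#'   original observed mean (mean-balanced variant).
#' * `Rlr`: robust linear regression (M-estimation) of each sample against
#'   the row-median reference profile; the fitted systematic trend is
#'   removed and the reference profile retained.
#' * `lossf`: as `Rlr` with a smooth local-regression (lowess) fit instead
#'   of a line.
#'
#' @param x An [expr_matrix()].
#' @param method One of the registered normalization options.
#' @return The normalized [expr_matrix()]; the transformation record (a
#'   list with the method, parameters and per-sample statistics needed to
#'   replay it) is appended to the matrix's `records` attribute and
#'   retrievable with [preprocess_records()].
#' @examples
#' m <- expr_matrix(
#'   tibble::tibble(protein = c("a", "b", "c"), s1 = 1:3, s2 = c(2, 4, 6)),
#'   scale = "log2"
#' )
#' em_values(normalize_matrix(m, "center.median"))
#' @export
normalize_matrix <- function(x, method = "none") {
  opts <- .registry$normalization
  if (!method %in% c(opts$builtin, opts$plugin)) {
    abort(paste0("unknown normalization method '", method, "'"))
  }
  if (!method %in% opts$builtin) {
    fn <- plugin_fn("normalization", method)
    if (is.null(fn)) {
      abort(paste0("normalization '", method,
                   "' is a plugin slot with no registered implementation"))
    }
    out <- fn(x)
    return(add_record(out, list(method = method, plugin = TRUE)))
  }
  needs_log2 <- c("center.mean", "center.median", "Rlr", "lossf")
  needs_raw <- c("div.mean", "div.median", "total", "max")
  if (method %in% needs_log2 && em_scale(x) != "log2") {
    abort(paste0("'", method, "' requires a log2-scale matrix"))
  }
  if (method %in% needs_raw && em_scale(x) != "raw") {
    abort(paste0("'", method, "' requires a raw-scale matrix"))
  }
  v <- em_values(x)
  rec <- list(method = method, per_sample = NULL)
  stat <- switch(method,
    none = NULL,
    center.mean = apply(v, 2, mean, na.rm = TRUE),
    center.median = apply(v, 2, median, na.rm = TRUE),
    div.mean = apply(v, 2, mean, na.rm = TRUE),
    div.median = apply(v, 2, median, na.rm = TRUE),
    max = apply(v, 2, max, na.rm = TRUE),
    total = apply(v, 2, sum, na.rm = TRUE),
    NULL
  )
  out_v <- switch(method,
    none = v,
    center.mean = ,
    center.median = sweep(v, 2, stat, `-`),
    div.mean = ,
    div.median = ,
    max = sweep(v, 2, stat, `/`),
    total = sweep(v, 2, stat / mean(stat), `/`),
    quantiles = quantile_normalize(v, ref_fun = mean),
    quantiles.robust = quantile_normalize(v, ref_fun = median),
    MBQN = {
      q <- quantile_normalize(v, ref_fun = mean)
      pre <- apply(v, 2, mean, na.rm = TRUE)
      post <- apply(q, 2, mean, na.rm = TRUE)
      stat <- pre - post
      sweep(q, 2, stat, `+`)
    },
    Rlr = regression_normalize(v, smooth = FALSE),
    lossf = regression_normalize(v, smooth = TRUE)
  )
  if (!is.null(stat)) {
    rec$per_sample <- tibble::tibble(sample = colnames(v), statistic = stat)
  }
  stopifnot(identical(is.na(out_v), is.na(v)))
  add_record(em_replace(x, out_v), rec)
}

# quantile normalization with missingness handled by rank interpolation:
# each column's sorted observed values are interpolated onto a common
# probability grid, averaged into a reference curve (ref_fun = mean or
# median), and each observed value is mapped to the reference at its
# (average-tie) rank probability
quantile_normalize <- function(v, ref_fun = mean) {
  n <- nrow(v)
  grid <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  curves <- apply(v, 2, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) return(rep(NA_real_, n))
    if (length(obs) == 1L) return(rep(obs, n))
    quantile(obs, probs = grid, type = 7, names = FALSE)
  })
  ref <- apply(curves, 1, ref_fun, na.rm = TRUE)
  out <- v
  for (j in seq_len(ncol(v))) {
    idx <- which(!is.na(v[, j]))
    m <- length(idx)
    if (m == 0L) next
    r <- rank(v[idx, j], ties.method = "average")
    p <- if (m == 1L) 0.5 else (r - 1) / (m - 1)
    out[idx, j] <- approx(grid, ref, xout = p, rule = 2, ties = "ordered")$y
  }
  out
}

# regression-based normalization against the row-median reference profile:
# fit each sample on the reference (robust line or lowess curve), subtract
# the fitted systematic component, and retain the reference profile so that
# cross-sample bias is removed without flattening protein effects
regression_normalize <- function(v, smooth = FALSE) {
  ref <- apply(v, 1, median, na.rm = TRUE)
  out <- v
  for (j in seq_len(ncol(v))) {
    idx <- which(!is.na(v[, j]) & !is.na(ref))
    if (length(idx) < 5L) next
    y <- v[idx, j]
    r <- ref[idx]
    fitted <- if (smooth) {
      if (length(unique(r)) < 3L) next
      lw <- lowess(r, y, f = 2 / 3)
      approx(lw$x, lw$y, xout = r, rule = 2, ties = "ordered")$y
    } else {
      fit <- suppressWarnings(MASS::rlm(y ~ r, maxit = 50))
      unname(fit$coefficients[1L] + fit$coefficients[2L] * r)
    }
    out[idx, j] <- y - fitted + r
  }
  out
}

add_record <- function(x, rec) {
  attr(x, "records") <- c(attr(x, "records"), list(rec))
  x
}

#' Preprocessing records attached to a matrix
#'
#' @param x An [expr_matrix()] that has passed through
#'   [normalize_matrix()] or [impute_matrix()].
#' @return A list of records, one per transformation, each holding the
#'   method, its parameters, per-sample statistics and (for stochastic
#'   imputation) the seed -- enough to replay the transformation.
#' @export
preprocess_records <- function(x) attr(x, "records") %||% list()
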