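#' Reference DEA statistics
#'
#' Built-in per-protein differential-expression tests for two-group
#' contrasts on log2-scale intensities. All three return a `dea_result`
#' tibble with one row per protein: `protein`, `log2fc` (group A mean minus
#' group B mean), `pvalue`, `qvalue` (Benjamini-Hochberg), and `flag`
#' marking proteins that could not be tested (their p-value is set to 1 so
#' every protein keeps a record).
#'
#' * `dea_ttest()`: Welch two-sided t-test on observed values; needs at
#'   least two observed values per group.
#' * `dea_anova()`: classic one-way F-test across all design groups (equal
#'   variances); for two groups its p-value equals the pooled t-test's.
#'   The reported `log2fc` is always for the requested contrast pair.
#' * `dea_moderated_t()`: empirical-Bayes moderated t. The per-protein
#'   pooled residual variance \eqn{s^2} with \eqn{d} residual df is shrunk
#'   toward a prior \eqn{(d_0, s_0^2)} fitted by method of moments on
#'   \eqn{\log s^2}; the moderated statistic uses the posterior variance
#'   and gains \eqn{d_0} degrees of freedom.
#'
#' @param x A log2-scale [expr_matrix()].
#' @param design Data frame with columns `sample`, `group`.
#' @param contrast Length-2 character vector `(group_a, group_b)`; defaults
#'   to the first two groups in sorted order.
#' @return A `dea_result` tibble (see Details) carrying the contrast as an
#'   attribute.
#' @name dea_statistics
NULL

dea_groups <- function(x, design, contrast) {
  design <- tibble::as_tibble(design)
  if (is.null(contrast)) {
    contrast <- sort(unique(design$group))[1:2]
  }
  check_design(design, contrast)
  v <- em_values(x)
  samp <- em_samples(x)
  missing_samples <- setdiff(design$sample[design$group %in% contrast], samp)
  if (length(missing_samples) > 0L) {
    abort(paste0("design samples absent from matrix: ",
                 paste(missing_samples, collapse = ", ")))
  }
  list(
    values = v,
    a = samp %in% design$sample[design$group == contrast[1L]],
    b = samp %in% design$sample[design$group == contrast[2L]],
    contrast = contrast, design = design
  )
}

new_dea_result <- function(protein, log2fc, pvalue, flag, contrast,
                           workflow = NULL) {
  pvalue[is.na(pvalue)] <- 1
  pvalue <- unname(pmin(pmax(pvalue, 0), 1))
  out <- tibble::tibble(
    protein = unname(protein), log2fc = unname(log2fc), pvalue = pvalue,
    qvalue = bh_adjust(pvalue), flag = unname(flag)
  )
  structure(out,
    class = c("dea_result", class(tibble::tibble())),
    contrast = contrast, workflow = workflow
  )
}

#' @rdname dea_statistics
#' @export
dea_ttest <- function(x, design, contrast = NULL) {
  if (em_scale(x) != "log2") abort("DEA statistics require a log2-scale matrix")
  g <- dea_groups(x, design, contrast)
  res <- apply(g$values, 1, function(row) {
    a <- row[g$a][!is.na(row[g$a])]
    b <- row[g$b][!is.na(row[g$b])]
    lfc <- if (length(a) > 0 && length(b) > 0) {
      mean(a) - mean(b)
    } else if (length(a) + length(b) > 0) {
      0
    } else {
      0
    }
    if (length(a) < 2L || length(b) < 2L) {
      return(c(lfc, NA_real_, 1))
    }
    if (sd(c(a, b)) == 0) {
      return(c(0, 1, 0)) # identical observations: no evidence
    }
    p <- tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
    c(lfc, p, as.numeric(is.na(p)))
  })
  new_dea_result(
    protein = rownames(g$values), log2fc = res[1L, ], pvalue = res[2L, ],
    flag = res[3L, ] > 0, contrast = g$contrast
  )
}

#' @rdname dea_statistics
#' @export
dea_anova <- function(x, design, contrast = NULL) {
  if (em_scale(x) != "log2") abort("DEA statistics require a log2-scale matrix")
  g <- dea_groups(x, design, contrast)
  design <- tibble::as_tibble(design)
  samp <- em_samples(x)
  grp <- design$group[match(samp, design$sample)]
  res <- apply(g$values, 1, function(row) {
    ok <- !is.na(row) & !is.na(grp)
    a <- row[g$a][!is.na(row[g$a])]
    b <- row[g$b][!is.na(row[g$b])]
    lfc <- if (length(a) > 0 && length(b) > 0) mean(a) - mean(b) else 0
    tab <- table(grp[ok])
    if (length(tab) < 2L || any(tab < 2L)) {
      return(c(lfc, NA_real_, 1))
    }
    if (sd(row[ok]) == 0) {
      return(c(0, 1, 0))
    }
    p <- tryCatch(
      oneway.test(row[ok] ~ factor(grp[ok]), var.equal = TRUE)$p.value,
      error = function(e) NA_real_
    )
    c(lfc, p, as.numeric(is.na(p)))
  })
  new_dea_result(
    protein = rownames(g$values), log2fc = res[1L, ], pvalue = res[2L, ],
    flag = res[3L, ] > 0, contrast = g$contrast
  )
}

# Newton inversion of the trigamma function (for the moment estimator of
# the prior degrees of freedom)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    step <- (tri - y) / psigamma(x, deriv = 2)
    x <- max(x - step, 1e-8)
    if (abs(step) < 1e-10 * x) break
  }
  x
}

#' @rdname dea_statistics
#' @param prior Optional list `list(d0 = , s02 = )` overriding the fitted
#'   empirical-Bayes prior (moderated t only); `d0 = 0` recovers the
#'   ordinary pooled t-test, `d0 = Inf` uses the prior variance alone.
#' @export
dea_moderated_t <- function(x, design, contrast = NULL, prior = NULL) {
  if (em_scale(x) != "log2") abort("DEA statistics require a log2-scale matrix")
  g <- dea_groups(x, design, contrast)
  v <- g$values
  stats_tbl <- t(apply(v, 1, function(row) {
    a <- row[g$a][!is.na(row[g$a])]
    b <- row[g$b][!is.na(row[g$b])]
    na <- length(a)
    nb <- length(b)
    lfc <- if (na > 0 && nb > 0) mean(a) - mean(b) else 0
    d <- na + nb - 2L
    if (na < 1L || nb < 1L || d < 1L) {
      return(c(lfc, NA_real_, NA_real_, na, nb))
    }
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / d
    c(lfc, s2, d, na, nb)
  }))
  s2 <- stats_tbl[, 2L]
  d <- stats_tbl[, 3L]
  usable <- which(!is.na(s2) & s2 > 0 & d > 0)
  if (is.null(prior) && length(usable) < 10L) {
    warn("fewer than 10 proteins with finite residual variance; falling back to the ordinary t-test")
    return(dea_ttest(x, design, contrast))
  }
  if (!is.null(prior)) {
    d0 <- prior$d0
    s02 <- prior$s02 %||% 1
  } else {
    # method of moments on log s^2 (zero-residual-df proteins excluded)
    z <- log(s2[usable])
    e <- z - digamma(d[usable] / 2) + log(d[usable] / 2)
    emean <- mean(e)
    nfit <- length(e)
    evar <- mean((e - emean)^2 * nfit / (nfit - 1) - trigamma(d[usable] / 2))
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  }
  lfc <- stats_tbl[, 1L]
  na <- stats_tbl[, 4L]
  nb <- stats_tbl[, 5L]
  s2_use <- ifelse(is.na(s2), 0, s2)
  d_use <- ifelse(is.na(d), 0, d)
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2_use))
  } else {
    (d0 * s02 + d_use * s2_use) / (d0 + d_use)
  }
  df_total <- d_use + d0
  tstat <- lfc / sqrt(s2_post * (1 / pmax(na, 1) + 1 / pmax(nb, 1)))
  p <- 2 * pt(-abs(tstat), df = df_total)
  testable <- na >= 1 & nb >= 1 & d_use >= 1
  p[!testable] <- NA_real_
  out <- new_dea_result(
    protein = rownames(v), log2fc = lfc, pvalue = p,
    flag = !testable, contrast = g$contrast
  )
  attr(out, "prior") <- list(d0 = d0, s02 = s02)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with enforced monotonicity. Missing
#' p-values are treated as 1 so every protein keeps a record.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values in `[0, 1]`, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p[is.na(p)] <- 1
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed proteins
#'
#' A protein is called DE iff `|log2fc| >= logfc_thresh` (weak inequality)
#' and `qvalue < q_thresh` (strict), the conventional fold-change plus FDR
#' gate.
#'
#' @param result A `dea_result` tibble (or any data frame with `log2fc` and
#'   `qvalue`).
#' @param logfc_thresh Absolute log2 fold-change threshold; default
#'   `log2(1.5)`.
#' @param q_thresh q-value threshold; default 0.05.
#' @return The input with a logical `de` column appended.
#' @export
call_de <- function(result, logfc_thresh = log2(1.5), q_thresh = 0.05) {
  dplyr::mutate(result,
    de = abs(.data$log2fc) >= logfc_thresh & .data$qvalue < q_thresh
  )
}

#' Run one workflow end to end
#'
#' Composes the pipeline defined by a workflow spec: select the requested
#' matrix view, log2-transform raw intensity matrices, normalize, impute,
#' apply the DEA statistic, and BH-adjust. Preprocessing records and the
#' seed are attached to the result.
#'
#' @param views Named list mapping matrix type to [expr_matrix()].
#' @param spec One-row workflow tibble from [workflow()].
#' @param design Data frame with columns `sample`, `group`.
#' @param contrast Length-2 character vector `(group_a, group_b)`.
#' @param seed Integer seed for stochastic stages.
#' @return A `dea_result` tibble with the workflow spec attached.
#' @export
run_workflow <- function(views, spec, design, contrast = NULL, seed = 1L) {
  bad <- validate_workflow(spec)
  if (length(bad) > 0L) {
    abort(paste0("invalid workflow: ", paste(bad, collapse = "; ")))
  }
  if (!spec$matrix_type %in% names(views)) {
    abort(paste0("matrix type '", spec$matrix_type, "' not present in views"))
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("workflow stage '", what, "' failed: ",
                   conditionMessage(e)))
    })
  }
  m <- views[[spec$matrix_type]]
  if (is_intensity_type(spec$matrix_type) && em_scale(m) == "raw") {
    norm_raw <- spec$normalization %in% c("div.mean", "div.median", "total",
                                          "max")
    if (norm_raw) {
      m <- stage("normalize", normalize_matrix(m, spec$normalization))
      m <- stage("log_transform", log_transform(m))
    } else {
      m <- stage("log_transform", log_transform(m))
      m <- stage("normalize", normalize_matrix(m, spec$normalization))
    }
  } else {
    m <- stage("normalize", normalize_matrix(m, spec$normalization))
  }
  m <- stage("impute", impute_matrix(m, spec$imputation, seed = seed))
  res <- stage("dea", {
    builtin <- switch(spec$dea,
      ttest = dea_ttest, anova = dea_anova, moderated_t = dea_moderated_t,
      NULL
    )
    if (!is.null(builtin)) {
      builtin(m, design, contrast)
    } else {
      fn <- plugin_fn("dea", spec$dea)
      if (is.null(fn)) {
        abort(paste0("DEA '", spec$dea,
                     "' is a plugin slot with no registered implementation"))
      }
      raw <- tibble::as_tibble(fn(m, design, contrast))
      stopifnot(all(c("protein", "log2fc", "pvalue") %in% names(raw)))
      new_dea_result(
        protein = raw$protein, log2fc = raw$log2fc, pvalue = raw$pvalue,
        flag = raw$flag %||% rep(FALSE, nrow(raw)),
        contrast = contrast %||% sort(unique(design$group))[1:2]
      )
    }
  })
  attr(res, "workflow") <- spec
  attr(res, "records") <- preprocess_records(m)
  attr(res, "seed") <- seed
  res
}

#' Write / read DEA results as TSV
#'
#' Columns: `protein`, `log2fc`, `pvalue`, `qvalue`.
#'
#' @param result A `dea_result`.
#' @param path File path.
#' @return `write_dea_result()` returns `path` invisibly; `read_dea_result()`
#'   a `dea_result` tibble.
#' @export
write_dea_result <- function(result, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(result), "protein", "log2fc", "pvalue",
                  "qvalue"),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_dea_result
#' @export
read_dea_result <- function(path) {
  out <- readr::read_tsv(path, col_types = "cddd", progress = FALSE)
  out$flag <- FALSE
  structure(out, class = c("dea_result", class(tibble::tibble())))
}
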