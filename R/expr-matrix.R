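#' Expression matrix container
#'
#' An expression matrix is a tibble whose first column (`protein`) holds
#' unique protein-group identifiers and whose remaining columns hold one
#' numeric sample each. Missing values are encoded as `NA` throughout.
#' Three tags travel with the table: the value `scale` (`"raw"` intensities
#' or `"log2"`), the `matrix_type` (how the protein-level values were
#' summarized: spectral `counts`, `top0`/`top1`/`top3` peptide intensities,
#' `LFQ`, `dlfq`, or TMT `abd`/`ratio`/`phi`/`reporter`), and the
#' quantification `setting` the matrix belongs to.
#'
#' @param data A data frame with a `protein` character column followed by
#'   numeric sample columns.
#' @param scale `"raw"` or `"log2"`.
#' @param matrix_type One of the registered matrix types; see
#'   [registry_options()].
#' @param setting Quantification setting tag; defaults to `"generic"`.
#' @return A tibble of class `expr_matrix` with attributes `scale`,
#'   `matrix_type` and `setting`.
#' @examples
#' m <- expr_matrix(
#'   tibble::tibble(protein = c("P1", "P2"), s1 = c(4, 8), s2 = c(2, NA)),
#'   scale = "raw", matrix_type = "LFQ"
#' )
#' missing_rate(m)
#' @export
expr_matrix <- function(data, scale = c("raw", "log2"),
                        matrix_type = "LFQ", setting = "generic") {
  scale <- match.arg(scale)
  data <- tibble::as_tibble(data)
  if (ncol(data) < 2L) {
    abort("an expression matrix needs a protein column plus >= 1 sample column")
  }
  names(data)[1L] <- "protein"
  data$protein <- as.character(data$protein)
  dup <- unique(data$protein[duplicated(data$protein)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated protein ids: ", paste(dup, collapse = ", ")))
  }
  for (j in seq(2L, ncol(data))) {
    if (!is.numeric(data[[j]])) {
      abort(paste0("sample column '", names(data)[j], "' is not numeric"))
    }
  }
  vals <- as.matrix(data[, -1L])
  if (scale == "raw" && any(vals < 0, na.rm = TRUE)) {
    abort("raw-scale expression values must be non-negative where observed")
  }
  structure(data,
    class = c("expr_matrix", class(tibble::tibble())),
    scale = scale, matrix_type = matrix_type, setting = setting
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "# expr_matrix: %d proteins x %d samples [%s, %s, %s], %.1f%% missing\n",
    nrow(x), ncol(x) - 1L, em_type(x), em_scale(x), em_setting(x),
    100 * missing_rate(x)
  ))
  NextMethod()
}

#' Accessors for expression-matrix tags
#'
#' @param x An `expr_matrix`.
#' @return `em_scale()`, `em_type()` and `em_setting()` return the
#'   corresponding tag strings; `em_values()` the numeric protein x sample
#'   matrix (rownames = protein ids); `em_samples()` the sample ids.
#' @export
em_values <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$protein
  m
}

#' @rdname em_values
#' @export
em_scale <- function(x) attr(x, "scale")

#' @rdname em_values
#' @export
em_type <- function(x) attr(x, "matrix_type")

#' @rdname em_values
#' @export
em_setting <- function(x) attr(x, "setting")

#' @rdname em_values
#' @export
em_samples <- function(x) names(x)[-1L]

# rebuild an expr_matrix from a value matrix, keeping ids and tags
em_replace <- function(x, values, scale = em_scale(x)) {
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- em_samples(x)
  out <- dplyr::bind_cols(tibble::tibble(protein = x$protein), out)
  expr_matrix(out,
    scale = scale, matrix_type = em_type(x),
    setting = em_setting(x)
  )
}

# matrix types whose zeros mean "not quantified" (everything but counts)
is_intensity_type <- function(matrix_type) !identical(matrix_type, "counts")

#' Read an expression matrix from a delimited text file
#'
#' The first column must hold protein ids and the header row sample ids.
#' Empty cells, `NA` and `NaN` are read as missing. For intensity-type
#' matrices a stored 0 means "not quantified" and is converted to missing;
#' for spectral `counts`, 0 is a valid observation and is kept.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @inheritParams expr_matrix
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path, dialect = c("tsv", "csv"),
                        scale = c("raw", "log2"),
                        matrix_type = "LFQ", setting = "generic") {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (ncol(raw) < 2L) abort("expected a protein column plus sample columns")
  prot <- raw[[1L]]
  dup <- unique(prot[duplicated(prot)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated protein ids in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  vals <- lapply(seq(2L, ncol(raw)), function(j) {
    cell <- raw[[j]]
    missing <- cell %in% c("", "NA", "NaN")
    out <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(out))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-numeric cell '%s' at row %d (protein %s), column '%s'",
        cell[bad[1L]], bad[1L], prot[bad[1L]], names(raw)[j]
      ))
    }
    out[missing] <- NA_real_
    out
  })
  names(vals) <- names(raw)[-1L]
  tab <- dplyr::bind_cols(tibble::tibble(protein = prot), tibble::as_tibble(vals))
  if (is_intensity_type(matrix_type)) {
    for (j in seq(2L, ncol(tab))) {
      z <- which(!is.na(tab[[j]]) & tab[[j]] == 0)
      if (length(z) > 0L) tab[[j]][z] <- NA_real_
    }
  }
  expr_matrix(tab, scale = scale, matrix_type = matrix_type, setting = setting)
}

#' Write an expression matrix to a delimited text file
#'
#' Missing cells are written as empty strings; column order is preserved, so
#' `read_matrix(write_matrix(m))` round-trips values, ordering and
#' missingness exactly.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(tibble::as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}

#' Fraction of missing cells
#'
#' @param x An [expr_matrix()].
#' @return A number in `[0, 1]`: missing cells over total cells.
#' @export
missing_rate <- function(x) {
  v <- em_values(x)
  if (length(v) == 0L) abort("empty expression matrix")
  mean(is.na(v))
}

#' Log2-transform a raw-scale expression matrix
#'
#' Observed values `x` become `log2(x)`; zeros (not quantified) become
#' missing. Calling on an already log2-scale matrix is an error, as a guard
#' against double transformation.
#'
#' @param x A raw-scale [expr_matrix()].
#' @return The matrix on log2 scale.
#' @export
log_transform <- function(x) {
  if (em_scale(x) == "log2") abort("matrix is already on log2 scale")
  v <- em_values(x)
  if (any(v < 0, na.rm = TRUE)) abort("negative value in raw-scale matrix")
  v[!is.na(v) & v == 0] <- NA_real_
  em_replace(x, log2(v), scale = "log2")
}
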