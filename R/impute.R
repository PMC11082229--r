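#' Impute missing values in an expression matrix
#'
#' Missing-value imputation operators for log2-scale intensity matrices.
#' Left-censored methods (`min`, `MinDet`, `MinProb`) target
#' missing-not-at-random dropout, where low-abundance proteins fail to be
#' quantified; neighbour- and regression-based methods (`knn`, `SeqKNN`,
#' `Impseq`) exploit protein-profile similarity. Observed values are never
#' altered, and every method except `none` returns a matrix with zero
#' missing cells.
#'
#' Contracts per method:
#' * `none`: matrix unchanged (downstream tests must tolerate missing
#'   values).
#' * `zero`: missing cells become 0.
#' * `min`: missing cells become the global observed minimum.
#' * `MinDet`: per sample, missing cells become that sample's `q`-th
#'   observed quantile (deterministic minimum; default `q = 0.01`).
#' * `MinProb`: per sample, missing cells are drawn from
#'   `Normal(q-th observed quantile, tune * median per-protein observed sd)`
#'   (probabilistic minimum; seeded; sd floored at 1e-6).
#' * `knn`: each missing cell is the mean, over the `k = 10` nearest
#'   neighbour proteins observed at that sample, of their values there.
#'   Distance is root-mean-square difference over jointly observed samples
#'   (so it is comparable across different shared-sample counts); ties are
#'   broken toward the smaller protein index.
#' * `SeqKNN`: proteins are processed in ascending missing-rate order; the
#'   neighbour pool starts with complete proteins and each imputed protein
#'   joins it, so previously imputed proteins are eligible neighbours.
#' * `Impseq`: sequential like `SeqKNN`, but each missing cell is filled by
#'   least-squares regression of the target sample on the protein's
#'   observed samples, fitted over the current complete pool.
#'
#' A protein with no observed values (or an empty neighbour pool) falls
#' back to `MinDet` for its cells; the fallback is noted in the record.
#'
#' @param x A log2-scale [expr_matrix()] (`zero` and `none` also accept
#'   raw).
#' @param method One of the registered imputation options.
#' @param seed Integer seed for stochastic methods (`MinProb`).
#' @param q Quantile used by `MinDet`/`MinProb` (default 0.01).
#' @param tune Spread multiplier for `MinProb` (default 1).
#' @param k Neighbour count for `knn`/`SeqKNN` (default 10).
#' @return The imputed [expr_matrix()]; see [preprocess_records()] for the
#'   replay record.
#' @export
impute_matrix <- function(x, method = "none", seed = 1L, q = 0.01,
                          tune = 1, k = 10L) {
  opts <- .registry$imputation
  if (!method %in% c(opts$builtin, opts$plugin)) {
    abort(paste0("unknown imputation method '", method, "'"))
  }
  if (!method %in% opts$builtin) {
    fn <- plugin_fn("imputation", method)
    if (is.null(fn)) {
      abort(paste0("imputation '", method,
                   "' is a plugin slot with no registered implementation"))
    }
    out <- fn(x)
    return(add_record(out, list(method = method, plugin = TRUE, seed = seed)))
  }
  if (!method %in% c("none", "zero") && em_scale(x) != "log2") {
    abort(paste0("'", method, "' requires a log2-scale matrix"))
  }
  v <- em_values(x)
  rec <- list(method = method, seed = seed,
              parameters = list(q = q, tune = tune, k = k),
              fallback_proteins = character())
  if (method == "none") {
    return(add_record(x, rec))
  }
  miss <- is.na(v)
  out_v <- switch(method,
    zero = {
      v[miss] <- 0
      v
    },
    min = {
      v[miss] <- min(v, na.rm = TRUE)
      v
    },
    MinDet = impute_mindet(v, q),
    MinProb = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      impute_minprob(v, q, tune)
    },
    knn = ,
    SeqKNN = ,
    Impseq = {
      res <- impute_sequential(v, method, q, k)
      rec$fallback_proteins <- res$fallback
      res$values
    }
  )
  stopifnot(identical(v[!miss], out_v[!miss]))
  add_record(em_replace(x, out_v), rec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

impute_mindet <- function(v, q) {
  for (j in seq_len(ncol(v))) {
    idx <- is.na(v[, j])
    if (!any(idx)) next
    obs <- v[!idx, j]
    fill <- if (length(obs) > 0L) {
      quantile(obs, probs = q, type = 7, names = FALSE)
    } else {
      quantile(v[!is.na(v)], probs = q, type = 7, names = FALSE)
    }
    v[idx, j] <- fill
  }
  v
}

impute_minprob <- function(v, q, tune) {
  prot_sd <- apply(v, 1, function(r) {
    if (sum(!is.na(r)) >= 2L) sd(r, na.rm = TRUE) else NA_real_
  })
  spread <- max(tune * median(prot_sd, na.rm = TRUE), 1e-6)
  if (is.na(spread)) spread <- 1e-6
  for (j in seq_len(ncol(v))) {
    idx <- which(is.na(v[, j]))
    if (length(idx) == 0L) next
    obs <- v[!is.na(v[, j]), j]
    center <- if (length(obs) > 0L) {
      quantile(obs, probs = q, type = 7, names = FALSE)
    } else {
      quantile(v[!is.na(v)], probs = q, type = 7, names = FALSE)
    }
    v[idx, j] <- rnorm(length(idx), mean = center, sd = spread)
  }
  v
}

# rms distance over jointly observed samples; Inf when nothing is shared
protein_distance <- function(a, b) {
  shared <- which(!is.na(a) & !is.na(b))
  if (length(shared) == 0L) return(Inf)
  sqrt(sum((a[shared] - b[shared])^2) / length(shared))
}

impute_sequential <- function(v, method, q, k) {
  n <- nrow(v)
  miss_rate <- rowMeans(is.na(v))
  fallback <- character()
  fill_mindet <- function(i) {
    for (j in which(is.na(v[i, ]))) {
      obs <- v[!is.na(v[, j]), j]
      v[i, j] <<- if (length(obs) > 0L) {
        quantile(obs, probs = q, type = 7, names = FALSE)
      } else {
        quantile(v[!is.na(v)], probs = q, type = 7, names = FALSE)
      }
    }
    fallback <<- c(fallback, rownames(v)[i])
  }

  if (method == "knn") {
    orig <- v # neighbours are drawn from the original observed data
    for (i in which(miss_rate > 0)) {
      if (all(is.na(orig[i, ]))) {
        fill_mindet(i)
        next
      }
      d <- vapply(seq_len(n), function(p) {
        if (p == i) Inf else protein_distance(orig[i, ], orig[p, ])
      }, numeric(1))
      for (j in which(is.na(orig[i, ]))) {
        cand <- which(is.finite(d) & !is.na(orig[, j]))
        if (length(cand) == 0L) {
          obs <- orig[!is.na(orig[, j]), j]
          v[i, j] <- if (length(obs) > 0L) {
            quantile(obs, probs = q, type = 7, names = FALSE)
          } else {
            quantile(orig[!is.na(orig)], probs = q, type = 7, names = FALSE)
          }
          fallback <- c(fallback, rownames(v)[i])
          next
        }
        nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
        v[i, j] <- mean(orig[nb, j])
      }
    }
    return(list(values = v, fallback = unique(fallback)))
  }

  # SeqKNN / Impseq: ascending missing rate, sequential pool growth
  pool <- which(miss_rate == 0)
  todo <- order(miss_rate, seq_len(n))
  todo <- todo[miss_rate[todo] > 0]
  for (i in todo) {
    obs_cols <- which(!is.na(v[i, ]))
    mis_cols <- which(is.na(v[i, ]))
    if (length(obs_cols) == 0L || length(pool) == 0L) {
      fill_mindet(i)
      pool <- c(pool, i)
      next
    }
    if (method == "SeqKNN") {
      d <- vapply(pool, function(p) protein_distance(v[i, ], v[p, ]),
                  numeric(1))
      nb <- pool[order(d, pool)][seq_len(min(k, length(pool)))]
      for (j in mis_cols) v[i, j] <- mean(v[nb, j])
    } else { # Impseq
      for (j in mis_cols) {
        X <- v[pool, obs_cols, drop = FALSE]
        y <- v[pool, j]
        if (length(pool) <= length(obs_cols) + 1L) {
          # not enough complete proteins for a full fit; shrink predictors
          keep <- seq_len(max(1L, length(pool) - 2L))
          X <- X[, keep, drop = FALSE]
        }
        fit <- stats::lm.fit(cbind(1, X), y)
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        v[i, j] <- sum(beta * c(1, v[i, obs_cols[seq_len(ncol(X))]]))
      }
    }
    pool <- c(pool, i)
  }
  list(values = v, fallback = unique(fallback))
}
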