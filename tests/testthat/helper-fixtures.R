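# small in-code fixtures shared across tests

make_em <- function(values, scale = "log2", matrix_type = "LFQ",
                    setting = "generic") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  tab <- dplyr::bind_cols(
    tibble::tibble(protein = sprintf("P%03d", seq_len(nrow(values)))),
    tibble::as_tibble(as.data.frame(values))
  )
  expr_matrix(tab, scale = scale, matrix_type = matrix_type,
              setting = setting)
}

two_group_design <- function(n_per_group = 3L) {
  tibble::tibble(
    sample = c(paste0("A", seq_len(n_per_group)),
               paste0("B", seq_len(n_per_group))),
    group = rep(c("A", "B"), each = n_per_group)
  )
}

# random matrix with controlled missingness (log2 scale)
random_em <- function(n_prot, n_samp, miss = 0.1, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_prot * n_samp, 20, 2), n_prot, n_samp)
  if (miss > 0) {
    v[sample.int(length(v), round(miss * length(v)))] <- NA
  }
  colnames(v) <- c(paste0("A", seq_len(ceiling(n_samp / 2))),
                   paste0("B", seq_len(floor(n_samp / 2))))
  make_em(v)
}

# independent step-up BH oracle (naive double loop)
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# brute-force threshold-sweep pAUC oracle: explicit ROC vertex list with
# exact segment clipping at the cap
pauc_oracle <- function(conf, labels, cap) {
  thr <- sort(unique(conf), decreasing = TRUE)
  pts <- rbind(c(0, 0), t(vapply(thr, function(th) {
    c(sum(conf >= th & !labels) / sum(!labels),
      sum(conf >= th & labels) / sum(labels))
  }, numeric(2))))
  area <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    x1 <- pts[i, 1]; y1 <- pts[i, 2]
    x2 <- pts[i + 1, 1]; y2 <- pts[i + 1, 2]
    if (x1 >= cap) break
    if (x2 > cap) {
      y2 <- y1 + (y2 - y1) * (cap - x1) / (x2 - x1)
      x2 <- cap
    }
    area <- area + (x2 - x1) * (y1 + y2) / 2
  }
  area
}

# power-set frequent-itemset oracle
fp_oracle <- function(transactions, min_sr) {
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  combos <- unlist(
    lapply(seq_along(items), function(k) {
      m <- utils::combn(items, k, simplify = FALSE)
      m
    }),
    recursive = FALSE
  )
  res <- lapply(combos, function(set) {
    sup <- sum(vapply(transactions, function(tr) all(set %in% tr), logical(1)))
    list(items = set, sr = sup / n, support = sup)
  })
  res <- res[vapply(res, function(r) r$sr >= min_sr - 1e-9, logical(1))]
  tibble::tibble(
    pattern = vapply(res, function(r) paste(r$items, collapse = ","),
                     character(1)),
    support = vapply(res, function(r) r$support, numeric(1)),
    sr = vapply(res, function(r) r$sr, numeric(1))
  ) |> dplyr::arrange(dplyr::desc(sr), pattern)
}
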