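test_that("centering and scaling normalizations meet their per-sample contracts", {
  m <- make_em(cbind(s1 = c(1, 2, 3), s2 = c(4, 6, 11)))
  cm <- normalize_matrix(m, "center.median")
  expect_equal(unname(em_values(cm)[, 1]), c(-1, 0, 1))
  expect_equal(apply(em_values(cm), 2, median), c(s1 = 0, s2 = 0))
  ce <- normalize_matrix(m, "center.mean")
  expect_equal(unname(colMeans(em_values(ce))), c(0, 0))

  raw <- make_em(cbind(s1 = c(2, 3, 5), s2 = c(4, 6, 10)), scale = "raw")
  dm <- normalize_matrix(raw, "div.median")
  expect_equal(unname(apply(em_values(dm), 2, median)), c(1, 1))
  tt <- normalize_matrix(raw, "total")
  sums <- apply(em_values(tt), 2, sum)
  expect_equal(unname(diff(range(sums))), 0, tolerance = 1e-9)
  mx <- normalize_matrix(raw, "max")
  expect_equal(unname(apply(em_values(mx), 2, max)), c(1, 1))

  expect_error(normalize_matrix(raw, "center.median"), "log2")
  expect_error(normalize_matrix(m, "total"), "raw")
  expect_error(normalize_matrix(m, "bogus"), "unknown")
})

test_that("quantile normalization matches a brute-force oracle and equalizes columns", {
  # 5x2 oracle: reference = row means of sorted columns
  v <- cbind(s1 = c(5, 2, 9, 1, 7), s2 = c(10, 3, 20, 2, 15))
  ref <- rowMeans(cbind(sort(v[, 1]), sort(v[, 2])))
  expected <- apply(v, 2, function(col) ref[rank(col)])
  q <- normalize_matrix(make_em(v), "quantiles")
  expect_equal(unname(em_values(q)), unname(expected), tolerance = 1e-12)
  # identical rank order -> identical columns
  expect_equal(unname(em_values(q)[, 1]), unname(em_values(q)[, 2]))
  # full multiset equality across columns without missingness
  set.seed(9)
  v2 <- matrix(rnorm(40, 20, 3), 10, 4)
  q2 <- em_values(normalize_matrix(make_em(v2), "quantiles"))
  for (j in 2:4) expect_equal(unname(sort(q2[, 1])), unname(sort(q2[, j])))
  # robust variant uses the median reference
  ref_med <- apply(cbind(sort(v[, 1]), sort(v[, 2])), 1, median)
  qr <- normalize_matrix(make_em(v), "quantiles.robust")
  expect_equal(unname(em_values(qr)[, 1]), unname(ref_med[rank(v[, 1])]))
})

test_that("MBQN restores per-sample means after quantile normalization", {
  m <- random_em(40, 5, miss = 0.1, seed = 2)
  out <- normalize_matrix(m, "MBQN")
  expect_equal(
    apply(em_values(out), 2, mean, na.rm = TRUE),
    apply(em_values(m), 2, mean, na.rm = TRUE),
    tolerance = 1e-9
  )
})

test_that("regression normalizations remove a linear sample bias", {
  set.seed(4)
  base <- rnorm(60, 20, 2)
  # sample 2 carries an affine distortion of the shared profile
  v <- cbind(s1 = base + rnorm(60, 0, 0.05),
             s2 = 1.3 * base - 4 + rnorm(60, 0, 0.05),
             s3 = base + rnorm(60, 0, 0.05))
  for (meth in c("Rlr", "lossf")) {
    out <- em_values(normalize_matrix(make_em(v), meth))
    before <- median(abs(v[, 2] - rowMeans(v[, c(1, 3)])))
    after <- median(abs(out[, 2] - rowMeans(out[, c(1, 3)])))
    expect_lt(after, before / 4)
  }
})

test_that("normalization preserves the missingness pattern", {
  m <- random_em(50, 6, miss = 0.2, seed = 7)
  raw <- make_em(2^em_values(m), scale = "raw")
  for (meth in c("center.mean", "center.median", "quantiles",
                 "quantiles.robust", "MBQN", "Rlr", "lossf")) {
    expect_identical(is.na(em_values(normalize_matrix(m, meth))),
                     is.na(em_values(m)), label = meth)
  }
  for (meth in c("div.mean", "div.median", "total", "max")) {
    expect_identical(is.na(em_values(normalize_matrix(raw, meth))),
                     is.na(em_values(raw)), label = meth)
  }
})

test_that("simple imputation methods meet their contracts", {
  v <- cbind(s1 = c(10, 12, NA), s2 = c(20, NA, 24))
  m <- make_em(v)
  expect_equal(em_values(impute_matrix(m, "zero"))[3, 1], 0)
  expect_equal(em_values(impute_matrix(m, "min"))[3, 1], 10)
  # MinDet with q = 0 is the per-sample observed minimum
  md <- em_values(impute_matrix(m, "MinDet", q = 0))
  expect_equal(md[3, 1], 10)
  expect_equal(md[2, 2], 20)
  expect_error(impute_matrix(m, "bogus"), "unknown")
  expect_error(
    impute_matrix(make_em(v, scale = "raw"), "MinDet"), "log2"
  )
})

test_that("imputation never alters observed values and clears all missingness", {
  m <- random_em(60, 8, miss = 0.15, seed = 3)
  obs <- !is.na(em_values(m))
  for (meth in c("zero", "min", "MinDet", "MinProb", "knn", "SeqKNN",
                 "Impseq")) {
    out <- em_values(impute_matrix(m, meth, seed = 11))
    expect_identical(out[obs], em_values(m)[obs], label = meth)
    expect_false(anyNA(out), label = meth)
  }
  none <- impute_matrix(m, "none")
  expect_identical(em_values(none), em_values(m))
})

test_that("MinProb is seeded, reproducible, and draws below the sample median", {
  m <- random_em(400, 6, miss = 0.3, seed = 5)
  a <- em_values(impute_matrix(m, "MinProb", seed = 42))
  b <- em_values(impute_matrix(m, "MinProb", seed = 42))
  expect_identical(a, b)
  c2 <- em_values(impute_matrix(m, "MinProb", seed = 43))
  expect_false(identical(a, c2))
  # left-censored draws sit below each sample's observed median
  miss <- is.na(em_values(m))
  meds <- apply(em_values(m), 2, median, na.rm = TRUE)
  below <- mean(a[miss] < meds[col(a)][miss])
  expect_gt(below, 0.99)
})

test_that("knn imputation equals a brute-force all-pairs distance oracle", {
  knn_oracle <- function(v, k = 10) {
    out <- v
    n <- nrow(v)
    for (i in seq_len(n)) {
      for (j in which(is.na(v[i, ]))) {
        d <- rep(Inf, n)
        for (p in seq_len(n)) {
          if (p == i || is.na(v[p, j])) next
          shared <- which(!is.na(v[i, ]) & !is.na(v[p, ]))
          if (length(shared) == 0) next
          d[p] <- sqrt(sum((v[i, shared] - v[p, shared])^2) / length(shared))
        }
        cand <- which(is.finite(d))
        nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
        out[i, j] <- mean(v[nb, j])
      }
    }
    out
  }
  for (seed in 1:6) {
    m <- random_em(50, 8, miss = 0.12, seed = seed)
    got <- em_values(impute_matrix(m, "knn"))
    expect_equal(got, knn_oracle(em_values(m)), tolerance = 1e-12)
  }
  # exact duplicate protein: the duplicate supplies the value
  v <- matrix(rnorm(40, 20), 10, 4)
  v <- rbind(v, v[1, ])
  v[11, 2] <- NA
  got <- em_values(impute_matrix(make_em(v), "knn", k = 1))
  expect_equal(unname(got[11, 2]), unname(v[1, 2]))
})

test_that("sequential imputation handles the all-missing protein by MinDet fallback", {
  v <- matrix(rnorm(24, 20), 6, 4)
  v[3, ] <- NA
  m <- make_em(v)
  for (meth in c("knn", "SeqKNN", "Impseq")) {
    out <- impute_matrix(m, meth)
    expect_false(anyNA(em_values(out)))
    rec <- preprocess_records(out)[[1]]
    expect_true("P003" %in% rec$fallback_proteins, label = meth)
  }
})
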