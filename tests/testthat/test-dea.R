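test_that("Welch t-test matches the hand-computed toy example", {
  m <- make_em(rbind(c(1, 2, 3, 4, 5, 6)),
               matrix_type = "LFQ")
  names(m)[-1] <- c("A1", "A2", "A3", "B1", "B2", "B3")
  res <- dea_ttest(m, two_group_design(3), c("A", "B"))
  expect_equal(res$log2fc, -3)
  # equal variances, n = 3 + 3: Welch df = 4, |t| = 3 / sqrt(2/3)
  tval <- 3 / sqrt(2 / 3)
  expect_equal(res$pvalue, 2 * pt(-tval, df = 4), tolerance = 1e-10)
})

test_that("identical groups give zero fold change and p = 1", {
  m <- make_em(rbind(c(5, 5, 5, 5, 5, 5), c(1, 2, 3, 1, 2, 3)))
  names(m)[-1] <- c("A1", "A2", "A3", "B1", "B2", "B3")
  res <- dea_ttest(m, two_group_design(3), c("A", "B"))
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$pvalue[1], 1)
})

test_that("degenerate proteins are flagged with p = 1", {
  m <- make_em(rbind(c(1, 2, 3, NA, NA, NA), c(1, NA, NA, 4, 5, 6)))
  names(m)[-1] <- c("A1", "A2", "A3", "B1", "B2", "B3")
  res <- dea_ttest(m, two_group_design(3), c("A", "B"))
  expect_true(all(res$flag))
  expect_equal(res$pvalue, c(1, 1))
  expect_equal(res$log2fc[2], 1 - 5) # means of available observations
})

test_that("one-way F at two groups equals the pooled t-test", {
  set.seed(31)
  m <- random_em(100, 8, miss = 0, seed = 31)
  design <- two_group_design(4)
  fa <- dea_anova(m, design, c("A", "B"))
  v <- em_values(m)
  p_pooled <- apply(v, 1, function(row) {
    t.test(row[1:4], row[5:8], var.equal = TRUE)$p.value
  })
  expect_equal(fa$pvalue, unname(p_pooled), tolerance = 1e-12)
})

test_that("three-group F matches a brute-force sum-of-squares oracle", {
  set.seed(8)
  v <- matrix(rnorm(9 * 20, 20), 20, 9)
  colnames(v) <- paste0(rep(c("A", "B", "C"), each = 3), 1:3)
  m <- make_em(v)
  design <- tibble::tibble(sample = colnames(v),
                           group = rep(c("A", "B", "C"), each = 3))
  res <- dea_anova(m, design, c("A", "B"))
  g <- rep(1:3, each = 3)
  p_oracle <- apply(v, 1, function(row) {
    means <- tapply(row, g, mean)
    ssb <- sum(3 * (means - mean(row))^2)
    ssw <- sum((row - means[g])^2)
    f <- (ssb / 2) / (ssw / 6)
    pf(f, 2, 6, lower.tail = FALSE)
  })
  expect_equal(res$pvalue, unname(p_oracle), tolerance = 1e-10)
})

test_that("moderated t limit cases recover the pooled t and the prior-only t", {
  m <- random_em(80, 10, miss = 0, seed = 12)
  design <- two_group_design(5)
  # d0 = 0: ordinary pooled t
  plain <- dea_moderated_t(m, design, c("A", "B"),
                           prior = list(d0 = 0, s02 = 1))
  v <- em_values(m)
  p_pooled <- apply(v, 1, function(row) {
    t.test(row[1:5], row[6:10], var.equal = TRUE)$p.value
  })
  expect_equal(plain$pvalue, unname(p_pooled), tolerance = 1e-12)
  # d0 = Inf: every protein tested against s0
  s02 <- 0.09
  inf <- dea_moderated_t(m, design, c("A", "B"),
                         prior = list(d0 = Inf, s02 = s02))
  tstat <- inf$log2fc / sqrt(s02 * (1 / 5 + 1 / 5))
  expect_equal(inf$pvalue, 2 * pt(-abs(tstat), df = Inf), tolerance = 1e-12)
})

test_that("moderated t agrees with an independent step-by-step oracle", {
  # heteroscedastic proteins so the prior df is identifiable
  set.seed(99)
  sds <- exp(rnorm(200, -1, 0.6))
  v <- t(vapply(sds, function(s) rnorm(10, 20, s), numeric(10)))
  m <- make_em(v)
  names(m)[-1] <- c(paste0("A", 1:5), paste0("B", 1:5))
  design <- two_group_design(5)
  res <- dea_moderated_t(m, design, c("A", "B"))
  expect_true(is.finite(attr(res, "prior")$d0))
  # independent recomputation of the full empirical-Bayes pipeline
  v <- em_values(m)
  lfc <- rowMeans(v[, 1:5]) - rowMeans(v[, 6:10])
  s2 <- apply(v, 1, function(row) {
    (sum((row[1:5] - mean(row[1:5]))^2) +
      sum((row[6:10] - mean(row[6:10]))^2)) / 8
  })
  d <- 8
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2 * n / (n - 1) - trigamma(d / 2))
  # invert trigamma by bisection (independent of the package's Newton)
  target <- evar
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > target) lo <- mid else hi <- mid
  }
  d0 <- 2 * lo
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  s2post <- (d0 * s02 + d * s2) / (d0 + d)
  tmod <- lfc / sqrt(s2post * (2 / 5))
  p_oracle <- 2 * pt(-abs(tmod), df = d + d0)
  expect_equal(res$pvalue, unname(p_oracle), tolerance = 1e-8)
  expect_equal(res$log2fc, unname(lfc), tolerance = 1e-12)
})

test_that("moderated t agrees with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  sds <- exp(rnorm(300, -1, 0.5))
  v <- t(vapply(sds, function(s) rnorm(8, 20, s), numeric(8)))
  m <- make_em(v)
  names(m)[-1] <- c(paste0("A", 1:4), paste0("B", 1:4))
  design <- two_group_design(4)
  res <- dea_moderated_t(m, design, c("A", "B"))
  mm <- cbind(intercept = 1, grpA = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(em_values(m), mm))
  expect_equal(res$pvalue, unname(fit$p.value[, "grpA"]), tolerance = 1e-6)
  expect_equal(res$log2fc, unname(fit$coefficients[, "grpA"]),
               tolerance = 1e-10)
})

test_that("BH adjustment equals the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(3:1000, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # missing p-values are treated as 1
  expect_equal(bh_adjust(c(0.5, NA))[2], 1)
  # monotone after sorting by p, bounded by 1
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("DEA p-values are uniform under the null", {
  set.seed(2024)
  m <- random_em(2000, 10, miss = 0, seed = 2024)
  design <- two_group_design(5)
  for (fn in list(dea_ttest, dea_moderated_t)) {
    res <- fn(m, design, c("A", "B"))
    ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("call_de applies the fold-change and q-value gates with the stated inequalities", {
  res <- tibble::tibble(
    protein = c("a", "b", "c", "d"),
    log2fc = c(0.60, 1.2, 0.5, log2(1.5)),
    qvalue = c(0.01, 0.05, 0.001, 0.049)
  )
  de <- call_de(res)$de
  expect_equal(de, c(TRUE, FALSE, FALSE, TRUE))
  # call count monotone in the thresholds
  set.seed(3)
  res2 <- tibble::tibble(protein = paste0("p", 1:200),
                         log2fc = rnorm(200), qvalue = runif(200))
  n1 <- sum(call_de(res2, logfc_thresh = 0.3)$de)
  n2 <- sum(call_de(res2, logfc_thresh = 0.8)$de)
  expect_gte(n1, n2)
  n3 <- sum(call_de(res2, q_thresh = 0.2)$de)
  n4 <- sum(call_de(res2, q_thresh = 0.05)$de)
  expect_gte(n3, n4)
})

test_that("run_workflow with identity preprocessing equals the bare statistic", {
  ds <- simulate_spikein(sim_config(n_proteins = 150, views = "dlfq",
                                    target_missing = 0),
                         seed = 21)
  spec <- workflow("generic", "dlfq", "none", "none", "ttest")
  via_wf <- run_workflow(ds$views, spec, ds$design, seed = 1)
  direct <- dea_ttest(log_transform(ds$views$dlfq), ds$design, c("A", "B"))
  expect_equal(via_wf$pvalue, direct$pvalue)
  expect_equal(via_wf$log2fc, direct$log2fc)
})

test_that("run_workflow is deterministic under a fixed seed and validates its spec", {
  ds <- simulate_spikein(sim_config(n_proteins = 120, views = "dlfq"),
                         seed = 22)
  spec <- workflow("generic", "dlfq", "center.median", "MinProb",
                   "moderated_t")
  a <- run_workflow(ds$views, spec, ds$design, seed = 9)
  b <- run_workflow(ds$views, spec, ds$design, seed = 9)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  bad <- workflow("generic", "counts", "none", "none", "ttest")
  expect_error(run_workflow(ds$views, bad, ds$design), "invalid workflow")
})
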