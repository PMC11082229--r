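make_metrics <- function(values, ids = NULL) {
  n <- nrow(values)
  tibble::tibble(
    workflow = ids %||% sprintf("wf%02d", seq_len(n)),
    pauc001 = values[, 1], pauc005 = values[, 2], pauc01 = values[, 3],
    nmcc = values[, 4], gmean = values[, 5]
  )
}

test_that("rank aggregation averages the five per-metric ranks", {
  # three workflows with a strict performance order
  v <- rbind(
    c(0.009, 0.045, 0.09, 0.9, 0.9),
    c(0.005, 0.030, 0.06, 0.8, 0.8),
    c(0.001, 0.010, 0.02, 0.6, 0.6)
  )
  r <- aggregate_ranks(make_metrics(v))
  expect_equal(r$position, 1:3)
  expect_equal(r$rank_final, c(1, 2, 3))
  expect_equal(r$ranking_score, c(2, 1, 0))
  # mixed ranks average: metric ranks (1,2,3,4,5) -> final 3
  expect_equal(mean(1:5), 3)
  # best on all five metrics -> position 1
  expect_equal(r$workflow[r$position == 1], "wf01")
})

test_that("ties share rank_final and are broken lexicographically", {
  v <- rbind(c(0.5, 0.5, 0.5, 0.5, 0.5), c(0.5, 0.5, 0.5, 0.5, 0.5))
  r <- aggregate_ranks(make_metrics(v, ids = c("zeta", "alpha")))
  expect_equal(r$rank_final, c(1.5, 1.5))
  expect_equal(r$workflow, c("alpha", "zeta"))
  # untied rank_final means average over workflows = (N + 1) / 2
  set.seed(6)
  v2 <- matrix(runif(50), 10, 5)
  r2 <- aggregate_ranks(make_metrics(v2))
  expect_equal(mean(r2$rank_final), (10 + 1) / 2)
})

test_that("performance levels follow the ceiling rule and partition the list", {
  expect_equal(as.integer(table(label_levels(100))), c(5L, 20L, 25L, 50L))
  expect_equal(sum(label_levels(7852) == "H"), 393)
  expect_equal(sum(label_levels(4720) == "H"), 236)
  expect_equal(sum(label_levels(6284) == "H"), 315)
  expect_equal(sum(label_levels(1584) == "H"), 80)
  for (n in c(1:50, sample(51:10000, 80))) {
    lv <- label_levels(n)
    counts <- table(lv)
    expect_equal(as.numeric(counts["H"]), ceiling(0.05 * n), label = n)
    expect_equal(as.numeric(counts["H"] + counts["RH"]), ceiling(0.25 * n))
    expect_equal(as.numeric(counts["H"] + counts["RH"] + counts["RL"]),
                 ceiling(0.5 * n))
    expect_equal(sum(counts), as.integer(n))
  }
})

test_that("Spearman correlation matches the rank formula and rejects degenerate input", {
  expect_equal(spearman_cor(1:5, 1:5), 1)
  expect_equal(spearman_cor(1:5, 5:1), -1)
  expect_equal(spearman_cor(1:4, c(2, 1, 4, 3)), 1 - 6 * 4 / (4 * 15))
  expect_error(spearman_cor(1:2, 1:2), "length")
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("LODOCV returns one correlation per held-out dataset and detects shared structure", {
  # identical datasets: perfect transfer
  base <- make_metrics(matrix(runif(40), 8, 5))
  metrics <- dplyr::bind_rows(
    dplyr::mutate(base, dataset = "d1"),
    dplyr::mutate(base, dataset = "d2"),
    dplyr::mutate(base, dataset = "d3")
  )
  cv <- lodocv(metrics)
  expect_equal(nrow(cv), 3)
  expect_equal(cv$spearman, rep(1, 3))
  # shared workflow-quality structure plus noise: positive mean R
  set.seed(10)
  quality <- seq(0.9, 0.1, length.out = 10)
  noisy <- purrr::map_dfr(1:20, function(d) {
    v <- vapply(1:5, function(j) quality + rnorm(10, 0, 0.08), numeric(10))
    dplyr::mutate(make_metrics(v), dataset = paste0("d", d))
  })
  cvn <- lodocv(noisy)
  expect_equal(nrow(cvn), 20)
  expect_gt(mean(cvn$spearman), 0)
  expect_error(lodocv(metrics[metrics$dataset != "d3", ]), "at least 3")
})

test_that("Kruskal-Wallis on ranks enforces the group-size guard and detects shifts", {
  set.seed(15)
  # identical distributions: p roughly uniform over replicates
  ps <- replicate(60, {
    kruskal_wallis_ranks(rnorm(15), rep(c("a", "b", "c"), each = 5))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  # strong shift is detected
  shifted <- kruskal_wallis_ranks(
    c(rnorm(6), rnorm(6) + 50, rnorm(6)), rep(c("a", "b", "c"), each = 6)
  )
  expect_lt(shifted$p_value, 0.05)
  expect_error(
    kruskal_wallis_ranks(rnorm(9), rep(c("a", "b", "c"), c(4, 4, 1))),
    "min_n"
  )
})

test_that("matched-pair option comparison reproduces a brute-force toy oracle", {
  # 3 imputation options crossed with 2 normalizations; option quality
  # strictly ordered a > b > c on every metric
  grid <- tidyr::expand_grid(
    setting = "generic", matrix_type = "LFQ",
    normalization = c("none", "center.median"),
    imputation = c("a", "b", "c"), dea = "ttest"
  )
  bonus <- c(a = 0.3, b = 0.2, c = 0.1)[grid$imputation] +
    ifelse(grid$normalization == "none", 0.01, 0)
  metrics <- dplyr::mutate(
    grid,
    pauc001 = bonus, pauc005 = bonus, pauc01 = bonus,
    nmcc = bonus, gmean = bonus
  )
  out <- pairwise_option_compare(metrics, "imputation")
  expect_equal(out$option_ranks$option, c("a", "b", "c"))
  expect_equal(out$option_ranks$rank_final, c(1, 2, 3))
  ab <- dplyr::filter(out$comparisons, option_a == "a", option_b == "b",
                      metric == "pauc001")
  expect_equal(ab$n_pairs, 2L)
  expect_equal(ab$mean_diff, 0.1, tolerance = 1e-12)
  # dominant option on every matched pair ranks first on every metric
  expect_true(all(out$option_ranks[1, paste0("rank_", c(
    "pauc001", "pauc005", "pauc01", "nmcc", "gmean"
  ))] == 1))
})

test_that("cross-setting comparison pads absent proteins and drops multi-protein groups", {
  truth <- tibble::tibble(
    protein = c("p1", "p2", "p3", "p4"),
    is_de = c(TRUE, FALSE, TRUE, FALSE),
    true_log2fc = c(1, 0, 1, 0)
  )
  s1 <- tibble::tibble(
    protein = c("p1", "p2", "p3", "p4", "p5;p6"),
    log2fc = c(1, 0, 1, 0, 3),
    qvalue = c(0.01, 0.9, 0.01, 0.9, 0.001)
  )
  s2 <- tibble::tibble( # p3 (truly DE) and p4 (truly not) absent
    protein = c("p1", "p2"),
    log2fc = c(1, 0), qvalue = c(0.01, 0.9)
  )
  out <- cross_setting_compare(list(S1 = s1, S2 = s2), truth)
  expect_equal(out$setting, c("S1", "S2"))
  # multi-protein group p5;p6 removed everywhere
  expect_equal(out$tp + out$fp + out$tn + out$fn, c(4L, 4L))
  expect_equal(out$tp, c(2L, 1L))
  expect_equal(out$fn[out$setting == "S2"], 1L) # padded DE protein -> FN
  expect_equal(out$tn[out$setting == "S2"], 2L) # padded non-DE -> TN
  expect_error(cross_setting_compare(list(S1 = s1), truth), "two settings")
})
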