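#' Configuration for the spike-in simulator
#'
#' Describes a simulated gold-standard spike-in experiment: a constant
#' background proteome plus a fraction of differential ("spiked") proteins
#' at a known log2 fold change, measured in two groups of technical
#' replicates through several correlated quantification views, with
#' intensity-dependent (missing-not-at-random) dropout.
#'
#' Defaults emulate a label-free DDA spike-in at desk scale: latent log2
#' abundances `Normal(20, 2.5)`, 10% DE proteins at `|log2FC| = 1` with
#' random sign, replicate noise sd 0.3 (log2 units), 5 replicates per
#' group, five views (spectral counts plus top0/top3/LFQ/dlfq-like
#' intensity views with view-specific noise sd `0.3 * replicate_sd`), and
#' a 17% target missing rate per view (platform-typical for DDA; use 0.03
#' for DIA-like or 0.002 for TMT-like data).
#'
#' @param n_proteins Number of proteins.
#' @param de_fraction Fraction of truly DE proteins, in `[0, 1)`.
#' @param lfc_value Magnitude of the true log2 fold change (point mass).
#' @param lfc_sd Optional sd of a Normal jitter on the magnitude (0 =
#'   point mass).
#' @param base_mean,base_sd Latent log2-abundance distribution.
#' @param replicate_sd Technical-replicate noise sd (log2 units).
#' @param n_replicates Replicates per group (two groups, A and B).
#' @param views Character vector of matrix types to emit; `counts` gets a
#'   Poisson count link, all others are intensity views.
#' @param view_sd View-specific noise sd (log2 units).
#' @param target_missing Target missing rate per view, in `[0, 0.95]`.
#' @param mnar_steepness Steepness `s` of the logistic dropout
#'   `P(missing | x) = plogis((tau - x) / s)` on the log2 scale.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 1500L, de_fraction = 0.1,
                       lfc_value = 1, lfc_sd = 0,
                       base_mean = 20, base_sd = 2.5,
                       replicate_sd = 0.3, n_replicates = 5L,
                       views = c("counts", "top0", "top3", "LFQ", "dlfq"),
                       view_sd = 0.3 * replicate_sd,
                       target_missing = 0.17, mnar_steepness = 0.5) {
  stopifnot(
    de_fraction >= 0, de_fraction < 1,
    base_sd > 0, replicate_sd > 0, view_sd >= 0,
    target_missing >= 0, target_missing < 1,
    mnar_steepness > 0, n_replicates >= 2L
  )
  structure(
    list(
      n_proteins = as.integer(n_proteins), de_fraction = de_fraction,
      lfc_value = lfc_value, lfc_sd = lfc_sd,
      base_mean = base_mean, base_sd = base_sd,
      replicate_sd = replicate_sd, n_replicates = as.integer(n_replicates),
      views = views, view_sd = view_sd,
      target_missing = target_missing, mnar_steepness = mnar_steepness
    ),
    class = "sim_config"
  )
}

#' Calibrate the dropout threshold for a target missing rate
#'
#' Bisection on the logistic location `tau` until the expected missing
#' rate `mean(plogis((tau - x) / s))` over the supplied values is within
#' `1e-4` of the target. A target of 0 returns `-Inf` (no dropout).
#'
#' @param x Numeric vector of latent (log2) values.
#' @param target Target missing rate in `[0, 0.95]`.
#' @param steepness Logistic steepness `s`.
#' @return The calibrated `tau`.
#' @export
calibrate_dropout <- function(x, target, steepness = 0.5) {
  if (target < 0 || target > 0.95) abort("target missing rate must lie in [0, 0.95]")
  if (target == 0) return(-Inf)
  x <- x[!is.na(x)]
  rate <- function(tau) mean(plogis((tau - x) / steepness))
  lo <- min(x) - 50 * steepness
  hi <- max(x) + 50 * steepness
  if (rate(lo) > target || rate(hi) < target) {
    abort("target missing rate unreachable for these values")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- rate(mid)
    if (abs(r - target) < 1e-4) return(mid)
    if (r < target) lo <- mid else hi <- mid
  }
  abort("dropout calibration did not converge in 200 iterations")
}

#' Simulate a multi-view spike-in dataset
#'
#' Draws latent per-protein log2 abundances, shifts the DE proteins in
#' group A by their true log2FC (so `log2fc = mean A - mean B` recovers
#' the truth), adds per-replicate noise shared by all views, then emits
#' each view as latent plus view-specific noise (the `counts` view as a
#' Poisson draw from the scaled linear intensity). Each view is thinned by
#' logistic MNAR dropout calibrated to the target missing rate. Fully
#' reproducible from the seed; view-specific randomness is derived from
#' the master seed and the view name, so adding a view never perturbs the
#' others.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return A list with elements `views` (named list of raw-scale
#'   [expr_matrix()] objects), `truth` (tibble `protein`, `is_de`,
#'   `true_log2fc`), `design` (tibble `sample`, `group`) and `config`.
#' @export
simulate_spikein <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  n <- config$n_proteins
  set.seed(derive_seed(seed, "latent"))
  base <- rnorm(n, config$base_mean, config$base_sd)
  n_de <- round(config$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0L) is_de[sample.int(n, n_de)] <- TRUE
  mag <- abs(config$lfc_value + rnorm(n, 0, config$lfc_sd))
  true_lfc <- ifelse(is_de, mag * sample(c(-1, 1), n, replace = TRUE), 0)

  reps <- config$n_replicates
  samples <- c(paste0("A", seq_len(reps)), paste0("B", seq_len(reps)))
  groups <- rep(c("A", "B"), each = reps)
  protein <- sprintf("P%05d", seq_len(n))

  # latent replicate matrix shared across views: group A carries the shift
  mu <- outer(base, rep(1, 2 * reps)) +
    outer(true_lfc, as.numeric(groups == "A"))
  set.seed(derive_seed(seed, "replicates"))
  latent <- mu + matrix(rnorm(n * 2 * reps, 0, config$replicate_sd),
                        n, 2 * reps)

  views <- list()
  for (vname in config$views) {
    set.seed(derive_seed(seed, paste0("view:", vname)))
    noisy <- latent + matrix(rnorm(n * 2 * reps, 0, config$view_sd),
                             n, 2 * reps)
    tau <- calibrate_dropout(as.vector(noisy), config$target_missing,
                             config$mnar_steepness)
    drop <- matrix(
      runif(n * 2 * reps) <
        plogis((tau - noisy) / config$mnar_steepness),
      n, 2 * reps
    )
    if (identical(vname, "counts")) {
      # Poisson count link on the linear scale, rescaled to modest depth
      lambda <- 2^(noisy - config$base_mean + 5)
      vals <- matrix(rpois(n * 2 * reps, as.vector(lambda)), n, 2 * reps)
      vals[drop] <- NA_real_
      storage.mode(vals) <- "double"
    } else {
      vals <- 2^noisy
      vals[drop] <- NA_real_
    }
    colnames(vals) <- samples
    tab <- dplyr::bind_cols(
      tibble::tibble(protein = protein),
      tibble::as_tibble(as.data.frame(vals))
    )
    views[[vname]] <- expr_matrix(tab, scale = "raw", matrix_type = vname,
                                  setting = "generic")
  }

  list(
    views = views,
    truth = tibble::tibble(protein = protein, is_de = is_de,
                           true_log2fc = true_lfc),
    design = tibble::tibble(sample = samples, group = groups),
    config = config
  )
}

#' Simulate a collection of related spike-in datasets
#'
#' Generates `n_datasets` datasets from a shared configuration family with
#' per-dataset multiplicative jitter on the replicate noise and fold-change
#' magnitude, emulating a panel of benchmark datasets of common design but
#' different origin (as leave-one-dataset-out validation requires).
#' Per-dataset seeds are derived from the master seed.
#'
#' @param n_datasets Number of datasets (`>= 3`).
#' @param config Template [sim_config()].
#' @param jitter Relative jitter half-width (default 0.2: parameters vary
#'   uniformly within +/-20%).
#' @param seed Integer master seed.
#' @return A named list of datasets as returned by [simulate_spikein()].
#' @export
simulate_collection <- function(n_datasets = 3L, config = sim_config(),
                                jitter = 0.2, seed = 1L) {
  if (n_datasets < 3L) abort("a collection needs at least 3 datasets")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "collection"))
  factors <- matrix(runif(2 * n_datasets, 1 - jitter, 1 + jitter),
                    n_datasets, 2)
  out <- purrr::map(seq_len(n_datasets), function(i) {
    cfg <- config
    cfg$replicate_sd <- config$replicate_sd * factors[i, 1L]
    cfg$lfc_value <- config$lfc_value * factors[i, 2L]
    simulate_spikein(cfg, seed = derive_seed(seed, paste0("dataset", i)))
  })
  names(out) <- sprintf("sim%02d", seq_len(n_datasets))
  out
}
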