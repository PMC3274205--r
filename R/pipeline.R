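#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: simulation settings,
#' preprocessing switches, signature ranks, engine hyperparameters, the
#' cross-validation scheme and an optional robustness grid.
#'
#' @param simulation A [sim_config()].
#' @param normalize Vector-normalize spectra before the discriminators
#'   (default `FALSE`; the engines operate on raw counts like the
#'   acquisition pipeline).
#' @param signature_ranks Named chemical-component counts per fluid
#'   (reference ranks: blood 2, saliva 3, semen 3).
#' @param signature_max_spectra Per-fluid cap on spectra entering the ALS
#'   decomposition (keeps the alternating solver fast; fits are still
#'   evaluated on all spectra).
#' @param simca_a,simca_alpha SIMCA components per class and confidence
#'   level.
#' @param lda_compression,lda_a LDA score compression method and
#'   dimensionality (`NULL` = 99%-variance rule capped at 20).
#' @param run_lda_loo Run the full leave-one-out LDA (the slowest stage).
#' @param plsda_a PLS-DA latent variables or `"auto"`.
#' @param cv A [cv_scheme()] used for PLS-DA evaluation.
#' @param robustness_grid Optional data frame with columns `noise_factor`,
#'   `background_factor`.
#' @param holdout_donors Donors per fluid held out of training for the
#'   robustness evaluation split (default 5).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = sim_config(),
                              normalize = FALSE,
                              signature_ranks = c(blood = 2, saliva = 3,
                                                  semen = 3),
                              signature_max_spectra = 60,
                              simca_a = 2, simca_alpha = 0.95,
                              lda_compression = "pca", lda_a = NULL,
                              run_lda_loo = TRUE,
                              plsda_a = "auto",
                              cv = cv_scheme("venetian_blind", 10),
                              robustness_grid = NULL,
                              holdout_donors = 5) {
  stopifnot(inherits(simulation, "sim_config"),
            all(names(signature_ranks) %in% c("blood", "saliva", "semen")))
  if (!is.null(robustness_grid)) {
    stopifnot(all(c("noise_factor", "background_factor") %in%
                    names(robustness_grid)),
              all(robustness_grid$noise_factor >= 0),
              all(robustness_grid$background_factor >= 0))
  }
  structure(list(simulation = simulation, normalize = normalize,
                 signature_ranks = signature_ranks,
                 signature_max_spectra = signature_max_spectra,
                 simca_a = simca_a, simca_alpha = simca_alpha,
                 lda_compression = lda_compression, lda_a = lda_a,
                 run_lda_loo = run_lda_loo, plsda_a = plsda_a, cv = cv,
                 robustness_grid = robustness_grid,
                 holdout_donors = holdout_donors),
            class = "experiment_config")
}

# polynomial rolling hash over the deparsed config: a stable fingerprint
# for provenance (not cryptographic)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(verbose, stage, t0) {
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full pipeline end to end
#'
#' Generate -> preprocess -> per-fluid signatures (ALS + baseline, with
#' self-fit quality summaries) -> SIMCA on spot-level and sample-averaged
#' spectra -> leave-one-out LDA -> PLS-DA calibration and cross-validation
#' metrics -> optional robustness surface.  The report is fully
#' deterministic given the configuration.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Log per-stage wall time via `message()`.
#' @return A list of class `experiment_report`.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- as.numeric(Sys.time())
  d <- simulate_dataset(cfg$simulation)
  stage_log(verbose, "generate", t0)

  t0 <- as.numeric(Sys.time())
  if (cfg$normalize) d <- normalize_dataset(d)
  stage_log(verbose, "preprocess", t0)

  t0 <- as.numeric(Sys.time())
  sig_summary <- list()
  for (fluid in intersect(names(cfg$signature_ranks), unique(d$fluid))) {
    idx <- which(d$fluid == fluid)
    use <- idx[seq_len(min(length(idx), cfg$signature_max_spectra))]
    sig <- fluid_signature(dataset_subset(d, use), fluid,
                           cfg$signature_ranks[[fluid]])
    qual <- t(vapply(idx, function(i) {
      q <- fit_signature(dataset_spectrum(d, i), sig)$quality
      c(q$sse, q$r_square, q$rmse)
    }, numeric(3)))
    sig_summary[[fluid]] <- c(mean_sse = mean(qual[, 1]),
                              mean_r_square = mean(qual[, 2]),
                              mean_rmse = mean(qual[, 3]))
  }
  stage_log(verbose, "signatures", t0)

  t0 <- as.numeric(Sys.time())
  simca_spot <- simca_classify(
    simca_train(d, cfg$simca_a, cfg$simca_alpha), d)
  d_avg <- average_per_sample(d)
  simca_avg <- simca_classify(
    simca_train(d_avg, cfg$simca_a, cfg$simca_alpha), d_avg)
  stage_log(verbose, "simca", t0)

  t0 <- as.numeric(Sys.time())
  lda <- if (cfg$run_lda_loo) {
    lda_loo(d, cfg$lda_compression, cfg$lda_a)
  } else NULL
  stage_log(verbose, "lda", t0)

  t0 <- as.numeric(Sys.time())
  plsda <- plsda_train(d, cfg$plsda_a)
  plsda_metrics <- plsda_evaluate(plsda, d, cfg$cv)
  stage_log(verbose, "plsda", t0)

  robustness <- NULL
  if (!is.null(cfg$robustness_grid)) {
    t0 <- as.numeric(Sys.time())
    robustness <- robustness_study(cfg, cfg$robustness_grid)
    stage_log(verbose, "robustness", t0)
  }

  structure(list(
    dataset = list(n = nrow(d$intensities),
                   per_class = table(d$fluid)),
    signature_fit = sig_summary,
    simca = list(spot_accuracy = simca_spot$metrics$accuracy,
                 averaged_accuracy = simca_avg$metrics$accuracy),
    lda = if (!is.null(lda)) list(loo_accuracy = lda$accuracy,
                                  metrics = lda$metrics),
    plsda = list(a = plsda$a, cal = plsda_metrics$cal,
                 cv = plsda_metrics$cv),
    robustness = robustness,
    provenance = list(seed = cfg$simulation$seed,
                      config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("ramanid")))
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  dataset: %d spectra (%s)\n", x$dataset$n,
              paste(sprintf("%s %d", names(x$dataset$per_class),
                            x$dataset$per_class), collapse = ", ")))
  cat(sprintf("  SIMCA accuracy: spot %.3f, sample-averaged %.3f\n",
              x$simca$spot_accuracy, x$simca$averaged_accuracy))
  if (!is.null(x$lda)) {
    cat(sprintf("  LDA LOO accuracy: %.3f\n", x$lda$loo_accuracy))
  }
  cat(sprintf("  PLS-DA (a = %d): Cal accuracy %.3f, CV accuracy %.3f\n",
              x$plsda$a, x$plsda$cal$accuracy, x$plsda$cv$accuracy))
  invisible(x)
}

#' Donor-wise train/evaluation split
#'
#' Holds out whole donors (all their spots) per fluid, preventing donor
#' leakage between training and evaluation.
#'
#' @param d A [spectral_dataset()].
#' @param donors_per_fluid Number of held-out donors per fluid, or a named
#'   list of explicit donor ids.
#' @return A list: `train` and `test` [spectral_dataset()]s, plus
#'   `held_out` donor ids.
#' @export
donor_split <- function(d, donors_per_fluid = 5) {
  held <- character(0)
  for (fluid in unique(d$fluid)) {
    donors <- unique(d$donor[d$fluid == fluid])
    k <- if (is.list(donors_per_fluid)) {
      held <- c(held, donors_per_fluid[[fluid]]); next
    } else min(donors_per_fluid, length(donors) - 1L)
    held <- c(held, utils::tail(donors, k))
  }
  test_idx <- d$donor %in% held
  list(train = dataset_subset(d, !test_idx),
       test = dataset_subset(d, test_idx),
       held_out = held)
}

#' Engine robustness under corruption
#'
#' Trains the three engines once on a donor-wise training split, then for
#' each (noise_factor, background_factor) grid point corrupts a fresh copy
#' of the evaluation split with [inject_corruption()] and records every
#' engine's accuracy plus the majority-vote consensus accuracy.
#'
#' @param cfg An [experiment_config()].
#' @param grid Data frame with columns `noise_factor`, `background_factor`.
#' @param corruption_seed Seed of the corruption draws (shared across grid
#'   points, so corruption grows proportionally with the factors).
#' @return A data frame: the grid plus `simca`, `lda`, `plsda`,
#'   `consensus` accuracy columns.
#' @export
robustness_study <- function(cfg, grid, corruption_seed = 7) {
  stopifnot(nrow(grid) >= 1)
  d <- simulate_dataset(cfg$simulation)
  if (cfg$normalize) d <- normalize_dataset(d)
  sp <- donor_split(d, cfg$holdout_donors)
  models <- list(
    simca = simca_train(sp$train, cfg$simca_a, cfg$simca_alpha),
    lda = lda_pipeline_train(sp$train, cfg$lda_compression, cfg$lda_a),
    plsda = plsda_train(sp$train,
                        if (identical(cfg$plsda_a, "auto")) "auto"
                        else cfg$plsda_a,
                        schemes = cfg$cv)
  )
  out <- grid
  out$simca <- out$lda <- out$plsda <- out$consensus <- NA_real_
  for (i in seq_len(nrow(grid))) {
    dc <- inject_corruption(sp$test, grid$noise_factor[i],
                            grid$background_factor[i],
                            seed = corruption_seed)
    votes <- classify_unknowns(models, dc)
    out$simca[i] <- mean(votes$simca == dc$fluid)
    out$lda[i] <- mean(votes$lda == dc$fluid)
    out$plsda[i] <- mean(votes$plsda == dc$fluid)
    out$consensus[i] <- mean(votes$consensus == dc$fluid)
  }
  out
}
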