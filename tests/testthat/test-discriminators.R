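test_that("SIMCA limits follow the F and Jackson-Mudholkar formulas", {
  set.seed(20)
  wn <- seq_len(30)
  X <- matrix(rnorm(20 * 30), 20, 30) + 5
  d <- spectral_dataset(abs(X), wn, rep("blood", 20),
                        donor = rep("d", 20))
  # need a second class for training; make it distinct
  d2 <- spectral_dataset(abs(X) + 10, wn, rep("semen", 20),
                         donor = rep("e", 20))
  both <- spectral_dataset(rbind(d$intensities, d2$intensities), wn,
                           c(d$fluid, d2$fluid), c(d$donor, d2$donor))
  m <- simca_train(both, a_per_class = 2, alpha = 0.95)
  expect_equal(m$models$blood$t2_limit, 2 * 19 / 18 * qf(0.95, 2, 18),
               tolerance = 1e-12)
  expect_setequal(m$classes, c("blood", "semen"))
  expect_true(all(vapply(m$models, function(x) x$q_limit > 0, TRUE)))

  expect_error(simca_train(dataset_subset(both, c(1:2, 21:40)),
                           a_per_class = 2), "blood")
})

test_that("the Q limit covers ~alpha of points from a true low-rank class", {
  set.seed(21)
  n <- 500; p <- 40
  scores <- matrix(rnorm(n * 2, sd = c(4, 2)), n, 2)
  basis <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  X <- scores %*% t(basis) + matrix(rnorm(n * p, sd = 0.05), n, p) + 10
  other <- matrix(runif(20 * p) + 20, 20, p)
  d <- spectral_dataset(rbind(X, other), seq_len(p),
                        c(rep("blood", n), rep("semen", 20)))
  m <- simca_train(d, a_per_class = c(blood = 2, semen = 2), alpha = 0.95)
  pr <- pca_project(m$models$blood$pca, X)
  expect_gte(mean(pr$q <= m$models$blood$q_limit), 0.95)
})

test_that("SIMCA assigns spectra to the nearest class model", {
  d <- small_dataset(n_per = 8, spots = 5, seed = 23)
  m <- simca_train(d, 2, 0.95)
  expect_length(m$models, 3L)

  res <- simca_classify(m, d)
  # per-class correct-assignment rates are high on clean synthetic data
  for (cl in m$classes) {
    rate <- mean(res$nearest_class[d$fluid == cl] == cl)
    expect_gte(rate, 0.8)
  }

  # the class mean itself is unambiguous
  mean_blood <- colMeans(d$intensities[d$fluid == "blood", ])
  dm <- spectral_dataset(rbind(mean_blood, mean_blood), d$wavenumbers,
                         c("unknown", "unknown"))
  rm2 <- simca_classify(m, dm)
  expect_equal(rm2$nearest_class, c("blood", "blood"))
  expect_lt(rm2$distances[1, "blood"], min(rm2$distances[1, c("saliva",
                                                              "semen")]))

  # training spectra sit inside their own class limits
  own <- vapply(seq_len(nrow(d$intensities)), function(i) {
    res$in_class[i, d$fluid[i]]
  }, TRUE)
  expect_gte(mean(own), 0.9)

  # sample averaging sharpens the class models to perfection
  da <- average_per_sample(d)
  ra <- simca_classify(simca_train(da, 2, 0.95), da)
  expect_equal(ra$metrics$accuracy, 1)

  expect_error(simca_classify(m, spectral_dataset(matrix(1, 2, 10), 1:10,
                                                  c("blood", "blood"))),
               "grid")
})

test_that("LDA discriminants follow the closed-form Gaussian rule", {
  gs <- gaussian_scores(n_per = 20, dim = 3, sep = 10, seed = 24)
  m <- lda_train(gs$scores, gs$labels)

  # delta matches a brute-force evaluation of the formula
  set.seed(25)
  probes <- matrix(rnorm(30, sd = 5), 10, 3)
  pred <- lda_predict(m, probes)
  for (i in 1:10) {
    for (j in seq_along(m$classes)) {
      mu <- m$means[j, ]
      delta_oracle <- drop(probes[i, ] %*% m$cov_inv %*% mu) -
        0.5 * drop(mu %*% m$cov_inv %*% mu) + log(m$priors[j])
      expect_equal(unname(pred$delta[i, j]), delta_oracle,
                   tolerance = 1e-10)
    }
  }

  # two spherical classes: the boundary is the perpendicular bisector
  two <- list(scores = gs$scores[1:40, ], labels = gs$labels[1:40])
  m2 <- lda_train(two$scores, two$labels)
  for (i in 1:10) {
    x <- probes[i, ]
    d1 <- sum((x - m2$means[1, ])^2); d2 <- sum((x - m2$means[2, ])^2)
    expect_equal(lda_predict(m2, x)$class,
                 m2$classes[which.min(c(d1, d2))])
  }

  # agreement with the classical reference implementation
  skip_if_not_installed("MASS")
  ref <- MASS::lda(gs$scores, grouping = gs$labels,
                   prior = rep(1 / 3, 3))
  ref_pred <- as.character(predict(ref, probes)$class)
  expect_equal(lda_predict(m, probes)$class, ref_pred)
})

test_that("degenerate identical-mean classes tie and break by class order", {
  set.seed(26)
  X <- matrix(rnorm(60 * 2), 60, 2)
  labels <- rep(c("blood", "saliva", "semen"), 20)
  m <- lda_train(X, labels)
  pred <- lda_predict(m, rbind(colMeans(X)))
  spread <- diff(range(pred$delta))
  expect_lt(spread / max(abs(pred$delta)), 0.3)
  # exact ties resolve to the first class in sorted order
  m$means <- matrix(0, 3, 2, dimnames = dimnames(m$means))
  expect_equal(lda_predict(m, rbind(c(0, 0)))$class, "blood")
})

test_that("leave-one-out LDA runs on minimal data and respects leakage", {
  d <- small_dataset(n_per = 1, spots = 2, seed = 27)
  out <- lda_loo(d, a = 2)
  expect_length(out$predictions, 6L)
  expect_error(lda_loo(dataset_subset(d, c(1, 3, 5))), "more spectrum")
})

test_that("Gaussian-family variants agree with LDA where theory says so", {
  gs <- gaussian_scores(n_per = 15, dim = 2, sep = 12, seed = 28)
  d <- spectral_dataset(abs(gs$scores) + 1, c(1, 2), gs$labels)
  base <- lda_loo(d, a = 2)
  for (v in c("naive_bayes", "stratified_covariance", "mahalanobis")) {
    out <- gaussian_family_predict(d, v, a = 2)
    expect_equal(out$predictions, base$predictions,
                 label = sprintf("%s matches LDA on spherical classes", v))
  }

  # on realistic spectra each variant lands within 5 points of LDA
  ds <- small_dataset(n_per = 5, spots = 4, peak_snr = 25, seed = 29)
  acc_lda <- lda_loo(ds)$accuracy
  for (v in c("naive_bayes", "stratified_covariance", "mahalanobis")) {
    acc <- gaussian_family_predict(ds, v)$accuracy
    expect_lte(abs(acc - acc_lda), 0.05,
               label = sprintf("%s within 5 points of LDA", v))
  }
})

test_that("Mahalanobis with identity covariance is nearest-mean", {
  set.seed(30)
  tr <- rbind(matrix(rnorm(40, sd = 1), 20, 2),
              matrix(rnorm(40, mean = 8, sd = 1), 20, 2))
  labels <- rep(c("blood", "semen"), each = 20)
  probe <- c(3.9, 3.9)
  pred <- ramanid:::gaussian_rule(tr, labels, matrix(probe, 1), "mahalanobis")
  mu_b <- colMeans(tr[1:20, ]); mu_s <- colMeans(tr[21:40, ])
  nearest <- c("blood", "semen")[which.min(c(sum((probe - mu_b)^2),
                                             sum((probe - mu_s)^2)))]
  expect_equal(pred, nearest)
})

test_that("PLS-DA separates constructed and simulated classes", {
  # two 1-peak classes, a = 1: perfect calibration
  grid <- seq(400, 700, 2)
  set.seed(31)
  mk <- function(center, n) t(vapply(seq_len(n), function(i) {
    (1 + 0.1 * rnorm(1)) * lorentzian(grid, center, 12)
  }, numeric(length(grid))))
  d <- spectral_dataset(rbind(mk(500, 10), mk(600, 10)), grid,
                        rep(c("blood", "semen"), each = 10))
  m <- plsda_train(d, a = 1)
  pred <- predict(m, d)
  expect_equal(mean(pred$class == d$fluid), 1)
  # the decision is pure argmax of the indicator predictions
  expect_equal(pred$class,
               colnames(pred$indicator)[max.col(pred$indicator,
                                                ties.method = "first")])

  # PLS-DA with a = g - 1 matches LDA on well-separated data
  gs <- gaussian_scores(n_per = 15, dim = 4, sep = 12, seed = 32)
  dg <- spectral_dataset(abs(gs$scores) + 1, 1:4, gs$labels)
  mp <- plsda_train(dg, a = 2)
  lp <- lda_pipeline_train(dg, a = 4)
  agree <- mean(predict(mp, dg)$class == predict(lp, dg)$class)
  expect_gte(agree, 0.99)
})

test_that("PLS-DA latent scores cluster the fluids", {
  skip_if_not_installed("cluster")
  d <- small_dataset(n_per = 8, spots = 5, seed = 33)
  m <- plsda_train(d, a = 5)
  sc <- pls_predict(m$pls, d$intensities, type = "scores")[, 1:3]
  sil <- cluster::silhouette(as.integer(factor(d$fluid)), dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("PLS-DA evaluation separates calibration from cross-validation", {
  d <- small_dataset(n_per = 6, spots = 4, seed = 34)
  m <- plsda_train(d, a = 3)
  ev <- plsda_evaluate(m, d, cv_scheme("venetian_blind", 5))
  expect_equal(ev$cal$accuracy, 1)
  expect_true(all(ev$cal$per_class$sensitivity == 1))
  expect_true(all(ev$cal$per_class$specificity == 1))
  expect_true(all(ev$cal$per_class$class_error == 0))
  expect_true(all(is.finite(ev$cal$per_class$rmse)))
  expect_true(all(is.finite(ev$cv$per_class$rmse)))
  # CV indicator error cannot beat calibration on average
  expect_gte(mean(ev$cv$per_class$rmse), mean(ev$cal$per_class$rmse) - 1e-9)
})

test_that("engine ensembles vote and flag disagreement", {
  d <- small_dataset(n_per = 6, spots = 4, seed = 35)
  models <- list(simca = simca_train(d, 2),
                 lda = lda_pipeline_train(d),
                 plsda = plsda_train(d, a = 3))
  # a training spectrum is classified unanimously
  unk <- dataset_subset(d, 1:3)
  unk$fluid <- rep("unknown", 3)
  votes <- classify_unknowns(models, unk)
  expect_equal(votes$consensus, d$fluid[1:3])
  expect_equal(votes$simca, votes$lda)

  # the consensus rule itself
  expect_equal(consensus_vote(c("blood", "blood", "semen")), "blood")
  expect_equal(consensus_vote(c("blood", "saliva", "semen")), "ambiguous")
  expect_equal(consensus_vote("semen"), "semen")
})
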