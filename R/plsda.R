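#' Train a PLS-DA classifier
#'
#' Partial least squares regression of the spectra against the one-hot
#' class indicator, with the class decision by argmax of the predicted
#' indicator values (predicted rows need not sum to 1).  When
#' `a = "auto"`, the latent-variable count is chosen by [select_ncomp()]
#' under each supplied cross-validation scheme and the maximum selected
#' count across schemes is used (conservative).
#'
#' @param d A labelled [spectral_dataset()].
#' @param a Number of latent variables, or `"auto"`.
#' @param schemes A [cv_scheme()] or list of schemes used when
#'   `a = "auto"`; default: contiguous-block, leave-one-out,
#'   venetian-blind and random-subset (10 folds each where applicable).
#' @param max_a Largest latent-variable count considered by the selection.
#' @return A list of class `plsda_model`: `pls` (a [pls_fit()] model),
#'   `classes`, `a`, `selection` (per-scheme [select_ncomp()] results when
#'   auto).
#' @export
plsda_train <- function(d, a = "auto", schemes = NULL, max_a = 10) {
  classes <- sort(unique(d$fluid))
  if (length(classes) < 2L) stop("PLS-DA needs at least 2 classes")
  Y <- one_hot(d$fluid, classes)
  X <- d$intensities
  selection <- NULL
  if (identical(a, "auto")) {
    if (is.null(schemes)) {
      schemes <- list(cv_scheme("contiguous_block", 10),
                      cv_scheme("loo"),
                      cv_scheme("venetian_blind", 10),
                      cv_scheme("random_subset", 10, seed = 1))
    }
    if (inherits(schemes, "cv_scheme")) schemes <- list(schemes)
    selection <- lapply(schemes, function(sc) {
      select_ncomp(X, Y, sc, max_a)
    })
    a <- max(vapply(selection, `[[`, 1L, "a"))
  }
  structure(list(pls = pls_fit(X, Y, a), classes = classes, a = a,
                 selection = selection),
            class = "plsda_model")
}

#' Predict classes from a PLS-DA model
#'
#' @param object A [plsda_train()] model.
#' @param X Spectrum matrix or [spectral_dataset()].
#' @param ... Unused.
#' @return A list: `indicator` (predicted class-indicator matrix),
#'   `class` (argmax labels, ties broken by class order).
#' @export
predict.plsda_model <- function(object, X, ...) {
  if (inherits(X, "spectral_dataset")) X <- X$intensities
  ind <- pls_predict(object$pls, X)
  colnames(ind) <- object$classes
  list(indicator = ind,
       class = object$classes[max.col(ind, ties.method = "first")])
}

#' Calibration and cross-validated PLS-DA metrics
#'
#' Calibration (Cal) metrics come from self-prediction of the training
#' data; cross-validation (CV) metrics refit the PLS model (same
#' latent-variable count) inside each fold of `scheme` and predict the
#' held-out spectra once.  The per-class RMSE column is RMSEC for Cal and
#' RMSECV for CV.
#'
#' @param m A [plsda_train()] model.
#' @param d The labelled [spectral_dataset()] to evaluate on.
#' @param scheme A [cv_scheme()] (default venetian-blind, 10 folds).
#' @return A list: `cal` and `cv`, each a [class_metrics()].
#' @export
plsda_evaluate <- function(m, d, scheme = cv_scheme("venetian_blind", 10)) {
  stopifnot(inherits(m, "plsda_model"))
  classes <- m$classes
  Y <- one_hot(d$fluid, classes)
  X <- d$intensities
  cal_pred <- predict(m, X)
  cal <- class_metrics(d$fluid, cal_pred$class, classes,
                       indicator_pred = cal_pred$indicator)
  n <- nrow(X)
  cv_ind <- matrix(NA_real_, n, length(classes))
  for (f in cv_split(n, scheme)) {
    mf <- pls_fit(X[f$train, , drop = FALSE], Y[f$train, , drop = FALSE],
                  m$a)
    cv_ind[f$test, ] <- pls_predict(mf, X[f$test, , drop = FALSE],
                                    a = min(m$a, mf$a))
  }
  cv_class <- classes[max.col(cv_ind, ties.method = "first")]
  cv <- class_metrics(d$fluid, cv_class, classes, indicator_pred = cv_ind)
  list(cal = cal, cv = cv)
}

#' Classify unknown spectra by an engine ensemble
#'
#' Each trained engine votes on every unknown spectrum; the consensus is
#' the majority vote, flagged `"ambiguous"` when all engines disagree.
#'
#' @param models Named list of trained engines; recognised elements:
#'   `simca` ([simca_train()]), `lda` ([lda_pipeline_train()]), `plsda`
#'   ([plsda_train()]).
#' @param d_unknown A [spectral_dataset()] of unknowns on the training
#'   grid.
#' @return A data frame with one row per spectrum: a vote column per
#'   engine plus `consensus`.
#' @export
classify_unknowns <- function(models, d_unknown) {
  stopifnot(length(models) >= 1L)
  votes <- list()
  if (!is.null(models$simca)) {
    votes$simca <- simca_classify(models$simca, d_unknown)$nearest_class
  }
  if (!is.null(models$lda)) {
    votes$lda <- predict(models$lda, d_unknown)$class
  }
  if (!is.null(models$plsda)) {
    votes$plsda <- predict(models$plsda, d_unknown)$class
  }
  V <- as.data.frame(votes, stringsAsFactors = FALSE)
  V$consensus <- apply(as.matrix(V), 1, consensus_vote)
  V
}

#' Majority consensus of engine votes
#'
#' @param votes Character vector of one class vote per engine.
#' @return The majority class, or `"ambiguous"` when every engine votes
#'   differently (no majority exists).
#' @export
consensus_vote <- function(votes) {
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) == length(votes) && length(votes) > 1L) "ambiguous"
  else names(tab)[1]
}
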