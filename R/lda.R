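#' Fit a score-space compression model
#'
#' Compresses spectra to PCA or PLS scores before discriminant analysis.
#' For PCA, the default dimensionality is the number of components
#' retaining 99% of the variance, capped at 20; for PLS the latent
#' variables are fit against the one-hot class indicator.
#'
#' @param X Spectrum matrix.
#' @param labels Class labels (required for `"pls"`).
#' @param method `"pca"` or `"pls"`.
#' @param a Number of scores; `NULL` for the default rule.
#' @return A list of class `compression_model`.
#' @export
compress_fit <- function(X, labels = NULL, method = c("pca", "pls"),
                         a = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (method == "pca") {
    amax <- min(n - 1, ncol(X))
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd_right(Xc, min(20L, amax))  # one decomposition serves rule and model
    allvar <- sv$d^2 / (n - 1)
    if (is.null(a)) {
      cum <- cumsum(allvar) / sum(allvar)
      a <- min(which(cum >= 0.99), 20L, amax)
    }
    L <- t(sv$v[, seq_len(a), drop = FALSE])
    flip <- apply(L, 1, function(r) sign(r[which.max(abs(r))]))
    model <- structure(list(mean = mu, loadings = L * flip,
                            variances = allvar[seq_len(a)],
                            all_variances = allvar, a = as.integer(a), n = n),
                       class = "pca_model")
  } else {
    if (is.null(labels)) stop("PLS compression needs class labels")
    if (is.null(a)) a <- min(10L, n - 2L, ncol(X))
    model <- pls_fit(X, one_hot(labels), a)
  }
  structure(list(method = method, model = model, a = model$a %||% a),
            class = "compression_model")
}

#' @export
predict.compression_model <- function(object, X, ...) {
  if (object$method == "pca") {
    pca_project(object$model, X)$scores
  } else {
    pls_predict(object$model, X, type = "scores")
  }
}

#' Train a linear discriminant model on score vectors
#'
#' Fisher/Gaussian LDA with equal priors: class means, pooled within-class
#' covariance, and the linear discriminant score
#' `delta_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`.  A ridge
#' term `1e-8 * trace / dim` is added once if the pooled covariance is
#' numerically singular.  Ties in the argmax decision are broken by class
#' order (alphabetical: blood < saliva < semen).
#'
#' @param scores n x a score matrix.
#' @param labels Class labels, >= 2 classes.
#' @param priors Class priors (default equal).
#' @return A list of class `lda_model`.
#' @export
lda_train <- function(scores, labels, priors = NULL) {
  scores <- as.matrix(scores)
  classes <- sort(unique(labels))
  g <- length(classes)
  if (g < 2L) stop("LDA needs at least 2 classes")
  a <- ncol(scores)
  n <- nrow(scores)
  means <- t(vapply(classes, function(cl) {
    colMeans(scores[labels == cl, , drop = FALSE])
  }, numeric(a)))
  Sw <- matrix(0, a, a)
  for (cl in classes) {
    Xc <- scale(scores[labels == cl, , drop = FALSE], center = TRUE,
                scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - g)
  inv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(inv)) {
    Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / a, a)
    inv <- tryCatch(solve(Sw), error = function(e) {
      stop("pooled covariance singular even after ridge regularization")
    })
  }
  if (is.null(priors)) priors <- rep(1 / g, g)
  structure(list(classes = classes, means = means, cov = Sw, cov_inv = inv,
                 priors = priors, a = a),
            class = "lda_model")
}

#' Evaluate linear discriminant scores and predict classes
#'
#' @param m An [lda_train()] model.
#' @param scores Score matrix or vector.
#' @return A list: `delta` (n x g discriminant scores), `class` (predicted
#'   labels).
#' @export
lda_predict <- function(m, scores) {
  stopifnot(inherits(m, "lda_model"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  M <- m$cov_inv %*% t(m$means)                 # a x g
  delta <- scores %*% M -
    matrix(0.5 * colSums(t(m$means) * M), nrow(scores),
           length(m$classes), byrow = TRUE) +
    matrix(log(m$priors), nrow(scores), length(m$classes), byrow = TRUE)
  colnames(delta) <- m$classes
  list(delta = delta,
       class = m$classes[max.col(delta, ties.method = "first")])
}

#' Train the full LDA pipeline (compression + discriminant) on a dataset
#'
#' @param d A labelled [spectral_dataset()].
#' @param compression `"pca"` or `"pls"`.
#' @param a Score dimensionality (`NULL` = default rule, see
#'   [compress_fit()]).
#' @return A list of class `lda_pipeline` with `compression` and `lda`.
#' @export
lda_pipeline_train <- function(d, compression = c("pca", "pls"), a = NULL) {
  compression <- match.arg(compression)
  comp <- compress_fit(d$intensities, d$fluid, compression, a)
  structure(list(compression = comp,
                 lda = lda_train(predict(comp, d$intensities), d$fluid)),
            class = "lda_pipeline")
}

#' @export
predict.lda_pipeline <- function(object, X, ...) {
  if (inherits(X, "spectral_dataset")) X <- X$intensities
  lda_predict(object$lda, predict(object$compression, X))
}

#' Leave-one-out LDA on compressed spectra
#'
#' For each held-out spectrum the compression model AND the discriminant
#' are refit on the remaining n - 1 spectra (leakage-safe), and the
#' held-out spectrum is predicted once.
#'
#' @param d A labelled [spectral_dataset()].
#' @param compression `"pca"` (default) or `"pls"`.
#' @param a Score dimensionality (`NULL` = default rule).
#' @return A list: `predictions`, `truth`, `metrics` (a
#'   [class_metrics()]), `accuracy`.
#' @export
lda_loo <- function(d, compression = c("pca", "pls"), a = NULL) {
  compression <- match.arg(compression)
  X <- d$intensities
  n <- nrow(X)
  if (n < length(unique(d$fluid)) + 1L) {
    stop("need at least one more spectrum than classes")
  }
  preds <- character(n)
  for (i in seq_len(n)) {
    comp <- compress_fit(X[-i, , drop = FALSE], d$fluid[-i], compression, a)
    m <- lda_train(predict(comp, X[-i, , drop = FALSE]), d$fluid[-i])
    preds[i] <- lda_predict(m, predict(comp, X[i, , drop = FALSE]))$class
  }
  metrics <- class_metrics(d$fluid, preds)
  list(predictions = preds, truth = d$fluid, metrics = metrics,
       accuracy = metrics$accuracy)
}

#' Leave-one-out Gaussian discriminant variants
#'
#' The LDA family evaluated under leave-one-out with in-fold compression
#' refits: `naive_bayes` (per-class diagonal Gaussians),
#' `stratified_covariance` (per-class full covariance, quadratic rule) and
#' `mahalanobis` (minimal Mahalanobis distance to the class mean under the
#' pooled covariance).
#'
#' @param d A labelled [spectral_dataset()].
#' @param variant One of `"naive_bayes"`, `"stratified_covariance"`,
#'   `"mahalanobis"`.
#' @param compression `"pca"` or `"pls"`.
#' @param a Score dimensionality (`NULL` = default rule).
#' @return As [lda_loo()].
#' @export
gaussian_family_predict <- function(d, variant = c("naive_bayes",
                                                   "stratified_covariance",
                                                   "mahalanobis"),
                                    compression = c("pca", "pls"),
                                    a = NULL) {
  variant <- match.arg(variant)
  compression <- match.arg(compression)
  X <- d$intensities
  n <- nrow(X)
  preds <- character(n)
  for (i in seq_len(n)) {
    comp <- compress_fit(X[-i, , drop = FALSE], d$fluid[-i], compression, a)
    tr <- predict(comp, X[-i, , drop = FALSE])
    te <- predict(comp, X[i, , drop = FALSE])
    preds[i] <- gaussian_rule(tr, d$fluid[-i], te, variant)
  }
  metrics <- class_metrics(d$fluid, preds)
  list(predictions = preds, truth = d$fluid, metrics = metrics,
       accuracy = metrics$accuracy)
}

gaussian_rule <- function(train_scores, labels, test_scores, variant) {
  classes <- sort(unique(labels))
  a <- ncol(train_scores)
  ridge <- function(S) {
    if (any(!is.finite(S)) || inherits(tryCatch(solve(S),
                                       error = function(e) e), "error")) {
      S <- S + diag(1e-8 * max(sum(diag(S)), 1e-12) / a, a)
    }
    S
  }
  score <- vapply(classes, function(cl) {
    Xc <- train_scores[labels == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    dx <- drop(test_scores) - mu
    switch(variant,
      naive_bayes = {
        v <- apply(Xc, 2, stats::var)
        v[v <= 0 | !is.finite(v)] <- 1e-12
        -sum(dx^2 / v) / 2 - sum(log(v)) / 2
      },
      stratified_covariance = {
        S <- ridge(stats::cov(Xc))
        -drop(dx %*% solve(S, dx)) / 2 - determinant(S)$modulus / 2
      },
      mahalanobis = {
        Sw <- matrix(0, a, a)
        for (c2 in classes) {
          Z <- scale(train_scores[labels == c2, , drop = FALSE],
                     center = TRUE, scale = FALSE)
          Sw <- Sw + crossprod(Z)
        }
        Sw <- ridge(Sw / (nrow(train_scores) - length(classes)))
        -drop(dx %*% solve(Sw, dx))
      })
  }, 0)
  classes[which.max(score)]
}
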