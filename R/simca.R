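#' Train a SIMCA model
#'
#' Soft independent modeling of class analogy: one PCA model per class,
#' with Hotelling T-squared and Q (squared orthogonal residual) confidence
#' limits at level `alpha`.  The T-squared limit is
#' `a (n - 1) / (n - a) * F^{-1}(alpha; a, n - a)`; the Q limit follows
#' Jackson-Mudholkar from the discarded eigenvalues.
#'
#' @param d A [spectral_dataset()] with known labels.
#' @param a_per_class Principal components per class submodel: a scalar or
#'   a named vector per class (default 2).
#' @param alpha Confidence level of the class limits (default 0.95).
#' @return A list of class `simca_model`: `classes`, `alpha`, and per class
#'   a list with `pca`, `t2_limit`, `q_limit`, `a`, `n`.
#' @export
simca_train <- function(d, a_per_class = 2, alpha = 0.95) {
  classes <- sort(unique(d$fluid))
  models <- list()
  for (cl in classes) {
    a <- if (length(a_per_class) > 1L || !is.null(names(a_per_class))) {
      a_per_class[[cl]]
    } else a_per_class
    X <- d$intensities[d$fluid == cl, , drop = FALSE]
    n <- nrow(X)
    if (n < a + 1L) {
      stop(sprintf("class '%s' has %d spectra; needs at least a + 1 = %d",
                   cl, n, a + 1L))
    }
    pca <- pca_fit(X, a)
    t2_limit <- a * (n - 1) / (n - a) * stats::qf(alpha, a, n - a)
    q_limit <- jackson_mudholkar_limit(pca$all_variances, a, alpha)
    models[[cl]] <- list(pca = pca, t2_limit = t2_limit, q_limit = q_limit,
                         a = a, n = n)
  }
  structure(list(classes = classes, alpha = alpha, models = models),
            class = "simca_model")
}

# Q (SPE) confidence limit from the discarded eigenvalues
jackson_mudholkar_limit <- function(eigenvalues, a, alpha) {
  resid_ev <- eigenvalues[-seq_len(a)]
  resid_ev <- resid_ev[resid_ev > 0]
  if (!length(resid_ev)) return(.Machine$double.eps)
  th1 <- sum(resid_ev); th2 <- sum(resid_ev^2); th3 <- sum(resid_ev^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-4
  z <- stats::qnorm(alpha)
  th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
           1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Classify spectra with a SIMCA model
#'
#' Each spectrum is projected into every class submodel; the reduced
#' distance to a class is
#' `d_c = sqrt((T2 / T2_lim)^2 + (Q / Q_lim)^2)`.  A spectrum is assigned
#' to its nearest class, and is inside a class model when
#' `d_c <= sqrt(2)` (both statistics at their limits).
#'
#' @param m A [simca_train()] model.
#' @param d A [spectral_dataset()] on the same grid.
#' @return A list of class `simca_assignment`: `distances` (n x g reduced
#'   distances), `t2`, `q` (n x g raw statistics), `nearest_class`,
#'   `in_class` (n x g logical), and `metrics` (a [class_metrics()]) when
#'   the dataset carries non-`unknown` labels.
#' @export
simca_classify <- function(m, d) {
  stopifnot(inherits(m, "simca_model"))
  if (ncol(d$intensities) != length(m$models[[1]]$pca$mean)) {
    stop("dataset grid does not match the SIMCA model")
  }
  g <- length(m$classes)
  n <- nrow(d$intensities)
  dist <- t2m <- qm <- matrix(NA_real_, n, g,
                              dimnames = list(NULL, m$classes))
  for (j in seq_len(g)) {
    sub <- m$models[[m$classes[j]]]
    pr <- pca_project(sub$pca, d$intensities)
    t2m[, j] <- pr$t2
    qm[, j] <- pr$q
    dist[, j] <- sqrt((pr$t2 / sub$t2_limit)^2 + (pr$q / sub$q_limit)^2)
  }
  nearest <- m$classes[max.col(-dist, ties.method = "first")]
  out <- list(distances = dist, t2 = t2m, q = qm,
              nearest_class = nearest, in_class = dist <= sqrt(2))
  if (any(d$fluid != "unknown")) {
    out$metrics <- class_metrics(d$fluid, nearest, m$classes)
  }
  structure(out, class = "simca_assignment")
}
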