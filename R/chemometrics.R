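#' Principal component analysis of a spectrum matrix
#'
#' Mean-centered SVD.  Loadings are the top-`a` right singular vectors
#' (rows), sign-fixed so each loading's largest-magnitude element is
#' positive; variances are `sigma^2 / (n - 1)`.
#'
#' @param X Numeric matrix, observations in rows.
#' @param a Number of principal components, `1 <= a <= min(n - 1, p)`.
#' @return A list of class `pca_model`: `mean`, `loadings` (a x p),
#'   `variances` (length a), `all_variances` (full eigenvalue spectrum),
#'   `a`, `n`.
#' @export
pca_fit <- function(X, a) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (a < 1 || a > min(n - 1, p)) {
    stop(sprintf("a must be in [1, %d]", min(n - 1, p)))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  L <- t(sv$v[, seq_len(a), drop = FALSE])
  flip <- apply(L, 1, function(r) sign(r[which.max(abs(r))]))
  L <- L * flip
  structure(list(mean = mu, loadings = L,
                 variances = sv$d[seq_len(a)]^2 / (n - 1),
                 all_variances = sv$d^2 / (n - 1), a = a, n = n),
            class = "pca_model")
}

# Singular values plus the first `a` right singular vectors of Xc.
# When n < p this goes through the n x n Gram matrix, which is much
# cheaper than a full SVD for wide spectrum matrices.
svd_right <- function(Xc, a) {
  n <- nrow(Xc); p <- ncol(Xc)
  a <- min(a, n, p)
  if (n < p) {
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    pos <- which(d > max(d) * 1e-12)
    a <- min(a, length(pos))
    v <- crossprod(Xc, eg$vectors[, seq_len(a), drop = FALSE]) %*%
      diag(1 / d[seq_len(a)], a)
    list(d = d, v = v)
  } else {
    sv <- svd(Xc, nu = 0)
    list(d = sv$d, v = sv$v[, seq_len(a), drop = FALSE])
  }
}

#' Project spectra into a PCA model
#'
#' Returns the scores plus the two SIMCA decision statistics: Hotelling's
#' T-squared (`sum_a t_a^2 / variance_a`, the Mahalanobis distance of the
#' scores from the model center) and Q (the squared residual norm
#' orthogonal to the model subspace).
#'
#' @param m A [pca_fit()] model.
#' @param X Matrix (rows = spectra) or a single numeric vector on the model
#'   grid.
#' @return A list: `scores` (n x a), `t2` (length n), `q` (length n).
#' @export
pca_project <- function(m, X) {
  stopifnot(inherits(m, "pca_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(m$mean)) stop("X does not match the model grid")
  Xc <- sweep(as.matrix(X), 2, m$mean)
  scores <- Xc %*% t(m$loadings)
  t2 <- drop(scores^2 %*% (1 / m$variances))
  resid <- Xc - scores %*% m$loadings
  list(scores = scores, t2 = t2, q = rowSums(resid^2))
}

#' Partial least squares regression by SIMPLS
#'
#' SIMPLS deflation producing `a` latent variables for a class-indicator
#' (or general) response.  Score vectors are mutually orthogonal; the
#' prediction operator is `Yhat = (X - x_mean) B_a + y_mean` and is
#' available for every truncation `1..a` from a single fit.
#'
#' @param X Predictor matrix (n x p).
#' @param Y Response matrix (n x g), e.g. a one-hot class indicator.
#' @param a Number of latent variables.
#' @return A list of class `pls_model`: `x_mean`, `y_mean`, `weights` (R,
#'   p x a), `x_loadings` (P, p x a), `y_loadings` (Q, g x a), `scores`
#'   (T, n x a), `coefficients` (B at full `a`), `a`.
#' @export
pls_fit <- function(X, Y, a) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); g <- ncol(Y)
  stopifnot(nrow(Y) == n, a >= 1)
  if (all(apply(X, 2, stats::var) == 0)) stop("X has no variance")
  if (g > 1 && any(colSums(Y != 0) == n) && all(Y %in% c(0, 1))) {
    stop("single-class indicator: no between-class variance to model")
  }
  if (g > 1 && all(Y %in% c(0, 1)) && length(unique(max.col(Y))) < 2) {
    stop("single-class indicator: no between-class variance to model")
  }
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, p, a); P <- matrix(0, p, a)
  Q <- matrix(0, g, a); TT <- matrix(0, n, a); V <- matrix(0, p, a)
  for (i in seq_len(a)) {
    q1 <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% q1
    tt <- Xc %*% r
    tt <- tt - mean(tt)
    nt <- sqrt(sum(tt^2))
    if (nt < 1e-12) { a <- i - 1L; break }  # rank exhausted
    tt <- tt / nt; r <- r / nt
    pload <- crossprod(Xc, tt)
    qload <- crossprod(Yc, tt)
    v <- pload
    if (i > 1) {
      Vi <- V[, seq_len(i - 1), drop = FALSE]
      v <- v - Vi %*% crossprod(Vi, pload)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, i] <- r; P[, i] <- pload; Q[, i] <- qload; TT[, i] <- tt; V[, i] <- v
  }
  if (a < 1) stop("no usable latent variable (degenerate X)")
  R <- R[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]; TT <- TT[, seq_len(a), drop = FALSE]
  structure(list(x_mean = xm, y_mean = ym, weights = R, x_loadings = P,
                 y_loadings = Q, scores = TT,
                 coefficients = R %*% t(Q), a = a),
            class = "pls_model")
}

#' Predict responses (or scores) from a PLS model
#'
#' @param m A [pls_fit()] model.
#' @param X New predictor matrix or vector.
#' @param a Number of latent variables to use (default: all fitted).
#' @param type `"response"` for predicted Y, `"scores"` for latent scores.
#' @return Matrix of predictions (n x g) or scores (n x a).
#' @export
pls_predict <- function(m, X, a = NULL, type = c("response", "scores")) {
  stopifnot(inherits(m, "pls_model"))
  type <- match.arg(type)
  if (is.null(a)) a <- m$a
  stopifnot(a >= 1, a <= m$a)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xc <- sweep(as.matrix(X), 2, m$x_mean)
  Ra <- m$weights[, seq_len(a), drop = FALSE]
  if (type == "scores") return(Xc %*% Ra)
  B <- Ra %*% t(m$y_loadings[, seq_len(a), drop = FALSE])
  sweep(Xc %*% B, 2, m$y_mean, `+`)
}

#' Cross-validation scheme
#'
#' The four standard chemometric splitters: `contiguous_block` (fold j =
#' the j-th run of consecutive indices), `venetian_blind` (fold j = every
#' k-th index starting at j), `random_subset` (seeded permutation then
#' contiguous blocks) and `loo` (leave-one-out).
#'
#' @param method One of `"contiguous_block"`, `"venetian_blind"`,
#'   `"random_subset"`, `"loo"`.
#' @param n_splits Number of folds (ignored for `loo`).
#' @param seed Seed for `random_subset`.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(method = c("venetian_blind", "contiguous_block",
                                 "random_subset", "loo"),
                      n_splits = 10, seed = 1) {
  method <- match.arg(method)
  stopifnot(n_splits >= 1)
  structure(list(method = method, n_splits = as.integer(n_splits),
                 seed = seed),
            class = "cv_scheme")
}

#' Split indices into train/test folds
#'
#' Every index lands in exactly one test fold; folds are non-empty and
#' deterministic given `(n, scheme)`.
#'
#' @param n Number of observations.
#' @param scheme A [cv_scheme()].
#' @return List of folds, each `list(train = , test = )` (integer indices).
#' @export
cv_split <- function(n, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  k <- if (scheme$method == "loo") n else scheme$n_splits
  if (k > n) stop(sprintf("n_splits (%d) exceeds n (%d)", k, n))
  idx <- seq_len(n)
  test_sets <- switch(scheme$method,
    loo = as.list(idx),
    contiguous_block = lapply(seq_len(k) - 1L, function(j) {
      (floor(j * n / k) + 1L):floor((j + 1) * n / k)
    }),
    venetian_blind = lapply(seq_len(k), function(j) {
      idx[(idx - 1L) %% k == (j - 1L)]
    }),
    random_subset = {
      perm <- with_seed(scheme$seed, sample.int(n))
      lapply(seq_len(k) - 1L, function(j) {
        sort(perm[(floor(j * n / k) + 1L):floor((j + 1) * n / k)])
      })
    }
  )
  lapply(test_sets, function(te) list(train = setdiff(idx, te), test = te))
}

#' Select the number of PLS latent variables by cross-validation
#'
#' Fits SIMPLS with `max_a` latent variables on each training fold,
#' evaluates every truncation on the test fold under the chosen criterion
#' (`rmsecv`: root mean squared indicator error; `classification_error`:
#' argmax misclassification rate), and applies the one-standard-error
#' rule: the smallest `a` whose mean criterion is within one standard
#' error of the global minimum.
#'
#' @param X Predictors (n x p).
#' @param Y One-hot class-indicator responses (n x g).
#' @param scheme A [cv_scheme()].
#' @param max_a Largest latent-variable count considered.
#' @param criterion `"rmsecv"` (default) or `"classification_error"`.
#' @return A list of class `ncomp_selection`: `a` (selected count),
#'   `curve` (mean criterion, length `max_a`), `se` (fold standard error
#'   per `a`), `criterion`.
#' @export
select_ncomp <- function(X, Y, scheme = cv_scheme("venetian_blind", 10),
                         max_a = 10,
                         criterion = c("rmsecv", "classification_error")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  folds <- cv_split(n, scheme)
  max_a <- min(max_a, min(vapply(folds, function(f) length(f$train), 1L)) - 1L,
               ncol(X))
  stopifnot(max_a >= 1)
  per_fold <- matrix(NA_real_, length(folds), max_a)
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    m <- pls_fit(X[f$train, , drop = FALSE], Y[f$train, , drop = FALSE],
                 max_a)
    for (a in seq_len(max_a)) {
      aa <- min(a, m$a)
      pred <- pls_predict(m, X[f$test, , drop = FALSE], aa)
      per_fold[fi, a] <- if (criterion == "rmsecv") {
        sqrt(mean((Y[f$test, , drop = FALSE] - pred)^2))
      } else {
        truth <- max.col(Y[f$test, , drop = FALSE], ties.method = "first")
        mean(max.col(pred, ties.method = "first") != truth)
      }
    }
  }
  curve <- colMeans(per_fold)
  se <- apply(per_fold, 2, stats::sd) / sqrt(nrow(per_fold))
  best <- which.min(curve)
  a_sel <- min(which(curve <= curve[best] + se[best]))
  structure(list(a = as.integer(a_sel), curve = curve, se = se,
                 criterion = criterion),
            class = "ncomp_selection")
}
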