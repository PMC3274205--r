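#' Fit-quality summary
#'
#' @param residuals Numeric residual vector (observed minus fitted).
#' @param observed Observed values (for the total sum of squares).
#' @return A list of class `fit_quality` with `sse`, `r_square`
#'   (`1 - SSE / SS_tot` about the mean; may be negative for terrible fits,
#'   not clipped) and `rmse` (`sqrt(SSE / n)`).
#' @export
fit_quality <- function(residuals, observed) {
  sse <- sum(residuals^2)
  sst <- sum((observed - mean(observed))^2)
  structure(list(sse = sse,
                 r_square = if (sst > 0) 1 - sse / sst else NA_real_,
                 rmse = sqrt(sse / length(residuals))),
            class = "fit_quality")
}

#' Significant factor analysis rank estimation
#'
#' Eigendecomposition of the covariance of the mean-centered spectra with
#' Malinowski's factor indicator function:
#' `IND(k) = RE(k) / (c - k)^2` with
#' `RE(k) = sqrt(sum_{j>k} lambda_j / (r (c - k)))`, where — following
#' Malinowski's convention — `c` is the smaller and `r` the larger matrix
#' dimension (the indicator only develops a minimum when the `(c - k)^2`
#' term runs over the smaller dimension).  The rank estimate is the
#' minimizer of IND over `k = 1..max_k` (the indicator is unreliable near
#' the boundary `k = c - 1`).  IND is an advisory tool: on noisy real data
#' it is unstable, so signature ranks are normally fixed by configuration
#' and checked against the eigenvalue spectrum reported here.
#'
#' @param d A [spectral_dataset()] or numeric matrix (spectra in rows).
#' @param max_k Largest admissible rank (default 10).
#' @return A list of class `sfa_report`: `eigenvalues` (descending),
#'   `indicator` (IND(k), k = 1..min(r, c) - 1), `rank_estimate`, `cumvar`.
#' @export
sfa_rank <- function(d, max_k = 10) {
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  r <- nrow(X); c <- ncol(X)
  if (r < 3L) stop("SFA requires at least 3 spectra")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  lambda <- numeric(min(r, c))
  lambda[seq_along(sv)] <- sv^2 / (r - 1)
  cs <- min(r, c); rl <- max(r, c)   # Malinowski orientation
  kmax <- cs - 1L
  ind <- vapply(seq_len(kmax), function(k) {
    re <- sqrt(sum(lambda[(k + 1):length(lambda)]) / (rl * (cs - k)))
    re / (cs - k)^2
  }, 0)
  rank_est <- which.min(ind[seq_len(min(as.integer(max_k), kmax))])
  structure(list(eigenvalues = lambda, indicator = ind,
                 rank_estimate = rank_est,
                 cumvar = cumsum(lambda) / sum(lambda)),
            class = "sfa_report")
}

# exact NNLS via Lawson-Hanson; pracma returns list(x, resnorm)
nnls_solve <- function(A, b) {
  pracma::lsqnonneg(A, b)$x
}

# exact NNLS for many right-hand sides: columns whose unconstrained least
# squares solution is already feasible are optimal as-is (feasible
# stationary point of a convex problem); only the rest go through
# Lawson-Hanson.
nnls_multi <- function(A, B) {
  W <- qr.coef(qr(A), B)
  W[is.na(W)] <- 0
  bad <- which(apply(W, 2, min) < -1e-12)
  for (j in bad) W[, j] <- nnls_solve(A, B[, j])
  pmax(W, 0)
}

#' Multivariate curve resolution by non-negative alternating least squares
#'
#' Factorizes the spectra matrix `D (n x p)` as `C S` with `C (n x k)` and
#' `S (k x p)` both pointwise non-negative, alternating exact non-negative
#' least squares on each factor (Lawson-Hanson active set).
#' Initialization is the deterministic purest-variable heuristic: the
#' concentration matrix starts from the data columns (wavenumber channels)
#' that are mutually most dissimilar — each chemical component has
#' selective bands, so these channels track individual concentrations.
#' Optional seeded random restarts keep the best fit.  Components are
#' max-normalized with the compensating scale moved into the
#' concentrations.
#'
#' @param d A [spectral_dataset()] or non-negative matrix (spectra in rows).
#' @param k Number of components, `1 <= k < min(n, p)`.
#' @param max_iter Maximum alternation sweeps (default 500).
#' @param tol Relative lack-of-fit change convergence threshold
#'   (default 1e-6).
#' @param restarts Additional seeded random initializations (default 0).
#' @param seed Seed of the random restarts.
#' @param fixed Optional matrix of known fixed spectra (rows on the same
#'   axis, e.g. the constant and tilted fluorescence baseline) included in
#'   the bilinear model with unconstrained coefficients; they soak up
#'   baseline variation so the resolved chemical components stay clean.
#' @return A list of class `als_result`: `concentrations` (n x k),
#'   `components` (k x p), `fixed_weights` (n x f when `fixed` is given),
#'   `residual_history` (lack of fit `sqrt(SSE / sum(D^2))` per iteration,
#'   non-increasing), `converged`.
#' @export
als_decompose <- function(d, k, max_iter = 500, tol = 1e-6,
                          restarts = 0, seed = 1, fixed = NULL) {
  D <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  n <- nrow(D); p <- ncol(D)
  if (k < 1 || k >= min(n, p)) {
    stop(sprintf("k must satisfy 1 <= k < min(n, p) = %d", min(n, p)))
  }
  if (all(D == 0)) stop("cannot decompose all-zero data")
  if (!is.null(fixed)) {
    fixed <- as.matrix(fixed)
    stopifnot(ncol(fixed) == p)
  }
  f <- if (is.null(fixed)) 0L else nrow(fixed)
  ssd <- sum(D^2)

  run_one <- function(C0) {
    C <- C0
    Cf <- matrix(0, n, f)
    S <- matrix(0, k, p)
    history <- numeric(0)
    lof_prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      resid_fix <- if (f > 0) D - Cf %*% fixed else D
      S <- nnls_multi(C, resid_fix)
      if (f > 0) {
        # chemical weights >= 0, fixed-spectrum weights free (split +/-)
        W <- nnls_multi(t(rbind(S, fixed, -fixed)), t(D))
        C <- t(W[seq_len(k), , drop = FALSE])
        Cf <- t(W[k + seq_len(f), , drop = FALSE] -
                  W[k + f + seq_len(f), , drop = FALSE])
      } else {
        C <- t(nnls_multi(t(S), t(D)))
      }
      fit <- C %*% S + (if (f > 0) Cf %*% fixed else 0)
      lof <- sqrt(sum((D - fit)^2) / ssd)
      history <- c(history, lof)
      if (lof < 1e-10 ||
          (is.finite(lof_prev) && lof_prev - lof < tol * lof_prev)) {
        converged <- TRUE
        break
      }
      lof_prev <- lof
      dead <- which(colSums(C) == 0 | rowSums(S) == 0)
      if (length(dead)) {   # revive collapsed components from the residual
        R <- D - fit
        for (cj in dead) {
          wcol <- which.max(colSums(pmax(R, 0)^2))
          C[, cj] <- pmax(R[, wcol], 0)
          if (all(C[, cj] == 0)) C[, cj] <- 1
        }
      }
    }
    list(C = C, S = S, Cf = Cf, history = history, converged = converged)
  }

  # purest-variable initialization: greedily pick mutually dissimilar
  # data columns; their intensities seed the concentration profiles
  init_pure <- function() {
    picked <- which.max(colSums(D^2))
    for (j in seq_len(k - 1)) {
      B <- D[, picked, drop = FALSE]
      Q <- qr.Q(qr(B))
      R <- D - Q %*% crossprod(Q, D)
      cand <- setdiff(seq_len(p), picked)
      picked <- c(picked, cand[which.max(colSums(R[, cand, drop = FALSE]^2))])
    }
    D[, picked, drop = FALSE]
  }

  inits <- list(init_pure())
  if (restarts > 0) {
    inits <- c(inits, with_seed(seed, {
      lapply(seq_len(restarts), function(i) {
        matrix(stats::runif(n * k), n, k)
      })
    }))
  }
  best <- NULL
  for (C0 in inits) {
    res <- run_one(C0)
    if (is.null(best) ||
        utils::tail(res$history, 1) < utils::tail(best$history, 1)) {
      best <- res
    }
  }
  scale <- apply(best$S, 1, max)
  scale[scale == 0] <- 1
  structure(list(concentrations = sweep(best$C, 2, scale, `*`),
                 components = sweep(best$S, 1, scale, `/`),
                 fixed_weights = if (f > 0) best$Cf,
                 residual_history = best$history,
                 converged = best$converged),
            class = "als_result")
}

#' Assemble a fluid's multi-dimensional spectroscopic signature
#'
#' The signature is the fluid's resolved non-negative chemical component
#' spectra augmented with two fixed fluorescence baseline terms: a constant
#' (all-ones) and a tilted line (linear ramp 0 to 1 across the axis).  Any
#' measured spectrum of the fluid should be reproducible as a non-negative
#' combination of the components plus an unconstrained baseline
#' contribution.
#'
#' @param fluid Fluid class label.
#' @param als An [als_decompose()] result.
#' @param wavenumbers The working axis the components live on.
#' @return A list of class `raman_signature`: `fluid`, `wavenumbers`,
#'   `components` (k x p, max-normalized), `baseline` (2 x p: constant,
#'   ramp), `k`.
#' @export
build_signature <- function(fluid, als, wavenumbers) {
  stopifnot(inherits(als, "als_result"))
  p <- ncol(als$components)
  stopifnot(length(wavenumbers) == p)
  ramp <- (wavenumbers - wavenumbers[1]) /
    (wavenumbers[p] - wavenumbers[1])
  structure(list(fluid = fluid, wavenumbers = as.numeric(wavenumbers),
                 components = als$components,
                 baseline = rbind(constant = rep(1, p), tilt = ramp),
                 k = nrow(als$components)),
            class = "raman_signature")
}

#' @export
print.raman_signature <- function(x, ...) {
  cat(sprintf("<raman_signature> fluid=%s, %d components + 2 baseline terms, %d points\n",
              x$fluid, x$k, length(x$wavenumbers)))
  invisible(x)
}

#' Fit a spectrum against a signature
#'
#' Least squares with the chemical component weights constrained
#' non-negative and the two baseline weights unconstrained (solved exactly
#' by splitting each baseline term into its positive and negative part and
#' running non-negative least squares on the augmented design).  Fit
#' quality (SSE, R-squared, RMSE) is computed on the full residual.
#'
#' @param s A [raman_spectrum()] on the signature's axis.
#' @param sig A [build_signature()] result.
#' @return A list: `weights` (length k + 2: components then constant, tilt),
#'   `quality` (a [fit_quality()]), `fitted` (numeric vector).
#' @export
fit_signature <- function(s, sig) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(sig, "raman_signature"))
  if (!isTRUE(all.equal(s$wavenumbers, sig$wavenumbers))) {
    stop("spectrum axis does not match the signature grid")
  }
  A <- t(rbind(sig$components, sig$baseline, -sig$baseline))
  w <- nnls_solve(A, s$intensities)
  k <- sig$k
  weights <- c(w[seq_len(k)],
               w[k + 1] - w[k + 3],    # constant: positive minus negative part
               w[k + 2] - w[k + 4])    # tilt
  names(weights) <- c(rownames(sig$components) %||%
                        paste0("component_", seq_len(k)),
                      "constant", "tilt")
  fitted <- drop(weights %*% rbind(sig$components, sig$baseline))
  list(weights = weights,
       quality = fit_quality(s$intensities - fitted, s$intensities),
       fitted = fitted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a signature for one fluid from a dataset
#'
#' Convenience wrapper: subsets the fluid's spectra, runs
#' [als_decompose()] with `k` chemical components on the (despiked, raw)
#' intensities — by default with the constant and tilted baseline spectra
#' included as fixed free-coefficient terms, so fluorescence variation
#' never contaminates the chemical components — and appends the baseline
#' terms to the signature.  The reference ranks are semen 3, blood 2,
#' saliva 3.
#'
#' @param d A [spectral_dataset()].
#' @param fluid Fluid to model.
#' @param k Number of chemical components.
#' @param baseline Include the fixed baseline terms in the decomposition
#'   (default `TRUE`).
#' @param ... Passed to [als_decompose()].
#' @return A `raman_signature`.
#' @export
fluid_signature <- function(d, fluid, k, baseline = TRUE, ...) {
  idx <- d$fluid == fluid
  if (!any(idx)) stop("no spectra labelled '", fluid, "'")
  p <- ncol(d$intensities)
  fixed <- if (baseline) {
    rbind(rep(1, p),
          (d$wavenumbers - d$wavenumbers[1]) /
            (d$wavenumbers[p] - d$wavenumbers[1]))
  }
  als <- als_decompose(d$intensities[idx, , drop = FALSE], k,
                       fixed = fixed, ...)
  build_signature(fluid, als, d$wavenumbers)
}
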