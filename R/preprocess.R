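#' Remove cosmic-ray spikes from a spectrum
#'
#' Cosmic rays hit CCD detectors as isolated one- or two-channel intensity
#' spikes.  Points are flagged when the modified z-score of the first
#' difference, computed within a rolling window, exceeds `z_thresh`; flagged
#' points are replaced by the median of their window.
#'
#' @param s A [raman_spectrum()].
#' @param window Odd rolling-window width, >= 3 (default 11).
#' @param z_thresh Positive modified z-score threshold (default 8).
#' @return A despiked [raman_spectrum()].
#' @export
despike <- function(s, window = 11, z_thresh = 8) {
  stopifnot(inherits(s, "raman_spectrum"))
  n <- length(s$intensities)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (window >= n) stop("window must be smaller than the spectrum length")
  if (z_thresh <= 0) stop("z_thresh must be positive")
  y <- s$intensities
  dy <- c(0, diff(y))
  half <- (window - 1L) %/% 2L
  spike <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- dy[lo:hi]
    med <- stats::median(w)
    mad <- stats::median(abs(w - med))
    if (mad == 0) mad <- .Machine$double.eps
    # 0.6745 = Phi^-1(0.75): scales MAD to a sd-consistent estimate
    if (abs(0.6745 * (dy[i] - med) / mad) > z_thresh) spike[i] <- TRUE
  }
  # a spike contaminates the difference at its own and the following channel
  spike <- spike | c(spike[-1], FALSE)
  out <- y
  for (i in which(spike)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    keep <- setdiff(lo:hi, which(spike))
    if (!length(keep)) keep <- lo:hi
    out[i] <- stats::median(y[keep])
  }
  raman_spectrum(s$wavenumbers, out, s$meta)
}

#' Resample a spectrum onto a target grid by linear interpolation
#'
#' Extrapolation is forbidden: the target grid must lie inside the
#' spectrum's wavenumber support.
#'
#' @param s A [raman_spectrum()].
#' @param grid Strictly increasing target axis within `range(s$wavenumbers)`.
#' @return The resampled [raman_spectrum()].
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "raman_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavenumbers) || max(grid) > max(s$wavenumbers)) {
    stop(sprintf("grid [%.6g, %.6g] outside spectrum support [%.6g, %.6g]",
                 min(grid), max(grid),
                 min(s$wavenumbers), max(s$wavenumbers)))
  }
  it <- stats::approx(s$wavenumbers, s$intensities, xout = grid,
                      method = "linear", ties = "ordered")$y
  raman_spectrum(grid, it, s$meta)
}

#' Normalize a spectrum
#'
#' `"vector"` scales to unit Euclidean norm; `"area"` scales so the
#' trapezoidal integral over the axis equals 1.
#'
#' @param s A [raman_spectrum()].
#' @param mode `"vector"` (default) or `"area"`.
#' @return The normalized [raman_spectrum()].
#' @export
normalize_spectrum <- function(s, mode = c("vector", "area")) {
  stopifnot(inherits(s, "raman_spectrum"))
  mode <- match.arg(mode)
  y <- s$intensities
  if (all(y == 0)) stop("cannot normalize an all-zero spectrum")
  sc <- switch(mode,
    vector = sqrt(sum(y^2)),
    area   = trapz_integral(s$wavenumbers, y)
  )
  if (sc == 0) stop("normalization constant is zero in mode '", mode, "'")
  raman_spectrum(s$wavenumbers, y / sc, s$meta)
}

trapz_integral <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Normalize every row of a dataset
#'
#' @param d A [spectral_dataset()].
#' @param mode Passed to [normalize_spectrum()].
#' @return The normalized [spectral_dataset()].
#' @export
normalize_dataset <- function(d, mode = c("vector", "area")) {
  mode <- match.arg(mode)
  X <- d$intensities
  sc <- if (mode == "vector") {
    sqrt(rowSums(X^2))
  } else {
    apply(X, 1, function(y) trapz_integral(d$wavenumbers, y))
  }
  if (any(sc == 0)) stop("cannot normalize all-zero spectra (rows ",
                         paste(which(sc == 0), collapse = ","), ")")
  spectral_dataset(X / sc, d$wavenumbers, d$fluid, d$donor, d$spot)
}

#' Average the spectra of each sample
#'
#' Collapses all spots acquired on the same dry trace to their pointwise
#' mean, yielding one spectrum per (fluid, donor) pair.  Averaging across
#' spots suppresses the spot-to-spot heterogeneity of dry traces and is the
#' single most effective preprocessing step for SIMCA discrimination.
#'
#' @param d A [spectral_dataset()] with donor ids populated.
#' @return A [spectral_dataset()] with one row per sample (`spot` set to
#'   `"avg"`).
#' @export
average_per_sample <- function(d) {
  if (anyNA(d$donor)) stop("donor ids must be populated for averaging")
  key <- paste(d$fluid, d$donor, sep = "\r")
  groups <- split(seq_along(key), key)
  groups <- groups[order(vapply(groups, min, 1L))]  # preserve first-seen order
  X <- t(vapply(groups, function(idx) {
    colMeans(d$intensities[idx, , drop = FALSE])
  }, numeric(ncol(d$intensities))))
  first <- vapply(groups, min, 1L)
  spectral_dataset(X, d$wavenumbers, d$fluid[first], d$donor[first],
                   rep("avg", length(groups)))
}

#' Per-class difference spectra
#'
#' Computes the grand mean spectrum and, for each fluid class, the deviation
#' of that class's mean from the grand mean.  These difference traces locate
#' the wavenumbers that carry discriminating intensity.
#'
#' @param d A [spectral_dataset()] with at least two classes.
#' @return A list with `wavenumbers`, `grand_mean` (numeric vector),
#'   `differences` (matrix, one row per class) and `classes`.
#' @export
difference_spectra <- function(d) {
  classes <- sort(unique(d$fluid))
  if (length(classes) < 2L) {
    stop("difference spectra require at least two classes")
  }
  grand <- colMeans(d$intensities)
  diffs <- t(vapply(classes, function(cl) {
    colMeans(d$intensities[d$fluid == cl, , drop = FALSE]) - grand
  }, numeric(ncol(d$intensities))))
  rownames(diffs) <- classes
  list(wavenumbers = d$wavenumbers, grand_mean = grand,
       differences = diffs, classes = classes)
}
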