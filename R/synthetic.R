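#' Default working wavenumber grid
#'
#' 300-1800 cm^-1 in 2 cm^-1 steps (751 points): covers every published band
#' of the three fluids' chemical components (smallest 323, largest
#' 1744 cm^-1).
#'
#' @return Numeric axis of length 751.
#' @export
default_grid <- function() seq(300, 1800, by = 2)

# Published band positions (cm^-1) of the chemical components that dominate
# each fluid's resolved Raman spectra.
COMPONENT_PEAKS <- list(
  semen = list(
    tyrosine = c(641, 798, 829, 848, 983, 1179, 1200, 1213, 1265, 1327, 1616),
    protein  = c(715, 759, 1003, 1240, 1336, 1448, 1668),
    sph      = c(888, 958, 1011, 1055, 1065, 1125, 1317, 1461, 1494)
  ),
  blood = list(
    hemoglobin = c(1000, 1368, 1542, 1620),
    fibrin     = c(967, 1248, 1342)
  ),
  saliva = list(
    mucin    = c(1002, 1444, 1653),
    acetate  = c(323, 521, 632, 1295, 1434, 1744),
    arginine = c(544, 919, 991)
  )
)

#' Peak specification
#'
#' @param center Band center in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1, > 0.
#' @param amplitude Relative height, > 0.
#' @return A list of class `peak_spec`.
#' @export
peak_spec <- function(center, fwhm = 12, amplitude = 1) {
  stopifnot(fwhm > 0, amplitude > 0)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude),
            class = "peak_spec")
}

#' Chemical component specification
#'
#' @param name Component name (e.g. `"hemoglobin"`).
#' @param fluid Fluid class the component belongs to.
#' @param peaks List of [peak_spec()] objects (at least one).
#' @return A list of class `component_spec`.
#' @export
component_spec <- function(name, fluid, peaks) {
  stopifnot(length(peaks) >= 1L,
            all(vapply(peaks, inherits, TRUE, "peak_spec")))
  structure(list(name = name, fluid = fluid, peaks = peaks),
            class = "component_spec")
}

#' Render a component spectrum from its peak list
#'
#' Each band is a Lorentzian line
#' \eqn{L(\nu) = A (\Gamma/2)^2 / ((\nu - c)^2 + (\Gamma/2)^2)}; the sum over
#' bands is max-normalized to 1.
#'
#' @param spec A [component_spec()].
#' @param grid Wavenumber axis.
#' @return A [raman_spectrum()], non-negative with maximum 1.
#' @export
make_component <- function(spec, grid) {
  stopifnot(inherits(spec, "component_spec"))
  grid <- as.numeric(grid)
  centers <- vapply(spec$peaks, `[[`, 0, "center")
  if (any(centers < min(grid) | centers > max(grid))) {
    stop(sprintf("component '%s' has peak(s) outside the grid: %s",
                 spec$name,
                 paste(centers[centers < min(grid) | centers > max(grid)],
                       collapse = ", ")))
  }
  y <- numeric(length(grid))
  for (p in spec$peaks) {
    hw2 <- (p$fwhm / 2)^2
    y <- y + p$amplitude * hw2 / ((grid - p$center)^2 + hw2)
  }
  raman_spectrum(grid, y / max(y),
                 meta = list(fluid = spec$fluid, donor = spec$name))
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' The fluid component library
#'
#' Builds the eight chemical components of the three fluids (semen:
#' tyrosine-, protein- and spermine-phosphate-like; blood: hemoglobin- and
#' fibrin-like; saliva: mucin-, acetate/carbohydrate- and arginine-like)
#' from their published band positions.  Relative band amplitudes are drawn
#' log-uniformly in \[0.2, 1\] from a frozen library seed, and each component
#' receives low-amplitude copies (10-30%) of its sibling components' bands
#' (curve-resolved components always show this cross-mixing).
#'
#' @param grid Wavenumber axis (default [default_grid()]).
#' @param fwhm Lorentzian FWHM in cm^-1 (default 12, typical for dry-phase
#'   biological Raman bands).
#' @param library_seed Frozen seed of the amplitude draw (default 101);
#'   change only to study a different amplitude realization.
#' @return A named list per fluid, each element a list of
#'   [raman_spectrum()] components (named by chemical identity), with
#'   attribute `specs` holding the [component_spec()] objects.
#' @export
component_library <- function(grid = default_grid(), fwhm = 12,
                              library_seed = 101) {
  specs <- with_seed(library_seed, {
    out <- list()
    for (fluid in names(COMPONENT_PEAKS)) {
      comps <- COMPONENT_PEAKS[[fluid]]
      amps <- lapply(comps, function(ctrs) {
        exp(stats::runif(length(ctrs), log(0.2), log(1)))
      })
      for (nm in names(comps)) {
        peaks <- mapply(function(c, a) peak_spec(c, fwhm, a),
                        comps[[nm]], amps[[nm]], SIMPLIFY = FALSE)
        for (other in setdiff(names(comps), nm)) {
          mix <- stats::runif(1, 0.1, 0.3)
          peaks <- c(peaks, mapply(function(c, a) peak_spec(c, fwhm, mix * a),
                                   comps[[other]], amps[[other]],
                                   SIMPLIFY = FALSE))
        }
        out[[fluid]][[nm]] <- component_spec(nm, fluid, peaks)
      }
    }
    out
  })
  lib <- lapply(specs, function(fl) lapply(fl, make_component, grid = grid))
  attr(lib, "specs") <- specs
  lib
}

#' Simulation configuration
#'
#' Defaults reproduce the package's reference study conditions: 17 donors
#' per fluid, 10 spots per dry trace, peak signal-to-noise ratio 25,
#' Dirichlet concentration 50 for donor-level abundances, fluorescence
#' baseline up to 0.3 x the signal maximum, spot-level lognormal sigma 0.15
#' (doubled for saliva, whose dry traces are markedly more heterogeneous).
#'
#' @param n_samples_per_fluid Donors per fluid (scalar or named per fluid).
#' @param spots_per_sample Spots per dry trace: a scalar, a length-2 range
#'   (spot counts drawn uniformly, e.g. `c(16, 36)` for mapping-stage
#'   acquisition), or a named list of explicit per-sample spot-count vectors.
#' @param peak_snr Ratio of the spot's maximum chemical signal to the
#'   additive Gaussian noise standard deviation.
#' @param donor_variability Dirichlet concentration of donor-level component
#'   abundances (larger = more similar donors).
#' @param baseline_strength Fluorescence baseline scale as a fraction of the
#'   signal maximum.
#' @param spot_sigma Spot-level lognormal abundance jitter (0 disables).
#' @param seed Integer RNG seed.
#' @param fluids Fluid classes to simulate.
#' @param grid Wavenumber axis.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_fluid = 17, spots_per_sample = 10,
                       peak_snr = 25, donor_variability = 50,
                       baseline_strength = 0.3, spot_sigma = 0.15,
                       seed = 42, fluids = c("blood", "saliva", "semen"),
                       grid = default_grid()) {
  stopifnot(all(unlist(n_samples_per_fluid) >= 1),
            peak_snr > 0, donor_variability > 0,
            baseline_strength >= 0, spot_sigma >= 0,
            all(fluids %in% c("blood", "saliva", "semen")))
  if (is.numeric(spots_per_sample)) {
    stopifnot(all(spots_per_sample >= 1), all(spots_per_sample <= 100))
  }
  structure(list(n_samples_per_fluid = n_samples_per_fluid,
                 spots_per_sample = spots_per_sample, peak_snr = peak_snr,
                 donor_variability = donor_variability,
                 baseline_strength = baseline_strength,
                 spot_sigma = spot_sigma, seed = seed, fluids = fluids,
                 grid = as.numeric(grid)),
            class = "sim_config")
}

# donor-level mean mixing proportions and total intensities (counts);
# hemoglobin dominates dried blood, with a smaller coagulation (fibrin) share
FLUID_BASE_MIX <- list(
  semen  = c(tyrosine = 0.45, protein = 0.35, sph = 0.20),
  blood  = c(hemoglobin = 0.75, fibrin = 0.25),
  saliva = c(mucin = 0.40, acetate = 0.35, arginine = 0.25)
)
FLUID_TOTAL_INTENSITY <- c(semen = 100, blood = 120, saliva = 80)

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate one spot spectrum
#'
#' A spot is a non-negative mixture of the fluid's component spectra with
#' spot-level lognormal jitter around the sample abundances, a fluorescence
#' baseline (constant plus tilted line), and additive Gaussian detector
#' noise with standard deviation `max(signal)/peak_snr`.  Intensities are
#' clipped at zero.
#'
#' @param fluid Fluid class.
#' @param sample_abundance Non-negative component weights for this sample
#'   (length = number of that fluid's components).
#' @param cfg A [sim_config()].
#' @param library Component library from [component_library()] (rebuilt on
#'   `cfg$grid` when omitted).
#' @param baseline Optional fixed baseline coefficients `c(b0, b1)`:
#'   intensity adds `b0 + b1 * (v - v_min)/(v_max - v_min)`.  When `NULL`,
#'   coefficients are drawn per spot scaled by
#'   `baseline_strength * max(signal)`.
#' @return A [raman_spectrum()].
#' @export
simulate_spot <- function(fluid, sample_abundance, cfg = sim_config(),
                          library = NULL, baseline = NULL) {
  if (is.null(library)) library <- component_library(cfg$grid)
  comps <- library[[fluid]]
  if (is.null(comps)) stop("no components for fluid '", fluid, "'")
  w <- as.numeric(sample_abundance)
  if (length(w) != length(comps)) {
    stop(sprintf("fluid '%s' has %d components but %d weights were given",
                 fluid, length(comps), length(w)))
  }
  if (any(w < 0)) stop("mixing weights must be non-negative")
  sigma <- cfg$spot_sigma * if (fluid == "saliva") 2 else 1
  if (sigma > 0) w <- w * exp(stats::rnorm(length(w), 0, sigma))
  S <- do.call(rbind, lapply(comps, `[[`, "intensities"))
  signal <- drop(w %*% S)
  smax <- max(signal)
  grid <- cfg$grid
  ramp <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  if (is.null(baseline)) {
    b0 <- stats::runif(1, 0.2, 1) * cfg$baseline_strength * smax
    b1 <- stats::runif(1, -0.5, 0.5) * b0
  } else {
    b0 <- baseline[1]; b1 <- baseline[2]
  }
  y <- signal + b0 + b1 * ramp
  if (is.finite(cfg$peak_snr) && smax > 0) {
    y <- y + stats::rnorm(length(y), 0, smax / cfg$peak_snr)
  }
  raman_spectrum(grid, pmax(y, 0), meta = list(fluid = fluid))
}

resolve_spots <- function(cfg, fluid, n_samples) {
  sp <- cfg$spots_per_sample
  if (is.list(sp)) {
    v <- sp[[fluid]]
    if (is.null(v)) stop("spots_per_sample list lacks fluid '", fluid, "'")
    if (length(v) != n_samples) {
      stop(sprintf("fluid '%s': %d spot counts for %d samples",
                   fluid, length(v), n_samples))
    }
    return(as.integer(v))
  }
  if (length(sp) == 2L && sp[1] != sp[2]) {
    return(sample(seq(sp[1], sp[2]), n_samples, replace = TRUE))
  }
  rep(as.integer(sp[1]), n_samples)
}

#' Simulate a multi-donor multi-spot dataset
#'
#' For each fluid, donor-level component abundances are drawn from a
#' Dirichlet distribution (concentration `donor_variability` times the
#' fluid's mean mixing proportions) scaled by a fluid-specific total
#' intensity with 10% lognormal donor variation; each donor contributes
#' `spots_per_sample` spot spectra via [simulate_spot()].  Fully
#' reproducible under a fixed seed; the caller's RNG stream is untouched.
#'
#' @param cfg A [sim_config()].
#' @return A [spectral_dataset()] with fluid, donor and spot annotation.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  library <- component_library(cfg$grid)
  with_seed(cfg$seed, {
    spectra <- list()
    for (fluid in cfg$fluids) {
      n_samples <- if (length(cfg$n_samples_per_fluid) > 1L ||
                       !is.null(names(cfg$n_samples_per_fluid))) {
        cfg$n_samples_per_fluid[[fluid]]
      } else cfg$n_samples_per_fluid
      spots <- resolve_spots(cfg, fluid, n_samples)
      base <- FLUID_BASE_MIX[[fluid]]
      total <- FLUID_TOTAL_INTENSITY[[fluid]]
      for (j in seq_len(n_samples)) {
        abund <- rdirichlet1(cfg$donor_variability * base) *
          total * exp(stats::rnorm(1, 0, 0.1))
        donor <- sprintf("%s_%02d", fluid, j)
        for (k in seq_len(spots[j])) {
          s <- simulate_spot(fluid, abund, cfg, library)
          s$meta$donor <- donor
          s$meta$spot <- as.character(k)
          spectra[[length(spectra) + 1L]] <- s
        }
      }
    }
    dataset_from_spectra(spectra)
  })
}

#' Per-sample spot counts matching the reference acquisition totals
#'
#' Explicit spot-count lists giving 170 blood (17 x 10), 252 saliva and 693
#' semen spectra — 1115 in total.  The saliva/semen compositions are one
#' integer partition consistent with those totals; pass your own list to
#' [sim_config()] for a different one.
#'
#' @return Named list of integer vectors.
#' @export
reference_spot_lists <- function() {
  list(blood  = rep(10L, 17),
       saliva = c(rep(15L, 14), rep(14L, 3)),
       semen  = c(rep(14L, 43), rep(13L, 7)))
}

#' Corrupt a dataset with extra noise and background
#'
#' Emulates degraded field measurements: adds Gaussian noise scaled by
#' `noise_factor` times each spectrum's maximum, and a broad random Gaussian
#' fluorescence hump (center uniform on the axis, FWHM uniform in 400-800
#' cm^-1) scaled by `background_factor` times the spectrum maximum.  The
#' random draws depend only on `seed`, so the same seed with larger factors
#' yields proportionally larger corruption.  The input is unchanged.
#'
#' @param d A [spectral_dataset()].
#' @param noise_factor,background_factor Non-negative scale factors.
#' @param seed Integer seed.
#' @return The corrupted [spectral_dataset()].
#' @export
inject_corruption <- function(d, noise_factor = 0, background_factor = 0,
                              seed = 1) {
  stopifnot(is.finite(noise_factor), is.finite(background_factor),
            noise_factor >= 0, background_factor >= 0)
  X <- d$intensities
  p <- ncol(X)
  wn <- d$wavenumbers
  with_seed(seed, {
    for (i in seq_len(nrow(X))) {
      noise <- stats::rnorm(p)
      center <- stats::runif(1, min(wn), max(wn))
      fwhm <- stats::runif(1, 400, 800)
      hump <- exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
      m <- max(X[i, ])
      X[i, ] <- X[i, ] + noise_factor * m * noise + background_factor * m * hump
    }
  })
  spectral_dataset(X, wn, d$fluid, d$donor, d$spot)
}
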