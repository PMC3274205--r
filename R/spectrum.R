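#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is a single trace on a wavenumber axis (cm^-1) with
#' intensities in arbitrary detector counts and provenance metadata.
#'
#' @param wavenumbers Numeric, strictly increasing axis in cm^-1, length >= 2.
#' @param intensities Numeric intensities, same length as `wavenumbers`.
#' @param meta Named list of metadata; recognised fields are `fluid`
#'   (`"blood"`, `"saliva"`, `"semen"` or `"unknown"`), `donor`, `spot` and
#'   `source_file`.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities` and `meta`.
#' @examples
#' s <- raman_spectrum(seq(400, 500, 2), rexp(51), meta = list(fluid = "blood"))
#' print(s)
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length")
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points")
  }
  if (anyNA(wavenumbers) || anyNA(intensities)) {
    stop("NA values are not allowed in a spectrum")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumber axis must be strictly increasing")
  }
  meta <- utils::modifyList(
    list(fluid = "unknown", donor = NA_character_, spot = NA_character_,
         source_file = NA_character_),
    as.list(meta)
  )
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm^-1, fluid=%s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$meta$fluid))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

VALID_FLUIDS <- c("blood", "saliva", "semen", "unknown")

#' Read a spectrum from a two-column text file
#'
#' Expects comma- or whitespace-separated numeric columns (wavenumber cm^-1,
#' intensity counts); lines starting with `#` are ignored.  A descending axis
#' is reversed (with the intensities) so the returned axis is ascending.
#'
#' @param path Path to the spectrum file.
#' @param meta Metadata list passed to [raman_spectrum()]; `source_file` is
#'   filled in automatically.
#' @return A [raman_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, meta = list()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) {
    stop("spectrum file has fewer than 2 data rows: ", path)
  }
  parts <- strsplit(trimws(lines), "[,\t ]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  )
  bad <- union(bad, which(colSums(is.na(vals)) > 0))
  if (length(bad)) {
    stop(sprintf("non-numeric spectrum row in %s at line %d: '%s'",
                 path, lineno[min(bad)], lines[min(bad)]))
  }
  wn <- vals[1, ]
  it <- vals[2, ]
  if (wn[1] > wn[length(wn)]) {   # descending acquisition
    wn <- rev(wn)
    it <- rev(it)
  }
  meta$source_file <- path
  raman_spectrum(wn, it, meta)
}

#' Write a spectrum as two-column CSV
#'
#' @param s A [raman_spectrum()].
#' @param path Output file path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, digits = 10) {
  stopifnot(inherits(s, "raman_spectrum"))
  lines <- sprintf("%s,%s",
                   formatC(s$wavenumbers, digits = digits, format = "g"),
                   formatC(s$intensities, digits = digits, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds spectra that share one wavenumber axis as the
#' rows of a matrix, together with per-row fluid labels, donor ids and spot
#' ids.  It is the exchange object of the whole pipeline.
#'
#' @param intensities Numeric matrix, one spectrum per row.
#' @param wavenumbers Shared axis, length = `ncol(intensities)`.
#' @param fluid Character vector of class labels (subset of
#'   blood/saliva/semen/unknown), one per row.
#' @param donor,spot Character vectors of donor and spot ids, one per row.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(intensities, wavenumbers, fluid,
                             donor = NULL, spot = NULL) {
  intensities <- as.matrix(intensities)
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(intensities)
  if (ncol(intensities) != length(wavenumbers)) {
    stop("ncol(intensities) must equal length(wavenumbers)")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumber axis must be strictly increasing")
  }
  fluid <- as.character(fluid)
  if (length(fluid) != n) stop("one fluid label per spectrum required")
  bad <- setdiff(unique(fluid), VALID_FLUIDS)
  if (length(bad)) {
    stop("unknown fluid label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(VALID_FLUIDS, collapse = ", "), ")")
  }
  donor <- if (is.null(donor)) rep(NA_character_, n) else as.character(donor)
  spot  <- if (is.null(spot))  rep(NA_character_, n) else as.character(spot)
  if (length(donor) != n || length(spot) != n) {
    stop("donor and spot must have one entry per spectrum")
  }
  dimnames(intensities) <- NULL
  structure(list(intensities = intensities, wavenumbers = wavenumbers,
                 fluid = fluid, donor = donor, spot = spot),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  tab <- table(x$fluid)
  cat(sprintf("<spectral_dataset> %d spectra x %d points (%.0f-%.0f cm^-1)\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Extract one row of a dataset as a spectrum
#'
#' @param d A [spectral_dataset()].
#' @param i Row index.
#' @return A [raman_spectrum()].
#' @export
dataset_spectrum <- function(d, i) {
  raman_spectrum(d$wavenumbers, d$intensities[i, ],
                 meta = list(fluid = d$fluid[i], donor = d$donor[i],
                             spot = d$spot[i]))
}

#' Subset the rows of a dataset
#'
#' @param d A [spectral_dataset()].
#' @param idx Integer or logical row index.
#' @return A [spectral_dataset()] with the selected rows.
#' @export
dataset_subset <- function(d, idx) {
  spectral_dataset(d$intensities[idx, , drop = FALSE], d$wavenumbers,
                   d$fluid[idx], d$donor[idx], d$spot[idx])
}

#' Stack spectra sharing an axis into a dataset
#'
#' @param spectra List of [raman_spectrum()] objects on the identical axis.
#' @return A [spectral_dataset()].
#' @export
dataset_from_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  wn <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavenumbers, wn))) {
      stop("all spectra must share an identical axis; resample first")
    }
  }
  spectral_dataset(
    do.call(rbind, lapply(spectra, function(s) s$intensities)), wn,
    vapply(spectra, function(s) s$meta$fluid, ""),
    vapply(spectra, function(s) as.character(s$meta$donor), ""),
    vapply(spectra, function(s) as.character(s$meta$spot), "")
  )
}

#' Load a dataset from a manifest file
#'
#' The manifest is a header CSV with columns `file,fluid,donor,spot`; each
#' `file` is a two-column spectrum CSV readable by [read_spectrum()].
#' Spectra whose axes differ are linearly interpolated onto the intersection
#' grid (the densest axis restricted to the common wavenumber range).
#'
#' @param manifest Path to the manifest CSV.
#' @param base_dir Directory against which relative `file` entries are
#'   resolved; defaults to the manifest's directory.
#' @return A [spectral_dataset()].
#' @export
load_dataset <- function(manifest, base_dir = dirname(manifest)) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                       comment.char = "#")
  need <- c("file", "fluid", "donor", "spot")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ","))
  }
  bad <- setdiff(unique(m$fluid), VALID_FLUIDS)
  if (length(bad)) {
    rows <- which(m$fluid %in% bad)
    stop("manifest rows ", paste(rows, collapse = ","),
         " carry unknown fluid label(s): ", paste(bad, collapse = ", "))
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", m$file), m$file,
                  file.path(base_dir, m$file))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("manifest rows ", paste(which(missing), collapse = ","),
         " reference missing files: ",
         paste(utils::head(paths[missing], 5), collapse = ", "))
  }
  spectra <- lapply(seq_len(nrow(m)), function(i) {
    read_spectrum(paths[i], meta = list(fluid = m$fluid[i],
                                        donor = m$donor[i], spot = m$spot[i]))
  })
  lo <- max(vapply(spectra, function(s) min(s$wavenumbers), 0))
  hi <- min(vapply(spectra, function(s) max(s$wavenumbers), 0))
  if (lo > hi) stop("spectra have no common wavenumber range")
  # densest axis restricted to the common range defines the shared grid
  dens <- which.max(vapply(spectra, function(s) {
    sum(s$wavenumbers >= lo & s$wavenumbers <= hi)
  }, 0))
  grid <- spectra[[dens]]$wavenumbers
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L) stop("spectra have no common wavenumber range")
  spectra <- lapply(spectra, resample_to_grid, grid = grid)
  dataset_from_spectra(spectra)
}

#' Write a dataset as spectrum CSVs plus a manifest
#'
#' @param d A [spectral_dataset()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(d$intensities)
  files <- sprintf("spectrum_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    write_spectrum(dataset_spectrum(d, i), file.path(dir, files[i]))
  }
  manifest <- data.frame(file = files, fluid = d$fluid, donor = d$donor,
                         spot = d$spot, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
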