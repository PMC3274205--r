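test_that("spectrum construction enforces its invariants", {
  expect_error(raman_spectrum(c(400, 400), c(1, 2)), "strictly increasing")
  expect_error(raman_spectrum(400, 1), "at least 2")
  expect_error(raman_spectrum(c(400, 401), c(1, 2, 3)), "equal length")
  s <- raman_spectrum(c(400, 401), c(1, 2))
  expect_identical(s$meta$fluid, "unknown")
})

test_that("spectrum files parse, reverse descending axes, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "400,10", "401,12"), f)
  s <- read_spectrum(f)
  expect_equal(s$wavenumbers, c(400, 401))
  expect_equal(s$intensities, c(10, 12))

  writeLines(c("500,1", "499,2", "498,3"), f)
  s <- read_spectrum(f)
  expect_equal(s$wavenumbers, c(498, 499, 500))
  expect_equal(s$intensities, c(3, 2, 1))

  writeLines(c("400,10", "401,abc"), f)
  expect_error(read_spectrum(f), "non-numeric.*line 2")
  writeLines("400,10", f)
  expect_error(read_spectrum(f), "fewer than 2")

  orig <- raman_spectrum(seq(300, 310), sqrt(seq(0.1, 10.1)))
  write_spectrum(orig, f)
  back <- read_spectrum(f)
  expect_equal(back$wavenumbers, orig$wavenumbers, tolerance = 1e-6)
  expect_equal(back$intensities, orig$intensities, tolerance = 1e-6)
})

test_that("despiking removes spikes and leaves genuine bands alone", {
  x <- seq(400, 600, by = 2)
  flat <- raman_spectrum(x, rep(10, length(x)))
  spiked <- flat
  spiked$intensities[40] <- 1000
  out <- despike(spiked)
  expect_lt(max(abs(out$intensities - 10)) / 10, 0.01)

  # a genuine Lorentzian band (FWHM 10) must survive untouched
  peak <- raman_spectrum(x, 5 + 100 * lorentzian(x, 500, 10))
  expect_equal(despike(peak, z_thresh = 8)$intensities, peak$intensities)

  # two adjacent spike channels need window >= 5
  two <- flat
  two$intensities[50:51] <- c(800, 900)
  out2 <- despike(two, window = 7)
  expect_lt(max(abs(out2$intensities - 10)) / 10, 0.01)

  # idempotence
  once <- despike(spiked)
  expect_equal(despike(once)$intensities, once$intensities)

  expect_error(despike(flat, window = 4), "odd")
  expect_error(despike(raman_spectrum(1:4, 1:4), window = 5), "smaller")
})

test_that("grid resampling is exact for identity, linear and Lorentzian cases", {
  x <- seq(400, 500, by = 1)
  ramp <- raman_spectrum(x, 2 * x + 3)
  expect_equal(resample_to_grid(ramp, x)$intensities, ramp$intensities)

  mid <- seq(400.5, 499.5, by = 1)
  expect_equal(resample_to_grid(ramp, mid)$intensities, 2 * mid + 3)

  lor <- raman_spectrum(x, lorentzian(x, 450, 10))
  coarse <- seq(400, 500, by = 2)
  err <- max(abs(resample_to_grid(lor, coarse)$intensities -
                   lorentzian(coarse, 450, 10)))
  expect_lt(err, 0.005)   # < 0.5% of unit peak height

  expect_error(resample_to_grid(lor, seq(390, 500, 2)), "outside")
})

test_that("normalization modes hit their closed forms and are idempotent", {
  s <- raman_spectrum(c(100, 200), c(3, 4))
  expect_equal(normalize_spectrum(s)$intensities, c(0.6, 0.8))
  expect_equal(normalize_spectrum(normalize_spectrum(s))$intensities,
               c(0.6, 0.8))

  # scale invariance
  s2 <- raman_spectrum(c(100, 200), 37.5 * c(3, 4))
  expect_equal(normalize_spectrum(s2)$intensities, c(0.6, 0.8))

  # uniform spectrum over span W integrates to W => constant 1/W
  x <- seq(0, 10, 0.5)
  u <- raman_spectrum(x, rep(7, length(x)))
  expect_equal(normalize_spectrum(u, "area")$intensities,
               rep(1 / 10, length(x)))

  expect_error(normalize_spectrum(raman_spectrum(1:3, c(0, 0, 0))),
               "all-zero")
})

test_that("per-sample averaging collapses spots and preserves grand means", {
  wn <- seq(400, 410, 2)
  X <- rbind(rep(0, 6), rep(2, 6), rep(5, 6), rep(5, 6))
  d <- spectral_dataset(X, wn, rep(c("blood", "semen"), each = 2),
                        donor = c("d1", "d1", "d2", "d2"),
                        spot = c("1", "2", "1", "2"))
  avg <- average_per_sample(d)
  expect_equal(dim(avg$intensities), c(2L, 6L))
  expect_equal(avg$intensities[1, ], rep(1, 6))
  expect_equal(avg$intensities[2, ], rep(5, 6))
  expect_equal(avg$fluid, c("blood", "semen"))

  # equal spot counts: averaging samples then averaging rows = grand mean
  d2 <- small_dataset(n_per = 3, spots = 4)
  a2 <- average_per_sample(d2)
  expect_equal(colMeans(a2$intensities), colMeans(d2$intensities),
               tolerance = 1e-12)

  # 17 samples x 10 spots per fluid collapses to 51 sample spectra
  expect_equal(nrow(average_per_sample(default_study_dataset())$intensities),
               51L)
})

test_that("difference spectra are centered, symmetric and peak-located", {
  wn <- seq(400, 410, 2)
  m1 <- c(1, 2, 3, 4, 5, 6); m2 <- c(6, 5, 4, 3, 2, 1)
  d <- spectral_dataset(rbind(m1, m1, m2, m2), wn,
                        rep(c("blood", "semen"), each = 2),
                        donor = c("a", "b", "c", "d"))
  ds <- difference_spectra(d)
  expect_equal(ds$differences["blood", ], (m1 - m2) / 2)
  expect_equal(ds$differences["semen", ], (m2 - m1) / 2)

  # identical classes give a zero trace
  d0 <- spectral_dataset(rbind(m1, m1), wn, c("blood", "semen"),
                         donor = c("a", "b"))
  expect_equal(max(abs(difference_spectra(d0)$differences)), 0)

  expect_error(difference_spectra(dataset_subset(d, 1:2)), "two classes")

  # class-size-weighted differences sum to zero
  dd <- small_dataset()
  dsd <- difference_spectra(dd)
  wts <- as.numeric(table(dd$fluid)[dsd$classes])
  resid <- colSums(dsd$differences * wts) / sum(wts)
  expect_lt(max(abs(resid)) / max(abs(dsd$grand_mean)), 1e-10)

  # each fluid's difference trace peaks at one of that fluid's band positions
  dn <- normalize_dataset(default_study_dataset())
  dsn <- difference_spectra(dn)
  peak_lists <- list(
    blood = c(1000, 1368, 1542, 1620, 967, 1248, 1342),
    saliva = c(1002, 1444, 1653, 323, 521, 632, 1295, 1434, 1744, 544, 919,
               991),
    semen = c(641, 798, 829, 848, 983, 1179, 1200, 1213, 1265, 1327, 1616,
              715, 759, 1003, 1240, 1336, 1448, 1668, 888, 958, 1011, 1055,
              1065, 1125, 1317, 1461, 1494)
  )
  # the strongest positive deviation (enrichment relative to the grand
  # mean) sits on one of the fluid's own bands; the strongest negative
  # deviation may instead mark another fluid's dominant band
  for (cl in dsn$classes) {
    wmax <- dsn$wavenumbers[which.max(dsn$differences[cl, ])]
    expect_lte(min(abs(wmax - peak_lists[[cl]])), 6,
               label = sprintf("%s difference argmax at %g cm^-1", cl, wmax))
  }
})

test_that("datasets round-trip through spectrum CSVs and a manifest", {
  d <- small_dataset(n_per = 2, spots = 2)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(d, dir)
  back <- load_dataset(manifest)
  expect_equal(dim(back$intensities), dim(d$intensities))
  expect_equal(back$fluid, d$fluid)
  expect_equal(back$donor, d$donor)
  expect_equal(back$intensities, d$intensities, tolerance = 1e-6)
})

test_that("manifest validation names offending rows and tokens", {
  dir <- withr::local_tempdir()
  d <- small_dataset(n_per = 1, spots = 3)
  manifest <- write_dataset(dataset_subset(d, 1:3), dir)

  m <- read.csv(manifest)
  m$fluid[2] <- "serum"
  bad <- file.path(dir, "bad.csv")
  write.csv(m, bad, row.names = FALSE)
  expect_error(load_dataset(bad), "serum")

  m <- read.csv(manifest)
  m$file[1] <- "nonexistent.csv"
  write.csv(m, bad, row.names = FALSE)
  expect_error(load_dataset(bad), "rows 1")
})

test_that("mismatched axes are aligned on the intersection grid", {
  dir <- withr::local_tempdir()
  s1 <- raman_spectrum(seq(400, 500, 1), lorentzian(seq(400, 500, 1), 450, 10))
  s2 <- raman_spectrum(seq(410, 520, 2), lorentzian(seq(410, 520, 2), 450, 10))
  write_spectrum(s1, file.path(dir, "a.csv"))
  write_spectrum(s2, file.path(dir, "b.csv"))
  writeLines(c("file,fluid,donor,spot", "a.csv,blood,d1,1", "b.csv,blood,d1,2"),
             file.path(dir, "m.csv"))
  d <- load_dataset(file.path(dir, "m.csv"))
  expect_equal(range(d$wavenumbers), c(410, 500))
  expect_equal(nrow(d$intensities), 2L)

  # disjoint ranges cannot be aligned
  s3 <- raman_spectrum(seq(600, 700, 1), rep(1, 101))
  write_spectrum(s3, file.path(dir, "c.csv"))
  writeLines(c("file,fluid,donor,spot", "a.csv,blood,d1,1", "c.csv,blood,d1,2"),
             file.path(dir, "m2.csv"))
  expect_error(load_dataset(file.path(dir, "m2.csv")), "common wavenumber")
})
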