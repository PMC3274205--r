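# Shared fixtures.  The default study dataset (17 donors/fluid, 10 spots,
# peak SNR 25, seed 42) is memoized because several tests evaluate
# different engines on it.

.fixture_env <- new.env(parent = emptyenv())

default_study_dataset <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- simulate_dataset(sim_config())
  }
  .fixture_env$default
}

small_dataset <- function(n_per = 6, spots = 4, peak_snr = 25, seed = 11,
                          ...) {
  simulate_dataset(sim_config(n_samples_per_fluid = n_per,
                              spots_per_sample = spots,
                              peak_snr = peak_snr, seed = seed, ...))
}

# analytic Lorentzian on an axis
lorentzian <- function(x, center, fwhm, amplitude = 1) {
  amplitude * (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
}

cosine_sim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# best-assignment cosine similarity over all component permutations
best_assignment_cosine <- function(found, truth) {
  k <- nrow(found)
  perms <- pracma::perms(seq_len(k))
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    sims <- vapply(seq_len(k), function(j) {
      cosine_sim(found[perms[i, j], ], truth[j, ])
    }, 0)
    if (min(sims) > best) best <- min(sims)
  }
  best
}

# two well-separated spherical Gaussian classes in score space
gaussian_scores <- function(n_per = 20, dim = 3, sep = 10, sd = 1,
                            seed = 1) {
  set.seed(seed)
  mu <- rbind(rep(0, dim), c(sep, rep(0, dim - 1)), c(0, sep, rep(0, dim - 2)))
  X <- do.call(rbind, lapply(1:3, function(g) {
    matrix(rnorm(n_per * dim, sd = sd), n_per, dim) +
      matrix(mu[g, ], n_per, dim, byrow = TRUE)
  }))
  list(scores = X, labels = rep(c("blood", "saliva", "semen"), each = n_per))
}
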