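---
title: "Identifying body-fluid traces from Raman spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying body-fluid traces from Raman spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanid)
```

## The problem

Blood, saliva and semen are the body fluids most often recovered at crime
scenes, and a confirmatory, non-destructive identification method is of
direct forensic value. Near-infrared Raman microspectroscopy probes the
full biochemical composition of a dry trace: hemoglobin and fibrin bands
dominate dried blood, tyrosine, whole-protein and spermine-phosphate bands
dominate dried semen, and mucin/glycoprotein, acetate/carbohydrate and
arginine-consistent bands mark dried saliva. Two complications make naive
template matching useless. First, a dry trace is chemically heterogeneous:
spectra taken at different spots of the same stain differ. Second,
composition varies from donor to donor. `ramanid` addresses both with a
two-level strategy:

1. **Multi-dimensional spectroscopic signatures** — per fluid, a small set
   of non-negative component spectra (resolved by constrained alternating
   least squares) plus two fluorescence baseline terms, whose non-negative
   linear combinations reproduce any measured spectrum of that fluid; and
2. **Discriminant engines** — SIMCA, the LDA family and PLS-DA — trained
   on labelled multi-donor, multi-spot datasets.

## The generative model behind the synthetic data

No measured spectra ship with the package, so a first-class synthetic
generator (`simulate_dataset()`) emulates the acquisition. Its components
are built from published band positions:

* each band is a Lorentzian
  $L(\nu) = A\,(\Gamma/2)^2 / \big((\nu-c)^2 + (\Gamma/2)^2\big)$ with
  default FWHM $\Gamma = 12\ \mathrm{cm^{-1}}$, a typical dry-phase
  biological linewidth — only band *positions* are published, so shape and
  width are modelling choices;
* eight chemical components across the three fluids (semen: tyrosine-,
  protein-, SPH-like; blood: hemoglobin-, fibrin-like; saliva: mucin-,
  acetate/carbohydrate-, arginine-like), each max-normalized, with
  relative band amplitudes drawn log-uniformly in $[0.2, 1]$ once from a
  frozen library seed, and 10–30% cross-mixing of sibling components'
  bands (curve-resolved components always show such cross-mixing);
* a spot spectrum is
  $y(\nu) = \sum_i w_i s_i(\nu) + b_0 + b_1 \tilde\nu + \varepsilon(\nu)$
  with $\tilde\nu$ the 0–1 ramp across the axis,
  $\varepsilon \sim N(0, (\max \text{signal} / \mathrm{SNR})^2)$, clipped
  at zero;
* donor-level abundances are Dirichlet draws (concentration
  `donor_variability` × the fluid's mean mixing proportions, default 50)
  scaled by a fluid-specific total intensity with 10% lognormal donor
  variation; spot-level weights jitter lognormally around the donor
  abundances (σ = 0.15, doubled for saliva, whose dry traces are markedly
  more heterogeneous).

The working axis is 300–1800 cm⁻¹ in 2 cm⁻¹ steps (751 points), covering
every published band (323–1744 cm⁻¹). The reference study conditions are
17 donors per fluid with 10 spots each (peak SNR 25, seed 42); an
alternative configuration via `reference_spot_lists()` reproduces the
published per-fluid acquisition totals 170/252/693 = 1115 spectra. Spot
counts of 16–36 per trace (the mapping-stage acquisition range) are
available through `spots_per_sample = c(16, 36)`.

What the generator does **not** emulate: photobleaching kinetics,
instrument response and wavelength-calibration error, Poisson shot noise
(noise is additive Gaussian, the CCD read-noise regime), substrate
contributions and fluid mixtures. Perfect synthetic classification
therefore demonstrates internal consistency of the pipeline under the
stated model, not field performance on real stains.

## Signature construction

`sfa_rank()` estimates how many independent sources a spectra matrix
contains: eigenvalues of the covariance of the mean-centered data and
Malinowski's factor indicator
$\mathrm{IND}(k) = \mathrm{RE}(k)/(c-k)^2$,
$\mathrm{RE}(k) = \sqrt{\sum_{j>k}\lambda_j / (r(c-k))}$, with $c$ the
*smaller* and $r$ the larger matrix dimension — with $c$ taken as the
channel count the $(c-k)^2$ term is nearly constant and the indicator
never develops a minimum. The argmin is restricted to `1..max_k`: IND is
unreliable near $k = c-1$, and without a noise floor (noise-free data) it
decreases monotonically, so the eigenvalue spectrum and cumulative
variance in the report are the primary diagnostics there. Because IND is
unstable on noisy data, signature ranks are fixed by configuration in the
pipeline (semen 3, blood 2, saliva 3 chemical components) with `sfa_rank`
as an advisory check.

`als_decompose()` alternates exact non-negative least squares
(Lawson–Hanson active set; a fast path accepts the unconstrained solution
whenever it is already feasible) between concentrations $C$ and component
spectra $S$. Initialization is the deterministic purest-variable
heuristic: greedily pick the mutually most dissimilar data *columns*
(wavenumber channels) and seed $C$ with their intensities. Each component
has selective bands, so these channels track individual concentrations;
initializing instead from data *rows* was tried and rejected — every row
is an interior mixture and the factorization then converges to a rotated
solution (fibrin recovered at cosine 0.87 rather than ≥ 0.95). Seeded
random restarts (`restarts`) are available and keep the best fit.
Convergence: relative lack-of-fit change below `tol = 1e-6` or lack of
fit below 1e-10 (exact-rank data), capped at `max_iter = 500` sweeps.
The residual history is non-increasing because each half-step is an exact
minimization; collapsed components are re-seeded from the positive
residual *before* the next exact update, which preserves monotonicity.

A fluid's signature (`fluid_signature()`) appends two fixed baseline
spectra — all-ones and the 0–1 ramp — to the resolved components. During
the decomposition the same two spectra participate as fixed terms with
*unconstrained* coefficients (`fixed` argument), so fluorescence
variation is soaked up by the lines rather than contaminating the
chemical components; this implements the decision to handle baseline
exclusively by the two appended lines rather than by an extra ALS
component (which would double-count background). `fit_signature()` solves
the mixed-constraint least squares (components ≥ 0, baseline free, via
sign-splitting the baseline columns inside one NNLS) and reports SSE,
$R^2 = 1 - \mathrm{SSE}/\mathrm{SS}_{tot}$ (negative for terrible fits;
deliberately not clipped) and $\mathrm{RMSE} = \sqrt{\mathrm{SSE}/n}$.
At peak SNR 25 the self-fit residual is essentially the noise floor;
blood, whose hemoglobin/fibrin band structure is sparsest, shows the
lowest self-fit $R^2$ (≈ 0.89 on small runs) for that reason, while
noise-free self-fits reach $R^2 \ge 0.999$.

## Discriminant engines

**SIMCA** (`simca_train()`): one PCA model per class (default 2
components); membership statistics are Hotelling's
$T^2 = \sum_a t_a^2/\lambda_a$ and the orthogonal residual $Q$. Limits at
confidence $\alpha = 0.95$: $T^2_{lim} = a(n-1)/(n-a) \cdot
F^{-1}(\alpha; a, n-a)$ and the Jackson–Mudholkar $Q$ limit from the
discarded eigenvalues. Classification is by the reduced distance
$d_c = \sqrt{(T^2/T^2_{lim})^2 + (Q/Q_{lim})^2}$ to the nearest class —
the standard chemometric composition of the two statistics; a spectrum is
*inside* a class when $d_c \le \sqrt 2$. Averaging the spots of each
sample (`average_per_sample()`) before modeling suppresses trace
heterogeneity and is the single most effective step for SIMCA.

**LDA family** (`lda_loo()`, `gaussian_family_predict()`): spectra are
compressed to PCA scores (enough components for 99% variance, capped at
20) or PLS scores, then classified by the Gaussian linear discriminant
$\delta_c(x) = x^\top\Sigma^{-1}\mu_c - \tfrac12\mu_c^\top\Sigma^{-1}\mu_c
+ \log\pi_c$ with pooled covariance and equal priors — the published
class imbalance (170/252/693) is an acquisition artifact, not a
prevalence statement. Under leave-one-out validation the compression is
refit inside every fold: fitting PCA/PLS once globally would leak the
held-out spectrum into the model and inflate accuracy. Variants: naive
Bayes (diagonal covariances), stratified covariance (quadratic rule) and
Mahalanobis distance (pooled covariance, no prior term). A ridge term
(`1e-8 × trace/dim`) rescues singular pooled covariances once; ties break
by fixed class order (blood < saliva < semen).

**PLS-DA** (`plsda_train()`): SIMPLS regression of spectra on the one-hot
class indicator; SIMPLS was chosen over NIPALS for determinism and
because the difference is far below test tolerances at these problem
sizes. The class decision is pure argmax of the predicted indicators.
The latent-variable count is selected by cross-validated RMSE under the
one-standard-error rule (no selection rule is canonical; one-SE guards
against overfitting the count), run under any of the four standard
splitters — contiguous block, venetian blind, random subset, leave-one-
out — and, when several schemes are supplied, the maximum selected count
across schemes is used (conservative). Calibration (RMSEC) and
cross-validated (RMSECV) metrics refit the PLS model inside each fold.

**Ensembles** (`classify_unknowns()`): each engine votes; the consensus
is the majority, flagged `"ambiguous"` when all engines disagree. The
blind-test protocol holds out whole donors (`donor_split()`), never
individual spectra, so no donor appears on both sides.

## Numerical choices and degenerate inputs

* Despiking flags channels whose first-difference modified z-score within
  a rolling window (default 11 points) exceeds 8, replacing them with the
  spot-free window median; a flagged channel also flags its successor
  because a spike contaminates two first-differences. The algorithm is
  deliberately conservative: genuine Lorentzian bands (FWHM ≥ 10 cm⁻¹ on
  a 2 cm⁻¹ grid) are never touched.
* Dataset alignment interpolates linearly onto the densest axis restricted
  to the common range; extrapolation is refused.
* Vector normalization is the default scaling for visual comparison; the
  engines operate on raw counts by default since no pre-statistics
  normalization is part of the reference workflow.
* All-zero spectra, single-class indicator matrices, out-of-range
  component counts and axis mismatches raise immediate errors naming the
  offender.
* Every stochastic stage takes an explicit seed and restores the caller's
  RNG stream (`simulate_dataset()`, `inject_corruption()`,
  random-subset splits), so identical configurations give bitwise
  identical results.

## Problem sizes and runtime

The default experiment (510 spectra × 751 channels) was sized so that a
full run — generation, signatures, SIMCA, leave-one-out LDA with per-fold
PCA refits, PLS-DA selection and evaluation — completes in about a minute
on a single core. Leave-one-out LDA dominates the cost; its per-fold PCA
uses a Gram-matrix eigendecomposition (n < p), which is several times
faster than a full SVD at this shape. The robustness study trains engines
once on a donor-wise split and re-evaluates on corrupted copies of the
evaluation split; corruption draws are reused across grid points so that
larger factors yield proportionally larger corruption, making
"accuracy non-increasing in corruption" a well-posed comparison.

## Known limitations

* Synthetic-only validation: the perfect classification rates certify the
  pipeline under the stated generative model, not performance on real
  stains, substrates, mixtures or contaminated samples.
* The ALS factorization is unique only up to the usual rotational
  ambiguity of non-negative factorizations; the purest-variable
  initialization selects a chemically sensible member of the solution
  set but cannot guarantee it in general.
* Malinowski's indicator needs a genuine noise floor; on noise-free or
  strongly structured residuals its argmin is a boundary artifact.
* PLS-DA indicator predictions are not calibrated probabilities, and no
  ROC-style analysis is provided.
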