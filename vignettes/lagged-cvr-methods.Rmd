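---
title: "Methods: lagged-GLM CVR mapping and its coupling with baseline perfusion"
author: "lagcvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged-GLM CVR mapping and its coupling with baseline perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagcvr)
```

## The scientific problem

Cerebrovascular reactivity (CVR) is the blood-flow response to a vasoactive
stimulus, here quantified as the percent BOLD signal change per mmHg change
in end-tidal CO~2~ (P~ET~CO~2~). Because the BOLD response lags the arterial
CO~2~ stimulus by a spatially variable hemodynamic delay, CVR amplitude must
be estimated jointly with a per-voxel lag. This package implements the
lagged-GLM approach: the P~ET~CO~2~ regressor is convolved with a canonical
hemodynamic response function, shifted over a grid of lags (±15 s in 0.3 s
steps by default), and a full multiple regression is refit at every shift;
the shift maximizing the full-model R² wins. The resulting CVR maps are then
related to baseline cerebral blood flow (bCBF) from pseudo-continuous
arterial spin labeling (pCASL), both *between* subjects (gray-matter medians,
Pearson) and *within* subjects (96-parcel means, Spearman), with a
permutation repeated-measures ANOVA testing how the acquisition segment
(breath-hold, cued-deep-breathing, or rest-only data) and the
lag-optimization scheme affect that coupling.

Because suitable raw data cannot be redistributed, the package ships a
fully seeded synthetic world (`simulate_subject()`, `run_study()`) with
planted ground truth, so every stage is validated by parameter recovery
rather than by fixture files.

## The CVR model

For voxel $v$ with series $y_v(t)$ over the analyzed volumes,

$$ y_v(t) = \beta_{0,v}\Big(1 + \frac{\mathrm{CVR}_v}{100}\, x_{\ell_v}(t)\Big)
  + \text{drift} + \text{motion} + \varepsilon $$

where $x_\ell(t)$ is the baseline-subtracted, HRF-convolved P~ET~CO~2~ tide
curve delayed by lag $\ell$ (positive lag = BOLD lags CO~2~; the sign
convention is stated here once and used everywhere). The design contains an
intercept, an orthonormal polynomial drift block (one order per 150 s of
scan, the common mass-univariate heuristic), six demeaned motion
parameters, and the CO~2~ regressor. The regressor is *not* demeaned, and
all nuisance columns are mean-free, so the fitted intercept estimates the
voxel mean and $\mathrm{CVR}_v = 100\,\hat\beta_{x}/\hat\beta_0$ is exactly
the percent signal change per mmHg. With `optimize = "lag"` the model is
refit per lag and the largest full-model R² selects the voxel's lag; ties
break toward the smallest absolute lag, negative first, making results
deterministic and favouring near-zero physiological delays. Lags selected
at the grid edge are flagged (and can be censored with
`censor_boundary = TRUE`, off by default since unthresholded amplitude maps
feed the correlation analyses).

Numerically, the solver uses a centered normal-equations formulation shared
across lags (the nuisance cross-products are computed once), which makes
the 101-lag fit over a whole brain a few hundred milliseconds and keeps the
selected-lag fit bit-identical regardless of voxel processing order.

### HRF and kernel normalization

The canonical HRF is the usual double-gamma (peak delay 6 s, undershoot
delay 16 s, dispersions 1 s, undershoot ratio 1/6, 32 s support). The
kernel is normalized to **unit area** by default: a sustained 1 mmHg
end-tidal change then passes through convolution with unit gain, so the
regressor genuinely stays in mmHg and CVR in %BOLD/mmHg. Unit-peak
normalization (available via `normalize = "peak"`) does not have this
property — with a unit-peak kernel the convolved amplitude depends on the
sampling rate through the kernel's discrete sum — which is why area
normalization is the default even though unit-peak kernels are also common
in the field.

### End-tidal detection and regressor construction

`detect_end_tidal()` locates one expiratory peak per breath: a ~0.3 s
smoothed copy of the 1000 Hz trace provides candidate maxima (minimum
separation, minimum prominence), and the reported value/time is the raw
trace maximum in a small window around each candidate. Reporting the raw
maximum makes detection exact on noiseless traces and matches how
capnography plateaus are read in practice. The continuous tide curve is the
linear interpolation of the peaks (during breath holds no peaks exist and
the interpolation bridges the hold, which is also standard practice), the
baseline is the mean end-tidal value inside free-breathing rest events
(configurable), and the pipeline order is fixed and documented:
interpolate → subtract baseline → convolve → shift → sample at volume
times. Shifted samples that fall outside the recorded peak span use
edge-held values and the affected rows are flagged.

## Baseline CBF

The pCASL series (11 tag + 11 control + 1 M0) is reduced by
`tag_control_diff()` (mean control−tag) and quantified with the
single-compartment consensus formula

$$ \mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\, e^{\mathrm{PLD}/T_{1b}}}
   {2\,\alpha\, T_{1b}\, M_0\, (1 - e^{-\tau/T_{1b}})} $$

in ml/100 g/min, with λ = 0.9 ml/g, α = 0.85, τ = PLD = 1.8 s (inflow time
3.6 s) and blood T1 = 1.65 s. Two deliberate simplifications relative to
Bayesian ASL toolboxes: (1) the closed-form single-PLD model replaces
variational kinetic inversion — it is transparent, exactly invertible, and
the study-level parameters map directly onto it; (2) "adaptive" spatial
regularization is replaced by optional fixed-FWHM Gaussian smoothing
(`smooth_cbf()`, mask-aware so constant images are unchanged at mask
edges). A tissue T1 of 1.3 s is carried in `asl_params()` as metadata
because kinetic-inversion tools consume it, but the closed-form formula
uses blood T1; both constants are logged in provenance.

## Resting-state fluctuation metrics

`rsfc_metrics()` follows the common 3dRSFC-style order: quadratic
detrending, optional Gaussian smoothing (4 mm default, double the 2 mm
voxel), then per voxel: ALFF = mean one-sided amplitude-spectrum value in
0.01–0.1 Hz; fALFF = in-band amplitude sum over the full non-DC spectrum up
to Nyquist (source conventions vary between mean and sum and between
denominators — the choice only rescales maps and cannot change rank
correlations, and it is recorded in the output); RSFA = SD of the ideally
bandpassed series; mRSFA = RSFA normalized by the voxel mean. The bandpass
is an exact frequency-domain boxcar (DC always removed) rather than an IIR
design, so unit gain in-band and zero gain out-of-band are testable to
machine precision. Both smoothed and unsmoothed maps are always produced,
because parcel correlations of ALFF/mRSFA with CBF are materially sensitive
to smoothing.

## Correlation statistics

*Between subjects*: Pearson correlation of gray-matter medians, with
influential subjects screened once by Cook's distance > 4/n on the simple
regression and the fit recomputed on the retained points; both screened and
unscreened results are kept, and p-values are reported raw and
Benjamini–Hochberg corrected across the family of 10 tests (5 segments × 2
schemes).

*Within subjects*: Spearman correlation across the 96 parcel means.
Outlier parcels are screened by Cook's distance > 4/n computed on the
rank-rank regression — ranks rather than raw values, consistent with the
rank correlation (the alternative is configurable in principle but ranks
are the coherent choice). Screening is single-pass by design: influence is
computed once on the full data and all flagged points are removed together;
iterating the rule at n = 9 subjects or with heavy-tailed parcel values is
unstable. Significance uses the large-sample Fisher-Z form
$\operatorname{atanh}(\rho)\sqrt{n-3}$ against the two-tailed normal
critical value (1.96 at α = 0.05); since removing parcels lowers n, the
equivalent threshold on |ρ| (`adjusted_critical_value()`) rises and is
reported alongside.

## Permutation repeated-measures ANOVA

`perm_rm_anova()` computes the classical two-way within-subject F
statistics (subject, subject×scheme, subject×segment and residual error
strata; cross-checked against `aov()` with Error terms in the tests) and
builds null distributions by permuting the 10 cell labels independently
within each subject — observations are exchangeable within the subject
stratum under the global null, and no Gaussianity or sphericity is assumed.
P-values are $(1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$. The package default
is 100 000 permutations; the test-suite and acceptance runs use 999–2000,
which changes the p-value floor but not calibration (the type-I error of
the test is itself verified by simulation in the suite). When the number of
distinct relabelings is smaller than `n_perm` the null is enumerated
exhaustively. Simple main effects are within-subject sign-flip permutation
tests per level pair (exhaustive when $2^S \le n_{perm}$; a parametric
paired-t mode is also provided since conventions differ), with BH-FDR over
the contrast family. `extreme_outlier_screen()` applies the Tukey 3×IQR
extreme-value rule per design cell with type-7 quantiles (the quartile
convention changes flags at n = 9, so it is fixed and stated), and
`sensitivity_anova()` reruns the ANOVA on full data, with flagged subjects
removed, and with flagged values replaced by their cell mean.

## The synthetic world

`simulate_subject()` generates, per subject: five data segments — a
rest-only acquisition (8 min at TR 1.2 s, 400 volumes of which the first 10
are discarded, leaving 390), breath-hold (3 hypercapnic cycles: 24 s paced
breathing with 3 s cues, 15 s hold, 18 s recovery) and cued-deep-breathing
(2 hypocapnic blocks of 4 deep breaths with 2 s cues) variants padded with
rest to the common length, plus matched rest-only segments — a 1000 Hz
capnography trace, motion traces, and a pCASL series. Ground truth plants
parcel-level CVR amplitudes uniform in 0.1–0.4 %BOLD/mmHg, lags uniform in
±10 s snapped to the 0.3 s grid (so on-grid recovery is well defined), and
a bCBF map coupled to the CVR parcel means at a target Spearman ρ (0.6 by
default) through a Gaussian-copula construction
(`couple_fields()`; the mixing coefficient is $2\sin(\pi\rho/6)$ so the
*rank* correlation, which downstream statistics use, hits the target in
expectation).

The capnography model is a raised-cosine breath train between a ~2 mmHg
inspiratory level (nasal-cannula room air) and end-tidal peaks that track
the planted end-tidal curve: baseline 38 mmHg; +9 mmHg after each hold
(a typical excursion for 15 s end-expiration holds) washing out with a 15 s
time constant, the most recent hold governing; −6 mmHg progressive dips
during deep breathing; and a slow autoregressive rest fluctuation of SD
1.2 mmHg with ~25 s correlation time — the small "natural" P~ET~CO~2~
variability that is all a rest-only fit has to work with. Each planted peak
falls on exactly one output sample with zero local slope, so at zero sensor
noise the detector recovers peaks exactly and the whole
generate→detect→regress chain closes to machine precision.

The BOLD forward model uses the *same* regressor-construction code as the
analysis (same HRF, baseline rule, lag grid), plus polynomial drift and a
motion-coupled term that are mean-free over the analyzed window — both
exactly removable by the GLM, which is what makes the noiseless closure
tests sharp (< 1e-6 relative amplitude error, exact on-grid lags). Noisy
simulations add: white thermal noise at `tsnr` (mean/SD, default 50);
voxelwise-independent band-limited intrinsic fluctuations (0.3–1.5% of the
voxel mean); and six spatially smooth shared components (0.5% each) — a
coarse model of resting-state networks. The shared components matter: with
purely independent noise, parcel averaging cancels rest-segment estimation
error and rest-only CVR–CBF correlations come out nearly as strong as
breath-hold ones, which real data contradict. Spatially structured
fluctuations survive parcel averaging and reproduce the qualitative
pattern: lag-optimized breath-hold segments show the strongest coupling
with planted bCBF, rest-only segments weaker and (on the correlation
scale) more variable coupling.

What the generator does **not** emulate: MR physics (no k-space,
distortion, or motion-resampling), registration (everything lives in one
common space, with masks provided), arterial transit heterogeneity in the
pCASL model, and genuinely neural spatial topographies. Passing tests
therefore validate the estimators and statistics, not robustness to
registration error or acquisition artifacts.

## Problem sizes and known limitations

The default grid is 24×24×12 voxels at a nominal 2 mm (≈2800 brain voxels,
≈2500 GM voxels, 96 parcels of ~26 voxels), chosen so a full
five-segment, 101-lag, 20-subject study runs in minutes on one core. The
test suite validates noiseless closure and noisy recovery on 20 subjects at
this size; the acceptance script uses 6 subjects for recovery, 200 seeds
for coupling recovery, 400 simulated datasets × 1999 permutations for null
calibration, and a 20-subject study for the scheme/segment effects.

Voxelwise precision at realistic noise deserves an honest statement: with a
single 3-cycle breath-hold task (~9 mmHg excursion), 390 volumes and
thermal tSNR 50, the Fisher information of the lagged GLM bounds the
per-voxel lag standard error at roughly 1.5–2 s and the relative amplitude
error at ~15% for mid-range amplitudes; the estimator attains this bound
(halving the noise halves the error, and at tSNR ≈ 200 the median lag error
reaches the 0.3 s grid). Per-voxel lag maps at ordinary single-task SNR are
therefore intrinsically noisy — parcel averaging, not the estimator, is
what makes the downstream correlations stable. Other limitations: single
post-label-delay CBF (no arterial-arrival-time estimation, no
partial-volume correction); no statistical thresholding of CVR maps; no
O~2~ regressors or respiration-volume-per-time modeling.
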