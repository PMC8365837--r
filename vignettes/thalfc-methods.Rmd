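---
title: "Thalamic connectivity centrality: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamic connectivity centrality: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalfc)
```

## The analysis in one paragraph

`thalfc` quantifies how strongly thalamic subregions are embedded in the
whole-brain functional network of children with focal epilepsy, and whether
that embedding is a persistent trait or an artifact of transient interictal
epileptiform discharges (IEDs). Per subject, region-mean BOLD timeseries on
a 102-region parcellation (90 cerebral AAL regions, with the two thalami
replaced by seven paired thalamic subregions) are confound-regressed,
band-pass filtered to 0.04–0.07 Hz, and correlated region-by-region to form
an adjacency matrix (diagonal zeroed, negative correlations zeroed). The
weighted graph is thresholded over a sweep of proportional network
densities (10–50% in 1% steps), and degree centrality (DC) and eigenvector
centrality (EC) are computed on each binarized graph. A region's summary is
the area under its centrality-vs-density curve (AUC). Group inference
compares the AUC of the thalamic region *ipsilateral* to the epileptogenic
zone (EZ) in patients against the median of left and right AUCs in
controls, using a permutation test on the difference of group medians, with
a Mann-Whitney effect size $r = z / \sqrt{n_1 + n_2}$. The IED correction
regresses HRF-convolved spike regressors out of every region's series by
orthogonal projection; re-running the identical pipeline on the corrected
series and comparing before vs after asks whether the group difference is
spike-locked or persistent.

## Hemodynamic model

IED-locked BOLD changes are modelled with the canonical double-gamma HRF

$$h(t) = \frac{t^{a_1-1}e^{-t/b_1}}{b_1^{a_1}\Gamma(a_1)} -
         \frac{1}{c}\,\frac{t^{a_2-1}e^{-t/b_2}}{b_2^{a_2}\Gamma(a_2)}$$

with the conventional parameter set (peak delay 6 s, undershoot delay 16 s,
both dispersions 1 s, peak:undershoot ratio $c = 6$, support 32 s), scaled
to unit peak. All six parameters are exposed through
`canonicalHRF(params = )`. The basis is completed by a temporal derivative
(finite difference under a 1 s onset shift) and a dispersion derivative
(finite difference under a 0.01 perturbation of the peak dispersion),
matching the usual informed-basis construction; an analytic derivative that
agrees with these differences within 1% would be equally acceptable, and
the unit tests pin the finite-difference behaviour.

Event regressors are built on a microtime grid (default resolution
TR/16): events with positive duration enter as boxcars with fractional
edge-bin coverage, zero-duration events as unit-mass impulses spread over
the two adjacent bins. The stimulus function is convolved with each basis
vector and sampled at the volume acquisition times $t_i = i\,\mathrm{TR}$
(slice-timing detail is out of scope). Fractional bin coverage is what
makes regressors built at resolutions dt and dt/2 agree within 1% relative
L2 error; naive whole-bin boxcars fail that bound at TR/16.

## Preprocessing contract

* **Confound regression** projects each region series onto the orthogonal
  complement of `[intercept | confounds]` by QR; rank-deficient confound
  sets are reduced to an independent subset with a warning. The intercept
  is always included: correlation is location-invariant, but residual
  orthogonality requires mean removal.
* **Band-pass filtering** is defined spectrally, not by a named
  implementation: a mid-band (0.055 Hz) sinusoid must retain at least 90%
  of its amplitude and out-of-band content (DC, 0.20 Hz) must be attenuated
  to at most 10%. The default implementation is a zero-phase
  forward–backward Butterworth of order 5 with odd-reflection padding and
  steady-state initial conditions; because this operation is linear and
  fixed for a given series length and band, the package materializes it
  once as a T×T operator and filters whole cohorts by matrix
  multiplication — bit-identical to per-column filtering but an order of
  magnitude faster across simulation studies. An ideal FFT band filter is
  provided as an alternative (`filterMethod = "fft"`), and both must pass
  the same spectral contract.
* **Ordering** is fixed as confound regression → band-pass; the IED
  projection is applied *after* filtering by default, with
  `correctionBeforeFilter = TRUE` as the declared alternative. The source
  analyses do not pin either ordering, so the defaults are declared
  choices, not inferences.
* Sessions of 300 raw volumes are expected to arrive with the first five
  volumes already discarded (295 retained); pre-trimmed inputs are taken
  as-is.

## IED correction

The correction is purely an orthogonal projection: with $X = [\,1 \mid
\text{design}\,]$ (three mean-centered columns per spike type),

$$Y_{\text{corr}} = Y - X X^{+} Y .$$

Residuals are exactly orthogonal to every design column, the projection is
idempotent, never increases per-region variance, and removes a planted
$\beta \cdot h$ component regardless of $\beta$ (the tests require residual
correlation with the regressor below $10^{-9}$). Rank-deficient designs
(e.g. duplicated spike types) are reduced to an independent column subset,
which spans the same space as the pseudoinverse solution. Derivative
columns are always kept and never orthogonalized against the canonical.

One ordering subtlety matters greatly: the design is built on the raw
volume grid, but the projection is applied (by default) to the
confound-regressed, band-passed series. Because filtering is linear, a
spike response that lies in the design span before filtering lies in the
span of the *equally filtered* design afterwards — but **not** in the span
of the raw design. The pipeline therefore passes the design columns
through the identical preprocessing (confound regression, and band-pass
when the projection follows the filter) before projecting, the standard
practice of filtering the design like the data. Simulation shows the
difference is not cosmetic: projecting filtered data on a raw design
leaves most of a planted spike-locked group difference in place, while the
matched projection removes it down to the null noise floor (the
specificity study below quantifies this). The alternative ordering —
project first, then filter — is available via
`correctionBeforeFilter = TRUE` and is algebraically equivalent in its
treatment of modelled spike signal.
Subjects without marked events pass through unchanged — the correction is
defined as a no-op rather than an error at the pipeline level, while the
low-level `buildIEDDesign()` refuses empty event sets loudly.

## Graph construction and centrality

Proportional thresholding retains the $\lfloor d \cdot R(R-1)/2 \rfloor$
largest-weight upper-triangle edges at density $d$, binarizes, and
symmetrizes. Three numerical choices matter:

* **Zero-weight edges are never retained**, so beyond the density at which
  all positive correlations are included the edge count plateaus —
  mirroring the empirical observation that motivated the 50% upper limit.
* **Ties** at the threshold boundary are broken lexicographically on
  region indices. Real-valued correlations make ties measure-zero; the
  rule exists for exact reproducibility.
* **Degree sweeps exploit nestedness**: since edge sets at increasing
  densities are nested (given the fixed tie rule), the sweep sorts edges
  once and accumulates degrees, which the tests verify to be exactly
  equivalent to independent thresholding at every density.

DC is the row sum of the binary graph ("number of links"); EC is the
entrywise non-negative leading eigenvector of the binary adjacency
(Perron–Frobenius convention), unit Euclidean norm, with isolated nodes at
zero. Both metrics are computed on the *binarized* graph — DC's textual
definition forces binarization, and EC follows the same convention for
comparability. On disconnected graphs EC uses the leading eigenvector of
the whole matrix (reported via a message); nodes outside the dominant
component score approximately zero.

The AUC convention is the plain **sum** of centrality values over the grid
points in the density window — 41 points for the default 10–50% range at
1% steps. With $R = 102$ this is what produces DC-AUC values on the order
of 1,300–1,500 for well-connected regions (bounded above by $41 \times
101 = 4141$); a trapezoidal integral over density is available via
`aucConvention = "trapezoid"` for unit-consistent comparisons across
different grids. The 1% step is adopted because it reproduces those
magnitudes and gives visually smooth curves; the original step size is not
printed anywhere authoritative.

The composite whole-thalamus result is computed by collapsing the seven
subregion series per side to their unweighted mean, yielding a 90-region
graph on the cerebral AAL base. This approximates a voxel-level thalamus
ROI mean only up to subregion volume weighting; when voxel data are
unavailable the approximation is declared, not asserted equivalent.

## Group statistics

The test statistic is the literal difference of group medians of the
lateralized AUC (patients: EZ-side region; controls: median = mean of the
left/right pair). The null is built by label permutation; the two-tailed
Monte-Carlo p-value uses add-one smoothing, $(1 + \#\{|T^\ast| \ge
|T_{\text{obs}}|\})/(B + 1)$, so $p \in (0, 1]$ and exact zeros are
impossible. For $n_1 + n_2 \le 12$ the test enumerates all label
assignments instead (no smoothing needed — the identity assignment is in
the enumeration). The default is $B = 10{,}000$; the simulation studies
reduce this to 999, which only coarsens the p-value grid.

The effect size is $r = z/\sqrt{n_1+n_2}$ with $z$ the tie-corrected
normal approximation of the Mann-Whitney U (no continuity correction),
cross-checked in the tests against `wilcox.test`. The before/after-IED
comparison reuses the unpaired permutation machinery by default for
fidelity with the source analysis; because the two conditions contain the
same subjects, a paired sign-flip variant is available
(`pairedBeforeAfter = TRUE`) as the statistically tighter option. IED
burden is related to the corrected ("residual") AUC by Spearman
correlation on midranks with the t-approximation p-value. Across the seven
thalamic subregions no multiplicity adjustment is applied: the anterior
nucleus carries the a-priori hypothesis and is flagged as such in the
output (`aPriori`); the remaining rows are exploratory and descriptive.

Median-based statistics have a consequence worth knowing when reading the
enumeration tests: because medians are robust, non-extreme label
assignments can tie the observed statistic even under complete group
separation, so exhaustive p-values for tiny groups are larger than the
$2/\binom{n}{n_1}$ a rank statistic would give.

## The synthetic cohort generator

No patient data are distributed, so every end-to-end claim is exercised on
synthetic cohorts whose defaults are the study conditions: 35 patients
(EZ lateralized left in 20, right in 15) versus 20 controls, 295 volumes at
TR 2.16 s, 102 regions, 2–450 IEDs per session (log-uniform totals, 1–4
spike types, uniform 0–1 s durations, uniform onsets).

The background signal is a zero-mean multivariate Gaussian whose temporal
spectrum is flat over 0.01–0.10 Hz (drawn directly in the frequency
domain, which is the same process as ideal-band filtering white noise) so
that the 0.04–0.07 Hz analysis band contains signal. Correlation structure
is imposed by a Cholesky factor of a block matrix — six equal blocks with
within-block correlation 0.3 — rather than an identity, because identity
covariance makes thresholded graphs structureless and centrality curves
degenerate. Patients additionally receive:

* a **planted hub effect**: the correlation between the EZ-side anterior
  thalamic region and a 20-region frontal cortical target set is raised by
  `hubEffect` (default 0.20); the implied matrix is checked for positive
  definiteness and
  repaired by eigenvalue clipping (with a message) when the planted effect
  is too large;
* an **IED-locked response**: the spike trains convolved with the
  canonical HRF, normalized to unit peak and scaled by `iedAmplitude`
  (default 1, in units of the unit-variance background signal),
  superimposed on a 10-region posterior cortical set disjoint from the hub
  targets — so that, by default, the planted group difference is carried
  by covariance, not by spikes, and survives IED correction.

For the correction-*specificity* study the roles are reversed:
`hubEffect = 0` and a large spike response (`iedAmplitude = 8`) is placed
on both anterior-thalamic regions plus twenty frontal carriers, with
per-session totals restricted to 5–60 events. The count restriction is a
calibration forced by the physics of the construction: with the default
log-uniform 2–450 totals, high-count patients' HRF responses overlap into
a near-constant elevation with almost no variance inside the 0.04–0.07 Hz
analysis band, so no spike-borne connectivity difference reaches the
graphs in the first place. Sparser trains keep response variance in-band,
making the planted uncorrected difference unambiguous (pilot: median
|group difference| ≈ 460 AUC units, power 1.0) so that its removal by the
projection (to ≈ 54, at the ≈ 37 null noise floor; a 88% reduction) is a
meaningful test of the correction rather than of the generator.

Twelve nuisance regressors (three cosine drifts, nine temporally smoothed
noise series) are mixed into the data with random coefficients
(SD 0.3), making confound regression consequential, and white measurement
noise (SD 0.25) is added on top.

`hubEffect` calibration is a simulation design choice — nothing available
estimates the real effect size, so it is sized for detectability: a pilot
power sweep at the design sample sizes (n = 35 vs 20, 999-permutation
tests) gave rejection rates of roughly 0.83 at $\Delta\rho = 0.15$ and
0.98 at $\Delta\rho = 0.20$; the default is 0.20, the smallest swept value
with a comfortable margin over the 80% recovery requirement, while a
non-hub subregion stays at its nominal false-positive rate.

What the generator does *not* emulate: spatial structure (no voxel-level
4-D synthesis beyond a toy NIfTI path for exercising region extraction),
physiological noise spectra, motion artifacts, between-subject variability
in HRF shape or in the connectivity structure itself, and age effects. A
passing simulation study therefore demonstrates that the pipeline recovers
what its own statistical model plants — not that the biological effect
exists; the negative controls (null cohorts, non-hub regions) demonstrate
that it does not invent effects under the model's null.

## Problem sizes used in the distributed studies

The simulation studies shipped with the package use the full design
(55 subjects × 295 volumes × 102 regions per cohort) with 500 replicate
cohorts for the null calibration study, 200 for the power study, and 40
each for the two correction-specificity studies, at 999 permutations per
test. These sizes give Monte-Carlo standard errors of about 0.01 on a
rejection rate near 0.05 and about 0.03 near 0.8.

## Known limitations

* The whole-thalamus composite is a subregion average, not a voxel mean.
* EC on disconnected thresholded graphs follows the dominant component;
  regions isolated at sparse densities contribute zeros to their AUC.
* The unpaired before/after test ignores the within-subject pairing and is
  conservative; the paired variant is provided but not the default.
* The permutation test assumes exchangeability of the lateralized values;
  the control value is a mean of two correlated sides and has slightly
  smaller variance than a patient value, which the null simulation study
  shows to be immaterial at these sample sizes.
* The Butterworth/FFT filters agree mid-band but differ near the band
  edges (rolloff vs brick wall); both satisfy the spectral contract, and
  the choice is configurable end to end.
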