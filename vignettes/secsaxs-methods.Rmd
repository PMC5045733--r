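---
title: "Models and methods behind secsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secsaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secsaxs)
```

This vignette documents the models implemented in `secsaxs`, the
assumptions they rest on, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate. It states no empirical
result that the package's test suite or `scripts/acceptance.R` does not
itself compute.

## Data model

A SEC-SAXS series is an `n_q × n_t` intensity matrix on a shared
momentum-transfer grid `q` (Å⁻¹, strictly increasing) with a matching
standard-deviation matrix and strictly increasing integer frame ordinals
(`secsaxs_dataset()`). Transposition between the frame view I_t(q) and the
chromatogram view I_q(t) is pure reindexing — no interpolation — so it is
exactly involutive. Frames load from 3-column whitespace ASCII
(q, intensity, sigma; `#` comments); files without a sigma column are
rejected unless the user opts into the fill rule
`sigma = k · sqrt(max(I, floor))`, because uncertainties should normally
come from the beamline reduction. Grids must agree to a relative `1e-8`
(one detector geometry). Frame order comes from the trailing integer in
each filename, the convention encoded in typical beamline frame numbering,
overridable with `order = "given"`.

**Trimming.** The rule used by the original interactive tool to discard
noise-only chromatograms is not published; `trim_noise_chromatograms()`
uses this package's own documented substitute — drop q rows whose mean
intensity-to-sigma ratio falls below a threshold (default 1.5) — and
reports what it dropped.

## Longest-run similarity statistics

Two curves sharing an abscissa are compared through the longest run C of
same-sign differences among the n points considered. Under the null of
two statistically identical curves the difference signs are independent
fair signs, and

P(n, C) = 1 − (number of ±1 sequences of length n with all runs < C) / 2ⁿ

is computed by the exact composition recursion carried in probability
scale, so it is stable for n in the thousands. Exact zeros terminate runs
and belong to none; this convention makes identical curves score P = 1
exactly. Two closed forms pin the implementation down: P(n, 1) = 1 and
P(n, n) = 2^(1−n); the test suite additionally checks the full
distribution against exhaustive enumeration of all 2ⁿ sequences up to
n = 16.

**Comparison options.** A q-range cutoff (default 0.05 Å⁻¹) concentrates
the test where the signal lives, and a stride (default 1) subsamples the
grid to decorrelate neighbouring detector pixels when beam cross-section
and pixel size are mismatched. The null length n is the number of points
*after* cutoff and stride — the points actually compared.

**Maps and classes.** All n(n−1)/2 pairs are scored and classed green
(P ≥ 0.05), yellow (0.01 ≤ P < 0.05) or red (P < 0.01). With the
Holm–Bonferroni option the same colors are assigned from the stepwise
procedure: red if rejected at family level 0.01, yellow if rejected at
0.05 but not 0.01. The exact threshold bookkeeping of the original
software lives in unpublished supporting material, so this is a faithful
reconstruction, flagged as such. Red clusters are maximal 4-connected
groups of red cells in the full mirrored matrix (diagonal excluded);
percentages are over unordered pairs. A screening flag marks maps with
more than 1% red pairs; it is a report, not a hard failure.

## Integral baseline for capillary fouling

Assumptions: deposits only accumulate (no cleaning), in proportion to the
sample's scattering above the already-deposited signal, with a
species-independent proportionality γ(q); buffer and instrument do not
foul; the series ends in a steady-state stretch [t_s1, t_sm] where only
buffer (plus deposits) flows. Then with I_BL(q) the steady-state average,
the deposit history is reconstructed per q by iterating from B = 0:

1. S_i = Σ over the elution region of [I(t_{k−1}) − B_i(t_{k−1})];
2. γ_i = I_BL / S_i;
3. B_{i+1}(t_k) = Σ_{j ≤ k} γ_i [I(t_{j−1}) − B_i(t_{j−1})];

stopping when max |B_{i+1} − B_i| ≤ ε (default 0, i.e. run to the cap
unless the baselines repeat exactly) or after `max_iter` iterations
(default 5, the regime where convergence is typically reached by the
fourth pass for mild fouling; severe fouling, γ near 10⁻², needs of order
30 iterations for ~10⁻⁴ relative recovery, and the tests run with an
explicit cap of 50). B(t_0) ≡ 0 — no deposit before any exposure. The
elution region runs from the first frame to t_s1; past t_s1 the same
recursion continues, which pins the plateau to I_BL by construction. If
S_i ≤ 0 the correction would *add* signal; that chromatogram is skipped
and flagged `0s`, reproducing the original naming convention.

The chromatogram used to *compute* the baseline is Gaussian-smoothed
(7 points by default; kernel sd = support/4, renormalized at the edges) to
tame low-q oscillation around the iterates, but the subtraction is always
applied to the raw data. A species-dependent γ is exposed in the data
model but not fitted, matching the method's stated first-approximation
scope.

**Region search.** A window (default 20 frames) slides over the candidate
range; per start frame the package computes (i) the average red-cluster
size of the window's pairwise P-value map, compared with the same
statistic over a buffer-only reference measured with identical options,
and (ii) the windowed mean ± sd of the cumulative intensity over the q
cutoff. Windows whose indicator (i) stays within the blanks' mean + 1 sd
are candidates; the chosen region is the *latest* consecutive run of
candidates (elution tails make early flat zones untrustworthy, so recency
wins; the run's indicator-(ii) flatness is reported). The suggestion is
"integral baseline" exactly when the minimum windowed cumulative intensity
stays above zero — the signal never returned to a clean-buffer level — and
"none/linear" otherwise. A plain linear baseline through two anchor
windows is provided for drift-only cases.

## Peak shapes

All shapes share a0 = area (intensity × frames), a1 = center, a2 = width
(frames; the time axis is the dimensionless frame index, seconds being
metadata). The EMG is the Gaussian ⊗ one-sided-exponential convolution
with time constant |a3| (sign selects tailing vs fronting; first moment
a1 + a3); the GMG is the Gaussian ⊗ half-Gaussian convolution with
half-width a3 (mean a1 + a3·√(2/π), variance a2² + a3²(1 − 2/π)); the
EMG+GMG hybrid is implemented as the equal-weight average of an EMG with
distortion a3 and a GMG with distortion a4 on the common (a0, a1, a2).
The ½–½ weighting is the common commercial-package convention for this
hybrid; whether the original implementation uses another affine
combination cannot be determined from published material, so the
convention is documented here for anyone reconciling outputs.

**Numerical evaluation.** The EMG is computed through the scaled
complementary error function, `erfcx(x) = exp(x²) erfc(x)`, with an
asymptotic branch beyond x = 25, and on the reflection branch through the
identity u² − x²/(2a2²) = a2²/(2τ²) − x/τ whose exponent is negative
whenever it is taken — so the evaluation neither overflows nor cancels
anywhere in the physically relevant range (tested to |t − a1|/a2 = 50 and
a3/a2 = 10⁻³). Because of this, the Gaussian-limit guard routes to the
exact Gaussian only below |a3| < 10⁻¹²·a2. A wider guard would be
numerically unnecessary and — more importantly — creates a zero-gradient
dead zone around a3 = 0 that stalls derivative-based fits whose finite
difference steps fall inside it; this was observed directly and is why
fits also *start* the distortions at a quarter of the initial width
rather than at the locally flat symmetric point.

## Decomposition

A decomposition model is a set of N peak families with one shape per
family shared by every chromatogram, and an n_q × N matrix of free
non-negative amplitudes. The fit cascade follows the workflow a user
would run interactively:

1. `svd_rank()` — the singular spectrum of the signal block, with an
   advisory suggestion (largest ratio gap); the component count remains
   the user's decision.
2. `fit_single()` — one low-q chromatogram, N shapes, bounded
   Levenberg–Marquardt (`minpack.lm::nls.lm`) over the shape parameters
   with the areas solved exactly per trial shape by weighted non-negative
   least squares (`pracma::lsqnonneg`) — a variable-projection scheme.
   Distortions are tied across peaks by default (one column-interaction
   mode for all species); the tie can be released.
3. `init_global()` — shapes copied to the selected chromatograms (e.g.
   one in four across the q range), amplitudes fitted per q; linear, so
   exact.
4. `global_fit()` — joint weighted least squares over all selected
   chromatograms with common centers/widths per family and global
   distortions; parameter groups can be frozen via bound pinning.
5. `fit_all_amplitudes()` — amplitude-only solves extended to every q.

**Tie-breaks and bounds.** Centers are parameterized as (first center,
positive gaps) with a minimum gap of half a frame, so family identity is
stable — centers cannot cross during optimization. Widths are bounded
below at half a frame; distortions at ± the frame span. Fit limits default
to excluding the first and last 5% of frames, where chromatograms are
noisiest. The optimizer is deterministic given the initialization; no
random restarts are performed by default.

**Identifiability.** The a3/a4 split of the EMG+GMG hybrid is only weakly
determined when the skew is mild relative to the width: near-identical
peak shapes arise from different (a3, a4) pairs, and at 1% noise the
parameters slide along this ridge even though the *shapes* (and
everything downstream: amplitudes, back-generated frames, R_g) are
recovered accurately. Parameter-level recovery claims are therefore only
meaningful for clearly skewed peaks, which is how the demonstration
layout is configured (distortions 12 and 9 on a width of 6).

**Goodness by q.** For every fitted chromatogram the package reports the
reduced χ² and the longest-run P value of data versus fit over the fit
limits, with the usual three-class code. The two indicators are
complementary: χ² inherits every defect of the σ estimates, while the
run-length test is σ-free.

**Back-generation.** Species frames are rebuilt as amplitude × unit shape.
Original uncertainties are reassigned unchanged; optionally a caller-chosen
fraction of the local |data − total fit| discrepancy is added in
quadrature, apportioned by the family's share of the total model intensity
at that point. No default fraction is implied by the method, so the
argument is required.

## Concentration channel

The UV (or RI) trace keeps its native time base and is shifted and
linearly interpolated onto the frame axis (detector sampling is dense
relative to frames); an automatic shift maximizes cross-correlation with a
reference chromatogram. The trace is then decomposed with the
SAXS-optimized families under the constraints that make the
correspondence meaningful: centers within ±2% of the SAXS values
(default), widths fixed (widths and distortions are strongly coupled
here), distortions and areas free. Traces usually carry no σ, so the fit
is unweighted and residuals are absolute.

**Reshaping.** Band broadening between detectors is undone by giving each
concentration family the SAXS family's shape while keeping its own fitted
area — conservation is exact by construction, and each reshaped family is
pointwise proportional to its SAXS counterpart. Per-frame concentrations
follow Beer–Lambert, c = signal/(E·path), with a 1 cm default path length;
frames are then normalized by c, and average curves use inverse-variance
weights. The known cost of reshaping: mass estimates along a reshaped
peak vary only with the residual misfit of the SAXS decomposition, i.e.
they are artificially flat.

## Scattering analysis

The Guinier fit is a weighted linear regression of ln I on q² with
σ_lnI = σ/I; R_g = √(−3·slope), I(0) = exp(intercept), standard deviations
from the weighted-regression covariance. Automatic mode shrinks q_max (at
most 20 rounds) until q_max·R_g ≤ 1.3, the community convention for
globular particles. Positive slopes are flagged unphysical rather than
propagated.

The concentration-independent mass uses the volume of correlation,
V_c = I(0)/∫ q I dq with the integral truncated at 0.2 Å⁻¹ and the
unmeasured low-q gap filled by the fitted Guinier model from q = 0;
Q_R = V_c²/R_g and M = (Q_R/0.1231)^1.0 (protein constants of the cited
volume-of-correlation calibration, converted to kg/mol). Warnings are
issued when the grid tops out below 0.2 Å⁻¹ or defaults are changed.
These constants are empirical, derived from real protein curves; an
idealized homogeneous sphere reads roughly a third low against them, which
the test suite asserts as a property rather than hiding.

The absolute-scale mass is M = I(0)·N_A/(c·Δρ_M²) with the contrast per
unit mass Δρ_M = r_e(n_e − ρ_solv·v̄), using 3.22×10²³ electrons/g of
protein, water at 334 e/nm³ and v̄ = 0.736 ml/g as defaults.

χ is the classical Pearson form normalized by n − 1, with an optional
closed-form optimal scale; r_σ is the RMS of the σ values — the form that
makes χ·r_σ exactly invariant under a global rescaling of the
uncertainties, which is the property the score exists for (the plain mean,
which shares the invariance, is available as an option). NNLS model
combination is σ-weighted, reports percentage weights and the best single
curve by χ·r_σ.

## The synthetic-data generator

`generate_sec_saxs()` builds I(q,t) = Σ_s F_s(q)·peak_s(t) + B*(q,t) +
noise with the deposit recursion B*(q,t_k) = B*(q,t_{k−1}) +
γ(q)·signal(q,t_{k−1}); σ(q,t) = a·I + b·max(I) on the noiseless
intensity (defaults a = 0.01, b = 10⁻³, a counting-statistics-like
heteroscedastic model); concentration profiles strictly proportional to
the elution shapes; a band-broadened UV trace (Gaussian kernel, area
conserved, default sd 3 frames); and buffer frames of pure floor noise,
optionally with a two-point moving-average correlation along q — chosen
because it gives correlation exactly ½ at lag 1 and exactly 0 at lag 2,
so stride-2 sampling restores independence, the cleanest mirror of the
pixel-smearing effect the stride option exists for. Everything is
reproducible from a single integer seed, and the full ground truth
(species surfaces, baseline, γ, concentrations) is returned.

The default layout is a four-species oligomer ladder: R_g 95/63/52/36 Å
with Guinier-exact form factors, EMG+GMG elution peaks at frames
60/85/105/130, width 6, shared distortions (12, 9), areas 30/80/150/600
(a 100-fold amplitude dynamic range through the form factors), γ = 2×10⁻⁴,
160 q points from 0.004 to 0.2 Å⁻¹ and 240 frames. The q density keeps a
dozen points inside the Guinier range of the largest species; global fits
use a one-in-four q subset (40 chromatograms), the workflow a real user
would run, with amplitudes extended to the full grid afterwards.

**What it does not emulate** — and hence what passing tests do not show
about real data: detector artifacts and masked pixels, inter-frame beam
intensity drift, buffer-subtraction residuals, radiation damage other
than fouling, q-dependent smearing, non-Gaussian counting noise at very
low counts, and species whose true form factors deviate from the
Guinier/sphere models. The fouling model is exactly the model the
correction assumes; real fouling that violates proportionality or cleans
the capillary will not be corrected this well.

## Problem sizes

The test suite and the acceptance script run, by design, at the sizes a
desk validation of this method calls for: 500-frame noiseless fouling
simulations over γ ∈ {10⁻⁴, 10⁻³, 10⁻²}; exhaustive run-length
enumeration to n = 16; 60 buffer frames (1770 pairs) for the map-level
statistics; the full four-species surface (160 q × 240 frames, 40
chromatograms in the global fit) for decomposition and reshaping; and 200
Monte-Carlo replicates for the Guinier calibration. The whole suite runs
in well under a minute of compute plus the workflow integration test.

## Known limitations

* The steady-state region search is O(windows × window² × n_q) in
  pairwise comparisons; very long scans with large windows are slow.
* The EMG/GMG distortion split is not identifiable for mildly skewed
  peaks (see above); interpret a3/a4 individually only when the skew is
  strong, and prefer shape-level comparisons otherwise.
* The fouling correction requires a genuine steady-state stretch; if
  elution never ends within the series, the method reports rather than
  guesses.
* Holm–Bonferroni coloring and the noise-trimming rule reconstruct
  behaviour whose exact original definitions are unpublished.
* SVD-subspace denoising and species-dependent fouling coefficients are
  deliberately out of scope.
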