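---
title: "Models and methods behind vesiclequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesiclequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclequant)
```

# The optical read-out and its generative model

A pHluorin-tagged vesicle protein is quenched at the acidic pH of the
vesicle lumen and fluoresces at the neutral pH of the bath. With
reacidification blocked by bafilomycin A1, the evoked fluorescence rise of
a bouton tracks cumulative exocytosis. The package's synthetic generator
produces bouton traces as

$$F(t) = e^{-t_\mathrm{elapsed}/\tau_\mathrm{bleach}}\,
  \bigl[B + T\,V(t)\bigr] + \varepsilon,\qquad
  \varepsilon \sim N(0,\ \sigma_\mathrm{rel} T),$$

where $T$ is the bouton's total fluorescence, $B$ the background level, and
the visible fraction at bath pH is

$$V(t) = s + (1-s)\bigl[c(t) + q_v\,(1 - c(t))\bigr],$$

with $s$ the surface (plasma-membrane) fraction, $q_v$ the residual
visibility of pHluorin at vesicular pH, and $c(t)$ the cumulative fused
fraction of the vesicular pool. NH4Cl superfusion sets $V = 1$ (the
total-pool reference) and an acidic MES bath sets $V = q_\mathrm{MES}$.
During tonic 10 Hz stimulation the recycling pool of relative size $R$ is
mobilized with first-order kinetics, $c(t) = R(1 - e^{-t/\tau})$, monotone
non-decreasing because bafilomycin removes reacidification. For the
readily-releasable-pool protocol, $c$ rises linearly to the RRP fraction
over the 2 s, 20 Hz burst (release of a finite primed pool), holds through
the 3 s recovery gap, and then resumes first-order kinetics toward $R$ when
10 Hz stimulation begins.

A useful identity follows from this model: after ΔF/F₀ and normalization to
the NH4Cl peak, the surface and quench terms cancel exactly and the
normalized trace *is* $c(t)$. This is what makes every downstream metric
analytically checkable, and it is the basis of the package's closed-form
tests.

## Protocols

Two evoked protocols and one buffer-sequence protocol ship as presets,
encoding the acquisition timings of the assay family: `pool_1200ap` (1200
AP at 10 Hz for 120 s, NH4Cl window 140–160 s, 1 s frames, baseline frames
at t = −5…−1 s), `rrp_40ap` (40 AP at 20 Hz over 2 s, 3 s recovery, then
10 Hz; frames at 10 Hz during the 5 s burst-plus-recovery and 1 s
elsewhere), and `partitioning` (saline / MES / NH4Cl windows with
perfusion-exchange gaps). Windows are half-open `[start, end)` in seconds
with t = 0 at stimulation onset; frames are 0-indexed.

## What the generator emulates — and what it does not

Emulated: quenched vesicular and visible surface fractions; cumulative
fusion under bafilomycin; NH4Cl dequench and MES quench windows;
exponential photobleaching shared between background and synaptic ROIs;
additive Gaussian acquisition noise; non-responsive ("dead") boutons that
dequench under NH4Cl but never fuse (15% of synaptic ROIs by default, to
exercise the QC screen); bouton-to-bouton parameter heterogeneity (±10%
uniform jitter around field-nominal values).

Not emulated: Poisson/shot noise (noise is Gaussian and additive after
bleach scaling — a documented simplification), spatial structure (the
generator works at trace level, not image level), XY drift (registration is
assumed upstream), endocytosis/reacidification (bafilomycin assumed
throughout), spontaneous release, and any bleach heterogeneity between
ROIs. Passing tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to, e.g., drift artefacts or
non-exponential bleaching in real recordings.

Default parameters are typical for the preparation: total bouton
fluorescence 1000 a.u., surface fraction 0.25, recycling fraction 0.55,
RRP fraction 0.08, τ = 20 s, vesicular residual visibility $q_v = 0.06$
(pHluorin is ~94% quenched at vesicular pH), MES residual
$q_\mathrm{MES} = 0.03$, bleach τ = 600 s, relative noise SD 0.02. The bath
quench residuals are literature-typical rather than measured for this
assay, and are configurable.

# Trace processing

**Bleach correction.** A single exponential $a e^{-bt}$ (no offset) is
fitted by nonlinear least squares to the mean background-ROI trace over the
experiment before NH4Cl onset, with $t$ from the first acquired frame. The
pure-exponential form matches the single-exponential correction convention
for background autofluorescence; an offset is unnecessary here because the
mean background is subtracted from synaptic ROIs before ΔF/F₀ anyway.
The correction multiplies each trace by $e^{+bt}$, leaving the first frame
unchanged. Fits are initialized from a log-linear regression; a
non-decaying background (log-slope ≥ −10⁻⁸/s) is clipped to $b = 0$ rather
than fitted, and fit failures raise after three bounded restarts.

**ΔF/F₀ and QC.** F₀ is the mean of the 5 frames immediately before
stimulation onset. An ROI is *responsive* when its mean ΔF/F₀ over the
stimulation window and its peak ΔF/F₀ in the NH4Cl window both exceed
`noise_k` baseline SDs (default `noise_k = 2`; the threshold multiplier is
a package choice, as the inclusion criterion "increased fluorescence from
baseline" needs a quantitative form). A field enters the final data only
with strictly more than 20 responsive ROIs. Raising `noise_k` can only
shrink the responsive set (a tested invariant).

**Normalization.** "Peak fluorescence at the end of stimulation" is
operationalized as the mean of the last 5 stimulation-window frames
(robust to single-frame noise); the NH4Cl reference is the window maximum.

# Exocytosis metrics

* **Recycling pool** = 100 × end-of-stimulation ΔF/F₀ / NH4Cl peak ΔF/F₀.
* **τ** from `P (1 − e^{−t/τ})` fitted over the entire stimulation window
  of the stim-peak-normalized trace. The plateau `P` is free and bounded in
  (0, 1.5] because stim-peak normalization pins the *endpoint*, not the
  asymptote, at 1 — fixing `P = 1` would bias τ downward for
  non-saturating traces. τ is bounded in (0.1 s, 10 × window]; a fit with
  any parameter on a bound (e.g. a near-linear trace pinning `P` at its
  cap) is flagged as non-interpretable. τ is fitted on the
  stim-peak-normalized trace, which the time-course normalization pairs
  with; this is an interpretation choice, stated here because either
  normalization admits a one-phase fit.
* **Initial rate** is the least-squares slope of the NH4Cl-normalized
  trace over t ∈ [0, 5] s, where cumulative fusion is still nearly linear;
  units are normalized (ΔF/F₀)/s.
* **% fused by n AP** reads the NH4Cl-normalized trace at the frame nearest
  t* = n_AP/frequency (200 AP at 10 Hz → exactly the 20 s frame at the 1 s
  frame interval; nearest-frame lookup, no interpolation).
* **RRP** is the mean NH4Cl-normalized ΔF/F₀ over the 3 s recovery gap
  (t ∈ [2, 5) s), using all the 10 Hz-sampled frames the protocol provides
  rather than a single burst-end frame.

Metrics are computed per field of view and only then aggregated per
variant (mean ± SEM over fields), uniformly for all metrics.

Note one small, intended bias pair: the recycling-pool estimator measures
$c(120) = R(1 - e^{-120/\tau})$, which undershoots $R$ for slow variants
(−2.7 points at R = 0.55, τ = 40 s), and the NH4Cl window maximum
overshoots the noiseless plateau by the expected maximum of the frame
noise. Both are properties of the estimator definitions, not defects, and
both are covered by the parameter-recovery tolerances.

# Localization metrics

The axonal coefficient of variation is the sample SD over mean of a
single-pixel line profile of ≥ 265 px (60 µm at 0.227 µm/px); a field-level
value averages five such profiles. Membrane partitioning uses plateau
means over the central 80% of each buffer window (avoiding
perfusion-transition frames, for which no published rule exists):
surface % = 100 (F_saline − F_MES)/(F_NH4Cl − F_MES), vesicular % is its
complement, and noise-driven negative estimates are clipped to 0 and
flagged rather than erroring. Because unfused vesicular probe retains
visibility $q_v$, the surface estimate carries a known upward bias of
$(1-s) q_v$ in the numerator — quantified analytically in the tests.
Expression fold-change is (transfected − background)/(untransfected −
background) on mean ROI intensities; background subtraction precedes
averaging.

# Group statistics

Each metric's per-variant samples are formally tested for normality
(Shapiro–Wilk, α = 0.05 per group — the α is a package default); if every
group passes, variants are compared to wild type by one-way ANOVA with
Dunnett's multivariate-t many-to-one adjustment, otherwise by
Kruskal–Wallis with Dunn's rank-based z-tests, Bonferroni-adjusted over
the variant-vs-control family only (matching many-to-one, not all-pairs,
usage). A Brown–Forsythe (median-centred Levene) statistic is reported as
a homoscedasticity diagnostic without influencing the gate.

Whole time courses are compared pointwise: at every timepoint on the
shared frame grid, per-field values of each variant are Dunnett-compared
to control, yielding the boolean significance mask that time-course
figures display as bars. A split-plot omnibus with Geisser–Greenhouse
correction (ε from the double-centred pooled within-group covariance, no
sphericity assumption) is attached as a diagnostic; the displayed
quantity — the mask — depends only on the per-timepoint comparisons, which
is why the mixed-model machinery is not reimplemented beyond this
contract.

# Permutation correlation stage

Spearman's ρ is the Pearson correlation of average-ranked vectors. The
permutation p-value is two-sided under exchangeability of one margin: for
n ≤ 8 (the cohort scale — 8 variants) all n! permutations are enumerated
exactly, p = #{|r*| ≥ |r_obs|}/n!, with a 10⁻¹² tolerance so permutations
tying the observed statistic count as extreme; for larger n a Monte-Carlo
sample is used with the add-one correction (#+1)/(n_perm+1), default
n_perm = 10 000. Age-controlled cells (CVI total and DBC self-injury; the
VABS measures are age-standardized already) use rank-residual partial
correlation: x-ranks and y-ranks are residualized on age-ranks and the
residuals correlated, with Freedman–Lane-style permutation of the
y-residuals. If the y-ranks are an exact function of the age-ranks the
residuals vanish and the partial ρ is defined as 0 (p = 1).

BH-FDR is applied across all computed cells of the 3-metric × 5-measure
family (step-up, flags plus the data-dependent cutoff). Replaying the
reported clinical p-value family (shipped in `extdata`, with "< 0.001"
encoded as 0.0009 — any value below the first step-up threshold of 0.0033
gives identical flags) reproduces exactly the four originally starred
cells. The originally reported global threshold "p ≤ 0.019" is *not* what
standard step-up BH yields on those 15 p-values (the data-dependent cutoff
is 0.005); the flag set is identical either way, and this package
implements standard BH.

Incomplete phenotype pairs are dropped per cell; a cell with fewer than 4
complete pairs (5 when age-controlled) is reported as not computed rather
than raising.

## Synthetic cohort calibration

The phenotype generator links the VABS measures to the % fused by 200 AP
with slopes 0.6–0.8 score units per percentage point and additive score
noise of SD 1, chosen so that realized rank correlations on linked cells at
n = 8 fall in the 0.89–0.98 range of the reported association structure the
cohort emulates; the remaining measures are pure noise around typical base
levels (movement-disorder count rounded to a non-negative ordinal, DBC
self-injury clipped to its 0–10 range). Note that with 9 null cells in the
BH family at q = 0.05, a run of the full synthetic cohort flags at least
one spurious cell in roughly 15–20% of replicates even under perfect
links — a property of the prescribed test family, visible in the end-to-end
recovery tests.

# Numerical choices and degenerate inputs

* Nonlinear fits use Levenberg–Marquardt with analytic-free residuals,
  tight tolerances (ftol = ptol = 10⁻¹⁵ for the one-phase fit, so exact
  model inputs are recovered to machine precision) and box constraints.
* Half-open windows and 0-indexed frames remove boundary ambiguity; t* for
  the AP read-out tolerates half a frame interval beyond the window edge so
  the 1200 AP endpoint remains readable.
* Degenerate inputs raise informative errors rather than propagating NaN:
  zero-variance vectors in correlations, constant groups in the normality
  gate, F₀ ≤ 0 after background subtraction, missing buffer windows,
  NH4Cl ≤ MES plateau (no dynamic range), double application of a
  processing step.
* All simulation entry points take explicit seeds; the Monte-Carlo
  permutation path restores the caller's RNG state.

# Problem sizes used by the test-suite

The suite validates at the assay's natural scale: fields of 25 responsive +
5 dead + 4 background ROIs, 9 fields per condition (the typical per-variant
n of 7–11 coverslips), a τ ∈ {15, 25, 40} s × R ∈ {0.3, 0.55} recovery
grid, 50 fields for QC operating characteristics, 100 seeded fields for
bleach-trend coverage, 2000 null replicates for permutation-test
calibration, 1000 simulated datasets for the normality-gate and Dunnett
calibration, and 100 end-to-end cohort replicates for link recovery.

# Known limitations

* Field-level kinetics only: no per-bouton fitting, release probability,
  quantal size or endocytic rate estimation.
* The bleach model is a pure exponential fitted per field on the mean
  background; per-ROI bleach heterogeneity is not modelled or corrected.
* Confidence intervals for ρ are not part of the correlation contract (the
  reporting convention for them is not standardized for permutation
  Spearman tests at n = 8).
* The synthetic cohort links phenotypes to a single functional metric;
  correlated multi-metric link structures are expressible through
  `phenotype_link()` but not defaulted.
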