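---
title: "Quantifying activity-dependent blood-brain barrier modulation: methods and design notes"
author: "bbbquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying activity-dependent blood-brain barrier modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bbbquant` implements the quantification pipelines used to relate prolonged
somatosensory stimulation to blood-brain barrier (BBB) permeability: an
intravital angiography permeability index (PI), a DCE-MRI voxelwise leakage
mapper with control-cohort thresholding, somatosensory evoked potential (SEP)
plasticity measures, transcriptome-divergence statistics, and the supporting
nonparametric/FDR machinery. Every modality has a synthetic generator with
stored ground truth, so the full chain is testable at desk scale without
animal or human data. This vignette records the models, the tunable
parameters, and the design decisions taken where the methods left genuine
freedom.

# Intravital permeability index

## Model

A fluorescent tracer bolus transits the cortical vasculature; extravasation
into the neuropil marks increased BBB permeability. Per pixel, the measured
intensity is compared to the arterial input function (AIF) extracted from the
feeding artery. For an extravascular pixel $x$ with pre-injection baseline
$b_x$ and a late analysis window $W$:

$$\mathrm{PI}(x) = \frac{\overline{I_x(W)} - b_x}{\overline{A(W)} - b_A}$$

where $A$ is the AIF. A pixel whose tracer content merely tracks the
vasculature has PI near 1; accumulating pixels exceed 1, and pixels with
PI > 1 (strict) are counted as leaking. The pipeline is
registration (integer translation by FFT cross-correlation, median fill) →
vessel segmentation (Otsu threshold on a temporal 95th-percentile
projection, minimum component area 10 px) → AIF extraction → PI map →
summary.

## Design decisions

* **Scalarization.** Dividing curve by curve pointwise is unstable wherever
  the AIF excess crosses zero, so the PI is formed as a ratio of
  baseline-subtracted means over a late window (default: final 20% of
  frames; configurable). This makes the PI exactly scale- and
  offset-invariant, which the tests assert to 1e-9.
* **Baseline.** Mean over frames before the injection frame.
* **Segmentation window.** The temporal projection is restricted to the
  early post-injection frames (first quarter of the post-injection span,
  at least 5 frames). Over the whole movie a strong leakage focus
  accumulates enough tracer to rival vessel brightness and would be
  absorbed into the vessel mask, silently removing exactly the pixels of
  interest; during bolus transit only the lumen is bright. This failure
  mode is visible in the generator at default influx.
* **Summary statistic.** The leak map is summarized three ways
  (`leak_fraction`, `mean_pi`, `pi_p95`) because the scalar convention
  behind published per-animal PI comparisons is not fixed; `leak_fraction`
  (fraction of extravascular pixels with PI > 1) is the primary output.
* **Registration.** Translation-only; cranial-window movies are near-rigid
  and integer shifts make ground-truth recovery exact. Rotation is out of
  scope.
* **Diameter tracking.** Vessel diameter along a cross-section is the
  full width at half maximum of the background-subtracted interpolated
  profile, with sub-pixel linear interpolation at the crossings.

## Synthetic generator

Vessel pixels carry `baseline + AIF(t)`, extravascular pixels
`baseline + K * cumulative-integral(AIF)` — a unidirectional (Patlak-like)
influx model, the simplest consistent with monotone tracer accumulation;
the real dye kinetics are not specified by any of the methods this package
implements, so K is a plumbing parameter, not a physiological estimate.
The AIF is a gamma-variate bolus (shape 3, scale 1.5 s, peak 100 a.u.)
plus a recirculation plateau at 30% of peak: without recirculation the
late-window AIF excess would vanish and the PI denominator with it, which
does not match fluorescein imaging, where the intravascular signal
persists for minutes. Acquisition defaults follow the angiography
protocol: 512 x 512 px over ~1 x 1 mm, 5 frames/s; movies default to 30 s
with injection at 5 s. The default leak focus uses K = 0.05/s, calibrated
once so that the focus exceeds the PI > 1 rule under the default AIF (a
leak invisible to the rule would exercise nothing); the baseline
condition in the analysis scripts uses K = 0.01/s (PI ≈ 0.4, sub-threshold).
A static per-pixel texture (SD 5 a.u.) gives the field the spatial
structure that anchors registration, and additive Gaussian noise
(SD 1 a.u.) models shot/read noise. Motion is integer rigid translation
only, so registration recovery can be exact.

What the generator does **not** emulate: photobleaching, depth-dependent
scattering, pulsation/non-rigid motion, dye recirculation kinetics beyond
a fixed plateau, and vessel-diameter dynamics. Passing tests therefore
demonstrate correctness of the measurement chain, not robustness to every
optical artifact of real cranial-window imaging.

# DCE-MRI leakage mapping

## Model

Subtle BBB leakage produces slow late-phase accumulation of a gadolinium
agent. Per voxel the pipeline estimates pre-contrast T1 by the
variable-flip-angle (VFA) method — fitting the spoiled-gradient-echo (SPGR)
equation

$$S(\alpha) = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}$$

via the standard linearization $S/\sin\alpha = E_1 \, S/\tan\alpha +
M_0(1-E_1)$ — then inverts the SPGR equation along the dynamic series to
get $T_1(t)$ and concentration $C(t) = (1/T_1(t) - 1/T_1(0))/r_1$, fits an
ordinary least-squares line to the late phase, normalizes each voxel's
slope to the subject's transverse-sinus slope, and flags voxels exceeding
the 95th percentile of the mean control-cohort CDF. Regional leak
percentages are tabulated per atlas parcel and hemisphere, and compared
task-vs-control by two-way ANOVA with two-stage FDR correction; leak masks
are also intersected with an fMRI activation mask (counts, percent of
activated voxels leaky, Dice).

## Parameters

| parameter | default | notes |
|---|---|---|
| repetitions × spacing | 100 × 10 s | 16.7 min scan; injection after 5 baseline repetitions |
| VFA flip angles | 5, 15, 20, 25° (TR 10 ms) | dynamic scan at 20°, TR 4 ms |
| relaxivity $r_1$ | 3.5 L mmol$^{-1}$s$^{-1}$ | literature value for a macrocyclic Gd chelate at 3 T; configuration value, not an estimated quantity |
| control percentile | 0.95 | threshold on the mean control CDF |
| CDF grid | 1000 points | spanning the pooled control range, linear interpolation |

## Design decisions

* **Late window.** "Later stage of the scan" is operationalized as the
  final two-thirds of post-bolus repetitions. Bolus end is detected on the
  brain-mean concentration curve as the first repetition after the
  steepest rise whose increment falls below 10% of the peak increment.
  The curve *maximum* is not used: in accumulating tissue the mean curve
  is monotone and its maximum sits on the last repetition, leaving no
  post-bolus phase at all. The window is configurable.
* **Concentration conversion.** T1-based inversion is the primary mode; a
  relative-enhancement fallback ($\Delta S/S_0$, proportional to
  concentration in the linear regime) is provided because acquisition
  protocols that collect VFA T1 do not always use it.
* **Sinus summary.** Median of the raw slopes inside the sinus mask —
  robust to partial-volume voxels at the sinus boundary.
* **Mean CDF.** Average of per-subject empirical CDFs on a common
  1000-point grid; the threshold interpolates linearly between grid
  points. With equal voxel counts per control this makes the pooled
  control flag rate 1 − percentile almost exactly, which the tests verify
  against a binomial 99% interval.
* **Strict inequality** at both the PI threshold and the slope threshold.
* **Hemispheres.** Atlas labels carry explicit `i`/`c` tags; no laterality
  is inferred from image orientation (the radiological-vs-neurological
  flip is a classic silent error; masks are authoritative).
* **Indexing.** Volumes are `(z, y, x)` arrays; NIfTI affines are
  preserved on I/O but ignored by the analysis, which assumes pre-aligned
  grids.

## Synthetic cohort

The generator draws per-voxel *normalized* late-phase slopes — null
N(0, 0.02) for every control voxel, N(0.15, 0.05) for the leak fraction
(default 20% of the contralateral postcentral parcel, PoG_c, in task
subjects) — multiplies by the sinus raw slope (5e-4 mM/s), builds the
piecewise concentration curve (flat baseline, 3-repetition bolus ramp to
0.1 mM in tissue and 1.0 mM in the sinus, then the linear late phase),
and synthesizes the SPGR signal through the full T1 forward model with
matching VFA series (tissue T1 1.2 s, blood 1.6 s, M0 1000), plus 0.5%
Gaussian signal noise. The default grid is 4 x 32 x 32 voxels with eight
parcels (PrG/PoG/MFG/MOG × i/c) and a sinus strip: small enough that a
16-subject cohort runs in seconds, large enough that each parcel holds
448 voxels and percentile thresholds are stable. The piecewise model is
deliberate: the analysis fits only a late-phase line, so a full
pharmacokinetic model would add parameters without exercising any
additional code path.

Not emulated: B1 inhomogeneity, T2*/transverse effects, motion,
partial-volume mixing, water-exchange effects on relaxivity. The
noiseless chain recovers true normalized slopes to ~1e-13, which verifies
the inversion algebra, not MR physics.

# SEP plasticity measures

Traces digitized at 1 kHz are band-pass filtered (4th-order Butterworth,
1 Hz high-pass, 45 or 300 Hz low-pass, applied forward-backward for zero
phase; the trace mean is removed first so a large DC offset cannot ring
through the filter edges). Epochs of −50 to +300 ms around each stimulus
are averaged; the baseline is the pre-stimulus mean. Two measures over
10–160 ms post-stimulus (0–10 ms is excluded as stimulus artifact):

* **max amplitude** — absolute value of the global minimum of the
  baseline-referenced waveform (the dominant negative peak; ties broken
  by earliest latency through the minimum);
* **absolute AUC** — trapezoidal integral of |waveform − baseline|,
  capturing positive and negative deflections alike.

Both are compared to the same session's pre-stimulation baseline as
percent change, which cancels inter-animal SEP-morphology differences.
Spontaneous-activity spectra use Welch PSD (2 s Hann windows, 50%
overlap, one-sided, Parseval-scaled) over 10-minute segments; the paired
test on log band power (1–45 Hz) pairs consecutive 30 s blocks by index —
the pairing unit is a design choice, and identical traces return t = 0,
p = 1 by explicit convention rather than a 0/0.

The generator inserts a fixed evoked template (dominant negative peak at
20 ms, width 8 ms, 150 µV, with a smaller positive lobe at 60 ms) into
1/f Gaussian noise (exponent 1, SD 20 µV — a typical LFP spectrum), at
6 Hz trains of 360 pulses (60 s), scaling post-marker responses by the
potentiation factor. Consecutive 6 Hz responses overlap a 300 ms epoch
window; the template is confined to 0–160 ms so the measures themselves
are unaffected, and the averaging tests use non-overlapping trains where
the iid averaging law is asserted. Not emulated: spike activity, drifting
electrode impedance, line noise, state-dependent SEP variability.

# Transcriptome divergence

Counts are normalized by median-of-ratios size factors (geometric-mean
reference over genes with no zero count; library-size fallback with a
warning when no such gene exists). Factors are rescaled to geometric mean
1, which makes normalization exactly idempotent. Divergence between the
paired hemispheres of each animal uses the Jensen-Shannon divergence on
probability-normalized profiles, base-2 logs, 0·log0 = 0 (no pseudocount
needed under that convention):

$$\mathrm{JSD}(p, q) = \tfrac12 KL(p \| m) + \tfrac12 KL(q \| m),
\quad m = \tfrac{p+q}{2} \in [0, 1]\ \mathrm{bits}$$

Per-animal JSDs are compared between timepoint groups with an exact
rank-sum test. DEG-category comparisons use the Pearson chi-square
without continuity correction on an explicit contingency table — the
expected-count models behind published cell-type comparisons are not
reconstructable from headline numbers, so the operation takes the table
rather than guessing one. DEG *calling* (Wald tests, shrinkage) is out of
scope; `is_deg` flags are inputs.

The generator draws negative-binomial counts (log-normal gene means,
dispersion 0.05, size factors in [0.7, 1.4]) for 8 animals per timepoint
with both hemispheres, and perturbs the contralateral hemisphere in a DE
fraction of genes — 7.3% at 1 hr and 13.2% at 24 hr, the observed DEG
rates for this design — with |log2FC| ~ N(1, 0.5). The larger 24 hr DE
fraction is what drives the higher paired JSD at 24 hr that the tests
recover. Not emulated: batch effects, gene-gene correlation, length
biases.

# Statistical machinery

* **Exact Wilcoxon signed-rank.** Zero differences dropped (the original
  convention), midranks for ties, and for n ≤ 25 the exact null
  distribution of the positive-rank sum by dynamic programming over the
  doubled (hence integer) ranks — equivalent to enumerating all $2^n$
  sign assignments, which the tests verify exhaustively for n ≤ 8. Above
  n = 25, the normal approximation with tie and continuity correction.
  Two-sided p doubles the smaller tail, capped at 1; the smallest
  attainable two-sided p is $2^{1-n}$ (0.03125 at n = 6 — which is why
  n = 6 paired results reported at p = 0.0312 imply a uniformly one-sided
  sample; at n = 5 the two-sided minimum is 0.0625, so a reported 0.0312
  at n = 5 can only be one-sided — both alternatives are exposed).
* **Two-stage step-up FDR (Benjamini-Krieger-Yekutieli).** Stage 1:
  linear step-up at q′ = q/(1+q), giving r1 rejections; r1 = 0 rejects
  nothing, r1 = m everything; otherwise stage 2 reruns the step-up at
  q′·m/(m−r1). Q-values are obtained by inverting the rule (bisection on
  the smallest nominal q at which the hypothesis is rejected; the rule is
  monotone in q). One subtlety: the two-stage set is *not* always a
  superset of plain BH at the same q — that holds only when the stage-2
  level reaches q (r1 ≥ m·q/(1+q)); the property tests assert exactly the
  guaranteed relations.
* **Nested t-test.** Sections are collapsed to per-animal means and an
  equal-variance two-sample t-test is run on the means (df =
  n_A + n_B − 2). This is the aggregation reading of a nested design —
  equivalent to nested ANOVA when balanced, and immune to
  pseudo-replication; a mixed-model variant could differ under strong
  imbalance.
* **Omnibus + post-hoc.** Kruskal-Wallis (pairwise rank-sum post-hoc) or
  two-way ANOVA `y ~ group * block` (per-block t contrasts), corrected
  with the two-stage FDR. Recovery properties are stated in FDR terms:
  the seeded contrast is essentially always detected, while falsely
  rejected null contrasts are bounded in expectation by m·q — demanding
  *zero* false rejections would test family-wise control that a
  step-up FDR procedure intentionally does not provide, and such a
  criterion would fail about one run in ten by design.

# Numerical choices and degenerate inputs

* Registration on a constant frame, segmentation of a uniform projection,
  an AIF without excess over baseline, a sinus with non-positive slope,
  all-zero paired differences, and zero-margin contingency tables raise
  errors rather than returning numbers.
* Non-physical VFA slopes (≤ 0 or ≥ 1) and non-invertible SPGR samples
  yield NaN per voxel/sample; flat-signal voxels are detected explicitly.
* All generators take explicit integer seeds and restore the caller's RNG
  state; identical parameters and seed give byte-identical outputs.

# Problem sizes

Tests and the acceptance script run reduced-size instances chosen to keep
every statistical check well-powered: 48–96 px angiography fields (the
acquisition default is 512 px), the 4 x 32 x 32 DCE grid with 6 task and
10 control subjects per cohort and 20 cohorts for the end-to-end
recovery, 100-seed sweeps for potentiation recovery, the full 20,000-gene
default for count cohorts, and 500–1000 replicate null simulations for
the FDR machinery.

# Known limitations

* The Patlak-like influx model is a stand-in: no published kinetic model
  exists for the fluorescein extravasation this emulates, so K values are
  internally consistent but not physiologically calibrated.
* The PI scalarization and the late-window conventions are defensible
  choices among several; both are configurable and the summary exposes
  alternative statistics.
* The DCE atlas is a toy parcellation; real use requires registered
  anatomical atlases and the affine-aware plumbing deliberately left out
  of scope.
* The SEP measures assume a dominant *negative* peak; recordings with
  inverted polarity must be flipped upstream.
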