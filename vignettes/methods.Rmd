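---
title: "Fingerprint, clustering and single-marker quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint, clustering and single-marker quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamsfp)
```

## The problem

Fermented *Cordyceps sinensis* products are marketed in three dosage
forms (Jinshuibao capsules and tablets, fermented with *Paecilomyces
hepiali*; Bailing capsules, fermented with *Hirsutella sinensis*) whose
pharmacopoeial standards cover only a subset of constituents. A combined
evaluation uses the HPLC-UV fingerprint at 260 nm: ten common peaks, of
which five are the marker nucleosides — in the template used here,
common peaks 4, 7, 8, 9 and 10 are uracil, uridine, adenine, guanosine
and adenosine. Three analyses share that fingerprint: similarity
analysis of whole standardized chromatograms, hierarchical clustering of
common-peak-area vectors, and single-marker (QAMS) quantification of the
four non-marker nucleosides from the adenosine peak.

The raw instrument traces behind the published assay are not deposited,
so the package pairs the analysis stages with a synthetic chromatogram
generator carrying full ground truth, and bundles the published summary
tables as plain-text fixtures whose statistics are recomputed, not
transcribed.

## The synthetic study

`simulate_chromatogram()` builds a trace as a sum of Gaussian peaks plus
baseline drift and white detector noise. Peaks are Gaussian because no
peak-shape data are published and the Gaussian gives closed-form areas
(`area = height · σ · √(2π)`) against which integration is testable; the
generator parametrizes each peak by its true area
`amount (µg/mL) × response_factor`, with the nucleoside response factors
set to their calibration-curve slopes so that simulation, external
standard calibration and QAMS are mutually consistent.

Key defaults, chosen once as plausible values for this assay and held
fixed:

* **Grid** 0–30 min at 0.005 min — the published separation completes
  within 30 min; 0.005 min (0.3 s) is a typical DAD sampling period.
* **Retention times** 2.2, 3.0, 5.3, 6.8 (uracil), 13.5, 20.0, 21.5
  (uridine), 23.2 (adenine), 25.0 (guanosine), 27.5 (adenosine) min.
  This layout reconciles three published statements that cannot all hold
  under typical early nucleoside elution: the identification of
  fingerprint peaks 4/7/8/9/10 as the five nucleosides, the near-absence
  in Bailing capsules of the constituents at 5.3, 13.5 and 20 min, and
  Bailing's *high* guanosine and adenosine contents. The 5.3/13.5/20 min
  peaks are therefore unidentified constituents (indices 3, 5, 6),
  suppressed in the Bailing-like class; the tablet-like class carries
  the lowest level of the 3.0 min constituent.
* **Peak widths** σ = 0.06–0.15 min, increasing with retention time as
  on a real column; adjacent template peaks stay baseline-separated.
* **Noise** sd 0.5 detector units; the smallest quantified peak (uracil
  in the Bailing-like class) then has S/N ≈ 700, so LOD/LOQ remain far
  below working levels, as in the published validation.
* **Baseline drift** amplitude 2 units — a gentle ramp plus one slow
  sine cycle, small against the smallest peak (height ≈ 350) but large
  against the noise, so baseline handling is actually exercised.
* **Retention-time error**: a per-sample multiplicative warp
  (sd 0.4%) shared by all peaks — the dominant run-to-run mode that the
  retention-time normalization step must undo — plus small per-peak
  jitter (sd 0.008 min).
* **Contents** (mg/g) per class follow the published orderings
  (Jinshuibao: adenosine > uridine > guanosine > adenine > uracil;
  Bailing: adenosine > guanosine > uridine > uracil > adenine), with
  magnitudes in the ranges of the published 30-sample content table.
* **Between-sample variability**: a shared lognormal potency factor
  (CV 8%) times small per-analyte lognormal noise (CV 1.5%). A shared
  factor is the realistic dominant mode (fill weight, extraction yield)
  and preserves the per-sample content orderings that independent 8%
  noise would frequently break; it is also invisible to cosine-based
  similarity, which is scale-invariant, so class separation rests on the
  profile shapes, as it should.
* **Unit path**: content (mg/g) → solution concentration via the 1.00 g
  in 50 mL preparation, `C (µg/mL) = content × 1000 / 50`; both ESM and
  QAMS invert the same path, so the two routes are comparable to
  machine precision when exact.

What the generator does *not* emulate: gradient-induced baseline steps,
tailing/fronting peak shapes, co-eluting interferents, detector
saturation, and inter-instrument response differences beyond a scalar.
Passing tests therefore demonstrate the correctness of the computations
and their statistical behaviour under a clean, known model — not
robustness to every pathology of real chromatography.

## Peak processing

Noise is estimated on a peak-free window (default 8.5–12 min) as the
normal-scaled median absolute deviation of linearly detrended intensity;
the published assay does not define its noise estimator, and the MAD is
robust to small baseline curvature. Detection smooths the trace with a
Savitzky–Golay filter (order 3, 21 points), takes local maxima whose
chord-corrected height reaches `min_snr × noise` (default 10), and walks
to the flanking valleys, capping bounds at ±5 σ-equivalents estimated
from the full width at half maximum. With zero stated noise, a floor of
10⁻⁶ of the trace amplitude suppresses numerical smoothing ripples.
Integration is the trapezoid of intensity minus the chord between the
bound intensities (each averaged over ±3 points to stabilise the anchors
against noise); this chord-baseline trapezoid is a documented choice —
the published integration rules are unstated.

Common-peak matching assigns detected apexes to the nearest template
time within a relative tolerance (default 2%; the published work states
none), keeps at most one peak per index (closest wins, ties to the
larger area), and computes RRT/RPA against adenosine. A sample lacking
the adenosine peak is flagged and excluded from RRT/RPA with a warning
rather than failing the run.

Retention-time normalization is a piecewise-linear warp through the
matched anchors, extended outside them with the nearest segment's slope,
followed by linear-interpolation resampling onto the common grid. A
multiplicative warp is exactly undone by this map given ≥ 2 anchors.

## Calibration, LOD/LOQ, ESM

Calibration is ordinary least squares of area on concentration over six
levels (two-fold serial dilution from the top of each linear range);
R² is the squared Pearson correlation. LOD and LOQ use the 3:1 and 10:1
signal-to-noise definitions on an auxiliary *height* calibration, since
S/N is a height ratio and the published choice of height vs area is not
stated; `loq/lod = 10/3` identically. RSDs throughout use the sample
(n−1) standard deviation — the convention under which the published
per-injection-volume correction factors reproduce their printed RSDs
(the population denominator does not).

## QAMS

Correction factors are measured from standard-mixture injections
(`measure_rcf()`), summarized per robustness axis by mean and RSD, and
the grand mean per analyte is applied in batch quantification; adenosine
itself is always ESM-quantified. Injection volume scales all areas
jointly, so it serves as a robustness axis only and cancels from the
content formula. Substituting the definition of the factor into the
quantification formula with the same standards reproduces ESM exactly
(an algebraic identity held to machine precision in the tests), so any
QAMS–ESM discrepancy measures condition drift and noise, not algebra.

Two notes on the bundled reference tables, recorded here because the
tests deliberately work around them: the printed RSDs of the
instrument/column, flow-rate and temperature tables are not reproducible
from their own printed factors under either SD denominator, so only the
means are asserted for those tables; and two uridine ESM rows of the
30-sample comparison (1.189, 1.192 where ≈ 1.81 and ≈ 1.90 would
continue the otherwise-constant QAMS/ESM ratio) look like misprints —
uridine's agreement cosine (0.9957) is therefore reported but not held
to the ≥ 0.999 bar the other analytes meet. The per-sample QAMS/ESM
ratio in the printed uracil columns is constant only to about 1%, and
the tests assert near-constancy at that level.

## Similarity and clustering

The similarity stage offers two fingerprint modes: the full standardized
trace (with a running-median baseline subtracted; default window 2 min)
for whole-chromatogram similarity, and the 10-element common-peak-area
vector for clustering and quantification. The reference is the pointwise
arithmetic mean ("mean chromatogram"); a median reference is available.
Both cosine and Pearson are reported because the published account uses
both terms for its per-sample values.

Between-groups linkage is implemented as unweighted average linkage
(UPGMA) — the standard reading of that method name in SPSS, where the
published clustering was run. The implementation is the package's own
(O(n³) agglomeration with a documented lexicographic tie-break on
cluster ids), returning a standard `hclust` structure; tests verify it
against the independent reference implementation in `stats::hclust`
(equal heights and cophenetic matrices, identical partitions at every
cut) on random matrices up to size 12. Cuts undo the last k−1 merges —
well defined even under the height inversions average linkage can
produce on non-ultrametric input; inversions are recorded in an
attribute, never silently reordered.

On the default synthetic study, the k = 2 cut isolates the ten
Bailing-like samples from the twenty Jinshuibao-like ones, the
two-group structure reported for the real 30-sample panel. The published
subgroup memberships below that split are not modelled: they depend on
the unavailable raw chromatograms (and the published subgroup labels
are internally inconsistent, e.g. tablet samples beyond B10).

## Problem sizes and determinism

The default study is 30 chromatograms of 6001 points each; a full
pipeline run (simulation, detection, calibration of five analytes at six
levels, similarity, clustering, QAMS at seven injection volumes) takes a
couple of seconds, and the whole test suite runs in well under a minute.
All randomness flows from the configuration seed through fixed
per-sample and per-stage offsets, so a config determines its output
bundle byte for byte.
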