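---
title: "Interpretable ROP severity screening: models, geometry and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable ROP severity screening: models, geometry and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Retinopathy of prematurity (ROP) is a vasoproliferative disease of the
immature retina. Treatment-requiring ("severe") disease is defined
clinically by three components read off wide-field fundus photographs of
each eye: the **stage** (the type of the most severe retinal lesion: a
demarcation line, a ridge, a ridge with extraretinal fibrovascular
proliferation, or subtotal detachment), the **zone** (how close the
disease sits to the posterior pole, measured from the optic disc), and
**plus disease** (dilation and tortuosity of the posterior retinal
vessels). Black-box image classifiers can predict a severity grade, but
clinicians cannot audit *why*. `ropscreen` implements the alternative:
an explicit pipeline whose every intermediate — detected lesions, their
panoramic positions, the zone geometry, the vessel features, the fired
rule — is inspectable.

The pipeline stages are:

1. per-field lesion detections (typed boxes with confidences) arrive
   from any detector; the package ships a controllable simulated one;
2. orientation fields of one eye are registered into a per-eye panorama
   by similarity transforms;
3. detections are re-projected into panorama coordinates and duplicates
   merged;
4. stage = the maximum lesion type; an eye with no lesions is stage 0;
5. zone = the zone of the most severe lesion's centre under concentric
   ICROP templates centred on the optic disc;
6. plus disease is scored from vessel tortuosity and calibre on the
   disc-centred field, restricted to zone I;
7. a rule engine issues the severity call and reports which rule fired.

## Zone geometry

The frame is defined by the optic disc centre, the fovea centre, the
laterality (nasal is +x for OD, −x for OS; the fovea is temporal to the
disc), and the disc-to-nasal-ora distance. With $d$ the disc–fovea
distance and $r$ the distance of a point from the disc centre:

* zone I: $r \le 2d$;
* zone II: $r \le$ the nasal ora radius;
* zone III: everything beyond.

Two simplifications are deliberate. Boundary points resolve *inward*
(the more posterior, more severe zone): for a screening instrument the
conservative direction is the one that does not miss disease. And zone
III is modelled as the whole annulus beyond the zone II circle, ignoring
the nasal sector where zone III does not anatomically exist; the
package never needs the distinction because no rule treats zone III
differently by sector. The zone of an eye follows the *most severe*
lesion (its box centre); when several equally severe lesions disagree,
the most posterior zone wins. A configuration switch
(`from_most_severe = FALSE` in `eye_zone()`) instead takes the most
posterior lesion overall — common clinical practice — but the default
follows the staging-linked definition.

## The severity rule engine

`classify_severity()` encodes the treatment criteria verbatim: severe
iff (zone I with any staged lesion) or (stage 2, zone II, plus) or
(stage 3, zone II) or (stage 4); everything else is mild. Stage 5 is
out of range by design — such eyes are referred, not screened. Plus
disease with no staged lesion fits no rule; it is returned as
`not_severe` but flagged (`plus_without_lesions`) so it stays visible.
`rule_table()` enumerates all 26 valid (stage, zone, plus) combinations
for clinician review, and the test suite checks the implementation
against an independently hand-transcribed copy of that table.

## Registration

Fields are related to the panorama by similarity transforms (scale,
rotation, translation) — the contact camera re-orients between shots
but the retina is locally rigid. Estimation is classical and fully
deterministic: rotation and scale from the log-polar cross-correlation
of Fourier magnitude spectra, translation from phase correlation with
subpixel (parabolic) peak interpolation. Three numerical choices
matter:

* translation phase correlation is computed **zero-padded** (linear,
  not circular), because field offsets can exceed half the frame and
  the circular estimate then aliases to the complementary shift;
* because magnitude spectra are only translation-invariant for circular
  shifts, large translations are pre-aligned by plain phase correlation
  before the log-polar stage, and a few coarse rotation hypotheses are
  tried as a fallback when the spectral estimate collapses;
* every estimate is scored by the Pearson correlation of the
  overlapping pixels after warping; scores gate which pairs enter the
  montage graph (default threshold 0.25).

Global transforms are chained along the maximum-score spanning tree
rooted at the disc-centred anchor field, whose transform is the
identity — panorama coordinates therefore inherit the disc-centred
frame, which is also what the plus classifier expects. No bundle
adjustment is performed (five fields do not warrant it); consistency
residuals of non-tree pairs are reported so failures are visible, and
the montage interface accepts externally supplied transforms so a
learned registration model can be plugged in unchanged. If
registration fails for every non-anchor field the eye is assessed from
the anchor field alone and flagged `degraded`.

Detections are re-projected as the axis-aligned hull of their mapped
box corners. Copies of one lesion seen in overlapping fields are
merged when same-typed and either closer than `merge_radius`
(default 15 px, a quarter disc diameter) or with one centre inside the
other box — the latter handles copies clipped at a field border, whose
centres can drift apart by more than the radius while the boxes still
nest. The highest-confidence copy is kept; ties break toward the
larger (unclipped) box, then the nearest field centre. The merge is
idempotent.

## Plus disease

The scorer uses exactly the two features plus disease is defined by.
Vessel centerlines are extracted from the disc-centred field: the
mid-intensity vessel band is thresholded, thinned (Zhang–Suen), and
each 8-connected component traced outward from the disc. Two
digitization details are load-bearing: connected components are
labelled after a one-pixel dilation (the underlying labeller is
4-connected, which would fragment diagonal skeleton runs), and traced
pixel chains are moving-average smoothed (window 9, subsampled every
3rd point) before measuring length — a raw pixel staircase inflates
the arc/chord ratio of even a perfectly straight vessel by ~25%.
Width is estimated from the Euclidean distance transform as
$2d - 0.5$, splitting the parity bias between odd- and even-width
strokes.

Tortuosity is the classical arc-over-chord index (1.0 for a straight
vessel). Features are the mean tortuosity and mean width over the
centerline portions inside zone I. The score is a logistic function of
the standardised features with **fixed** coefficients shipped as a
plain-text fixture (`inst/extdata/plus_calibration.json`), calibrated
once by `calibrate_plus_model()` on 200 synthetic disc-centred fields
(balanced classes, seed 2024) with a small ridge penalty — the two
regimes are linearly separable, and the penalty keeps the coefficients
finite while preserving their sign. Both coefficients are required to
be non-negative, which makes the score provably monotone in tortuosity
and in width. Nothing is refit at runtime. An image with no traceable
vessels yields an *indeterminate* result, distinct from a negative
call.

## The synthetic-eye generator

No public dataset accompanies this problem, so the generator is a
first-class module: it emulates the *structure* of a RetCam-style
screening exam, not its photometry. A ground-truth eye has a disc at
the panorama centre (anatomical scale fixed at disc diameter = 60 px),
a fovea at 145–155 px (the disc–fovea distance), a nasal ora radius of
450 px (so zone II strictly contains zone I), eight vessels leaving the
disc at evenly spaced angles with sinusoidal normal displacement, and
up to one lesion per type, each type present independently with
probability 0.35/0.30/0.20/0.08 for types 1–4 — a severity mix that
yields roughly a quarter severe eyes, echoing the imbalance of real
screening cohorts. Plus prevalence is 0.25. Plus status drives the
vessel regime: amplitude 4–8 px and width 5–7 px versus 0–1.5 px and
3–4 px for normal vessels — deliberately non-overlapping ranges, since
the package's claim is about the pipeline, not about resolving
borderline pre-plus morphology.

The default camera plan is five 640×480 fields — disc-centred, nasal,
temporal, superior, inferior — offset 300 px from the disc as pure
translations, every peripheral field overlapping the anchor by well
over 25%. Lesion centres are rejection-sampled so each lesion box is
fully visible in at least one field, mirroring the fact that a
screening exam photographs the clinically assessable retina; a custom
plan that misses a lesion produces a warning in the generation report.
Lesion glyphs are type-coded schematic shapes (line, arc, arc with
dots, wedge) drawn brighter than the vessel band so vessel extraction
is not confounded. Rasters support registration and vessel tracing;
they make no attempt at photorealism (no blur, no illumination
falloff — an additive-noise knob exists for robustness checks).

The simulated detector applies noise *per lesion* (a missed or
type-confused lesion is missed or confused in every field that sees
it), jitter per field occurrence, and Poisson false positives per
field. All draws happen in a fixed order whatever the rates, so runs
with the same seed at different miss rates are coupled by common
random numbers — a lesion missed at rate 0.2 is also missed at 0.4,
which is what makes paired-seed degradation sweeps monotone in
expectation.

## Severity score for ROC analysis

The rule engine is binary, but ROC analysis needs a continuous score.
The score is 1.0 when any rule fires; otherwise
$0.95\,(0.6\,p + 0.4\,c)$, where $p$ is the plus score and $c$ the
highest detection confidence among zone I/II lesions. The 0.95 cap
keeps every rule-positive eye strictly above the graded tail: without
it, a mild eye with plus disease and a confident zone II stage 1
lesion can reach exactly 1.0 and tie with rule-positive eyes, making
the continuous score contradict the binary call it is supposed to
refine. An indeterminate plus score contributes 0 to the tail. The
weights live in `run_config()`.

## Evaluation suite

Stage agreement uses an unweighted Cohen's kappa over labels 0–4
(categories are nominal; no weighting scheme is implied by the
criteria), zone kappa over labels I–III with truth-`none` eyes
excluded (they have no zone to agree on), and the binary tasks report
accuracy, sensitivity, specificity, precision and F1 by the textbook
formulas, with zero-denominator metrics returned as `NA` rather than
poisoning the report. AUC is computed by a tie-grouped threshold sweep
and trapezoid integration, which equals the Mann–Whitney rank
statistic exactly — the suite checks this identity against a
brute-force pairwise oracle. The AUC confidence interval is a
stratified percentile bootstrap (2000 replicates, seeded): resampling
within class keeps both classes in every replicate. For screening, the
suite also reports specificity at full recall: the threshold is the
minimum score among true positives, and specificity is the fraction of
negatives strictly below it.

## Validation strategy, problem sizes, and what passing shows

The acceptance suite checks properties, not reproductions of any
published figure: rule-engine equivalence on all 26 combinations; zone
monotonicity and scale equivariance on a 10⁴-point grid; registration
recovery over 50 randomized pairs (scale 0.9–1.1, rotation ±15°,
translation up to 30% of width; median errors under 1 px and 0.5°);
metric identities against brute-force oracles; perfect-input
identifiability (200 zero-noise eyes recovered with kappa 1.0 across
the board — the pipeline adds no error of its own); predictable
degradation (stage accuracy under adjacent-type confusion 0.3 matches
a closed-form expectation within 3 standard errors on 500 eyes; mean
severity AUC over 10 paired seeds is non-increasing in miss rate);
tortuosity closed forms; and byte-for-byte reproducibility of every
output file, bootstrap intervals included. Cohort sizes (60–500 eyes)
were chosen so each property is tested at its natural scale: large
enough for the statistical bands to bite, small enough to run
routinely.

Passing these tests shows the pipeline is *correct*: faithful to the
clinical rules, geometrically sound, and lossless when its inputs are
clean. It does not show performance on real fundus photographs —
lesion glyphs are schematic, vessel regimes are separable by
construction, and the simulated detector's noise is simpler than a
real CNN's error structure. The plus scorer in particular makes no
claim of equivalence to trained vessel-analysis systems; it is a
transparent stand-in behind the same interface.

## Known limitations

* Zone III's nasal absence is not modelled; zone templates are perfect
  circles.
* The lesion reference point is the box centre; large lesions spanning
  a zone boundary are assigned wholly to the centre's zone.
* Montage blending is last-writer-wins; no seam optimization or
  photometric correction.
* Pre-plus, aggressive-posterior ROP and stage 5 are out of scope.
* Per-eye accounting is used throughout; per-image accounting would
  need the detector's raw per-field output, which the evaluation layer
  deliberately abstracts away.
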