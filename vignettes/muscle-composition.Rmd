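---
title: "Quantifying muscle composition and intrinsic strength from multi-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle composition and intrinsic strength from multi-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoseg)
```

## The problem

Aging skeletal muscle loses contractile tissue and accumulates
intramuscular adipose tissue (IMAT) and intramuscular connective tissue
(IMCT). Because force scales with the contractile cross-section rather
than with gross muscle size, this remodeling degrades *intrinsic strength*
(specific force — tendon force per unit physiological cross-sectional
area) faster than it shrinks the muscle. `myoseg` implements an MRI-based
pipeline that quantifies all three tissue compartments of the triceps
surae (gastrocnemius medialis, GM; gastrocnemius lateralis, GL; soleus,
SOL) and propagates them into specific-force estimates, together with a
synthetic phantom generator that makes every stage testable against known
ground truth.

## Segmentation model

### IMAT from water-saturated gradient-echo images

On a water-saturated FGRE image, muscle and connective tissue are both
suppressed and fat is bright, so adipose voxels can be isolated from a
single contrast. After bias-field correction and cropping to the muscle
masks, each axial slice's in-mask intensities are clustered by fuzzy
C-means (FCM) with three clusters — dark (muscle), bright (fat), and an
intermediate cluster that absorbs partial-volume voxels so that the pure
clusters are not biased. The slice is then thresholded at the *valley*
between the two brightest clusters, defined as the intensity at which
their fuzzy memberships are equal. For scalar FCM this membership-equality
point is the midpoint of the two centroids (for any fuzziness exponent),
which makes the rule closed-form, scale-equivariant, and testable against
a brute-force membership search. Clustering is two-dimensional (per slice)
so the threshold adapts to residual shading that survives bias correction.
The output is deliberately binary — each voxel is counted as entirely fat
or entirely water; no partial-volume weighting is applied.

Two numerical choices matter here:

* **Centroid initialization.** The dark centroids start at the 10th and
  50th percentile of the slice intensities; the bright centroid starts at
  the slice *maximum*. IMAT typically occupies well under 10 % of a slice,
  so a high-percentile start (e.g. the 90th) still lies inside the muscle
  population; three-cluster FCM then splits the fat mode and the valley
  threshold lands inside fat. Seeding the top centroid at the maximum
  fixes this in both the noise-free and the noisy regime, and keeps the
  algorithm fully deterministic.
* **Fat-free slices.** A slice yields zero IMAT, with a logged notice,
  when it has fewer in-mask voxels than clusters or when the gap between
  its two brightest centroids falls below a configurable fraction
  (default 0.3) of the volume-wide bright reference intensity (the 99th
  percentile of in-mask intensities). Without this floor, FCM happily
  manufactures a "bright" cluster out of the upper noise tail and
  hallucinates fat on fat-free slices. The floor is expressed against a
  volume-wide reference rather than per-slice statistics so that a
  genuinely fat-free slice in a fat-containing volume is recognized as
  such. Its known limitation: a volume containing *no* fat anywhere
  lowers the reference and can re-admit noise clusters; in that regime
  the per-slice notices should be inspected.

Noise-free slices have only a handful of distinct intensities; when there
are fewer distinct values than clusters, `segment_imat()` falls back to as
many clusters as there are distinct values (at least two) instead of
failing, so exactly constructed data segment exactly.

Default FCM settings: 3 clusters, fuzziness exponent m = 2 (the literature
standard; the configuration exposes it), at most 100 iterations, and a
convergence level of 1e-5 on the largest centroid update.

### IMCT from dual-echo UTE T2* maps

Collagen-rich connective tissue has an effective transverse relaxation
time (T2*) of a few milliseconds and is invisible at conventional echo
times. With an ultra-short first echo (TE1 = 8 microseconds) and a second
echo at TE2 = 2.6 ms, the mono-exponential magnitude model
S(TE) = S0 · exp(−TE/T2*) gives a per-voxel estimate

T2* = (TE2 − TE1) / ln(M1 / M2),

in which S0 and the phase factors cancel. Voxels where the ratio cannot be
inverted (M1 ≤ 0, M2 ≤ 0, or M1 ≤ M2) are flagged invalid rather than
given an arbitrary value; they are labelled non-muscle only when both echo
intensities exceed a noise floor (by default 3× the background standard
deviation of the first echo, estimated outside the mask union — the
two-echo inversion is unstable at low signal and air must not leak into
the tissue maps). For export the map is clamped to (0, 100] ms;
segmentation uses the unclamped values.

In-mask voxels with T2* below 8 ms are labelled non-muscle. The 8 ms value
is an empirical threshold separating muscle (≈14–19 ms) from IMAT
(≈4–6 ms) and IMCT (≈2–4 ms); it is a configuration default, not a
constant. Because fat's T2* overlaps IMCT's, the short-T2* map cannot
separate them directly; the IMAT voxels found on the water-saturated
images are therefore removed from the non-muscle map to produce the
fat-free IMCT map. Echo subtraction (echo1 − echo2, clipped at zero) is
provided for visualization but is not used for segmentation.

By construction IMAT, IMCT and contractile tissue partition the mask
union exactly, which the tests assert as a conservation law.

### Spatial adjacency

Fat infiltration tends to track the connective-tissue scaffolding. The
package quantifies this as the percentage of IMAT voxels having at least
one IMCT voxel among the 26 voxels of their 3×3×3 neighborhood (center
excluded; neighborhoods truncated at the volume border, which is
equivalent to zero padding). The implementation (26 array shifts) is
tested for equality against a naive triple-loop scan.

## Strength model

* Ankle center of rotation: least-squares (Kåsa) circle fit to landmark
  points on the talus; exact for points on a circle, with an RMS radial
  residual reported.
* Moment arm: perpendicular distance from the fitted center to the
  Achilles tendon's line of action, given as two explicit points (the
  package does not attempt to detect the tendon).
* Tendon force: F = T / MA from the MVC plantarflexion torque; a linear
  voltage-to-torque calibration helper is included.
* PCSA per muscle: Vol · cos(θ) / Lf, with the pennation angle in degrees
  at the interface and fascicle length in cm; per-muscle PCSAs are
  computed per subject and summed to the triceps-surae PCSA, and cohort
  values aggregate per-subject results (mean of ratios, not ratio of
  means — the two differ, and both conventions are exposed where
  relevant).
* Specific force 1 = F / PCSA; specific force 2 uses the PCSA of the
  corrected volume (total − IMAT − IMCT). Only *measured* tissues are
  subtracted: SOL, whose IMCT is not measured, contributes no IMCT term,
  and the record lists which muscles entered the correction.

Between-group contrasts are summarized with the symmetrized percent
difference, 100·|a − b| / ((a + b)/2). This statistic is scale-invariant,
symmetric in its arguments, and is the convention under which the
package's group-level percentage differences are computed from group
means.

## Group statistics

Each variable passes a Shapiro–Wilk gate (α = 0.05 per sample, both
samples must pass); gated variables are compared with an independent-
samples pooled-variance t-test, others with a Mann–Whitney U test (exact p
for groups of ≤ 8 without ties, tie-corrected normal approximation
otherwise). Effect sizes use the matching transformation:
r = √(t²/(t² + df)) or r = |Z|/√N. Constant samples are routed to the U
path, where the degenerate case resolves to p = 1 rather than an error.
All tests are two-tailed.

## The phantom: what it emulates and what it does not

The synthetic lower leg is three disjoint ellipsoidal muscles inside a
cylindrical leg with a subcutaneous fat ring and a bone shaft. Within each
muscle, IMCT is laid down as thin septa (regularly spaced fascial sheets)
and IMAT voxels are sampled so that a controlled proportion `p_adj`
(default 0.86, old-like; ≈0.62 is young-like) sit adjacent to IMCT —
making the adjacency statistic exercisable with known truth. Realized
tissue fractions land within one voxel of their targets. The generator
emits:

* water- and fat-saturated contrasts (tissue-mean lookup; absolute units
  are arbitrary since all downstream logic is intensity-relative),
* a dual-echo UTE pair following the mono-exponential decay with
  per-voxel T2* drawn uniformly from tissue ranges (muscle 14–19, IMAT
  4–6, IMCT 2–4 ms),
* a clean fat-fraction reference map (1 on adipose labels) playing the
  role a quantitative fat/water reconstruction plays for real data,
* one smooth multiplicative polynomial bias field (defaults: order 2,
  ±20 %) shared by all acquired contrasts, as a common RF-coil
  inhomogeneity would be, and
* independent Rician noise per contrast (default σ = 5, i.e. 5 % of the
  fat/S0 intensity of 100 — the scanned cohort's intensity distributions
  are not published, so the SNR default is an assumption, stated as
  such).

Default grid: 64 × 64 × 40 voxels at 1.5 × 1.5 × 5 mm (the 5 mm slice
matches the acquisition convention; the in-plane resolution is a
package choice since only matrix and field-of-view are conventionally
reported). These sizes keep a full pipeline run at around two seconds, so
the test suite and multi-seed recovery studies run in well under a minute.
Default tissue fractions are old-like: 8.1 % IMAT and 12 % IMCT per
muscle.

The phantom deliberately does **not** model curved fascicles or
aponeuroses, k-space acquisition, chemical-shift effects, or
partial-volume mixing (labels are crisp). Passing the recovery suite
therefore demonstrates the correctness of the algorithms under the stated
forward model — clean tissue contrast, smooth multiplicative bias,
Rician noise — not their performance on scanner data, where unmodeled
artifacts (motion, incomplete fat suppression, partial volume) dominate
the error budget.

A noise-free, bias-free phantom is *exactly* segmentable, and the test
suite pins the whole pipeline to that oracle: any regression that moves a
single voxel fails the suite.

## Bias correction

RF-coil inhomogeneity is modeled as a smooth multiplicative field. The
corrector fits a polynomial (default order 3) to the log intensities of
foreground voxels above a small floor (the 5th foreground percentile, so
suppressed near-zero tissue does not dominate the log fit), exponentiates,
normalizes to mean 1 over the foreground, and divides. This is a
deliberately simple, fully testable estimator of smooth shading: it
recovers log-polynomial fields to machine precision and reduces the
foreground coefficient of variation for the phantom's 1 + polynomial
fields, but — like any single-contrast estimator without histogram
sharpening — it absorbs some anatomy into the field on structured images.
The per-slice thresholding downstream is designed to tolerate exactly this
kind of residual shading. The pipeline fits the field over all voxels with
appreciable signal (above the median), not just the muscle masks, to give
the polynomial spatial support.

## Synthetic cohorts

`generate_cohort()` draws per-subject muscle volumes, tissue contents,
architecture (fascicle length, pennation angle), and tendon forces from
Gaussian distributions with the young/old group means and SDs of the
study population, truncated at physiological bounds. Per-muscle volumes
share a common subject-size factor (correlation 0.9): independent draws
would give the triceps-surae total an SD of about 40 cm³ where the
published cohort shows 63.9 cm³, i.e. real per-muscle volumes are strongly
correlated within a subject. The Achilles tendon moment arm is not a
published group statistic; 0.05 ± 0.005 m is used as the physiological
adult value and MVC torque is back-computed as force × moment arm, which
keeps the force–torque–moment-arm triplet exactly consistent and lets
round-trip tests assert equality to machine precision.

## Reproducibility and degenerate inputs

Every stochastic stage takes a seed; stage seeds are derived from the run
seed with a label hash so streams are independent but reproducible, and
seeded sampling never disturbs the caller's RNG state. Identical
(configuration, seed) pairs produce byte-identical reports, and the run
manifest records an MD5 hash of the scientific configuration (excluding
the output location). Degenerate inputs resolve to defined behavior
rather than silent misbehavior: empty masks, all-background bias
foregrounds, coincident tendon points, collinear circle points, equal top
centroids, zero-variance samples and empty IMAT maps each either raise a
named error or return a flagged zero, as documented on the respective
functions; ties in the maximum-cross-section search break to the lowest
slice index.

## Known limitations

* The valley is the FCM membership-equality point, not a histogram
  minimum; on strongly skewed slice histograms the two differ.
* The separation floor assumes the volume contains bright fat somewhere.
* The two-echo T2* estimate is noise-limited: at noise well above ~5 % of
  S0, muscle voxels increasingly alias below the 8 ms threshold and IMCT
  specificity degrades (the IMAT channel, driven by the high-contrast
  water-saturated image, is far more robust).
* IMCT is validated for the gastrocnemius heads; applying the same
  threshold to the soleus is possible in the interface but carries no
  validation claim.
* Group-level percentage differences computed from group means differ
  from means of per-subject ratios; both conventions exist in the
  interface and the cohort aggregation uses per-subject values.
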