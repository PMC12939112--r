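---
title: "Quantifying peripheral pulmonary vessel morphology: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripheral pulmonary vessel morphology: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pulmovasc` turns a contrast-enhanced thoracic CT volume into a labeled
forest of pulmonary vessel centerlines and a vector of morphometric
readouts, and turns a table of per-patient readouts and hemodynamics into
diagnostic statistics for pulmonary hypertension (PH, defined as resting
mPAP > 20 mmHg). This vignette explains the model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
validation data can and cannot show.

All geometry is computed in world millimetres (`world = origin +
index·spacing`), never in voxel units: clinical reconstructions are
anisotropic (sub-millimetre in-plane, ~1 mm slices), and lengths, angles,
radii and volumes must not depend on the grid.

## Lungs and airways

Both are attenuation-defined. The airway lumen is air (≈ −1000 HU), the
inflated parenchyma ≈ −850 HU, so a threshold between them
(`airway_hu_max = -950` HU) isolates the lumen; growth starts from the
most superior connected air component (the trachea) and proceeds in
breadth-first waves with a leakage guard: if one wave multiplies the
accumulated volume by more than `airway_leak_factor = 2` (after a 12-wave
burn-in), growth stops — the classic failure mode of airway segmentation
is a sudden leak into the parenchyma. A failed airway segmentation flags
the scan (`segmentation-failed`) rather than aborting a batch; cohorts are
processed with exclusion-and-continue semantics.

Lungs are the two largest components below `lung_hu_max = -400` HU after
airway removal, excluding components that touch the lateral image border
(outside air). Contrast-filled vessels are far above this threshold and
would be carved out of the mask, so each lung is closed morphologically
(`lung_closing_radius_mm = 3`) and 3D holes are filled; this matters
because the lung volume V (litres, voxel count × voxel volume × 10⁻⁶) is
the denominator of every density readout, and the convention here is that
intrapulmonary vessels count toward V. That convention is configurable but
fixed for all shipped analyses. Left/right are assigned by centroid
laterality along the first axis.

## Vesselness and scale

Tubes are enhanced with a Frangi-type Hessian filter for bright tubes on a
dark background (contrast-filled vessels in parenchyma), with
spacing-aware Gaussian derivative kernels (σ in voxels = σ_mm / spacing
per axis) instead of isotropic resampling. Scales cover radii 1–5 mm
(`scales_mm = seq(1, 5, by = 0.5)`), i.e. the analysed 2–10 mm diameter
range; requesting scales outside that range is a configuration error. The
sensitivity parameters are the conventional α = β = 0.5; the
structure-strength normalizer c is set to half the maximum scale-normalized
Hessian norm *across all scales* of the scan. Using a per-scale c is a
subtle trap we hit and rejected: it renormalizes every scale to its own
maximum, flattens the response-vs-scale curve, and makes the argmax scale
meaningless.

Two further numerical choices:

* the response support is eroded by `mask_margin_vox = 2` voxels, because
  the body/lung intensity step at the pleura mimics large-scale structure;
* γ = 2 scale normalization (Hessian × σ²), the standard choice that makes
  responses comparable across scales.

The spec-level convention "Gaussian scale = tube radius" holds for
detection, but the argmax scale is a poor radius *estimator*: on solid
tubes it peaks near radius/1.4 and saturates at the smallest probed scale
for thin tubes (we measured this on noise-free cylinders of radius
1.2–4.5 mm). Node radii are therefore *refined* by half-maximum edge
detection: HU profiles along 8 rays perpendicular to the tube axis, radius
= median distance at which the profile crosses the midpoint between the
centre intensity and the local background. On benchmark phantoms this
recovers per-segment diameters to ≈0.2 mm mean absolute error (the test
suite asserts ≤ 0.5 mm through the full pipeline).

## From maxima to a vessel forest

Candidate nodes are transverse local maxima: a voxel above
`response_threshold = 0.08` whose response is not below its interpolated
neighbours one voxel away along both directions perpendicular to the local
tube axis. Comparing against the *smaller* of the two opposite sides keeps
ridge points even where an axial response gradient leaks into a slightly
wrong orientation. Non-maximum suppression then enforces
`min_spacing_mm = 3` along each accepted node's axis and
`nms_radius_factor = 1.5` × scale laterally (cylindrical suppression:
spacing must be tight along the vessel but wide across it, otherwise
shoulder responses of thick vessels survive as parallel ghost chains).
Accepted nodes are recentered to the intensity centroid of their
perpendicular cross-section, deduplicated, radius-refined, and their
orientations re-estimated from the principal axis of neighbouring node
positions — after recentering, node positions are a far cleaner direction
source than per-voxel Hessian eigenvectors.

Candidate edges join each node to its `knn = 5` nearest neighbours within
`max_edge_mm = 12`. The edge cost is

```
cost = w_par·par + w_dir·(mean angle)/90° + w_dia·|r_i − r_j|/max(r_i, r_j) + w_len·len/10 mm
```

with weights (1, 0.5, 0.5, 0.1) and hard caps: direction change > 45° or
diameter jump > 50% makes an edge inadmissible. The parenchyma term is the
mean vesselness sampled along the chord *normalized by the endpoint node
responses*: the raw response level varies with vessel size and scene
contrast, so the absolute form ("1 − mean response") cannot serve as a
comparable cost across vessels; the normalized form is ≈0 for a chord that
stays on a vessel and ≈1 for one crossing parenchyma. A minimum-cost
spanning forest (one MST per component; equal costs broken
deterministically by node-id pair) is extracted, tree edges above
`edge_cost_threshold = 0.8` are cut, leaf twigs shorter than
`prune_twig_mm = 15` hanging off branch points are pruned (they are almost
always residual shoulder detections; genuine terminal branches in the
2–10 mm range are longer), and isolated components shorter than
`min_component_mm = 12` are dropped. Maximal paths between branch points
and endpoints become the *vessel segments* — the counting unit of every
readout. Known cost of the conservative end handling: on capsule-ended
tubes the last one or two nodes per end can be pruned, eroding segment
length by a few node spacings; counts, diameters, bins and labels are
unaffected.

## Artery/vein separation as an integer program

Labeling acts per connected subtree (unit). Two evidence sources:

* **Intertwining.** Arteries and veins are spatially interleaved in the
  lung; a pairwise weight `w(u,v)` — the count of cross point pairs within
  `neighbor_radius_mm = 10`, normalized by the product of the unit sizes —
  rewards giving *opposite* labels to close unit pairs.
* **Bronchus parallelism.** Arteries run alongside bronchi; veins do not.
  A unit's affinity `b_u ∈ [0,1]` is the fraction of its centerline points
  within `bronchus_dist_max_mm = 10` of an airway voxel *and* locally
  parallel (≤ `parallel_tol_deg = 30`) to the airway's principal axis.
  This is the only evidence that breaks the global artery/vein symmetry.

The objective, maximized over x ∈ {0,1}ⁿ (1 = artery):

```
Σ_{u<v} w(u,v)·[x_u ≠ x_v] + λ Σ_u (b_u·x_u + (1 − b_u)·(1 − x_u))
```

with λ defaulting to twice the mean positive pairwise weight, so bronchus
evidence can override weak intertwining. Problems up to
`av_exact_max_units = 24` are solved exactly by depth-first branch and
bound with an optimistic tail bound; the first incumbent in a fixed branch
order (unit 1 tries its affinity-preferred label first, later units try
artery first, strict improvement required) makes ties deterministic.
Larger problems fall back to greedy assignment with local flips, reported
as status `"fallback"`. A plain exhaustive enumeration ships as a separate
code path and serves as the oracle: the suite checks objective equality on
random problems up to 20 units.

Labeling accuracy against ground truth is *length-weighted* — the fraction
of centerline length correctly labeled — approximating a reader's visual
share-of-tree judgment. The global label swap is only allowed when the
scan carries no airway evidence (the polarity is then genuinely
unidentifiable). Scans below `min_av_accuracy = 0.80` are excluded from
the artery/vein subcohort; the rule is strict (< 0.80 excluded, exactly
0.80 retained).

## Morphometric readouts

Per scan: total segment count; vessel volume as a frustum sum
Σ π·r̄²·Δs over centerline sections; density = count / V (1/L);
normalized vessel volume = vessel volume / V; per label and diameter bin
(2–4, 4–6, 6–10 mm; half-open `[2,4)`, `[4,6)`, `[6,10]` so the bins
partition the filter's range) counts and densities; artery−vein density
differences and artery/vein count ratios per bin (NA when the vein count
is zero, never a silent division); and tortuosity as the sum-of-angles
metric, `SOAM = Σ θ_i / Σ |s_i|` in rad/mm with θ_i the angle between
adjacent polyline sections. The denominator is the *total* polyline length
(all sections); the alternative reading — only sections adjacent to a
computed angle — differs by O(1/n) and vanishes with sampling density. A
segment's representative diameter is twice the *median* per-point radius,
robust to radius inflation at branch ends. Unknown-label segments count
toward totals but never toward artery/vein metrics.

Closed-form anchors used in the tests: a straight polyline has SOAM 0
exactly; a single 90° bend over two 5 mm sections gives (π/2)/10 rad/mm
exactly; a circle of radius 10 mm sampled every 0.5 mm of arc converges to
its curvature 0.100 rad/mm (the chord-angle deficit is one interior angle
over the whole polyline, < 1% at that length); a helix of radius R and
pitch c tends to R/(R²+c²).

## Cohort statistics

All group comparisons are nonparametric: Wilcoxon rank-sum for two groups,
tie-corrected Kruskal–Wallis plus Dunn z-tests with Bonferroni
multiplication for more. Spearman correlations use mid-ranks and the
t-approximation, with pairwise NA deletion and the per-cell n reported —
cohort tables have per-parameter missingness, and every estimate must
carry its own denominator. The ROC machinery is implemented from DeLong's
structural components: AUC as tie-aware Mann–Whitney concordance, variance
S10/m + S01/n, Wald 95% CI clipped to [0,1], and the paired AUC comparison
from the covariance of the components (identical or rank-identical scores
give Δ = 0, p = 1 by convention). The installed `pROC` package is used in
the tests only as an independent reference, never as the implementation.

Marker combination follows the linear risk-score framework: a logistic
regression of the outcome on the marker columns, whose linear predictor is
the combined score fed back into the ROC analysis (ROC is rank-invariant,
so the linear predictor and the fitted probability are equivalent scores).
Among the published combination approaches we chose the logistic
risk score over a direct AUC-maximizing linear search because it is
convex, deterministic and oracle-checkable on bi-normal synthetic data,
where the optimal-combination AUC has the closed form Φ(δ/√2) for
independent unit-variance markers with shifts δ₁, δ₂, δ = √(δ₁²+δ₂²).
Perfect separation triggers a small-ridge fallback, flagged in the output.
No multiplicity correction is applied across readouts (post hocs excepted);
raw p-values are reported.

## What the synthetic data emulates — and what it does not

**Phantoms** place ellipsoidal "lungs" (parenchyma −850 HU) in a 0 HU
body, tube trees with spline centerlines and known radii (vessels
+300 HU, airways −1000 HU, rounded capsule ends), companion bronchi offset
laterally from flagged arteries, a connected trachea, and additive
Gaussian noise (σ = 20 HU). The seed fully determines the volume. The
standard benchmark (128³ voxels at 1.5 mm; problem size chosen so a full
pipeline run takes about half a minute) has 16 vessels in 8 artery/vein
pairs, parallel curves at constant 9 mm separation — intertwined within
the 10 mm evidence radius but never merging — spanning all three diameter
bins for both labels. An earlier draft with independently phased bends let
tube surfaces touch; merged tubes are unresolvable by construction and do
not represent paired pulmonary anatomy, so the geometry was fixed before
the validation thresholds were frozen.

What passing on phantoms does *not* show: real CTPA has textured
parenchyma, cardiac motion, heterogeneous contrast, touching vessels at
the hilum, incomplete airway trees and lobar anatomy. The phantom results
validate the geometry and optimization machinery, not clinical
performance.

**Cohorts** are generated from a Gaussian copula: a single latent uniform
drives both group membership (PH prevalence 149/170, the referral-cohort
rate) and mPAP (log-normal within group, median 17 [16–19] mmHg without
PH, 38 [29–48] with PH, truncated so group = mPAP > 20 exactly).
Hemodynamics (PVR, PAWP, CI, SvO₂, RAP) follow group-conditional
log-normal marginals matched to typical referral cohorts with calibrated
latent links; DMPA is linear in mPAP plus noise; the 6–10 mm artery/vein
ratio is linked at Spearman ρ = 0.41 (converted to the Pearson copula
parameter via 2·sin(πρ/6)); the vein 6–10 mm density carries a weak
negative link, and the arterial density *emerges* as ratio × vein density,
keeping count/density/ratio identities exact within each row. Segment
totals centre on 1843 with density = count / lung volume holding exactly.
Labeling accuracies are planted with an exact sub-threshold count
(53 of 170 by default) to exercise the exclusion flow deterministically.
Rank statistics depend only on the copula, which is why the Spearman
calibration transfers to the generated marginals.

What the cohort generator does not emulate: real missingness mechanisms
(only MCAR is available), measurement error correlated across readouts,
and any causal structure — links are associational by construction.

## Known limitations

* Central/hilar vessels and vessels under 2 mm diameter are out of scope,
  matching the method's validity range.
* Segment ends erode by a few node spacings on capsule-ended tubes
  (see above); length-based readouts inherit a small negative bias.
* The greedy fallback above 24 units has no optimality guarantee (status
  reports it); phantom-scale problems never reach it.
* The MetaImage reader supports uncompressed MET_UCHAR/CHAR/SHORT/USHORT/
  INT/FLOAT/DOUBLE with identity orientation; compressed `.mha` is
  rejected with a format error rather than silently mis-read.
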