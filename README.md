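# pulmovasc

Quantitative morphology of the peripheral pulmonary vasculature from
contrast-enhanced thoracic CT, with the cohort-level statistics needed to
evaluate those readouts as diagnostic markers of pulmonary hypertension
(PH). The package is aimed at thoracic-imaging and pulmonary-circulation
researchers who want a fully automated, rule-based (non-learned) pipeline
from a CT volume to per-scan vascular readouts, and from a table of
per-patient readouts and hemodynamics to ROC-based marker evaluation.

PH is defined hemodynamically as a resting mean pulmonary arterial pressure
(mPAP) above 20 mmHg at right heart catheterization. Established CT markers
(main pulmonary artery diameter D<sub>MPA</sub>, its ratio to the ascending
aorta D<sub>MPA</sub>/D<sub>Ao</sub>) look only at the central arteries;
the disease, however, remodels the *peripheral* vessels — distal pruning
with relative proximal dilation. `pulmovasc` quantifies that periphery:
vessels of 2–10 mm diameter are extracted, separated into arteries and
veins, and summarized as diameter-binned counts, densities and tortuosity.

## The pipeline

1. **Lungs and airways** are identified by attenuation: region growing from
   an automatically seeded trachea (lumen < −950 HU) with a leakage guard,
   then the two largest low-attenuation components (< −400 HU) with
   morphological closing and 3D hole filling so vessels stay inside the
   lung volume `V` (litres).
2. **Vesselness**: a multiscale Hessian (Frangi-type) filter for bright
   tubes, with spacing-aware Gaussian derivatives at scales covering radii
   1–5 mm. Each voxel gets a response in [0,1], a scale estimate and the
   tube axis (eigenvector of the smallest-magnitude eigenvalue).
3. **Centerline forest**: regularly spaced response maxima (transverse
   non-maximum suppression, intensity-centroid recentering, half-maximum
   radius refinement) are linked by a minimum-cost spanning forest whose
   edge costs penalize crossing parenchyma and abrupt changes of direction
   or diameter. Maximal paths between branch points and endpoints define
   the *vessel segments* counted everywhere else.
4. **Artery/vein separation**: one binary variable per connected subtree;
   an exact branch-and-bound solves the integer program
   `max Σ w(u,v)·[x_u ≠ x_v] + λ Σ (b_u x_u + (1−b_u)(1−x_u))`,
   where `w` rewards opposite labels for spatially intertwined subtrees and
   `b_u` is the fraction of a subtree running parallel to and close beside
   a bronchus (arteries accompany bronchi; veins do not).
5. **Morphometrics** per scan: segment counts and densities (count / `V`,
   unit 1/L) in the diameter bins 2–4, 4–6 and 6–10 mm per label, vessel
   volume, normalized vessel volume, artery−vein density differences,
   artery-to-vein count ratios, and tortuosity as the sum-of-angles metric
   `SOAM = Σ θ_i / Σ |s_i|` (rad/mm) with the median over segments
   reported.
6. **Cohort statistics**: Spearman correlations with pairwise deletion (n
   reported per cell), Wilcoxon / Kruskal–Wallis with Dunn–Bonferroni post
   hocs, ROC analysis with DeLong variance and 95% CI, paired DeLong AUC
   comparisons, logistic risk-score marker combination, and the strict
   exclusion rule: scans with less than 80% correctly labeled vessel length
   leave the artery/vein subcohort.

Because clinical CT data cannot ship with a package, `pulmovasc` also
generates its own validation data: CT-like phantoms (lung ellipsoids,
tube trees of known centerline/radius/identity, companion bronchi beside
arteries, Gaussian noise) with exact ground truth, and synthetic cohorts
whose hemodynamics and readouts are tied through a Gaussian copula with
calibrated Spearman links.

## Worked example

```r
library(pulmovasc)

ph  <- standard_benchmark_phantom()            # 128^3 CT-like phantom
res <- process_scan(ph$volume, truth = ph$truth)
res$graph
#> <vessel_graph> 16 segments (8 artery / 8 vein / 0 unknown), 0 branch adjacencies
res$accuracy
#> [1] 1
dplyr::select(res$report, n_segments_total, lung_volume_L, ratio_av_6_10)
#> # A tibble: 1 x 3
#>   n_segments_total lung_volume_L ratio_av_6_10
#> 1               16          1.17             1
```

All 16 ground-truth tubes are recovered as single segments, every artery
and vein is labeled correctly (accuracy 1.0 against the generator's truth),
and the 6–10 mm artery-to-vein ratio is 1 because the phantom plants two
arteries and two veins in that bin.

At the cohort level:

```r
tab    <- make_cohort(cohort_spec(n_patients = 170, seed = 42))
bundle <- run_cohort(tab)
bundle
#> <cohort_stats_bundle> 170 patients (117 in the A/V subcohort)
#> ROC summary:
#>   marker                   auc  ci_low ci_high
#> 1 ratio_av_2_4           0.463   0.298   0.627
#> 2 ratio_av_4_6           0.523   0.329   0.717
#> 3 ratio_av_6_10          0.772   0.640   0.903
#> 4 DMPA                   0.934   0.892   0.976
#> 5 DMPA_DAo               0.814   0.714   0.914
#> 6 DMPA+ratio_av_6_10     0.961   0.923   1.000
#> 7 DMPA_DAo+ratio_av_6_10 0.908   0.840   0.975
```

The synthetic cohort plants 53 of 170 scans below the 80% labeling-accuracy
threshold, so the artery/vein subcohort holds 117 patients. The 6–10 mm
artery/vein ratio is the most informative of the three bins (here AUC 0.77
with a calibrated Spearman link of ≈0.4 to mPAP), and combining it with a
diameter marker raises the AUC without reaching significance in the paired
DeLong test — the qualitative behaviour such markers show on real referral
cohorts. `autoplot(bundle)` overlays the ROC curves; `tidy()` / `glance()`
methods expose curves and summaries as tibbles.

A thin command-line wrapper ships in `inst/cli/pulmovasc`
(`segment`, `morph`, `stats`, `synth phantom|cohort` subcommands).

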