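# filletbend

Sideview imaging analysis of fillet bending for detecting the **wooden
breast condition (WBC)** in broiler breast fillets.

Wooden breast is a growth-related myopathy that makes the pectoralis major
abnormally hard and rigid. Processing plants still sort affected fillets by
hand palpation. When a fillet travels over the discharge roller of a belt
conveyor, its unsupported part briefly bends before it falls — and a rigid
wooden-breast fillet bends visibly less than a normal one. A sideview
camera aimed along the roller axle captures that bending event at high
frame rate, and this package turns the image sequence into per-fillet
bending measurements and a binary WBC classification.

`filletbend` is aimed at machine-vision and meat-science researchers who
want to reproduce, test, or extend the image-analysis side of this idea
without access to a physical conveyor line: it ships a synthetic
conveyor-scene simulator with exact ground truth, so the entire pipeline is
testable end to end.

## The measurements

For each fillet pass, delimited by two software trigger lines (an arrival
column and a departure row), every frame is segmented by global
thresholding → hole filling → median filtering → morphological opening →
object size filtering. Two bending descriptors are tracked:

* **Bending energy.** The segment is rotated so its major axis is
  horizontal, its medial-axis skeleton is fitted with a quadratic
  y = a·x² + b·x + c, and the fitted curvature C(k) = |y″|/(1+y′²)^(3/2)
  is sampled at the L columns the skeleton spans:

      BE = (P² / L) · Σₖ C²(k)

  with P the contour perimeter (the P²/L normalization makes BE
  scale-invariant). **MBE** is the per-fillet maximum of BE over the pass;
  it *decreases* with WBC severity.

* **Minimum distance measure.** dᵢ is the distance from the fillet
  centroid to the roller axle center; it is normalized by the per-fillet
  scale factor H = hₜ + R measured on the first (flat) frame. **MDM** =
  min dᵢ and **NMDM** = min dᵢ/H both *increase* with WBC severity,
  because a flexible fillet drapes toward the axle.

The first flat frame also yields MAXH, AVGH, MAXL, AREA, PERIM, HTR and
HBR, completing the 10-feature vector per fillet. The statistics layer
provides per-feature ANOVA + Tukey letters, Spearman correlation against
the ordinal severity score, and binary normal-vs-WBC classification (LDA,
QDA, decision tree, SVM, k-NN on one feature at a time) scored by
10-repeated stratified 5-fold cross-validation with OACC, BACC, F1 and MCC.

## Worked example

Simulate one floppy (normal-like) and one stiff (wooden-breast-like)
fillet through the same reduced-scale scene and extract their features:

```r
library(filletbend)

geom <- scene_geometry(image_w = 320, image_h = 240, belt_row = 100,
                       edge_col = 200, roller_radius = 18,
                       arrival_col = 140, departure_row = 185, line_speed = 5)
soft  <- fillet_profile(100, 26, taper = 0.45, rigidity = 20)   # normal-like
stiff <- fillet_profile(100, 26, taper = 0.45, rigidity = 300)  # WBC-like
params <- seg_params(min_object_area = 150)

for (p in list(soft, stiff)) {
  pass <- simulate_pass(p, geom, seed = 1, noise_sd = 0)
  ft <- extract_features(pass, geom, params)
  print(ft[c("NMDM", "MDM", "MBE", "MAXH", "AVGH", "MAXL", "AREA", "PERIM")],
        digits = 3)
}
#>    NMDM  MDM  MBE MAXH AVGH MAXL AREA PERIM
#> 1 0.496 16.6 39.8   26   19   97 1846   217
#>    NMDM  MDM  MBE MAXH AVGH MAXL AREA PERIM
#> 1 0.676 22.6 5.01   26   19   97 1846   217
```

The two fillets are geometrically identical — same length, thickness,
area — yet the floppy one drapes toward the axle (NMDM 0.50 vs 0.68) and
stores far more bending energy at peak (MBE 39.8 vs 5.0). Those two numbers
are the whole detection idea.

At full scene resolution (960×696 px), a 45-fillet cohort (15 per severity
class) built with `cohort_feature_table(15, scene_geometry(), master_seed)`
reproduces the expected group orderings (NMDM and MDM rise with severity,
MBE falls) and an SVM on NMDM alone detects wooden breast with
cross-validated overall accuracy around 0.98.

## Command line

A thin CLI over the same functions ships in `inst/scripts/filletbend`:

```sh
Rscript inst/scripts/filletbend simulate --out passes/ --n 15 --seed 1
Rscript inst/scripts/filletbend process  --in passes/ --out features.csv
Rscript inst/scripts/filletbend evaluate --in features.csv --out scores.csv
```

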