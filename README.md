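# lymphmap

Automated MRI post-processing for breast cancer–related lymphoedema (BCRL)
of the arm. BCRL mixes interstitial fluid and fat in the layer between the
skin and the muscle fascia, yet standard clinical assessment only measures
overall arm size. `lymphmap` turns three co-registered MR volumes of an arm
— Dixon water, Dixon fat, and a fluid-sensitive STIR — into quantitative
tissue-composition measurements and maps, so that a clinician can see not
only *how much* an arm is swollen but *what* the swelling is made of and
*where* it sits.

## Method

The workflow has three steps, applied per arm at 1 mm isotropic resolution:

1. **Volume selection.** The analysis extent is standardized to all
   transaxial slices between the wrist (distal radioulnar joint) and the
   65% upper-arm mark, the slice at
   `elbow + 0.65 × (shoulder_tip − elbow)` along the arm axis.
2. **Volume segmentation.** Each voxel contributes a feature vector
   `(I_water, I_fat, I_STIR)`. This 3-D feature space is partitioned into
   *k* = 5 clusters with Lloyd's k-means (k-means++ restarts, best
   within-cluster sum of squares kept). Clusters are mapped to tissue
   classes by centroid dominance: the darkest cluster is image noise; among
   the rest, the largest Dixon-fat centroid is fat, the largest STIR
   centroid is fluid, the largest Dixon-water centroid is muscle, and the
   remaining cluster holds mixed-composition voxels at tissue interfaces.
3. **Volume extraction.** Per slice, the external contour (whole arm
   cross-section, noise excluded) and the fascial contour (around the
   muscle compartment) are extracted by connected-component selection,
   morphological closing and hole filling. The compartment between the two
   contours is the epifascial layer, where lymphoedema fat and fluid
   accumulate; inside the fascial contour is the subfascial compartment.

Volumes are voxel counts (1 voxel = 1 mm³ = 0.001 mL): total arm,
subfascial, epifascial, muscle (subfascial), fat (epifascial) and fluid
(epifascial). For an affected/unaffected pair the package computes excess
volumes (affected − unaffected), percent changes
`(affected − unaffected)/unaffected`, relative excesses (divided by the
unaffected arm's epifascial volume), a 10-segment longitudinal excess map
(6 forearm + 4 upper-arm segments), and a 16-segment radial fluid-excess
map (8 sectors × internal/external epifascial layers split at the
midcontour, torso side always rendered on the right). Cohort statistics
follow the field's conventions: Shapiro–Wilk normality tests, two-tailed
paired *t* tests, Pearson correlation with a linear fit and 95% confidence
band, and Spearman rank correlation for clinical covariates.

A synthetic phantom generator (`phantom_spec()`, `generate_arm()`,
`generate_pair()`, `generate_cohort()`) builds tapered cylindrical arms
with a muscle core, fascia, epifascial fat, fluid pockets, vessel-like
interstitial structures, channel noise and bias fields — with voxel-exact
ground-truth labels, compartments and volumes for validation.

## Worked example

Build a phantom pair with 105 mL fat and 50 mL fluid excess injected into
the affected arm, run the full pipeline, and compare:

```r
library(lymphmap)

spec <- phantom_spec(noise_sd = 6.5, seed = 11)          # 200 x 120 x 120
pair <- generate_pair(spec, excess_spec(fat_ml = 105, fluid_ml = 50))
res  <- run_pair(pair$affected$stack,   pair$affected$ground_truth$landmarks,
                 pair$unaffected$stack, pair$unaffected$ground_truth$landmarks)
res$comparison
#> <arm_comparison>
#>             metric affected_ml unaffected_ml excess_ml percent_change
#>          total_arm    1037.520       882.532   154.988           17.6
#>         subfascial     376.024       376.024     0.000            0.0
#>         epifascial     661.496       506.508   154.988           30.6
#>  muscle_subfascial     353.929       353.929     0.000            0.0
#>     fat_epifascial     586.102       481.114   104.988           21.8
#>   fluid_epifascial      70.806        20.806    50.000          240.3
#> relative excess (of unaffected epifascial): epifascial 0.306, fat 0.207, fluid 0.099

res$radial_map
#> <radial_excess_map> fluid excess (mL), torso side right (right arm)
#>          s1 s2 s3 s4    s5    s6    s7   s8
#> internal  0  0  0  0  0.55 11.31 14.57 3.38
#> external  0  0  0  0 -0.55  5.68 10.80 4.26
#> total 50.00 mL, peak 14.57 mL
```

The injected 105/50 mL excess is recovered to within a fraction of a
percent (the muscle rows are identical because the generator leaves muscle
untouched), the entire excess is epifascial, and the radial map localizes
the injected fluid in the sectors around its placement angle. Writing
`outdir =` to `run_pair()` additionally produces the per-arm NIfTI label
maps, CSV tables, and PNG figures (longitudinal plots and intensity maps
with per-patient peak normalization).

A thin command-line front end is installed at `inst/cli/lymphmap`
(subcommands `phantom`, `run-arm`, `run-pair`, `run-cohort`).

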