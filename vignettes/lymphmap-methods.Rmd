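---
title: "Tissue-composition analysis of lymphoedematous arms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-composition analysis of lymphoedematous arms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast cancer–related lymphoedema (BCRL) is chronic swelling of the arm
after breast cancer treatment. The swelling is a mixture of interstitial
fluid (which first-line decongestive therapy can move) and adipose tissue
(which it cannot), accumulating almost entirely in the epifascial layer —
the compartment between the skin and the muscle fascia. Clinical tools such
as tape measures or the Perometer quantify overall arm size only.
`lymphmap` quantifies the *composition* of the swelling from three
co-registered MR volumes per arm: a Dixon water image (muscle bright), a
Dixon fat image (fat bright), and a STIR image (fluid bright). Both arms of
a patient are processed identically and compared.

## The segmentation model

Every voxel contributes a feature vector of its three channel intensities.
The model is deliberately simple: in this feature space, well-imaged arms
form five dense clusters — muscle, fat, fluid, image noise (voxels with no
signal), and mixed-composition voxels at tissue interfaces (including
connective tissue and vessels). The package partitions the feature space
with k-means, k = 5, and labels clusters by centroid dominance in a fixed
priority order:

1. *noise*: smallest channel sum;
2. *fat*: largest Dixon-fat centroid among the rest;
3. *fluid*: largest STIR centroid among the rest;
4. *muscle*: largest Dixon-water centroid among the rest;
5. *mixed*: the remaining cluster.

Ties at any step fall to the lower cluster index, making the labelling
deterministic. The assignment heuristic assumes the acquisition actually
delivers the stated contrasts; the phantom generator validates its
intensity table against the same assumption at construction time.

Assumptions worth stating: intensities are used raw (no per-channel
standardization by default, matching the practice of clustering the
combined images; a `standardize` flag exists for scanners with very
different channel scalings), clustering is spatially blind (no Markov
random field), and each arm is fitted separately so that inter-session
intensity drift cannot leak between arms.

### Numerical choices

* **Initialization**: k-means++ with a fixed seed; `nstart = 60` restarts,
  keeping the lowest within-cluster sum of squares (WCSS). Lloyd iterations
  stop when the largest centroid shift falls below `tol = 1e-4` of the
  feature range, or after 300 sweeps. Empty clusters keep their previous
  centroid. Nearest-centroid ties go to the lowest cluster index.
* **Subsampled fitting**: volumes of several million voxels are fitted on a
  deterministic random subsample of `fit_sample = 30000` voxels, and the
  winning centroids are then polished by full-volume Lloyd sweeps to
  convergence. Many cheap restarts beat few expensive ones here: the
  failure mode of a single run is a local optimum that merges the two
  smallest clusters (fluid and mixed tissue) while splitting the huge noise
  cluster, and the probability that sixty independent k-means++ seedings
  all miss the better basin is negligible. The final centroids are always
  converged on the full feature space.
* **Tiny problems**: when the fitting set has at most 50 points and at most
  500 k-subsets, every k-subset of the points is additionally swept as an
  initialization. This is deterministic and, in practice, attains the
  global WCSS optimum (verified against exhaustive partition enumeration in
  the test suite).
* **Degenerate input**: fewer distinct feature vectors than k is an error —
  there is no meaningful 5-way partition of a 4-point feature space.

## Compartments and contours

The program scrolls through each transaxial slice and builds two masks: the
external mask (largest connected component of non-noise voxels, closed with
a 3 mm disc, holes filled) and the subfascial mask (largest connected
component of muscle voxels, closed with a 5 mm disc, filled, constrained to
the external mask). Closing radii are package parameters: the erosion/
dilation sizes of the original IDL workflow are not published, so 3 mm
(smooths skin-surface noise without bridging to the table or coil) and 5 mm
(bridges the gaps where vessels or intermuscular fat interrupt the muscle
boundary, so all subfascial tissue falls inside the fascial contour) were
chosen once on anatomical grounds and are exposed in `pipeline_config()`.
Hole filling captures non-muscle subfascial structures (vessels, bone
marrow) that cluster as mixed tissue. A slice with no muscle voxels keeps
an empty subfascial mask and contributes zero subfascial volume — an
expected state distal to the wrist, flagged rather than fatal.

Compartments partition the grid exactly: outside, subfascial, and
epifascial (external minus subfascial). All volume measurements are voxel
counts times 0.001 mL at the enforced 1 mm isotropic resolution; no
sub-voxel modelling is attempted anywhere, which is why the partition
identities in the test suite can be asserted exactly rather than within a
tolerance.

Contours themselves are traced along pixel edges (not pixel centres), so a
contour's shoelace area equals its mask's voxel count exactly; exported
vertex lists are in mm.

## Maps

* **Longitudinal profile**: per-slice volumes (mL/slice) of muscle, fat,
  fluid, and total; the per-slice series sums exactly to the global
  volumes. Pairs are aligned at the elbow and trimmed to the common extent.
* **Longitudinal excess map**: the forearm is divided into 6 contiguous
  segments and the upper arm into 4. When slices do not divide evenly, the
  remainder is distributed one slice per segment starting at the distal
  end; only the counts 6 and 4 are inherited from the method's definition,
  the remainder rule is this package's (documented) choice. Per segment:
  fluid excess (mL), fat excess (mL), epifascial increase (% of the
  unaffected volume, undefined segments reported as missing). Rendered maps
  are normalized to the per-measure peak within the patient; the peaks are
  stored with the map so absolute values remain recoverable.
* **Midcontour split**: the epifascial layer is split into internal (above
  the muscle) and external (below the skin) sublayers by comparing each
  voxel's exact Euclidean distance to the nearest subfascial voxel versus
  the nearest outside voxel, per slice. This realizes the midcontour
  equidistant from the fascial and external contours without constructing
  it explicitly — equivalent, simpler, and exactly testable against a
  brute-force nearest-neighbour oracle. Ties go to internal. On slices with
  no subfascial mask every epifascial voxel is external (infinitely far
  from a fascia that is not there).
* **Radial map**: each slice is divided into 8 sectors by the horizontal,
  vertical and 45° lines through the slice's subfascial centre of mass
  (falling back to the external-mask centre when the subfascial mask is
  empty). The centre is computed per slice rather than once globally — the
  phrase "centre of mass of the subfascial volume" is ambiguous, and the
  per-slice reading tracks anatomical curvature along the arm. Fluid
  voxels accumulate into 2 × 8 (layer, sector) bins; the map is the
  affected-minus-unaffected difference, summed over the elbow-aligned
  extent. A voxel centred exactly on a partition line contributes half a
  voxel to each adjacent sector: this preserves the exact partition sum
  while keeping the map invariant under the grid's reflections (without
  it, voxels on the 45° diagonals all fall into one neighbour and a
  rotationally uniform annulus shows a spurious sector imbalance).
  Laterality handling: left arms are mirrored about the vertical axis so
  the torso-facing side is always rendered on the right.

## Statistics

Shapiro–Wilk for normality; two-tailed paired *t* for affected vs
unaffected volume sets (zero-variance differences are an explicit error for
the single test and a flagged, non-fatal state in cohort reports); Pearson
correlation with least-squares fit and 95% confidence band for volume–
volume relationships; Spearman rank correlation for clinical covariates,
with the exact null distribution for n ≤ 10 without ties and the asymptotic
approximation otherwise. No multiple-testing correction is applied — the
report mirrors how such pilot-cohort tables are conventionally presented,
and leaves adjustment to the reader.

## What the phantom emulates — and what it does not

The generator builds a tapered elliptical cylinder: muscle core (with
vessel-like interstitial tubes), fascia, an epifascial fat layer containing
fluid pockets (spherical blobs or annulus sectors, optionally interleaved
with fat on a 2-voxel lattice to mimic the trabecular "honeycomb" fluid
pattern), plus per-channel Gaussian noise clipped at zero and an optional
smooth polynomial bias field (default amplitude 0, since scanner-side
inhomogeneity correction is assumed).

The interstitial structures matter for honesty of the validation: real
arms contain mixed-composition voxels that occupy the fifth cluster. A
piecewise-constant phantom with only four populations would make k = 5
degenerate and would "validate" the method under conditions where it
cannot work as designed. The compact intermediate-intensity structures
give the mixed cluster a genuine population while keeping ground truth
exact. The noise reference scale, the *minimum inter-tissue contrast*, is
the smallest pairwise Euclidean distance between the class mean triples of
the intensity table (64.8 intensity units for the default table, so "10%
contrast noise" means per-channel SD 6.48).

Deliberate simplifications: additive clipped-Gaussian noise rather than
Rician magnitude statistics; no bone, no partial-volume blending at tissue
interfaces, no intensity nonuniformity within a tissue (beyond the bias
field); perfect co-registration between channels. Passing the phantom
suite therefore demonstrates the correctness of the geometry, counting,
mapping and statistics machinery, and the robustness of the clustering to
noise of realistic relative magnitude — it does not demonstrate robustness
to registration error, partial volume, or fibrosis, which the method does
not claim to handle.

Excess injection in `generate_pair()` is exact by construction: the
epifascial layer is thickened outwards slice by slice with a
voxel-counting feedback loop until the fat-plus-fluid target is met, then
exactly the fluid-target number of epifascial fat voxels (nearest the
requested angle, outermost first) are converted to fluid. Realized
ground-truth excesses therefore match their targets to well under 1%, and
the affected arm's muscle is untouched.

The cohort generator couples fluid to fat excess linearly
(`fluid = 0.5 × fat + noise`, clipped to at most 0.8 × fat) with a
truncated-normal fat distribution; the implied population Pearson
correlation is reported with the truth table so that recovery tests
compare against the generating value, not a refit.

## Scales used in the validation suite

Unit tests run on 80 × 72 × 72 phantoms (seconds each); the acceptance
suite exercises the full-size 200 × 120 × 120 geometry noise-free and at
ten noisy seeds, the 100-instance exhaustive k-means oracle, the mirror
and symmetry properties, 1000 null simulations for the paired test, and a
200-subject generated cohort. The complete suite runs in a few minutes on
one CPU. These sizes are the package's validation conditions, chosen to
keep exhaustive oracles (2^11 partitions, full nearest-neighbour searches)
tractable while exercising the full-resolution code paths.

## Indexing and I/O conventions

Slice indices are 1-based everywhere, including landmark sidecar files
(`wrist_slice`, `elbow_slice`, `shoulder_tip_slice`); axis 1 runs
wrist-to-shoulder; readers must reorient input to this convention (the
`axes` argument of `read_channel_stack()`). The analysis extent is
inclusive at the wrist and at the 65% mark, whose position
`elbow + 0.65 × (shoulder_tip − elbow)` is rounded half away from zero —
the rounding rule is a documented package decision, and the mark position
is invariant to the index origin. Resampling to 1 mm is node-centred
trilinear interpolation (nearest-neighbour for label volumes, which must
stay categorical) and preserves the physical extent to within one voxel.

## Known limitations

* Intramuscular fat is out of scope (it requires dedicated sequences);
  fibrosis is not separated from other mixed-composition tissue.
* Disconnected muscle cross-sections near the elbow are resolved by the
  largest-connected-component rule; thin second components are absorbed
  only if the 5 mm closing bridges them.
* The cluster-to-tissue labelling is a heuristic stand-in for an
  unpublished rule; it is validated on phantoms whose contrast satisfies
  the dominance assumption, and will mislabel acquisitions that violate it
  (e.g., fat-suppressed water images with very low muscle signal).
* k-means is a local optimizer; the restart schedule makes failures rare
  rather than impossible. The fitted model (centroids, WCSS, seed,
  assignment) is serialized next to every run for auditability.
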