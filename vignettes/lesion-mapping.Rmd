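---
title: "Mapping catecholaminergic lesions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping catecholaminergic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionmap)
```

# The problem

Unilateral striatal infusion of 6-hydroxydopamine (6-OHDA) kills
catecholaminergic neurons in a retrograde fashion, producing cell loss
concentrated in the substantia nigra pars compacta (SNpc) and widespread,
bilateral loss of tyrosine-hydroxylase-positive (TH+) fibers. Whole-brain
light-sheet imaging of cleared tissue yields 3D TH immunofluorescence
volumes; after registration to a common atlas, the scientific questions
are *where* TH signal differs between hemispheres and treatment groups,
and whether the voxel-level statistics correspond to real cell and fiber
density changes in the native ("tissue") resolution data.

`lesionmap` implements that quantitative chain: image conditioning,
voxel-wise permutation statistics for a 2x2 (side x treatment) design,
cluster-constrained FDR correction, cluster-level density validation,
region-wise counting, and optical-fractionator stereology — driven by a
synthetic-data generator with known ground truth, so every stage is
testable without imaging data.

# The statistical model

## Voxel-wise 2x2 permutation ANOVA

Each sample contributes two observations on a common hemisphere lattice:
its ipsilateral (right, the infused side) hemisphere and its mirrored
contralateral hemisphere. Per voxel, the classical two-way cell-means
model with factors side (ipsi/contra) and treatment (lesion/vehicle) is
fit; Type-III single-degree-of-freedom contrasts give the three F
statistics (each Type-III hypothesis in a 2x2 design is a contrast on the
four cell means with coefficients \(\pm\tfrac12\), so
\(SS = L^2 / \sum_c c_{ij}^2/n_{ij}\), exact for unbalanced cells such as
10 lesioned vs 8 vehicle brains).

Significance is assessed by permutation: empirical
\(p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (1 + n_{perm})\), with 18,000
permutations by default, so p is never exactly zero and is bounded below
by \(1/(n_{perm}+1)\). When the number of distinct label arrangements is
at most `n_perm` the test enumerates them exactly (recorded in the map's
metadata).

**Exchangeability.** All observations are treated as exchangeable units:
the joint (side, treatment) cell label vector is permuted as a whole
(Manly-type unrestricted permutation) for all three ANOVA statistics.
Shuffling only one factor's labels can empty a design cell in small
cohorts, which leaves the cell-means F undefined; the synchronized
full-label shuffle preserves cell counts by construction. Post hoc
contrasts permute the two-group label directly and compare |t| two-tailed.
A paired/sign-flip mode is deliberately out of scope: cluster validation
downstream uses *unpaired* t-tests, so the voxel stage matches.

This choice has a measurable consequence: the two hemisphere observations
of one sample share that sample's smooth background, so side contrasts
are mildly anti-conservative under free exchangeability, while treatment
contrasts (which permute whole samples, the true experimental unit) are
calibrated. The type-I acceptance test therefore calibrates on the
treatment factor, on *unsmoothed* volumes — smoothing changes spatial
correlation, not per-voxel validity, and only inflates the variance of
the voxel-fraction estimate.

## Post hoc gating

Voxels reaching uncorrected p < 0.05 for the main effect of side, the
main effect of treatment, or their interaction (the union by default;
per-effect gating is available) are evaluated further with four
permutation t contrasts: ipsi vs contra within each treatment group, and
lesion vs vehicle within each side.

## Cluster-size-constrained FDR

Benjamini–Hochberg step-up: order the p-values, scan from the largest for
the first \(p_{(i)} \le (i/m)\,q\); that p-value is the adjusted
threshold, and every p at or below it is significant. \(m\) is the number
of in-mask voxels for the contrast. Among a descending-stringency q grid
(0.05 down to 5e-5), the pipeline selects the *smallest* q at which at
least one connected cluster of >= 100 significant voxels survives; all
surviving clusters are then size-filtered at 100 voxels and split into
direction-homogeneous components by the t-map sign. Connectivity defaults
to 26 (faces + edges + corners), the common neuroimaging convention; 6
and 18 are available. Ties at the threshold p are retained (the
inequality is `<=`).

## Cluster validation

Each cluster (found on the hemisphere lattice) is embedded ipsilaterally
and mirrored contralaterally, warped to tissue space (nearest-neighbour),
and partitioned: the part overlapping dopaminergic/noradrenergic
cell-group regions is measured as TH+ *cell density* (counted 3D
components per mm^3), the remainder as TH+ *fiber density*
(100 x segmented voxels / cluster voxels). A cluster is valid if an
unpaired two-tailed pooled-variance t-test on the per-sample densities is
significant at alpha = 0.05 for any of its parts. Counting uses the
component-*centroid* membership rule rather than mask multiplication:
multiplying segmentations by cluster masks would split objects on the
cell/fiber partition boundary and double-count them.

## Stereology

The optical fractionator estimates total cell number from systematically
sampled sections: every 6th section (ssf = 1/6), a counting grid covering
20% of the region (asf = 0.20), and a thickness sampling fraction
tsf = h / t̄_Q with t̄_Q the count-weighted mean section thickness
\(\sum t_i Q_i / \sum Q_i\). The total is
\(\hat N = \sum Q \cdot (1/ssf)(1/asf)(1/tsf)\). Disector height and
guard zones are not part of the modelled design, so h defaults to the
full measured thickness (tsf = 1) — a documented assumption. Traced
contours are measured with the shoelace formula, orientation-free via the
absolute value. The 2D lesion-extent endpoint is the mean-fluorescence
ratio 100 x ipsi/contra.

# The synthetic world

The generator emulates the *structure* of a lesioned mouse brain, not its
appearance. A bilateral ellipsoidal brain carries mirror-symmetric
regions: dopaminergic nuclei (SNpc and VTA analogues), a noradrenergic
nucleus (LC analogue), projection regions (striatum and cortex
analogues, plus a supramammillary-like focal region), a ventricle-like
excluded region, and a root label for unassigned tissue.

Samples are rendered in **tissue space**, `tissue_factor` (default 2x)
finer than the atlas lattice — 25 um vs 50 um for the default 64x48x48
atlas — mirroring the pipeline's two-space structure: statistics in atlas
space after downsampling by two, counting at native resolution.

- **Somata** are uniform bright spheres (radius 22 um, amplitude 150)
  placed by a Poisson process at the stated density per nucleus. Uniform
  spheres, not Gaussian blobs: a blob smaller than a voxel has an
  offset-dependent peak value, which would make detection depend on
  sub-voxel position and bias counts. Default densities
  (350/mm^3 SNpc/VTA, 300/mm^3 LC) are far below biological TH-neuron
  densities (~10^4/mm^3); they are a countability compromise of the
  coarse toy lattice, chosen once so that somata remain resolvable as
  distinct 26-connected components. Density *ratios* — what the pipeline
  measures — are unaffected.
- **Neuropil and fibers** are 1-voxel-wide random walks with momentum
  (persistence 0.8): dense neuropil inside each nucleus (fill 0.5,
  scaled by the nucleus's *cell* effect factor, since dendritic TH tracks
  cell loss) and long-range fibers grown from each nucleus into its
  projection regions until a target fill is reached (striatum 0.6,
  cortex 0.35, SUM analogue 0.3 — dense innervation, as real TH
  projection fields are at 25-50 um voxels). Route voxels between source
  and target are genuinely marked, so tract-level signal loss emerges,
  as in the real pathway. Walks from other sources may overshoot a small
  region's fill; the truth record stores the realized fill.
- **The lesion** multiplies densities and fills per (region, side):
  defaults are cell 0.5 ipsi in the SNpc analogue, 0.8 ipsi in VTA,
  fibers 0.5 ipsi / 0.8 contra in projection regions, and a focal
  *compensatory increase* (fiber factor 1.5 ipsi) in the SUM analogue.
- **Imaging**: smooth low-frequency random background (amplitude 10) and
  i.i.d. Gaussian noise (sd 5) on a soma amplitude of 150 and fiber
  amplitude of 60. Ground truth (cell centres, per region/side counts,
  signal masks — thresholded at half the weakest rendered amplitude —
  and applied factors) is recorded before noise.

What the generator does **not** emulate: stripe/shadow artifacts,
depth-dependent attenuation, autofluorescence channels, registration
error (transforms are exact inputs), or realistic soma densities (see
above). A green planted-lesion test therefore establishes that the
statistical chain recovers planted effects under idealized imaging — not
that segmentation or registration of real light-sheet data would succeed.

# Segmentation stand-in

The modelled workflow segments cells and fibers with interactively
trained random-forest classifiers, which cannot be reproduced without
their annotations. The package substitutes deterministic thresholding:
Otsu's method for the overall TH+ signal (background vs signal separates
cleanly), and an **absolute calibrated threshold** for somata, midway
between the known fiber and soma amplitudes. An automatic two-level Otsu
was rejected after it provably split the dominant fiber mode instead of
isolating the tiny (<1% of signal voxels) soma class; calibrating the
threshold from the generator's known amplitudes is the deterministic
analogue of training the classifier on annotated samples. A fixed
quantile threshold and a user-supplied external mask (real classifier
output) remain available.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| rolling-ball radius | 20 | px | preserves somata/tracts, removes smooth background; applied per z-slice as grayscale opening with a flat disk |
| smoothing sigma | 0.05 | mm | world-unit sigma (the `fslmaths -s` convention is mm); converted to voxels via spacing |
| permutations | 18000 | – | p floor 1/18001; desk-scale runs use fewer |
| gating alpha | 0.05 | – | uncorrected ANOVA gate for post hoc maps |
| q grid | 0.05 … 5e-5 | – | candidate FDR stringencies |
| min cluster | 100 | voxels | clusters below this never survive |
| connectivity | 26 | – | neuroimaging convention; 6/18 configurable |
| ssf, asf, tsf | 1/6, 0.20, 1 | – | fractionator sampling design |
| validity alpha | 0.05 | – | two-tailed unpaired t on densities |

# Numerical choices

- Voxel-centre world convention, 0-based indices; out-of-bounds samples
  are 0 (brains are zeroed outside the mask anyway).
- Gaussian smoothing uses a discrete kernel truncated at 4 sigma and
  normalized to unit sum, with zero padding — reflective padding was
  rejected to avoid inventing signal at the brain boundary.
- Zero-variance voxels: F and t are defined as 0 when the effect sum of
  squares is also ~0 (all-equal data), +-Inf otherwise.
- Permutation comparisons use a relative tolerance (1e-8) so recomputed
  statistics that are equal up to float rounding count as ties.
- Cluster ids are assigned in decreasing size order, ties broken by the
  first (lexicographically smallest) voxel.
- Sign-0 voxels inside a cluster take the 26-neighbourhood majority sign;
  ties are excluded from the direction-split cluster set.
- The smoothing/flip order is irrelevant for the isotropic kernel (they
  commute; verified by test), so the pipeline smooths first.

# Known limitations

- Side contrasts are mildly anti-conservative under free exchangeability
  when observations of one sample share background (see above); a
  paired design is out of scope.
- Only affine transforms are ingested; the deformable registration of a
  real pipeline is external.
- Counting by component centroid differs from mask multiplication for
  border-clipped objects; the difference is documented, not configurable.
- The atlas-lattice soma densities are toy-scale; absolute densities are
  not comparable to tissue values, only their ratios.
- NIfTI support covers axis-aligned geometry only (sufficient for the
  package's own I/O contract); TIFF z-series import is not implemented.
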