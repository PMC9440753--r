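---
title: "Reconstructing and quantifying 3D neuronal networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and quantifying 3D neuronal networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotrace3d)
```

## The problem

Human neurons cultured in soft 3D hydrogels grow tortuous, branched,
densely interconnected neurite networks. Quantifying such networks from
multichannel confocal stacks — a neurite marker (beta-III-tubulin/MAP2),
a neuronal nuclear marker (NeuN) and a pan-nuclear stain (DAPI) — requires
reconstructing centrelines in 3D and reducing them to a small set of
robust measures: total network length, branching and ending points,
neurites per soma, network volume, and *connectedness*, defined as the
percentage of network volume (or length) that belongs to the largest
connected component:

$$
C = 100 \cdot \frac{\max_k V_k}{\sum_k V_k}
$$

where $V_k$ is the volume (or length) of the $k$-th connected component.
Connectedness separates a healthy, integrated network ($C$ near 100) from
a fragmented, damaged one even when tracing individual neurons is
hopeless.

This package implements the full measurement chain as open, tested code,
together with a ground-truthed simulator of such stacks, so every stage
can be validated against known geometry without access to real data.

## The synthetic-data generator

`sim_config()` + `generate_network()` build the *true* network geometry;
`render_stack()` turns it into a voxel image.

**Geometry.** Somas are placed by rejection sampling without overlap.
Neurites grow from the soma centre as constant-step random walks (step
2 um) whose direction receives an isotropic Gaussian perturbation per step
(`tortuosity`, s.d. in radians); boundaries reflect. Branching is a
Poisson process along arclength; branches leave the parent at a moderate
forward angle (30-65 degrees), as real neurite branches do. Commanded
neurite length is arclength *from the soma centre*, so a single straight
neurite commanded at 50 um contributes exactly 50 um of true length.
Where centrelines of different neurons pass within one tube diameter,
*contact edges* join them — these contacts are what make healthy control
cultures form one dominant component, and they guarantee that the true
component partition agrees with the rendered mask, where tubes that close
together physically merge.

**Rendering.** Neurites are swept as constant-radius tubes (spheres
stamped every half-voxel along the centreline); somas are spheres, and a
configurable fraction render as *hollow shells* in the neurite channel —
cytoskeletal stains do not fill the soma, which is the origin of the
loop artifacts the tracing stage must handle. NeuN fills neuronal nuclei
only; DAPI fills all nuclei, including a few NeuN-negative background
cells. A per-axis Gaussian PSF (default 0.2, 0.2, 0.6 um — confocal-like,
elongated in z) is followed by signal-scaled Poisson noise (default 100
photons per unit intensity) and Gaussian read noise (s.d. 0.02). The
default frame is 255 x 255 x 100 um at 0.33 x 0.33 x 0.5 um spacing, the
acquisition geometry the workflow was designed around; voxel centres sit
at $(i + 0.5) \cdot s$ with the origin at the corner of voxel (0,0,0).
All randomness flows from the single seed in the config; identical
configs give bit-identical ground truth and stacks.

**Damage model.** `apply_damage()` applies, in order: whole-neurite loss
at the soma (Poisson count per soma), distal pruning of an exact fraction
of the remaining total length (tips are trimmed until the commanded
length is removed, so remaining length is exactly
$(1-p_{\text{prune}})$ times the pre-pruning length), detachment of
neurites at the soma, fragmentation (Poisson-placed gaps of configurable
width that split edges and raise the component count), and soma swelling
(radius scaling only). For a gap to remain visible after rendering its
width must exceed one tube diameter (the hemispherical caps of the cut
ends) plus the PSF extent; narrower gaps fragment the true graph but can
re-fuse optically. All-zero parameters are the identity. The default
*composite* damage states couple pruning with fragmentation and
detachment because that is the observed phenotype of ionomycin- and
OGD-type injury: shorter networks *and* discontinuous fragments; pruning
alone barely moves connectedness once somas dominate the remaining
volume.

**What the simulator does not emulate.** No depth-dependent attenuation,
spectral bleed-through, deconvolution residuals, non-spherical nuclei, or
hydrogel autofluorescence. Passing tests on synthetic stacks therefore
validate the measurement chain's geometry and logic, not its robustness
to every optical artifact of real acquisitions; parameters such as the
binarization threshold still need per-dataset attention on real data.
Control-state abundance of free-floating fragments is likewise a free
parameter (default: none) — real cultures contain some debris.

## Preprocessing

- `merge_channels()`: the neurite channel is merged with NeuN before
  tracing so somas carry signal. The arithmetic is voxelwise maximum
  after per-channel [0, 1] rescaling — it preserves both signals without
  saturation and is commutative and idempotent.
- `gaussian_smooth()`: anisotropy-aware (sigma in voxels is
  `sigma_um / spacing` per axis), normalized, reflective boundaries. The
  default 0.33 um equals one xy voxel at the reference spacing.
- `cdd_filter()`: a curvature-driven diffusion step,
  $u_t = g(|\nabla u|)\,\kappa\,|\nabla u|$ with conductance
  $g(s) = 1/(1+(s/K)^2)$, in an explicit scheme. Curvature flow erodes
  small high-curvature speckle much faster than elongated tubes, which is
  exactly the enhancement of continuous structures wanted before
  binarization. The explicit update is accepted up to `dt = 0.0625`
  (the 3D stability bound; larger values error out), and each iteration
  clamps the field to the input range, enforcing the maximum principle
  discretely. The filter is contract-tested (speckle suppression, tube
  preservation, range bound); no claim is made of matching any
  proprietary implementation bit for bit.
- `binarize()`: fixed thresholds are recorded for reproducibility;
  `otsu` (256-bin between-class variance) stands in for interactive
  thresholding. When the two classes are separated by empty bins the
  variance maximum is a plateau; the threshold is its midpoint.
- `fill_holes()`: background components not 6-connected to the volume
  boundary become foreground (foreground 26 / background 6 — the standard
  complementary pairing that avoids topological paradoxes). This closes
  hollow-soma cavities so they are not traced as loops.
- `mask_nuclear_channel()`: DAPI voxels survive only where NeuN reaches a
  threshold. The NeuN level that distinguishes "NeuN-positive" is not a
  universal constant; it is a parameter (`neun_threshold`, default 0.1 of
  the intensity scale) with no claimed biological default.

Every operation appends its name and parameters to the stack's
provenance log.

## Soma detection

`detect_somas()` runs multiscale Laplacian-of-Gaussian blob detection at
three scales bracketing $\sigma = d/(2\sqrt{3})$ for expected diameter
$d$ (default 12 um), keeps local maxima above a threshold relative to the
strongest response, and suppresses duplicates closer than $d/2$.
Detections whose supporting intensity blob exceeds 1.6 times the expected
sphere volume are flagged `merged`; oversized blobs with only one LoG
maximum are split at local maxima of the Euclidean distance transform
(marker-based splitting). The 1.6 factor keeps splitting conservative —
merged somas are the dominant error mode of starting-point detection, but
aggressive splitting would fabricate somas. `detection_accuracy()` scores
detections against ground truth by greedy one-to-one nearest matching
(ties broken by detection index, so the score is deterministic and
auditable against brute force).

## Tracing

- `skeletonize()`: 3D thinning assumes an isotropic grid, so the mask is
  first resampled along z (and y if needed) to the x pitch by linear
  interpolation — 0.5 to 0.33 um at the reference spacing. Thinning is
  *distance-ordered homotopic thinning*: border voxels are deleted in
  increasing Euclidean-distance-transform order, only if they are simple
  points (deletion preserves topology; tested with the two-component
  characterization — one 26-connected foreground component in the
  26-neighbourhood and one 6-connected background component in the
  18-neighbourhood touching a face neighbour) and not curve endpoints.
  Deleting surface-first keeps the surviving curve on the medial axis; a
  naive direction-sequenced peel can lock onto surface "rails" and
  produce hairpin artifacts with roughly doubled length.
- `skeleton_to_graph()`: junction voxels (3 or more skeletal neighbours)
  are clustered by 26-adjacency and collapsed to their centroid — one
  branch node per junction, never several adjacent ones. Degree-2 chains
  become edges with polylines through the voxel centres; polyline
  interiors are smoothed with a short moving average (window 5) to remove
  the voxel staircase, which otherwise inflates arclengths of oblique
  runs by several percent. Edge lengths are always recomputable from the
  stored polylines.
- `prune_spurs()` (default 2 um, about two neurite diameters): terminal
  twigs attached at branch nodes, the classic artifact of uneven tube
  surfaces, are removed to a fixpoint; plain chains are never touched.
- `remove_loops()` (default 40 um, about the circumference of a 12 um
  soma): cycles with geodesic circumference at or below the threshold —
  the signature of hollow somas surviving binarization — are collapsed to
  their centroid; larger cycles are genuine network circuits and are
  kept. Removed count and length are reported.
- `bridge_gaps()` (default 4 um, 60 degrees): end-node pairs within the
  gap limit whose terminal directions both point along the connecting
  segment are joined greedily by ascending distance, each end used once.
  The angle gate is what prevents bridges between closely located but
  distinct neurites.
- `assign_somas()`: soma nodes are inserted at detected centres and fused
  with all graph nodes within the soma radius. `soma_rooted` mode then
  discards components without a soma (the behaviour of soma-seeded
  tracers — only neurites connected to a soma in the imaged region are
  analysed), reporting the discarded count; `skeleton` mode keeps every
  component including free fragments.

Branch-point counts are computed and reported but flagged as unreliable
at neurite crossings: a tracer cannot distinguish a crossing from a
branch, so crossing-dense cultures inflate the count. The neurites-per-
soma measure is the branching proxy of choice.

## Morphometrics conventions

- **Neurites per soma** (Sholl sphere, default radius 8 um): the count of
  transitions of the component's centreline geometry across the sphere
  surface. Branching beyond the sphere adds nothing; a neurite that
  leaves and re-enters counts twice (the convention is explicit because
  the crossing convention is otherwise ambiguous); the count is invariant
  to subdividing edges. Crossing detection densely resamples polylines at
  0.25 um.
- **Neurite-growing neurons**: somas with at least one crossing. Cells
  with weak NeuN expression but no growing neurites are thereby excluded.
- **Network volume**: foreground voxels times voxel volume on the
  hole-filled neurite mask (0.05445 um^3 per voxel at reference spacing).
- **Connectedness**: volume basis on masks (26-connectivity labeling),
  length basis on graphs; both are emitted, the volume basis being the
  headline figure. Undefined (an error) on an empty network.
- **Reported percentages** round half away from zero to integers,
  matching the convention that turns means of 10,500 and 4600 um into a
  56% reduction.

## Statistics

The group statistics mirror the study designs the measures feed:
Spearman rank correlation (midrank ties, t-approximation p) for paired
software comparisons; two-sided Mann-Whitney U with optional Bonferroni
correction (and a paired signed-rank alternative, since trace pairs from
the same images are arguably paired — the unpaired test is the default as
in the original analyses); tie-corrected Kruskal-Wallis H with Dunn's
post hoc z statistics for three-group designs, Bonferroni-adjusted over
all pairs by default (the multiplicity adjustment behind "Dunn's
multiple comparisons" is rarely named; the adjustment is switchable);
and the pooled-variance unpaired t-test for two-group designs.
Quartiles use linear interpolation (R type 7); Tukey box summaries place
whiskers at the most extreme data within 1.5 IQR of the quartiles.
Significance stars map * < 0.05, ** < 0.01, *** < 0.001.
`compare_conditions()` picks the design-matched test (t for 2 groups,
Kruskal-Wallis + Dunn for 3 or more) and reports percent reductions
against control. Under the null, all three tests hold their type-I error
within [0.03, 0.07] at alpha 0.05 (checked by simulation in the test
suite).

## Numerical choices and degenerate inputs

Zero-sigma smoothing, zero diffusion iterations, zero gap width, zero
spur length and all-zero damage are exact identities. Empty masks
skeletonize to empty graphs; empty channels yield empty detections (not
errors); empty networks make connectedness error out rather than return
a misleading number. Greedy matchings (gap bridging, detection scoring)
break ties by index so results are deterministic. Thresholds that the
source workflow left unstated — spur length 2 um, loop circumference
40 um, bridge angle 60 degrees, NeuN threshold, LoG relative threshold —
are exposed as arguments with the defaults documented here.

## Problem sizes used by the test suite

The validation suite runs at desk scale, chosen as the smallest sizes at
which every property is meaningful: geometry recovery uses twenty
noiseless 64 x 64 x 40 um stacks with 1.5 um tubes under the documented
no-close-crossings condition; the damage sweep uses 48 x 48 x 24 um
stacks, five prune levels, fifty seeds per level; null calibration uses
2000 simulated datasets with n = 10 per group. The acceptance script
simulates a three-condition study (control, IM-like, OGD-like; six
samples per condition) on 56 x 56 x 28 um stacks with full PSF and noise,
traces them with the soma-rooted pipeline and reports group means,
percent reductions, connectedness, detection accuracy and the
Kruskal-Wallis p-value.

## Known limitations

Crossing neurites closer than a tube diameter merge in the image and
cannot be re-identified as separate neurons — lengths through such
regions are counted once, branch points there are unreliable, and no
attempt is made to resolve per-neuron identity. The SWC exporter emits
spanning trees per component; cycle-closing edges (contacts) are
represented as extra leaf chains, so round-tripping a cyclic graph
through SWC loses cycle topology. Stacks are written as plain multi-page
TIFF with a JSON sidecar for spacing, channel names and provenance
rather than OME-XML metadata. The hollow-soma shell model is spherical;
real somas are not.
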