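---
title: "SynConnect: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SynConnect: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Expansion microscopy combined with lattice light sheet imaging (ExLLSM)
resolves individual synapses by light microscopy: after ~8x physical
expansion, presynaptic active zones labeled by Bruchpilot (BRP) appear as
discrete clusters of a few hundred to a few thousand voxels, and
genetically restricted postsynaptic markers (Drep2-style) or gap-junction
labels (innexin) form similar puncta.  Counting synaptic connections
between two identified neurons then reduces to an image-analysis problem:
segment the neurons, segment the punctate marker channels into individual
sites, and quantify colocalization — first between sites and neuron masks
(assignment), then between presynaptic and postsynaptic objects (contact).

SynConnect implements that post-acquisition pipeline as a tested R
package: volume I/O, neuron-mask post-processing, punctate instance
segmentation, the four connectivity workflows, blockwise execution for
volumes too large to process whole, instance-level evaluation, and a
synthetic phantom generator that provides exact ground truth so every
stage can be validated without any external data.

# Pipeline model

All volumes are 3D scalar grids in z,y,x axis order with a per-axis voxel
size in nanometres.  Coordinates reported anywhere (centroids, bounding
boxes, block boxes) are 0-based and boxes are inclusive on both ends; this
matches the first/last-slice convention of ROI cropping and makes centroid
arithmetic exact (the centroid of voxels (0,0,0) and (0,0,2) is
(0,0,1)).

The stages and their defaults:

| stage | operation | parameter | default | why |
|---|---|---|---|---|
| mask | intensity threshold | method | Otsu (Li, manual available) | separates neuron label from background; threshold rule everywhere is `value >= t` |
| mask | gap bridging | max gap / iterations | 20 voxels / 4 | labeling gaps along neurites are discontinuities in fluorophore expression or antibody access; 20-voxel bridging iterated 4 times reconnects them |
| mask | closing | structuring element | 3x3x3 | reconnects voxels separated by a single pixel |
| mask | size filter | min component | 2000 voxels | removes nonspecific specks; inclusive keep (a 2000-voxel component survives) |
| sites | probability threshold | threshold | 0.8 | binarizes the classifier's probability map |
| sites | size gate | presynaptic | 400 voxels | unclustered antibody signal is smaller than 400 voxels |
| sites | size gate | postsynaptic, gap junction | 200 voxels | receptor and innexin puncta run smaller than BRP clusters |
| assignment | colocalization | fraction | 0.5 | a site belongs to a neuron when 50% or more of its volume overlaps the mask (inclusive) |
| contact | colocalization | fraction | 0.001 | 0.1% of the query object — essentially any contact counts (inclusive) |
| blockwise | partition | block edge / halo | 512 / 64 voxels | subvolumes processed independently and re-merged |

Voxel adjacency defaults to 26-connectivity for foreground everywhere
(thin diagonal neurites survive); it is configurable (6/18/26), stated
once in the configuration and used consistently.

# Numerical choices

**Distances are isotropic voxel units.**  Gap tolerances and seed
separations are stated in voxels, so the package measures Euclidean
distance on voxel indices by default and exposes an anisotropic switch
(`anisotropicDistance`) that weights axes by their nm voxel size.  Typical
acquisitions have z voxels ~1.7x larger than lateral voxels; whether the
original gap filler accounted for that is unknowable from the outside, so
the simpler reading is the default.

**Gap bridging** is defined as: per round, label components at
26-connectivity; for every unordered pair of components whose minimum
surface-voxel distance is at most the tolerance, rasterize the 3D
Bresenham segment between the arg-min voxel pair (ties broken toward the
lowest raster-order pair) and add it, dilated by a 1-voxel ball, to the
foreground; repeat for the configured number of rounds or until stable.
Because bridges are thin local segments, the operation cannot inflate
shapes the way a global closing at radius 20 would, and iteration matters:
a component unreachable from any original component can become reachable
through a bridge laid in an earlier round.  Only surface voxels (those
with a 6-neighbor background voxel) enter the pair search, which changes
nothing about the minimum but keeps the exhaustive search affordable; the
contract is still defined — and tested — against exhaustive pair
distances.

**Watershed seeding.**  The splitting of touching puncta uses the
Euclidean distance transform (computed exactly with the
Felzenszwalb–Huttenlocher separable algorithm): seeds flood the negated
distance restricted to the foreground, claiming voxels in order of
decreasing distance with FIFO tie-breaking, so the labeling is fully
deterministic.  Seed selection needs care on rasterized data: the
distance transform of a digitized ellipsoid carries sub-voxel bumps along
its medial ridge, and naive local maxima would split a convex object.
SynConnect therefore takes *regional* maxima of the distance transform
quantized to whole voxels, then applies an exact prominence test at h = 1
voxel (a candidate separated from a higher peak only by a dip shallower
than one voxel is an artifact of rasterization, not a second object), and
finally the minimum seed separation (default 3 voxels, greedy by
decreasing peak height with raster tie-breaks, applied within each
connected component so no component loses its only seed).  Two genuinely
overlapping spheres still produce two seeds because their saddle lies
well below either peak; verified as a property test on random ellipsoids
and dumbbells.

**Thresholds.**  Otsu maximizes between-class variance over an exhaustive
scan of histogram levels (256 bins for 8-bit, 65,536 for 16-bit input,
256 uniform bins for real-valued data), breaking ties toward the lowest
optimum.  Li iterates the minimum-cross-entropy fixed point to 1e-6; data
are shifted only if negative values are present, since the log-mean update
assumes non-negative grays.  Constant volumes are a degenerate input for
both and raise an error advising a manual threshold; the mask
post-processing chain short-circuits a constant (e.g. empty) volume to an
empty mask.

**Probability providers.**  The trained 3D U-Net of the original pipeline
is replaced by a provider interface: any callable mapping a volume to a
same-shape probability array plugs in (`external_model`), and a built-in
`scaled_intensity` provider rescales intensity linearly between the 1st
and 99.9th percentiles.  When a channel is very sparse (signal occupying
less than 0.1% of voxels) those percentiles collapse to the background
value; the provider then falls back to rescaling the full intensity
range, and a truly constant volume maps to all-zero probability.  The
package's testable substance is everything downstream of the classifier,
which is why no weights ship and none are required.

**Contact measurement.**  The colocalization denominator is always the
query object — the postsynaptic site when testing contact with
presynaptic sites (workflow 2), the presynaptic site when testing contact
with the neuron-2 mask (workflow 3) — which makes the two workflows
symmetric.  Both the 50% assignment rule and the 0.1% contact rule are
inclusive at the boundary.  Contact requires genuine voxel overlap by
default; a `contactDilation` switch dilates each query site (per-site, in
its padded bounding box) for apposed-but-disjoint labelings, since
antibody geometry can hold pre- and postsynaptic signals a voxel apart.
A query contacting several presynaptic sites emits one connection per
pair (polyadic synapses), and the distinct-presynaptic-site count can
therefore be smaller than the connection count.

# Blockwise processing

Large volumes are partitioned into cubic cores (default edge 512) that
tile the volume exactly, each padded by a halo (default 64).  Site
detection runs per padded block; an instance is owned by the block whose
core contains the voxel holding its centroid, which deduplicates
instances seen by several blocks.  Owned instances merge into one label
volume, and assignment and contact analysis run after the merge, so the
blocked pipeline is equal to the global one whenever every site fits
inside the halo; a site whose bounding box presses against a padded block
face triggers a warning naming it, and a halo smaller than a conservative
site-diameter estimate warns up front.  Connected components are merged
across blocks differently — per-core labeling followed by a union-find
over all adjacent foreground voxel pairs — which is provably identical to
the global labeling for *any* input, independent of block order.
Blocks are pure functions of their padded input, so any scheduler may run
them; the merge is a deterministic reduction.  Block skipping
(`nonemptyBlocks`) identifies cores without neuron-mask voxels; in the
analysis workflows such blocks can only contribute sites that the
assignment rule would discard, so skipping them changes the work done,
not the connectivity results.  Detection totals over the whole volume
(e.g. workflow 4) are computed without skipping.

# Evaluation

Detections are scored against ground-truth instance labels by one-to-one
matching: candidate pairs with IoU of at least 0.1 are sorted by
decreasing overlap (ties toward lower ids) and accepted greedily.  The
permissive IoU default reflects ground truth curated by humans who treat
any plausibly coincident cluster as the same object.  Precision is
TP/(TP+FP) and recall TP/(TP+FN), each defined as 1 when its denominator
is empty; a voxel-level Dice coefficient is reported as an auxiliary
measure, and an optional evaluation mask restricts scoring to regions
where ground truth exists.  Swapping prediction and truth exchanges
precision and recall exactly.

# The phantom generator

`generatePhantom()` builds the statistical structure the pipeline
assumes, with ground truth recorded during placement (never re-derived):

- **Neurons** are bounded-curvature random-walk tubes (radius 4 voxels,
  ~1300 voxels of arclength) rasterized as spheres along a densified
  skeleton.  Each neuron is confined to its own slab of the volume with
  enough clearance (twice the tube-plus-bouton reach plus the bridging
  tolerance) that no operation can ever connect two neurons — separation
  holds by construction rather than by rejection sampling.
- **Labeling gaps** zero the tube over stretches whose surface-to-surface
  gap is about 10 voxels (at most 15), placed away from tube ends and not
  fully covered by any bouton, so default bridging closes all of them.
- **Presynaptic sites** are ellipsoids of 450–3000 voxels (mild
  elongation along the local tube direction) centered on the tube
  surface.  The neuron mask absorbs each site as a bouton-like swelling,
  so every site overlaps its own neuron completely and the 50% assignment
  rule is satisfied with margin.  Same-channel objects keep at least 3
  voxels of clearance so instances never merge.
- **Apposed postsynaptic sites** (250–1000 voxels) are placed along the
  outward radial direction of a randomly chosen neuron-1 partner site,
  sharing 1–30 overlap voxels; the size cap guarantees that even a single
  shared voxel meets the 0.1% contact rule.  A postsynaptic site may
  touch no presynaptic site other than its partner.  A `touching` mode
  places them adjacent but disjoint, to exercise the contact-dilation
  switch.
- **Nonspecific puncta** (20–350 voxels, below the presynaptic 400-voxel
  gate) go into the presynaptic channel; they sit at least 3 voxels from
  true sites so they form their own instances and are removed entirely by
  the size gate.  They are placed in the presynaptic channel because its
  gate (400) dominates their size range; the postsynaptic gate is 200, so
  200–350-voxel puncta there would not be sub-threshold.
- All randomness flows from one seeded RNG stream; a fixed seed yields a
  byte-identical dataset, and the generator restores the caller's RNG
  state.

What the phantom does *not* emulate: optics (no point-spread function,
no anisotropic blur), intensity variation within and between objects
beyond optional additive Gaussian background noise, real neuron
morphology (branching, varicosities), antibody chemistry, or
sub-voxel partial-volume effects.  Passing the end-to-end recovery tests
therefore demonstrates that the post-classifier pipeline — thresholding,
watershed splitting, gating, colocalization counting, blockwise merging —
is correct and exact on well-posed input; it says nothing about
classifier quality on real tissue, which is exactly the part the provider
interface leaves to the user.

# Test problem sizes

The package's own validation uses a 256^3 phantom with 3 neurons, 40
presynaptic sites per neuron and 15 apposed pairs for the end-to-end
recovery, gate-effectiveness and determinism checks; 128^3 two-neuron
phantoms for workflow properties and blocked-vs-unblocked equality (block
edge 64, halo 32); 96^3 grids (block edge 32, halo 8) and 50 random masks
for blockwise component equality; and 100 random 32^3 masks across all
three adjacencies for the component-labeling oracle.  These sizes give
every code path multiple instances to act on while keeping the whole
suite runnable on a laptop.

# Known limitations

- The bridging pair search is exhaustive over surface voxels per
  component pair; masks with very many components (thousands) in one
  volume will be slow.  The intended use post-processes neuron channels
  where the size filter keeps component counts small.
- h-maxima seeding merges genuinely distinct puncta whose distance
  transform saddle is within 1 voxel of both peaks — objects that
  overlap so deeply are not separable by shape alone.
- Per-site contact dilation is exact but per-instance; with tens of
  thousands of query sites and a large dilation radius it is the slowest
  path in the package.
- The chunked store is a self-describing N5-like layout (JSON attributes
  plus raw little-endian chunks) readable by this package; it does not
  implement the full N5 specification (no compression codecs, no
  multiscale pyramids).
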