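---
title: "Measuring gallery-system development from traced annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gallery-system development from traced annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gallerytrack)
```

## The problem and the approach

Animals that excavate — termites tunnelling toward food, ants digging
nests, mice building burrows — produce branching gallery systems whose
temporal development is the observable trace of their collective behaviour.
Time series of photographs of two-dimensional arenas are the standard
recording; the measurement bottleneck is turning each photograph into
lengths, branch identities and network structure. Fully automatic
segmentation needs clean, standardised images, which excavation experiments
rarely provide (loose substrate and the animals themselves confound
thresholding). `gallerytrack` therefore assumes a human traces each gallery
as a polyline and automates everything downstream of the clicks.

The unit of annotation is the *gallery*: one ordered polyline from a
gallery's origin to its tip, at least two points, consecutive points
distinct. An image's annotation adds a reference point, a scale line, a
status (`analyzed`, `skipped`, `empty`) and an append-mode flag. A project
collects the annotated images of one or more groups (experiments), keyed by
the `<group>_<serial>.<ext>` file-naming convention, with two global
parameters: the contact/snapping threshold in pixels and the real-world
length of the scale object in mm.

## Parameters that matter

* **`threshold_px`** (default 10 px): the contact distance. A gallery's
  start attaches to the pre-existing gallery nearest to it *if* that
  distance is strictly below the threshold; endpoint clusters within the
  threshold collapse into one network node. The default suits traces where
  clicks land within a few pixels of the intended junction; it should stay
  well below the smallest true inter-gallery distance, or unrelated
  structures will fuse.
* **`scale_mm`**: the real length of the scale object. Calibration is
  per-image (`mm/px = scale_mm / |scale line in px|`), so lens or camera
  changes between sessions are absorbed image by image. An image without a
  scale line inherits the nearest preceding one; a project that never draws
  one falls back to 1 mm/px, i.e. raw pixel units.
* **`tol_px`** for the append-mode check defaults to `threshold_px`:
  re-clicked inherited points jitter by a few pixels, and exact equality
  would flag every retrace.

## Identity classification

Ranks follow the four branching rules used for termite foraging tunnels:
primaries originate at the start point; a gallery emerging from the side of
a pre-existing gallery is a descendant with rank parent + 1; at a split the
shallower branch keeps the identity; a gallery merging into another ends
there. Three design choices deserve note:

* **Entrances are optional.** With entrance points supplied (in the
  reference-corrected frame), galleries starting within the threshold of
  one are primary and everything else must have a parent; without them,
  parentless galleries are primary. This covers both single-origin tunnel
  assays and multi-entrance arenas.
* **Attachment is tested from the child's start only.** Drawing direction
  is semantic: a polyline that begins in open space and ends on another
  gallery is a *merge* (`merged_end`), not a reversed branch. The package
  never re-segments or re-orients a user's polyline.
* **The shallow-angle rule is a validation, not a transformation.**
  `split_inheritance_check()` reports which branch of a split retains the
  identity so drawings (and the synthetic generator) can be checked, but
  the user's segmentation is authoritative.

Ranks are resolved by iterating rank = parent rank + 1 to a fixed point;
anything unresolved (circular or orphaned parentage) is flagged
`unclassified` with a warning naming the galleries, and the network builder
refuses such input rather than guessing. Ties in parent search (two
galleries exactly equidistant) break by smallest distance, then
lexicographically smallest gallery id — deterministic and documented rather
than order-dependent.

## Network reduction

Candidate nodes are all gallery starts and ends, plus each attachment and
merge point *projected onto the gallery it touches*. Candidates are snapped
by single-linkage clustering under the strict `<` threshold; each cluster's
node coordinate is the centroid of its members. Every polyline is split
into edges at the interior nodes on it (by arc-length position), so edge
lengths are measured along the drawn skeleton and sum exactly to the
gallery lengths. Node types: *entrance* if the cluster contains an entrance
point, else *end* if degree 1, else *intersection*. An entrance marker with
no gallery endpoint in its cluster is dropped — an unused entrance (or any
entrance on an empty image) is not part of the drawn structure.

Single linkage can chain: three points pairwise 4 px apart under a 5 px
threshold form one node even though the extremes are 8 px apart. This is
the simplest reading of "within the threshold counts as the same node", and
is the documented behaviour; annotations should keep distinct junctions
more than twice the threshold apart.

## Temporal logic

Within a group, a `skipped` image inherits a deep copy of the nearest
preceding analysed/empty image's galleries (transitively across runs of
skips); the first image may not be skipped. Reference points and scale
lines absent from any image are inherited the same way — the scale object
is typically traced once per sequence. Inheritance is materialised at
analysis time; the project file stores no copies, so it stays minimal.

Append mode asserts monotone growth: every earlier gallery must reappear
with its reference-corrected points a prefix (within `tol_px` per vertex)
of the later polyline. Violations are data — tibbles with
`(group, serial, gallery_id, reason)` — surfaced as warnings in batch runs
and as a nonzero exit under the command-line `--strict` flag. Backfilled
(shortened) structures are accommodated by marking the re-traced image
"not appending", which suspends the check for that transition.

## Numerical choices

* Strict `<` threshold comparisons throughout: a pair at exactly the
  threshold does not merge or attach.
* Contact distances project onto polyline segments, not just clicked
  vertices, so a branch meeting the middle of a long straight segment is
  found.
* Coordinates are stored raw (as clicked); reference correction is applied
  at analysis time and never destructively.
* Project JSON and CSV exports write doubles with 17 significant digits,
  which IEEE-754 guarantees to reproduce the stored double bit-exactly
  under a correctly-rounded parser; per-image totals are computed by
  summing the per-gallery mm lengths in gallery-id order, so re-aggregating
  the per-gallery table reproduces the totals bit for bit.
* Per-image summary columns pool ranks ≥ 4 into one category; the
  per-gallery table keeps true ranks. Rank colours in overlays cycle
  through a fixed four-colour palette beyond rank 4.
* Empty inputs are first-class: empty images produce all-zero records,
  empty projects produce header-only CSVs, an empty network summarises to
  zeros.

## The synthetic generator

`synth_growth()` emulates the geometry of an excavation time series so the
whole pipeline can be tested without photographs: one primary gallery grows
from a central entrance with small heading jitter (about 6° per step);
descendants branch from the side of existing galleries at about 50°,
clearly steeper than any continuation, so the shallow-angle convention
holds by construction; the camera shifts a few pixels between images, with
the reference point and the scale line moving accordingly. Elongation is
about 45 ± 10 px per step over a default 20-step, 1200 px arena — in the
default 0.5 mm/px calibration, roughly 20 mm of growth per interval, a
realistic pace for a desk-scale tunnelling assay. Branch points keep at
least twice the threshold away from every existing node, and a tip that
cannot advance without approaching another gallery stops, so ground-truth
recovery is unambiguous (a `hard_mode` flag relaxes the separation to probe
tie-breaking). The generator returns full bookkeeping — every gallery's
true rank, parent and attachment position, per-serial cumulative per-rank
lengths, and per-serial node/edge counts — which the test-suite treats as
the oracle.

What the generator does *not* emulate: click noise on gallery vertices
(annotations are geometrically exact), backfilling (injected explicitly in
tests instead), merges/anastomoses (constructed by hand in tests), multiple
entrances per group, and any biology of a particular species. Passing
recovery tests therefore demonstrates the correctness of the measurement
logic on clean drawings, not robustness to sloppy tracing — the latter is
governed by the threshold and tolerance parameters above.

## Validation problem sizes

The shipped test-suite checks the geometric primitives against independent
oracles (explicit per-segment sums on 1000 random polylines; dense
arc-length sampling at 0.002 px spacing, which bounds the oracle error at
0.001 px; an igraph-components union-find oracle on 200 random point sets),
identity and parent recovery on 100 seeded structures (ranks up to 5),
length conservation and the handshake and forest identities on the same
structures, temporal copy-forward/monotonicity/shortening-detection
properties, a 3-group × 20-image end-to-end study compared with generator
ground truth at 10⁻⁶ mm, calibration and camera-shift invariances, and a
1125-image batch through the full post-analysis. `scripts/acceptance.R`
re-runs the central quantities from a seed and writes them as JSON.

## Known limitations

* One reference point per image: alignment is translation-only, with no
  rotation or scale registration between images.
* Identity classification trusts the drawing; it cannot detect that a user
  split one physical tunnel into two polylines or vice versa.
* Single-linkage snapping can merge distinct junctions closer than the
  threshold (chaining).
* The interactive tracing interface is out of scope here: annotation
  projects are produced headlessly (JSON, `measure --from-annotations`, or
  the generator), which is also how the pipeline is tested.
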