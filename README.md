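# gallerytrack

Quantify the temporal development of gallery systems built by animals —
termite foraging tunnels, ant nest excavations, mouse burrows, shelter
tubes — from sequences of images annotated by hand as polylines.

Many subterranean and wood-boring animals build branching gallery systems,
and their construction behaviour is best captured by measuring how the
structure's length develops over a time series of photographs. Automated
segmentation struggles with dirty arenas (excavated substrate, the animals
themselves), so the field's standard workflow is manual: a person traces
every gallery on every image. `gallerytrack` takes over everything around
the tracing: aligning images via a clicked reference landmark, converting
pixels to millimetres from a traced scale object, classifying each gallery's
identity in the branching hierarchy, reducing the drawing to a node/edge
network, inheriting annotations across unchanged images, and exporting tidy
per-image, per-gallery, node and edge tables ready for analysis.

## The measurement model

Each image's annotation is a set of **galleries**: ordered polylines of
pixel coordinates, drawn from origin to tip. Three global conventions drive
the analysis:

* **Contact threshold** `t` (px). Two structures are in contact when their
  distance is strictly below `t`; gallery endpoints within `t` of each other
  are the same network node.
* **Reference point.** An identifiable landmark clicked in every image; all
  coordinates are analysed relative to it, so a repositioned camera does not
  corrupt the series. Absent a click, the image's top-left corner is used.
* **Scale object.** A line traced over an object of known length `S` mm
  gives the calibration `mm/px = S / |scale line|`; every exported length is
  in mm.

Gallery **identity** follows the branching rules used for termite foraging
tunnels. With rank r(g) of gallery g and parent p(g):

1. galleries originating at the start point (entrance) are *primary*,
   r = 1;
2. a gallery emerging from the side of a pre-existing gallery is a
   *descendant*: r(g) = r(p(g)) + 1 (secondary, tertiary, quaternary, ...);
3. where one tunnel splits in two, the branch with the shallower angle to
   the incoming direction keeps the parent's identity (a drawing convention,
   validated by `split_inheritance_check()`);
4. where a gallery merges into a pre-existing gallery, its polyline ends
   (`merged_end`).

The **network** reduction treats every gallery start/end and every
attachment or merge point as a candidate node, snaps candidates within `t`
by single linkage, splits each polyline at the interior nodes on it, and
types nodes as *entrance* (purple), *intersection* (green) or *end*
(yellow). Edge lengths are measured along the drawn polyline, so they sum
exactly to the traced gallery lengths.

Across a series, a **skipped** image inherits the previous annotation, an
**empty** image yields zero records, and **append mode** asserts that
galleries only extend over time — violated galleries (e.g. backfilled
tunnels) are reported with provenance, or permitted by switching the image
to "not appending".

## Worked example

No photographs are needed: the packaged generator grows a seeded branching
structure with full ground truth and writes a normal annotation project.

```r
library(gallerytrack)

gen <- synth_growth(growth_params(seed = 17, n_steps = 8, branch_prob = 0.7))
project <- gen$project
project
#> <gallery_project v1.0> 1 group(s), 8 image(s); threshold 10 px, scale object 100 mm
#>   synthA: serials 0, 1, 2, 3, 4, 5, 6, 7

compute_series(project, "synthA")
#>   serial total_mm len1_mm len2_mm len3_mm n_galleries n_nodes n_edges growth_mm
#> 1      0    31.79   31.79    0.00    0.00           1       2       1     31.79
#> 2      1    69.28   49.97   19.31    0.00           2       4       3     37.49
#> 3      2   103.78   65.85   37.93    0.00           2       4       3     34.50
#> 4      3   146.23   85.11   61.12    0.00           2       4       3     42.45
#> 5      4   193.50  108.56   84.94    0.00           2       4       3     47.27
#> 6      5   256.63  127.98  105.78   22.87           3       6       5     63.13
#> 7      6   352.10  145.53  140.49   66.07           4       8       7     95.46
#> 8      7   439.05  164.11  158.59  116.35           4       8       7     86.95
```

Each row is one image: total traced length (mm), the per-rank split
(primary/secondary/tertiary, with rank ≥ 4 pooled in `len4plus_mm`), the
gallery and network counts, and the growth increment since the previous
image. The same pipeline exposes its stages individually:

```r
series <- materialize_series(project, "synthA")   # copy-forward resolution
last   <- series[[length(series)]]
gal    <- translate_to_ref(last$galleries, last$ref_point)
cl     <- assign_identities(gal, project$threshold_px,
                            project$entrance_points[["synthA"]])
cl
#>   gallery_id rank parent_id attach_arclength_px merged_end length_px
#> 1        g01    1      <NA>                  NA      FALSE    328.21
#> 2        g02    2       g01               69.76      FALSE    317.18
#> 3        g03    3       g02              155.02      FALSE    136.96
#> 4        g04    3       g02              206.87      FALSE     95.75

net <- build_network(gal, project$threshold_px, classified = cl,
                     entrance_points = project$entrance_points[["synthA"]],
                     mm_per_px = 0.5)
net
#> <gallery_network> 8 nodes (1 entrance, 3 intersection, 4 end), 7 edges, total 439.05 mm
```

`autoplot(net)` draws the network with the entrance/intersection/end colour
scheme; `plot_series()` plots length development; `tidy(net)` and
`glance(net)` give the edge table and the one-row summary.
`postprocess_project(project, outdir = "out", overlay = TRUE)` writes the
four CSVs (`per_image.csv`, `per_gallery.csv`, `nodes.csv`, `edges.csv`)
plus an overlay PNG per image with galleries stroked by rank.

A batch command-line wrapper covers the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "gallerytrack.R", package = "gallerytrack"))') \
    postprocess --input project.json --output out --strict
```

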