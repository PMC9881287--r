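---
title: "Methods: gating, differential testing and overlay rendering in spotgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, differential testing and overlay rendering in spotgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotgate)
```

## What the package computes

Spatial omics platforms (Visium and kin) measure expression at barcoded
capture spots whose positions are known in the full-resolution pixel frame
of a stained tissue image. Downstream tools (SpaceRanger, Seurat, signature
scorers) emit per-spot tables: a tag, X/Y coordinates and any number of
numeric features — genes, pathway scores, antibody levels, cluster labels.
spotgate operates on those tables headlessly: it places spots on the image,
lets the user define polygon gates (regions of interest) in image space,
filters tables by gate membership, compares gate groups feature-by-feature,
and renders feature or cluster overlays. Everything is scriptable, so an
analysis that would otherwise be a sequence of clicks is reproducible from
a shell or an R session.

## Data model and coordinate conventions

A `spot_table` is a data.frame with a unique, non-empty tag per row, finite
X/Y coordinates, and feature columns. Coordinates are full-resolution
pixels with the origin at the top-left and y increasing downward — the
orientation of the PNG raster itself — and no y-flip is ever applied,
because SpaceRanger emits pixel coordinates in image orientation.
`to_image_coords()` multiplies by the `tissue_hires_scalef` (or lowres)
value from `scalefactors_json.json` to land spots on the provided image;
`which = "none"` is the identity for platforms whose tables are already in
image space (CosMx exports, spatial ATAC pipelines). We deliberately do not
guess per-platform conventions: the user states which frame the table is
in.

Column roles are auto-detected only when unambiguous: the tag column from
`barcode`/`spot`/`id`/..., x from `x`/`imagecol`/`pxl_col_in_fullres`/...,
y from the row equivalents, case-insensitively. Two candidate headers for
one role is an error, never a guess. Numbers use the dot decimal separator
(scientific notation accepted); a column with any unparseable cell is kept
as categorical text, so an integer cluster column stays numeric and is
treated as clusters only when the user names it as such.

## Gating

Gates are named polygons with at least three vertices, implicitly closed.
Membership is the even-odd (ray-casting) rule; we chose even-odd over
nonzero winding because hand-drawn lassos can self-intersect, and even-odd
gives a well-defined, orientation-independent answer there. Points exactly
on an edge or vertex count as inside (tolerance `1e-9` px): users expect a
spot under the drawn line to be captured. A degenerate zero-area polygon
therefore contains exactly its boundary points. The suite checks the
implementation against an independent rasterization oracle (the polygon
filled by the cairo renderer on a 4x supersampled grid, even-odd rule, no
antialiasing), excluding points within half a pixel of the boundary where
any two rasterizers legitimately disagree.

ROI interchange uses ImageJ/Fiji's vertex-list CSV ("save XY coordinates"):
a `X,Y` header, one vertex per line, full precision, closing vertex not
duplicated. The binary `.roi`/`RoiSet.zip` container is out of scope. A
gate set round-trips through a directory of ROI CSVs plus a TSV manifest
(name, group, file) so group-1/group-2 assignment survives. Spot lists are
plain newline-separated tags with an optional header line — the
interchange columns used by virtual-cytometry selection tools are not
formally specified, so import accepts tag-only or tag-plus-extra-columns
lines (first field wins) and export writes tag-only.

## Group comparison

For each numeric feature, group 1 (spots in any group-1 gate) is compared
to group 2 (spots in any group-2 gate, or the complement of group 1 in
`group1_vs_rest` mode; spots in both groups are excluded with a warning)
using a two-sided Mann-Whitney U test. With midranks for ties,

$$U = \sum_i \mathrm{rank}(a_i) - \frac{n_a(n_a+1)}{2}.$$

Two branches compute the p-value:

* **Exact** (`min(n) <= 8` by default): the full permutation null — all
  $\binom{n_a+n_b}{n_a}$ assignments of the pooled midranks — via dynamic
  programming over the rank-sum distribution (midranks are doubled to make
  them integers). The two-sided p is
  $P\left(|U - n_a n_b/2| \ge |U_{obs} - n_a n_b/2|\right)$, which is
  well-defined because the null distribution of U is symmetric about
  $n_a n_b / 2$ even under ties. The suite verifies this branch equals a
  brute-force enumeration over `combn()` exactly, for all group sizes up
  to 8.
* **Normal approximation** otherwise: tie-corrected variance
  $\sigma^2 = \frac{n_a n_b}{12}\left(N + 1 - \frac{\sum_t (t^3 - t)}{N(N-1)}\right)$
  with a 0.5 continuity correction shrunk toward zero (never past it).
  Gates typically hold tens to hundreds of spots, where this approximation
  is excellent; the exact branch is reserved for tiny gates where it is
  not. The cut at `min(n) = 8` keeps exact enumeration cheap
  ($\binom{16}{8} = 12870$ at worst along the boundary).

When all pooled values are identical the statistic is its null mean and
p = 1. Multiple testing uses Bonferroni only — $p_{adj} = \min(1, m\,p)$
with $m$ the number of features tested in the run, recorded in the output
header — matching the single correction the surrounding workflow expects;
no FDR alternative is offered.

Fold change is the ratio of group means, $\mathrm{FC} = \bar a / \bar b$.
Signature scores can be negative, and a ratio of signed means is not
meaningful, so FC is *flagged* `fc_undefined` (and dropped from the
volcano) whenever either mean is non-positive, rather than patched with a
hidden pseudocount; `fc_offset` lets a user shift all values explicitly if
they insist. Volcano coordinates are $x = \log_2 \mathrm{FC}$ and
$y = -\log_{10} p$ with p floored at $10^{-300}$; the y-axis uses the
adjusted p by default (the raw p is a switch away, and both columns are
always written) — whether the original interactive tools plot raw or
corrected p is not documented, so we default to the conservative choice.

## Overlay rendering

Feature values are clipped to `[vmin, vmax]` (the min/max intensity
contrast controls; outliers are clamped, not dropped), normalized to
$t \in [0,1]$, and mapped to color by either a channel-wise linear
two-color ramp or a 256-entry lookup table for Turbo, Viridis or Inferno
with linear interpolation between entries. The LUTs are the standard
published sRGB tables embedded as constants, so rendering needs no
plotting library and is bit-reproducible. The eight preset gradients are
five two-color ramps of our choosing (black-white, blue-yellow, blue-red,
white-red, green-magenta) plus the three rainbow tables; only the rainbow
three are externally fixed, the five pairs are documented substitutes.

Opacity is either constant or a value-driven gradient,
$\alpha = \alpha_0\,\mathrm{clamp}\!\left(\frac{v - a_{min}}{a_{max} - a_{min}}, 0, 1\right)$,
so spots below the lower threshold vanish entirely. Non-finite values
render fully transparent.

Dots are hard-edged filled discs — a pixel is painted when its center
(at `(col - 0.5, row - 0.5)`) lies within the dot radius — composited in
table order with source-over blending, `out = α·c + (1−α)·bg` per channel.
Hard edges (no antialiasing) make compositing exactly testable: a fully
transparent overlay is the identity on the image, an opaque radius-1 dot
reproduces its color exactly at the center pixel, and two stacked 50%
dots match the closed-form two-layer blend. Zoom (10–200%) is a
nearest-neighbor rescale of the final raster; native-resolution export
writes the unzoomed raster.

Cluster overlays map sorted cluster labels to one of three preset
16-color palettes; "shuffling" applies a seeded permutation to the
color-to-cluster assignment, so the same seed always reproduces the same
map. With 12 clusters and 3 palettes that is $3 \cdot 12! \approx 1.44
\times 10^9$ distinct renderings.

## The synthetic data generator

`make_dataset()` emulates the post-normalization tables the package
consumes, not raw sequencing: spots sit on a hexagonal-offset grid
(odd rows shifted half a spacing; rows $\mathrm{spacing}\cdot\sqrt{3}/2$
apart) like Visium's layout, so gate areas translate predictably into
spot counts; features are i.i.d. Gaussian noise, which is the honest
model for normalized expression and signature scores; planted features
add `effect_size * noise_sd` to every spot inside a region polygon; the
image is a flat background with the region outline faintly drawn; and a
hires scale factor of 0.5 guarantees full-resolution and image
coordinates genuinely differ, so scaling bugs cannot hide. The defaults —
a 15 x 14 grid (210 spots), 500 features, 5 planted, 2 SD effect, unit
noise — are the conditions under which the recovery and calibration
suites run.

What the generator does not emulate: count noise and mean-variance
coupling, spatial autocorrelation within tissue, segmentation artifacts,
or image texture. Passing tests therefore demonstrate correctness of the
geometry, statistics and rendering pipeline on clean inputs, not
robustness to upstream preprocessing failures.

Cluster labels are region-correlated by construction: inside spots draw
uniformly from clusters $1..\lceil k/2\rceil$, outside spots from the
rest, so `k = 2` separates the region perfectly — convenient ground truth
for cluster-display tests.

## Numerical choices and degenerate inputs

* Exact-p comparisons use an absolute slack of `1e-9` on the U scale to
  guard against floating-point ranks; the DP itself is integer-exact.
* On-edge tolerance for gating is `1e-9` px — effectively exact at pixel
  scales while absorbing rounding from ROI round trips.
* TSV output writes 15 significant digits; a write-read cycle reproduces
  doubles to better than `1e-9` (observed ~`1e-13`).
* Bonferroni caps at 1; `p_raw <= p_adj <= 1` holds by construction.
* Empty gate groups, gates covering every spot (empty "rest"), features
  that are constant across both groups, zero-area polygons and empty cell
  lists all have defined behavior (errors, p = 1, boundary-only
  membership, warnings) rather than undefined output.
* Problem sizes in the test suite: the permutation-oracle sweep uses 500
  random small-group datasets; calibration uses 2000 null features at 30
  spots per group (observed type-I rate near 0.04–0.05 at the 0.05
  level); recovery uses 100 generator seeds at the default conditions;
  the geometry oracle compares ~20,000 points across 100 random
  star-shaped 12-gons.

## Limitations

* Only linear scale alignment between table and image; no registration,
  rotation or nonlinear warp.
* One test (Mann-Whitney) and one correction (Bonferroni), matching the
  surrounding workflow; no spatial autocorrelation adjustment, so p-values
  on spatially smooth features are anti-conservative in the usual way.
* ROI interchange is the vertex-CSV dialect only.
* Rendering is raster-only (PNG); no vector export.
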