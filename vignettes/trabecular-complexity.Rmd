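---
title: "Isolating cancellous bone and measuring its topological complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating cancellous bone and measuring its topological complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cancellous (trabecular) bone is an intertwined lattice of rod- and
plate-like elements enclosed by the cortical shell. Its architecture
responds to mechanical load, so comparative studies read functional
signals from it — but two practical obstacles stand in the way. First,
classical analyses sample small volumes of interest whose placement is
hard to define homologously across species with different bone shapes,
and whose measurements depend on the sample size. Second, the lattice
has no analogue among regular solids, so conventional morphometrics
struggle to express its *complexity*.

`trabecula` addresses both: it isolates the **whole** cancellous
compartment from a binarized micro-CT stack with a reproducible
morphological protocol, reduces it to a topological skeleton graph, and
computes five complexity indices on that graph. Because the indices live
on the skeleton — nodes where trabeculae meet, branches tracing their
centrelines — they deliberately ignore features unrelated to lattice
complexity, such as trabecular thickness.

## The isolation protocol

The input is a binary stack (bone = 1). Binarization is provided via a
single global Otsu threshold over the pooled stack histogram
(`otsu_threshold()`); a per-slice threshold would make the compartments
inconsistent across slices, so the global variant is the only one
offered.

`split_bone()` applies five slice-wise operations built from iterated
binary dilation and erosion with an odd-sized structuring element:

1. **Mask** `c = close(b)`: `n` dilations bridge the spaces between
   trabeculae and between trabeculae and cortex, `n` erosions restore
   the outer contour. The result fills the whole bone region.
2. **Voids** `d = c − b`: enclosed space that is not bone.
3. **Interior** `e = close(d)`: closing the voids across the trabecular
   thickness yields the internal cavity (voids plus cancellous bone).
4. **Cortical** `f = c − e`: the compact shell.
5. **Cancellous** `g = c − d − f`: bone inside the cavity.

All subtractions are clamped set differences, so `d`, `f`, `g` partition
`c` exactly and `e = d ∪ g` — the suite asserts this voxel-for-voxel.

Parameters: the default structuring element is a 5 × 5 disc (pixels
within Euclidean radius 2.5) and the default iteration count is 5 for
both closings. As a rule of thumb, 4–6 iterations with a 5 × 5 element
suit typical micro-CT resolutions; more iterations (or a larger element)
are needed when the inter-trabecular spaces are wide relative to the
pixel pitch, since a closing only bridges gaps narrower than roughly
twice the accumulated dilation radius. Both knobs are exposed per step.

Numerical choices worth knowing:

* **Border padding.** Standalone `dilate()` pads out-of-image pixels
  with background and `erode()` with foreground, so the two remain
  exact complement-duals and erosion does not eat objects at the crop
  boundary.
* **Closings on an enlarged canvas.** Inside `split_bone()` each
  closing is evaluated on a canvas padded with background wide enough
  that the intermediate dilation never touches the canvas edge. This
  makes the closing the true Minkowski closing: without it, objects
  whose dilation reaches the image border acquire spurious mask bulges
  that leak voids around the cortex. Closing only adds voxels, so bone
  touching the crop boundary is never eroded away.
* **Slice-wise by default.** The protocol runs per slice along Z,
  matching how the stack is acquired and keeping the operator 2D; the
  compartments are stacked into 3D volumes afterwards.
* The optional `largest_component_filter()` cleanup for residual
  cortical fragments is off by default: small attached fragments are an
  accepted limitation of the protocol, and silently removing them would
  change the measured indices.

## Skeletonization

`thin_volume()` erodes the cancellous mask to a one-voxel-wide curve
skeleton with a topology-preserving 3D thinning: voxels are removed in
six directional sub-iterations, each candidate re-checked sequentially,
and only *simple* points — whose deletion changes neither the
26-connectivity of the foreground nor the 6-connectivity of the
background (checked via the two local component counts of the
Bertrand–Malandain characterization) — are deleted; endpoints are kept.
Connected components and tunnels of the input are therefore preserved
exactly. This stage replaces interactive skeletonization tools from
commercial packages; voxel-level agreement with any particular tool is
not promised — the graph-level statistics are the contract — and
`read_amira_spatialgraph()` lets users substitute an Amira/Avizo
skeleton for this stage entirely.

`extract_graph()` classifies skeleton voxels by 26-neighbour count
(1 = terminal, 2 = branch interior, ≥ 3 = junction), merges maximal
26-connected junction clusters into single nodes at their centroid,
traces branches as voxel chains, and emits polylines in physical
millimetres. Pure cycles (components with no junction or terminal, such
as a thinned torus) receive one anchor node carrying a self-loop so the
graph keeps the correct Euler characteristic. Junction–junction bridges
with fewer than two interior voxels — a common thinning artifact at
thick crossings — are contracted by merging their junctions
(`contract_below`, configurable).

## The five indices

All indices operate on the skeleton graph; `make_report()` aggregates
them and reports any index whose preconditions fail as missing with the
reason.

* **Node density** (`node_density()`): Gaussian product-kernel density
  of node positions on a regular grid (default 100³), scaled to nodes
  per cm³. Per-axis bandwidths follow Silverman's rule of thumb
  (`stats::bw.nrd0`), the classic normal-reference rule from the
  kernel-density literature the method descends from; it is recorded in
  the output and overridable. The grid spans the node bounding box
  expanded by three bandwidths per side so that the field integrates to
  the node count (a tighter grid would silently lose the kernel mass of
  hull nodes). Summary statistics are taken over support cells (density
  above 1% of the maximum, configurable) so empty corners do not dilute
  the mean. With `scale_length` the coordinates are first divided by a
  homologous measurement (e.g. femoral-head height) and densities are
  reported per unit cube of that dimensionless frame — both frames are
  legitimate; the report records which was used.
* **Trabecular angle** (`trabecular_angle()`): each branch contributes
  the unit vector between its end nodes. Trabecular directions are
  axial — a trabecula has no start or end — so before summation each
  vector is flipped into the hemisphere of the reference axis; without
  this convention antiparallel trabeculae cancel and the resultant is
  meaningless. The angle between the unit resultant and the axis lies in
  [0°, 90°]; percentage contributions of the three components are also
  reported. The reference axis comes from landmarks
  (`axis_from_landmarks()`) or, absent one, the principal axis of the
  node cloud (`axis = "major"`).
* **Connectivity** (`connectivity()`): mean and SD of branch count per
  node over non-terminal nodes (degree ≥ 2) only; terminals say nothing
  about inter-trabecular connection. Self-loops add 2 to their node.
* **Tortuosity** (`tortuosity()`): per branch, polyline arc length over
  the Euclidean distance between its end nodes; 1 is a straight
  trabecula, values rise without bound with convolution. Zero-chord
  branches (self-loops) would be infinite; they are excluded from the
  average and counted in `n_excluded_branches`.
* **Fractal dimension** (`fractal_dimension()`): box counting over all
  polyline vertices. Nested grids anchored at the bounding-box minimum
  halve their cell side from half the longest bounding-box side down to
  four times the median nearest-neighbour spacing of the points; the
  dimension is the OLS slope of log count against log inverse side. The
  single-box scale is excluded (its count is 1 by construction), counts
  are computed in bounding-box-normalized coordinates so the slope is
  exactly invariant under uniform scaling, and below the stopping scale
  counts would saturate and flatten the fit. The per-scale table and R²
  are returned for diagnostics.

## The phantom generator

`generate_phantom()` builds test volumes with exact ground truth: a
cortical-like shell (capped cylinder or ellipsoid) enclosing a cubic or
random lattice of rods rasterized by distance to analytically known
centrelines. The truth bundle contains the five compartment masks, the
designed skeleton graph (junctions at rod crossings, placed at the
tightest contact of the crossing so they sit exactly on the
centrelines), and blueprint statistics: the designed connectivity mean
by exhaustive degree enumeration, the analytic tortuosity of a
sinusoidal rod by numerical quadrature of arc length over chord, and
the junction count. Rod waviness snaps its wavelength to the lattice
spacing so wavy rods still pass through the junctions, and terminal
stubs shorter than one rod diameter are trimmed — sub-trabecular stubs
are absorbed by thinning and would only blur the comparison. The
default phantom is 120³ voxels at 0.03 mm spacing with a 4-pixel shell,
16-pixel lattice spacing and 2.5-pixel rod radius: inter-rod gaps of
about 11 pixels sit comfortably inside the default closing's bridging
range, as in a well-sampled micro-CT scan of an epiphysis.

`degrade()` renders the binary phantom at intensities 200 (bone) and
10 (background), adds salt-and-pepper impulse noise and then a
slice-wise Gaussian blur. The order matters and is deliberate: impulse
events are smoothed by the point-spread function, as projection-domain
outliers are in a reconstruction. (Hard specks injected *after* the
blur would be bridged by the closing into one solid mask — at a 1%
rate, specks sit only a few voxels apart in 3D — making the
isolation-robustness target unreachable by construction rather than
measuring anything about the method.)

What the phantoms do not emulate: beam hardening, ring artifacts,
partial-volume gradients at oblique interfaces, plate-like trabeculae,
or anisotropic resolution. Passing the suite therefore demonstrates
correctness of the operators and recovery under idealized acquisition,
not performance on any particular scanner's output.

## Test problem sizes and tolerances

The suite exercises phantoms up to 120³ voxels (about 1.7 M voxels) and
runs in well under a minute on one core; module tests use 64³–96³
variants of the same geometry. Recovery targets mirror what the
generator can guarantee: Dice ≥ 0.95 against truth compartments for
clean phantoms across shell thicknesses 2–6 px (≥ 0.90 after
degradation at blur σ = 1, noise 1%), connectivity within ±0.3 of the
blueprint mean, tortuosity within ±0.05 of the quadrature value,
junction count within ±10%, density-field integral within 5% of the
node count, and box-counting calibration of 1/2/3 ± 0.05/0.1/0.1 on
collinear, coplanar and volume-filling point sets.

## Known limitations

* The isolation protocol assumes the cortex closes around the cancellous
  region in-plane; bones cropped so that the shell is open to the image
  border can leak voids, as they would in any closing-based approach.
* Thinning is homotopy-exact but not medial-exact: branch endpoints
  retract by up to the local radius, so terminal branch lengths carry a
  bias of a few voxels.
* Comparative workflows often scale node density and fractal dimension
  by a homologous length while still quoting nodes/cm³; the report
  keeps the two frames explicit rather than resolving the ambiguity.
* Indices are descriptive; no between-group inference is provided.

## A worked run

```{r pipeline}
library(trabecula)

spec <- phantom_spec(seed = 1)
ph <- generate_phantom(spec)
gray <- degrade(ph$volume, noise_rate = 0.01, blur_sigma = 1, seed = 1)

bin <- otsu_threshold(gray)
comp <- split_bone(bin)                      # disc-5, 5 iterations
dice(comp$cancellous, ph$truth$compartments$cancellous)

graph <- extract_graph(thin_volume(comp$cancellous))
report <- make_report(graph,
                      axis = reference_axis(c(0, 0, 0), c(1, 0, 0)),
                      specimen = "phantom-1")
report
as.data.frame(report)
```

The same chain is scriptable per stage through `cmd_binarize()`,
`cmd_split()`, `cmd_skeletonize()`, `cmd_indices()` and `cmd_run_all()`,
or from a shell via the dispatcher installed at
`system.file("cli", "trabecula", package = "trabecula")`; every stage
writes a JSON sidecar with its resolved configuration, and identical
configurations reproduce identical outputs byte for byte.
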