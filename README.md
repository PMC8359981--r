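# trabecula

Virtual isolation and topological analysis of cancellous (trabecular)
bone from micro-CT image stacks.

Comparative studies of trabecular architecture face two recurring
obstacles: volumes of interest are hard to place homologously across
bones of different shape (and their measurements depend on the sample
size), and the lattice itself has no analogue among regular solids, so
its *complexity* escapes conventional morphometrics. `trabecula`
implements a workflow that sidesteps both: it isolates the whole
cancellous compartment from a binarized micro-CT stack with a
reproducible five-step morphological protocol, reduces it to a
topological skeleton graph, and quantifies the graph with five
complexity indices. It is aimed at biological anthropologists,
zoologists and bone biomechanics researchers working with micro-CT data.

## The method in brief

**Isolation** (`split_bone`). On each slice of the binary stack `b`,
with an odd structuring element (default: 5 × 5 disc) iterated *n*
times (default 5):

1. mask `c = close(b)` — dilations bridge inter-trabecular spaces,
   erosions restore the outer contour;
2. voids `d = c − b`;
3. interior `e = close(d)` — the cavity hosting voids and cancellous
   bone;
4. cortical `f = c − e`;
5. cancellous `g = c − d − f`.

By construction `d`, `f`, `g` partition `c` exactly.

**Skeletonization** (`thin_volume` + `extract_graph`).
Topology-preserving 3D thinning (only simple points are deleted, in six
directional sub-iterations with sequential re-checking; endpoints kept)
reduces the cancellous mask to a 1-voxel-wide skeleton, which is parsed
into nodes (junctions, endpoints) and branches (centreline polylines in
mm). Amira/Avizo SpatialGraph ASCII skeletons can be imported instead
(`read_amira_spatialgraph`).

**Indices** (`make_report`), on the skeleton graph:

| index | definition |
|---|---|
| node density | Gaussian kernel density of node positions on a regular 3D grid (default 100³), in nodes/cm³ |
| trabecular angle | angle in [0°, 90°] between a homologous reference axis and the unit resultant of all branch direction vectors (axial, hemisphere-oriented before summing) |
| connectivity | mean branches per non-terminal node (degree ≥ 2) |
| tortuosity | per branch, arc length over end-node distance (1 = straight) |
| fractal dimension | box-counting slope of log occupied cells vs log inverse cell side over nested grids |

A phantom generator (`generate_phantom`) builds shell-plus-rod-lattice
volumes with exact ground truth (compartment masks, centreline skeleton,
designed connectivity/tortuosity), so the whole pipeline is testable
without any scan data; `degrade` turns a phantom into a noisy, blurred
pseudo-acquisition.

## Worked example

```r
library(trabecula)

spec  <- phantom_spec(seed = 1)                      # 120^3 shell + lattice
ph    <- generate_phantom(spec)
gray  <- degrade(ph$volume, noise_rate = 0.01, blur_sigma = 1, seed = 1)

bin   <- otsu_threshold(gray)
attr(bin, "threshold")
#> [1] 92

comp  <- split_bone(bin)                             # disc-5 SE, 5 iterations
dice(comp$cancellous, ph$truth$compartments$cancellous)
#> [1] 0.9578516

graph <- extract_graph(thin_volume(comp$cancellous))
graph
#> skeleton_graph (computed): 255 nodes (122 terminal), 405 branches

make_report(graph, axis = reference_axis(c(0, 0, 0), c(1, 0, 0)),
            specimen = "phantom-1")
#> Complexity indices for phantom-1
#>   node density (nodes/cm^3): mean 7674.82, max 44876.03, sd 5944.34
#>   trabecular angle: 36.72 deg
#>   tortuosity: 1.028 +/- 0.064
#>   connectivity: 5.17 +/- 1.00 branches/node
#>   fractal dimension: 2.213
#>   nodes 255 (terminal 122), branches 405 (excluded 0)
```

Reading the numbers: the global Otsu threshold (92) falls between the
rendered background (10) and bone (200) intensities; after isolation the
cancellous mask overlaps the generator's ground truth with Dice 0.96
despite 1% impulse noise and a 1-voxel blur. The skeleton's 255 nodes
connect 405 branches; non-terminal nodes carry on average 5.2 branches
(the designed cubic lattice crosses three rods per junction, degree 6,
reduced at the cavity boundary), branches are nearly straight
(tortuosity 1.03, the rods are straight by design), and the box-counting
dimension of 2.2 sits between a surface and a space-filling structure,
as expected for a rod lattice.

Each stage is also available as a pipeline command — `cmd_binarize`,
`cmd_split`, `cmd_skeletonize`, `cmd_indices`, `cmd_phantom`,
`cmd_run_all` — writing NIfTI/Amira/CSV/PNG outputs plus JSON sidecars
with the resolved configuration, and as a shell dispatcher at
`system.file("cli", "trabecula", package = "trabecula")`:

```sh
trabecula run-all --out-dir run1 --seed 1
trabecula indices --skeleton skel.am --out-dir idx \
    --landmarks axis.landmarkAscii --axis-indices 1,2 --scale-indices 3,4
```

Supported formats: multi-page TIFF and NIfTI-1 stacks (with voxel
spacing), Amira LandmarkSet and SpatialGraph ASCII, CSV reports, PNG
blue-to-red density maps.

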