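graph_points <- function(graph) {
  do.call(rbind, lapply(graph$branches, `[[`, "polyline"))
}

#' Kernel density of skeleton nodes on a regular 3D grid
#'
#' Estimates the spatial density of skeleton nodes with a Gaussian product
#' kernel evaluated on a regular grid, scaled to node counts per unit
#' volume. In the native millimetre frame densities are reported as
#' nodes/cm^3; if `scale_length` is given, coordinates are first divided
#' by it and densities are nodes per unit cube of the scaled
#' (dimensionless) frame. Per-axis bandwidths default to Silverman's
#' rule of thumb ([stats::bw.nrd0()]). The grid spans the node bounding
#' box expanded by three bandwidths per side so that the field integrates
#' to the node count.
#'
#' Summary statistics (mean, max, SD) are taken over the field's support
#' cells — cells whose density exceeds `support_frac` of the field
#' maximum — so the empty corners of the bounding box do not dilute the
#' mean.
#'
#' @param graph A [skeleton_graph()] with >= 2 nodes spanning a
#'   non-degenerate bounding box.
#' @param grid_dims Grid resolution per axis (default 100 x 100 x 100).
#' @param scale_length Optional homologous length (mm) for pre-scaling.
#' @param bandwidth Optional per-axis bandwidth override.
#' @param support_frac Support threshold for summary statistics.
#' @return An object of class `density_field`: fields `values` (3D array),
#'   `cell_centers`, `cell_size`, `bandwidth`, `n_nodes`, `unit`, and
#'   `summary` (mean/max/sd over support cells plus the integral).
#' @export
node_density <- function(graph, grid_dims = c(100, 100, 100),
                         scale_length = NULL, bandwidth = NULL,
                         support_frac = 0.01) {
  stopifnot(inherits(graph, "skeleton_graph"))
  x <- graph$nodes
  if (nrow(x) < 2) stop("node density needs at least 2 nodes")
  unit <- "nodes/cm^3"
  to_cm3 <- 1000            # nodes/mm^3 -> nodes/cm^3
  if (!is.null(scale_length)) {
    if (scale_length <= 0) stop("scale_length must be positive")
    x <- x / scale_length
    unit <- "nodes/unit^3 (scaled frame)"
    to_cm3 <- 1
  }
  grid_dims <- rep(as.integer(grid_dims), length.out = 3)
  if (any(grid_dims < 2)) stop("grid_dims must be >= 2 per axis")
  n <- nrow(x)
  ax_names <- c("x", "y", "z")
  extent0 <- apply(x, 2, function(a) diff(range(a)))
  if (any(extent0 == 0))
    stop("degenerate node distribution along axis ",
         paste(ax_names[extent0 == 0], collapse = ", "),
         ": nodes are coplanar/collinear")
  if (is.null(bandwidth)) {
    bandwidth <- vapply(1:3, function(a) stats::bw.nrd0(x[, a]), numeric(1))
  } else {
    bandwidth <- rep(as.numeric(bandwidth), length.out = 3)
  }
  if (any(!is.finite(bandwidth) | bandwidth <= 0))
    stop("invalid bandwidth")
  lo <- apply(x, 2, min) - 3 * bandwidth
  hi <- apply(x, 2, max) + 3 * bandwidth
  centers <- lapply(1:3, function(a)
    seq(lo[a] + (hi[a] - lo[a]) / (2 * grid_dims[a]),
        hi[a] - (hi[a] - lo[a]) / (2 * grid_dims[a]),
        length.out = grid_dims[a]))
  cell <- (hi - lo) / grid_dims
  # product kernel by axis-wise Gaussian matrices: K_a[g, i] = phi((c_g - x_i)/h)
  KX <- outer(centers[[1]], x[, 1], function(g, p)
    stats::dnorm(g, p, bandwidth[1]))
  KY <- outer(centers[[2]], x[, 2], function(g, p)
    stats::dnorm(g, p, bandwidth[2]))
  KZ <- outer(centers[[3]], x[, 3], function(g, p)
    stats::dnorm(g, p, bandwidth[3]))
  vals <- array(0, grid_dims)
  for (k in seq_len(grid_dims[3])) {
    W <- KY * matrix(KZ[k, ], nrow(KY), ncol(KY), byrow = TRUE)
    vals[, , k] <- KX %*% t(W)    # sum over nodes of product kernels
  }
  # vals currently sums kernel products over nodes = n * fhat -> nodes per
  # unit^3 of the working frame
  vals <- vals * to_cm3
  integral <- sum(vals) * prod(cell) / to_cm3
  support <- vals > support_frac * max(vals)
  structure(list(values = vals, cell_centers = centers, cell_size = cell,
                 bandwidth = bandwidth, n_nodes = n, unit = unit,
                 support_frac = support_frac,
                 summary = list(mean = mean(vals[support]),
                                max = max(vals),
                                sd = stats::sd(vals[support]),
                                integral_nodes = integral)),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf(
    "density_field: %s grid, %d nodes, mean %.3g / max %.3g %s (integral %.1f)\n",
    paste(dim(x$values), collapse = "x"), x$n_nodes,
    x$summary$mean, x$summary$max, x$unit, x$summary$integral_nodes))
  invisible(x)
}

branch_direction <- function(br, nodes) {
  v <- nodes[br$node_b, ] - nodes[br$node_a, ]
  len <- sqrt(sum(v^2))
  if (len == 0) return(NULL)
  v / len
}

principal_axis <- function(points) {
  ctr <- colMeans(points)
  ev <- eigen(stats::cov(points), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  reference_axis(ctr, ctr + dir)
}

#' Trabecular angle against a reference axis
#'
#' Each branch contributes the unit vector between its end nodes.
#' Trabecular directions are axial (a trabecula has no start or end), so
#' every unit vector is flipped into the hemisphere of the reference axis
#' before the vector sum; the trabecular angle is the 3D angle between
#' the resultant of the sum and the axis, in `[0, 90]` degrees. Also
#' reported are the percentage contributions of the three coordinate
#' components of the unit resultant.
#'
#' @param graph A [skeleton_graph()] with >= 1 branch joining distinct
#'   nodes.
#' @param axis A [reference_axis()], or `"major"` to use the principal
#'   axis of the node coordinates.
#' @return List with `angle_deg`, `resultant` (unit vector), `axis_used`,
#'   `percent_contrib` (length 3) and `n_branches_used`.
#' @export
trabecular_angle <- function(graph, axis = "major") {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (identical(axis, "major")) {
    if (nrow(graph$nodes) < 2) stop("need >= 2 nodes for a major axis")
    axis <- principal_axis(graph$nodes)
    axis_source <- "major"
  } else {
    stopifnot(inherits(axis, "reference_axis"))
    axis_source <- "supplied"
  }
  a <- axis_direction(axis)
  dirs <- lapply(graph$branches, branch_direction, nodes = graph$nodes)
  dirs <- dirs[!vapply(dirs, is.null, logical(1))]
  if (length(dirs) == 0) stop("no branch with distinct endpoint nodes")
  dirs <- do.call(rbind, dirs)
  flip <- as.vector(dirs %*% a) < 0
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  res <- colSums(dirs)
  nr <- sqrt(sum(res^2))
  if (nr < 1e-12)
    stop("indeterminate direction: trabecular directions cancel out")
  unit_res <- res / nr
  cosang <- abs(sum(unit_res * a))
  angle <- acos(pmin(1, cosang)) * 180 / pi
  list(angle_deg = angle,
       resultant = unit_res,
       axis_used = axis, axis_source = axis_source,
       percent_contrib = 100 * abs(unit_res) / sum(abs(unit_res)),
       n_branches_used = nrow(dirs))
}

#' Trabecular connectivity
#'
#' Mean and SD of the number of branches connected to each non-terminal
#' node (degree >= 2). Terminal nodes are excluded from the average;
#' self-loop branches contribute 2 to their node's degree.
#'
#' @param graph A [skeleton_graph()] with at least one non-terminal node.
#' @return List with `mean`, `sd`, `degrees` (per included node),
#'   `n_nodes_used`, `n_terminal`, `n_self_loops`.
#' @export
connectivity <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  deg <- node_degrees(graph)
  keep <- deg >= 2
  if (!any(keep))
    stop("no non-terminal nodes: connectivity undefined")
  d <- deg[keep]
  list(mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else 0,
       degrees = d,
       n_nodes_used = length(d),
       n_terminal = sum(deg == 1),
       n_self_loops = sum(vapply(graph$branches, function(b)
         isTRUE(b$self_loop) || b$node_a == b$node_b, logical(1))))
}

#' Trabecular tortuosity
#'
#' Per branch, the arc length of its polyline divided by the straight-line
#' distance between its end nodes; 1 is a straight trabecula and values
#' grow without bound as branches convolute. Branches with coincident
#' endpoints (zero chord, e.g. self-loops) would be infinite and are
#' excluded from the average but counted.
#'
#' @param graph A [skeleton_graph()] with >= 1 branch with distinct
#'   endpoints.
#' @return List with `mean`, `sd`, `values` (per included branch),
#'   `n_excluded`.
#' @export
tortuosity <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  vals <- numeric(0)
  excluded <- 0L
  for (br in graph$branches) {
    chord <- sqrt(sum((graph$nodes[br$node_b, ] -
                         graph$nodes[br$node_a, ])^2))
    if (chord == 0) { excluded <- excluded + 1L; next }
    vals <- c(vals, branch_arc_length(br$polyline) / chord)
  }
  if (length(vals) == 0) stop("all branches have zero chord length")
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       values = vals, n_excluded = excluded)
}

median_nn_spacing <- function(pts, max_query = 500L, seed_pool = 20000L) {
  n <- nrow(pts)
  if (n < 2) return(NA_real_)
  qi <- if (n > max_query)
    round(seq(1, n, length.out = max_query)) else seq_len(n)
  pool <- if (n > seed_pool) round(seq(1, n, length.out = seed_pool)) else
    seq_len(n)
  ref <- pts[pool, , drop = FALSE]
  nn <- vapply(qi, function(i) {
    d2 <- (ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2 +
      (ref[, 3] - pts[i, 3])^2
    d2[d2 == 0] <- Inf
    sqrt(min(d2))
  }, numeric(1))
  stats::median(nn[is.finite(nn)])
}

#' Box-counting fractal dimension of the skeleton
#'
#' All polyline vertices of all branches form the point set. Nested
#' regular grids with cell sides halving from the longest bounding-box
#' side down to four times the median nearest-neighbour spacing of the
#' points (below which counts saturate) are overlaid, anchored at the
#' bounding-box minimum corner; the fractal dimension is the slope of the
#' ordinary least-squares line of log occupied-cell count against log
#' inverse cell side.
#'
#' @param graph A [skeleton_graph()] (or an n x 3 point matrix).
#' @param n_scales Maximum number of scales (>= 3).
#' @param scale_length Optional homologous length for pre-scaling
#'   (does not change the slope when scales adapt to the bounding box).
#' @return List with `fd`, `r_squared`, and a `scales` data frame
#'   (cell side, occupied count) for diagnostics.
#' @export
fractal_dimension <- function(graph, n_scales = 10, scale_length = NULL) {
  pts <- if (inherits(graph, "skeleton_graph")) graph_points(graph) else
    as.matrix(graph)
  if (is.null(pts) || nrow(pts) < 2) stop("degenerate point set")
  if (n_scales < 3) stop("need at least 3 scales")
  if (!is.null(scale_length)) {
    if (scale_length <= 0) stop("scale_length must be positive")
    pts <- pts / scale_length
  }
  lo <- apply(pts, 2, min)
  extent <- apply(pts, 2, max) - lo
  s0 <- max(extent)
  if (s0 == 0) stop("degenerate point set: zero extent")
  stop_scale <- 4 * median_nn_spacing(pts)
  if (!is.finite(stop_scale) || stop_scale <= 0) stop_scale <- s0 / 2^n_scales
  # the single-box scale s0 is excluded: its count is 1 by construction
  # and carries no information about the structure
  ks <- 1:n_scales
  ks <- ks[s0 / 2^ks >= stop_scale * (1 - 1e-9)]
  if (length(ks) < 3) ks <- 1:3   # guarantee a minimal fit range
  sides <- s0 / 2^ks
  # counting happens in bounding-box-normalized coordinates, where the
  # cell index is floor(x * 2^k): exact in binary arithmetic, so the
  # counts (and hence the slope) are invariant under uniform scaling
  ptn <- sweep(sweep(pts, 2, lo, `-`), 2, s0, `/`)
  extn <- extent / s0
  eps <- 1e-9
  counts <- vapply(ks, function(k) {
    r <- 2^k
    nb <- pmax(1, ceiling(extn * r - eps))
    ix <- pmin(floor(ptn[, 1] * r + eps), nb[1] - 1)
    iy <- pmin(floor(ptn[, 2] * r + eps), nb[2] - 1)
    iz <- pmin(floor(ptn[, 3] * r + eps), nb[3] - 1)
    length(unique(ix + 1e6 * iy + 1e12 * iz))
  }, numeric(1))
  lx <- log(1 / sides)
  ly <- log(counts)
  fit <- stats::lm(ly ~ lx)
  list(fd = unname(stats::coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       scales = data.frame(cell_side = sides, n_occupied = counts))
}

#' Full complexity-index report for one specimen
#'
#' Computes the five indices with the standard conventions: node density
#' and fractal dimension on the skeleton scaled by `scale_length` (when
#' given), trabecular angle against `axis`. Indices whose preconditions
#' fail are reported as missing with the reason rather than as numbers.
#'
#' @param graph A [skeleton_graph()].
#' @param axis A [reference_axis()] or `"major"`.
#' @param scale_length Optional homologous scaling length in mm.
#' @param specimen Identifier used in the CSV row.
#' @param grid_dims Density grid resolution.
#' @param n_scales Fractal-dimension scale count.
#' @return An object of class `index_report`; see [as.data.frame.index_report()].
#' @export
make_report <- function(graph, axis = "major", scale_length = NULL,
                        specimen = "specimen", grid_dims = c(100, 100, 100),
                        n_scales = 10) {
  stopifnot(inherits(graph, "skeleton_graph"))
  miss <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      miss[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  dens <- grab("node_density",
               node_density(graph, grid_dims, scale_length = scale_length))
  ang <- grab("trabecular_angle", trabecular_angle(graph, axis))
  conn <- grab("connectivity", connectivity(graph))
  tort <- grab("tortuosity", tortuosity(graph))
  fd <- grab("fractal_dimension",
             fractal_dimension(graph, n_scales, scale_length = scale_length))
  deg <- node_degrees(graph)
  structure(list(
    specimen = specimen,
    mean_node_density = if (!is.null(dens)) dens$summary$mean else NA_real_,
    max_node_density = if (!is.null(dens)) dens$summary$max else NA_real_,
    sd_node_density = if (!is.null(dens)) dens$summary$sd else NA_real_,
    density_unit = if (!is.null(dens)) dens$unit else NA_character_,
    trabecular_angle = if (!is.null(ang)) ang$angle_deg else NA_real_,
    mean_tortuosity = if (!is.null(tort)) tort$mean else NA_real_,
    sd_tortuosity = if (!is.null(tort)) tort$sd else NA_real_,
    mean_connectivity = if (!is.null(conn)) conn$mean else NA_real_,
    sd_connectivity = if (!is.null(conn)) conn$sd else NA_real_,
    fractal_dimension = if (!is.null(fd)) fd$fd else NA_real_,
    n_nodes = nrow(graph$nodes),
    n_branches = length(graph$branches),
    n_terminal_nodes = sum(deg == 1),
    n_excluded_branches = if (!is.null(tort)) tort$n_excluded else NA_integer_,
    scale_length = if (is.null(scale_length)) NA_real_ else scale_length,
    missing = miss,
    density_field = dens,
    angle_detail = ang),
    class = "index_report")
}

#' Convert an index report to a one-row data frame
#'
#' Column order mirrors the standard comparative-table layout (density
#' mean/max/SD, angle, tortuosity mean/SD, connectivity mean/SD, fractal
#' dimension) followed by counts.
#'
#' @param x An `index_report`.
#' @param ... Unused.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.index_report <- function(x, ...) {
  data.frame(specimen = x$specimen,
             mean_node_density = x$mean_node_density,
             max_node_density = x$max_node_density,
             sd_node_density = x$sd_node_density,
             trabecular_angle = x$trabecular_angle,
             mean_tortuosity = x$mean_tortuosity,
             sd_tortuosity = x$sd_tortuosity,
             mean_connectivity = x$mean_connectivity,
             sd_connectivity = x$sd_connectivity,
             fractal_dimension = x$fractal_dimension,
             n_nodes = x$n_nodes,
             n_branches = x$n_branches,
             n_terminal_nodes = x$n_terminal_nodes,
             n_excluded_branches = x$n_excluded_branches,
             stringsAsFactors = FALSE)
}

#' @export
print.index_report <- function(x, ...) {
  cat("Complexity indices for", x$specimen, "\n")
  cat(sprintf("  node density (%s): mean %.2f, max %.2f, sd %.2f\n",
              x$density_unit, x$mean_node_density, x$max_node_density,
              x$sd_node_density))
  cat(sprintf("  trabecular angle: %.2f deg\n", x$trabecular_angle))
  cat(sprintf("  tortuosity: %.3f +/- %.3f\n", x$mean_tortuosity,
              x$sd_tortuosity))
  cat(sprintf("  connectivity: %.2f +/- %.2f branches/node\n",
              x$mean_connectivity, x$sd_connectivity))
  cat(sprintf("  fractal dimension: %.3f\n", x$fractal_dimension))
  cat(sprintf("  nodes %d (terminal %d), branches %d (excluded %s)\n",
              x$n_nodes, x$n_terminal_nodes, x$n_branches,
              format(x$n_excluded_branches)))
  if (length(x$missing) > 0)
    for (nm in names(x$missing))
      cat(sprintf("  [missing] %s: %s\n", nm, x$missing[[nm]]))
  invisible(x)
}

#' Write index reports to CSV
#'
#' @param reports An `index_report` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "index_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a density-field slice as a blue-to-red colour map
#'
#' Extracts one plane of the density grid and writes a PNG with a
#' blue-to-red palette and a colour bar. `plane` selects the grid axis
#' held fixed: `"axial"` fixes z, `"coronal"` fixes y, `"parasagittal"`
#' fixes x. `position` is the fractional location of the slice along the
#' fixed axis.
#'
#' @param field A [node_density()] result.
#' @param plane `"coronal"`, `"parasagittal"` or `"axial"`.
#' @param position Fraction in `[0, 1]`.
#' @param path Output PNG path.
#' @param axis_labels Optional two labels for the in-plane axes.
#' @return `path`, invisibly.
#' @export
density_colormap_slices <- function(field,
                                    plane = c("coronal", "parasagittal",
                                              "axial"),
                                    position = 0.5, path,
                                    axis_labels = NULL) {
  stopifnot(inherits(field, "density_field"))
  plane <- match.arg(plane)
  if (length(position) != 1 || is.na(position) || position < 0 ||
      position > 1)
    stop("position must be in [0, 1]")
  d <- dim(field$values)
  fixed_axis <- switch(plane, parasagittal = 1, coronal = 2, axial = 3)
  k <- max(1L, min(d[fixed_axis], round(position * (d[fixed_axis] - 1)) + 1L))
  sl <- switch(plane,
               parasagittal = field$values[k, , ],
               coronal = field$values[, k, ],
               axial = field$values[, , k])
  pal <- grDevices::colorRampPalette(
    c("blue", "cyan", "green", "yellow", "red"))(256)
  rng <- range(field$values)
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(4, 4, 3, 1))
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1e-12
  graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl, col = pal,
                  zlim = rng, asp = 1,
                  xlab = if (!is.null(axis_labels)) axis_labels[1] else "",
                  ylab = if (!is.null(axis_labels)) axis_labels[2] else "",
                  main = sprintf("node density (%s, %s)", plane,
                                 field$unit))
  graphics::par(mar = c(4, 1, 3, 3))
  bar <- matrix(seq(rng[1], rng[2], length.out = 256), 1, 256)
  graphics::image(1, seq(rng[1], rng[2], length.out = 256), bar, col = pal,
                  xlab = "", ylab = "", xaxt = "n")
  invisible(path)
}

#' Export a density field as NIfTI
#'
#' @param field A [node_density()] result.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_density_nifti <- function(field, path) {
  stopifnot(inherits(field, "density_field"))
  img <- RNifti::asNifti(field$values)
  RNifti::pixdim(img) <- field$cell_size
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write NIfTI: ", path)
  invisible(path)
}
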