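#' Specify a synthetic bone phantom
#'
#' A phantom is a cortical-like shell (capped cylinder or ellipsoid)
#' enclosing a cancellous-like lattice of rods, rasterized with exact
#' ground truth: the true compartment masks and the true centreline
#' skeleton graph. All sizes are in voxels; `spacing` assigns a physical
#' voxel size.
#'
#' @param outer_shape `"cylinder"` (axis along z, capped) or `"ellipsoid"`.
#' @param semi_axes Semi-axes of the outer shape in voxels (length 3; for
#'   the cylinder: radius, radius, half-height).
#' @param shell_thickness Cortical shell thickness in voxels (>= 1).
#' @param lattice_type `"cubic_rods"`, `"random_rods"` or `"none"`.
#' @param lattice_spacing Rod-to-rod spacing in voxels; must exceed twice
#'   the rod radius.
#' @param rod_radius Rod radius in voxels.
#' @param rod_waviness Length-2 vector `c(amplitude, wavelength)` in
#'   voxels of the sinusoidal centreline perturbation; amplitude 0 gives
#'   straight rods. The wavelength is snapped to the lattice spacing so
#'   wavy rods still pass through junctions.
#' @param n_random_rods Rod count for `"random_rods"`.
#' @param noise Salt-and-pepper rate passed to [degrade()] by pipelines.
#' @param dims Volume dimensions in voxels.
#' @param spacing Voxel size in mm.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_shape = c("cylinder", "ellipsoid"),
                         semi_axes = c(44, 44, 52),
                         shell_thickness = 4,
                         lattice_type = c("cubic_rods", "random_rods",
                                          "none"),
                         lattice_spacing = 16,
                         rod_radius = 2.5,
                         rod_waviness = c(0, 16),
                         n_random_rods = 60,
                         noise = 0,
                         dims = c(120, 120, 120),
                         spacing = 0.03,
                         seed = 1L) {
  outer_shape <- match.arg(outer_shape)
  lattice_type <- match.arg(lattice_type)
  if (shell_thickness < 1) stop("shell_thickness must be >= 1")
  if (lattice_spacing <= 2 * rod_radius)
    stop("lattice_spacing must exceed 2 * rod_radius")
  if (noise < 0 || noise >= 1) stop("noise rate must be in [0, 1)")
  if (rod_waviness[1] > 0)
    rod_waviness[2] <- lattice_spacing   # keep junctions on the centreline
  structure(list(outer_shape = outer_shape, semi_axes = semi_axes,
                 shell_thickness = shell_thickness,
                 lattice_type = lattice_type,
                 lattice_spacing = lattice_spacing,
                 rod_radius = rod_radius, rod_waviness = rod_waviness,
                 n_random_rods = n_random_rods, noise = noise,
                 dims = as.integer(dims), spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# signed "inside outer shape" and "inside cavity" tests on voxel-centre
# coordinate grids (0-based indices)
shape_masks <- function(spec) {
  d <- spec$dims
  ctr <- (d - 1) / 2
  x <- (0:(d[1] - 1)) - ctr[1]
  y <- (0:(d[2] - 1)) - ctr[2]
  z <- (0:(d[3] - 1)) - ctr[3]
  a <- spec$semi_axes; t <- spec$shell_thickness
  if (spec$outer_shape == "ellipsoid") {
    q_out <- outer(outer((x / a[1])^2, (y / a[2])^2, `+`), (z / a[3])^2, `+`)
    ai <- pmax(a - t, 1)
    q_in <- outer(outer((x / ai[1])^2, (y / ai[2])^2, `+`), (z / ai[3])^2, `+`)
    list(outer = q_out <= 1, cavity = q_in <= 1)
  } else {
    r2 <- outer(x^2, y^2, `+`)
    in_rad <- array(rep(r2 <= a[1]^2, d[3]), d)
    in_z <- array(rep(abs(z) <= a[3], each = d[1] * d[2]), d)
    ri <- max(a[1] - t, 1)
    in_rad_i <- array(rep(r2 <= ri^2, d[3]), d)
    in_z_i <- array(rep(abs(z) <= a[3] - t, each = d[1] * d[2]), d)
    list(outer = in_rad & in_z, cavity = in_rad_i & in_z_i)
  }
}

# sample a rod centreline: straight segment from p to q plus sinusoidal
# offset along `normal` with given amplitude/wavelength (voxel units),
# phase chosen so the offset vanishes at p
rod_polyline <- function(p, q, amplitude, wavelength, normal,
                         step = 0.5) {
  v <- q - p
  len <- sqrt(sum(v^2))
  if (len == 0) return(NULL)
  n_pts <- max(2L, ceiling(len / step) + 1L)
  tt <- seq(0, len, length.out = n_pts)
  base <- outer(tt / len, v) + matrix(p, n_pts, 3, byrow = TRUE)
  if (amplitude > 0) {
    off <- amplitude * sin(2 * pi * tt / wavelength)
    base <- base + outer(off, normal)
  }
  base
}

# analytic tortuosity of one wavy rod span (one lattice cell long) by
# quadrature of the arc length over the chord
wavy_tortuosity <- function(amplitude, wavelength, chord) {
  if (amplitude == 0) return(1)
  f <- function(t) sqrt(1 + (amplitude * 2 * pi / wavelength *
                               cos(2 * pi * t / wavelength))^2)
  stats::integrate(f, 0, chord, rel.tol = 1e-10)$value / chord
}

# clip a segment [p, q] (voxel coords) to the cavity predicate by dense
# sampling; returns list of runs (sub-polylines) inside the cavity
clip_polyline <- function(poly, inside) {
  keep <- inside(poly)
  if (!any(keep)) return(list())
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    seg <- poly[starts[i]:ends[i], , drop = FALSE]
    if (nrow(seg) >= 2) out[[length(out) + 1L]] <- seg
  }
  out
}

#' Generate a phantom volume with ground truth
#'
#' Rasterizes the shell and rod lattice of a [phantom_spec()] and returns
#' the binary volume together with exact ground truth: the five
#' compartment masks (mask, voids, interior, cortical, cancellous) and
#' the designed skeleton graph (rod centrelines with junctions at rod
#' crossings), plus blueprint statistics (designed connectivity mean over
#' non-terminal nodes, analytic rod tortuosity from the waviness, and
#' junction count).
#'
#' Rods are rasterized by distance-to-centreline, so the truth polylines
#' are exact centrelines. Terminal rod stubs shorter than one rod
#' diameter beyond their last junction are trimmed. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (binary [image_stack()]), `truth` (list:
#'   `compartments`, `graph`, `blueprint`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  set.seed(spec$seed)
  sm <- shape_masks(spec)
  shell <- sm$outer & !sm$cavity
  cavity_idx <- which(sm$cavity)
  if (spec$lattice_type != "none" && length(cavity_idx) == 0)
    stop("lattice does not fit inside shell interior: cavity is empty")

  ctr <- (d - 1) / 2
  inside_fun <- function(poly) {
    # poly in 0-based voxel coords; look up the cavity mask with rounding
    ii <- round(poly) + 1
    ok <- ii[, 1] >= 1 & ii[, 2] >= 1 & ii[, 3] >= 1 &
      ii[, 1] <= d[1] & ii[, 2] <= d[2] & ii[, 3] <= d[3]
    res <- logical(nrow(poly))
    lin <- ii[ok, 1] + d[1] * (ii[ok, 2] - 1) + d[1] * d[2] * (ii[ok, 3] - 1)
    res[ok] <- sm$cavity[lin]
    res
  }

  centrelines <- list()
  amp <- spec$rod_waviness[1]; wl <- spec$rod_waviness[2]
  if (spec$lattice_type == "cubic_rods") {
    s <- spec$lattice_spacing
    gridpos <- function(extent) {
      k <- floor((extent - 1) / (2 * s))
      ctr0 <- (extent - 1) / 2
      ctr0 + s * (-k:k)
    }
    gx <- gridpos(d[1]); gy <- gridpos(d[2]); gz <- gridpos(d[3])
    # x-direction rods at (y, z) grid crossings, sinusoid along +z normal
    for (yy in gy) for (zz in gz)
      centrelines[[length(centrelines) + 1L]] <-
      list(p = c(0, yy, zz), q = c(d[1] - 1, yy, zz), normal = c(0, 0, 1),
           phase_origin = 0)
    for (xx in gx) for (zz in gz)
      centrelines[[length(centrelines) + 1L]] <-
      list(p = c(xx, 0, zz), q = c(xx, d[2] - 1, zz), normal = c(0, 0, 1),
           phase_origin = 0)
    for (xx in gx) for (yy in gy)
      centrelines[[length(centrelines) + 1L]] <-
      list(p = c(xx, yy, 0), q = c(xx, yy, d[3] - 1), normal = c(1, 0, 0),
           phase_origin = 0)
    # snap phases: offsets vanish at grid planes because the wavelength
    # equals the lattice spacing and rods start at integer multiples of it
    centrelines <- lapply(centrelines, function(cl) {
      v <- cl$q - cl$p
      ax <- which(v != 0)
      grid0 <- switch(ax, gx[1], gy[1], gz[1])
      cl$tshift <- cl$p[ax] - grid0
      cl
    })
  } else if (spec$lattice_type == "random_rods") {
    cav <- arrayInd(cavity_idx, d) - 1
    for (i in seq_len(spec$n_random_rods)) {
      p <- cav[sample.int(nrow(cav), 1), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      half <- stats::runif(1, spec$lattice_spacing,
                           3 * spec$lattice_spacing)
      nrm <- stats::rnorm(3); nrm <- nrm - sum(nrm * dir) * dir
      nl <- sqrt(sum(nrm^2)); if (nl == 0) nrm <- c(0, 0, 1) else nrm <- nrm / nl
      centrelines[[length(centrelines) + 1L]] <-
        list(p = p - half * dir, q = p + half * dir, normal = nrm,
             tshift = 0)
    }
  }

  # sample, apply waviness with the rod's phase shift, clip to cavity
  rods <- list()
  for (cl in centrelines) {
    poly <- rod_polyline(cl$p, cl$q, 0, wl, cl$normal)
    if (is.null(poly)) next
    if (amp > 0) {
      v <- cl$q - cl$p; len <- sqrt(sum(v^2))
      tt <- seq(0, len, length.out = nrow(poly)) + (cl$tshift %||% 0)
      poly <- poly + outer(amp * sin(2 * pi * tt / wl), cl$normal)
    }
    rods <- c(rods, clip_polyline(poly, inside_fun))
  }

  truth <- blueprint_graph(rods, spec)
  rods <- truth$rods      # after stub trimming

  # rasterize rods: mark all voxels within rod_radius of any centreline
  # sample (samples are 0.5 voxels apart, so coverage is tight)
  lattice <- array(FALSE, d)
  if (length(rods) > 0) {
    rr <- spec$rod_radius
    rball <- as.matrix(expand.grid(dx = -ceiling(rr):ceiling(rr),
                                   dy = -ceiling(rr):ceiling(rr),
                                   dz = -ceiling(rr):ceiling(rr)))
    rball <- rball[rowSums(rball^2) <= (rr + 0.25)^2, , drop = FALSE]
    pts <- do.call(rbind, rods)
    pi_ <- round(pts)
    pi_ <- pi_[!duplicated(pi_), , drop = FALSE]
    for (k in seq_len(nrow(rball))) {
      q <- sweep(pi_, 2, rball[k, ], `+`)
      ok <- q[, 1] >= 0 & q[, 2] >= 0 & q[, 3] >= 0 &
        q[, 1] <= d[1] - 1 & q[, 2] <= d[2] - 1 & q[, 3] <= d[3] - 1
      lin <- q[ok, 1] + 1 + d[1] * q[ok, 2] + d[1] * d[2] * q[ok, 3]
      lattice[lin] <- TRUE
    }
    lattice <- lattice & sm$cavity
  }

  vol <- shell | lattice
  spacing <- rep(spec$spacing, 3)
  as_stack <- function(m) image_stack(array(as.integer(m), d), spacing,
                                      is_binary = TRUE)
  volume <- as_stack(vol)
  compartments <- structure(list(
    binary = volume,
    mask = as_stack(sm$outer),
    voids = as_stack(sm$cavity & !lattice),
    interior = as_stack(sm$cavity),
    cortical = as_stack(shell),
    cancellous = as_stack(lattice)), class = "bone_compartments")

  # truth graph in physical mm
  g <- truth$graph
  if (nrow(g$nodes) > 0) {
    g$nodes <- g$nodes * spec$spacing
    g$branches <- lapply(g$branches, function(br) {
      br$polyline <- br$polyline * spec$spacing
      br
    })
  }
  list(volume = volume,
       truth = list(compartments = compartments, graph = g,
                    blueprint = truth$blueprint))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the designed skeleton graph from clipped rod polylines: junctions
# at rod crossings (sample points of different rods closer than 1 voxel),
# terminals at clipped rod ends; rods split into branches at junctions.
blueprint_graph <- function(rods, spec) {
  if (length(rods) == 0) {
    return(list(rods = rods,
                graph = skeleton_graph(matrix(numeric(0), 0, 3)),
                blueprint = list(connectivity_mean = NA_real_,
                                 tortuosity = 1, n_junctions = 0L)))
  }
  # candidate junction positions: pairwise near-contacts between rods
  rod_cuts <- vector("list", length(rods))
  # grid-hash sample points at integer resolution for near-contact search
  key_of <- function(p) paste(round(p[, 1]), round(p[, 2]), round(p[, 3]))
  hash <- new.env()
  for (i in seq_along(rods)) {
    ks <- key_of(rods[[i]])
    for (j in seq_along(ks)) {
      k <- ks[j]
      hash[[k]] <- rbind(hash[[k]], c(i, j))
    }
  }
  pairs <- list()
  for (k in ls(hash)) {
    ent <- hash[[k]]
    if (nrow(ent) < 2) next
    ri <- unique(ent[, 1])
    if (length(ri) < 2) next
    for (a in seq_len(nrow(ent) - 1)) for (b in (a + 1):nrow(ent)) {
      ia <- ent[a, 1]; ib <- ent[b, 1]
      if (ia == ib) next
      pa <- rods[[ia]][ent[a, 2], ]; pb <- rods[[ib]][ent[b, 2], ]
      d2 <- sum((pa - pb)^2)
      if (d2 <= 1) {
        pairs[[length(pairs) + 1L]] <- list(i = ia, ti = ent[a, 2],
                                            j = ib, tj = ent[b, 2],
                                            pos = (pa + pb) / 2, d2 = d2)
      }
    }
  }
  # cluster contact positions closer than 1 voxel into junction nodes
  jpos <- if (length(pairs) > 0)
    do.call(rbind, lapply(pairs, `[[`, "pos")) else
      matrix(numeric(0), 0, 3)
  jnode <- integer(nrow(jpos))
  centers <- list()
  # the junction position is the midpoint of the tightest contact pair in
  # its cluster: for exact rod crossings that pair has distance zero, so
  # truth nodes sit exactly on the designed centrelines
  for (i in seq_len(nrow(jpos))) {
    assigned <- FALSE
    for (c_ in seq_along(centers)) {
      if (sum((jpos[i, ] - centers[[c_]]$pos)^2) <= 1.0001) {
        if (pairs[[i]]$d2 < centers[[c_]]$best_d2) {
          centers[[c_]]$pos <- jpos[i, ]
          centers[[c_]]$best_d2 <- pairs[[i]]$d2
        }
        jnode[i] <- c_
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centers[[length(centers) + 1L]] <- list(pos = jpos[i, ],
                                              best_d2 = pairs[[i]]$d2)
      jnode[i] <- length(centers)
    }
  }
  for (p_ in seq_along(pairs)) {
    rod_cuts[[pairs[[p_]]$i]] <- rbind(rod_cuts[[pairs[[p_]]$i]] ,
                                       c(pairs[[p_]]$ti, jnode[p_]))
    rod_cuts[[pairs[[p_]]$j]] <- rbind(rod_cuts[[pairs[[p_]]$j]] ,
                                       c(pairs[[p_]]$tj, jnode[p_]))
  }

  node_pos <- do.call(rbind, lapply(centers, `[[`, "pos"))
  if (is.null(node_pos)) node_pos <- matrix(numeric(0), 0, 3)
  n_junctions <- nrow(node_pos)
  branches <- list()
  trimmed_rods <- list()
  min_stub <- 2 * spec$rod_radius

  for (i in seq_along(rods)) {
    poly <- rods[[i]]
    cuts <- rod_cuts[[i]]
    if (is.null(cuts) || length(cuts) == 0) {
      # free-floating rod: keep only if long enough to be a trabecula
      if (branch_arc_length(poly) >= min_stub) {
        a <- nrow(node_pos) + 1L
        node_pos <- rbind(node_pos, poly[1, ])
        b <- nrow(node_pos) + 1L
        node_pos <- rbind(node_pos, poly[nrow(poly), ])
        branches[[length(branches) + 1L]] <-
          list(node_a = a, node_b = b, polyline = poly, self_loop = FALSE)
        trimmed_rods[[length(trimmed_rods) + 1L]] <- poly
      }
      next
    }
    cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
    # merge repeated hits on the same junction (contiguous sample runs),
    # keeping the sample closest to the junction position
    grp <- cumsum(c(TRUE, diff(cuts[, 2]) != 0 | diff(cuts[, 1]) > 3))
    sel <- vapply(split(seq_len(nrow(cuts)), grp), function(gr) {
      jid <- cuts[gr[1], 2]
      d2 <- vapply(gr, function(r)
        sum((poly[cuts[r, 1], ] - node_pos[jid, ])^2), numeric(1))
      gr[which.min(d2)]
    }, integer(1))
    cuts <- cuts[sel, , drop = FALSE]
    segs <- list()
    # leading stub
    first_t <- cuts[1, 1]
    if (first_t > 1) {
      seg <- poly[1:first_t, , drop = FALSE]
      if (branch_arc_length(seg) >= min_stub)
        segs[[length(segs) + 1L]] <- list(from = NA, to = cuts[1, 2],
                                          poly = seg, terminal_at = "from")
    }
    if (nrow(cuts) > 1) {
      for (s_ in seq_len(nrow(cuts) - 1)) {
        if (cuts[s_, 2] == cuts[s_ + 1, 2]) next
        seg <- poly[cuts[s_, 1]:cuts[s_ + 1, 1], , drop = FALSE]
        if (nrow(seg) >= 2)
          segs[[length(segs) + 1L]] <- list(from = cuts[s_, 2],
                                            to = cuts[s_ + 1, 2],
                                            poly = seg, terminal_at = "none")
      }
    }
    last_t <- cuts[nrow(cuts), 1]
    if (last_t < nrow(poly)) {
      seg <- poly[last_t:nrow(poly), , drop = FALSE]
      if (branch_arc_length(seg) >= min_stub)
        segs[[length(segs) + 1L]] <- list(from = cuts[nrow(cuts), 2],
                                          to = NA, poly = seg,
                                          terminal_at = "to")
    }
    rod_kept <- list()
    for (sg in segs) {
      pl <- sg$poly
      if (is.na(sg$from)) {
        a <- nrow(node_pos) + 1L; node_pos <- rbind(node_pos, pl[1, ])
      } else {
        a <- sg$from
        pl[1, ] <- node_pos[a, ]
      }
      if (is.na(sg$to)) {
        b <- nrow(node_pos) + 1L; node_pos <- rbind(node_pos, pl[nrow(pl), ])
      } else {
        b <- sg$to
        pl[nrow(pl), ] <- node_pos[b, ]
      }
      pl <- pl[c(TRUE, rowSums(abs(diff(pl))) > 0), , drop = FALSE]
      if (nrow(pl) < 2) next
      branches[[length(branches) + 1L]] <-
        list(node_a = a, node_b = b, polyline = pl, self_loop = a == b)
      rod_kept[[length(rod_kept) + 1L]] <- pl
    }
    if (length(rod_kept) > 0)
      trimmed_rods[[length(trimmed_rods) + 1L]] <- do.call(rbind, rod_kept)
  }

  graph <- skeleton_graph(node_pos, branches, validate = FALSE)
  deg <- node_degrees(graph)
  conn_mean <- if (any(deg >= 2)) mean(deg[deg >= 2]) else NA_real_
  tort <- wavy_tortuosity(spec$rod_waviness[1], spec$rod_waviness[2],
                          spec$lattice_spacing)
  list(rods = trimmed_rods, graph = graph,
       blueprint = list(connectivity_mean = conn_mean,
                        connectivity_degrees = deg[deg >= 2],
                        tortuosity = tort,
                        n_junctions = n_junctions))
}

#' Degrade a binary phantom into a pseudo-acquisition grayscale stack
#'
#' Renders foreground at intensity 200 and background at 10, applies a
#' slice-wise Gaussian blur and salt-and-pepper noise. This emulates the
#' contrast, partial-volume smoothing and impulse noise of a micro-CT
#' acquisition well enough to exercise thresholding and isolation
#' end-to-end; it does not model beam hardening or ring artifacts.
#'
#' @param stack Binary [image_stack()].
#' @param noise_rate Fraction of voxels replaced by salt (255) or pepper
#'   (0), half each.
#' @param blur_sigma Gaussian sigma in voxels (0 = no blur).
#' @param seed Integer seed.
#' @return Grayscale [image_stack()].
#' @export
degrade <- function(stack, noise_rate = 0.01, blur_sigma = 1, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  set.seed(seed)
  v <- array(ifelse(stack$voxels > 0, 200, 10), dim(stack$voxels))
  # impulse noise precedes the blur (the PSF smooths it), mimicking how
  # projection-domain outliers arrive attenuated in the reconstruction
  if (noise_rate > 0) {
    n <- length(v)
    idx <- sample.int(n, round(noise_rate * n))
    half <- length(idx) %/% 2
    if (half > 0) v[idx[seq_len(half)]] <- 255
    if (length(idx) > half) v[idx[(half + 1):length(idx)]] <- 0
  }
  if (blur_sigma > 0)
    v <- as.array(EBImage::gblur(v, sigma = blur_sigma))
  image_stack(round(v), stack$spacing, stack$origin)
}

#' Dice overlap coefficient between two binary stacks
#'
#' `2|A n B| / (|A| + |B|)`; 1 is perfect agreement.
#'
#' @param a,b Binary [image_stack()]s (or arrays) of equal dimensions.
#' @return Numeric in `[0, 1]` (1 when both are empty).
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "image_stack")) a$voxels else a
  bv <- if (inherits(b, "image_stack")) b$voxels else b
  stopifnot(all(dim(av) == dim(bv)))
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1)
  2 * sum(av * bv) / (sa + sb)
}
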