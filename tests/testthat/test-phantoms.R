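# Smaller-than-default phantoms keep the routine suite fast; the
# acceptance tests exercise the default 120-voxel configuration.
small_spec <- function(...) {
  phantom_spec(dims = c(80, 80, 80), semi_axes = c(30, 30, 34),
               lattice_spacing = 14, rod_radius = 2.5, ...)
}

test_that("phantom generation is deterministic and respects the spec", {
  sp <- small_spec(seed = 21)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  expect_identical(p1$truth$graph$nodes, p2$truth$graph$nodes)
  expect_error(phantom_spec(lattice_spacing = 4, rod_radius = 2.5),
               "exceed")
  expect_error(phantom_spec(shell_thickness = 0), "thickness")
})

test_that("phantom truth masks satisfy the compartment invariants", {
  ph <- generate_phantom(small_spec(seed = 22))
  tc <- ph$truth$compartments
  part <- tc$voids$voxels + tc$cortical$voxels + tc$cancellous$voxels
  expect_true(all(part == tc$mask$voxels))
  expect_true(all(tc$voids$voxels * tc$cancellous$voxels == 0))
  expect_identical(tc$interior$voxels,
                   tc$voids$voxels + tc$cancellous$voxels)
  expect_true(all(tc$cancellous$voxels <= ph$volume$voxels))
})

test_that("straight rods have blueprint tortuosity 1; wavy rods match quadrature", {
  ph <- generate_phantom(small_spec(seed = 23, rod_waviness = c(0, 14)))
  expect_identical(ph$truth$blueprint$tortuosity, 1)

  sp <- small_spec(seed = 23, rod_waviness = c(1.5, 14))
  ph2 <- generate_phantom(sp)
  bt <- ph2$truth$blueprint$tortuosity
  expect_gt(bt, 1)
  # independent quadrature of arc length over one lattice period
  f <- function(t) sqrt(1 + (1.5 * 2 * pi / sp$lattice_spacing *
                               cos(2 * pi * t / sp$lattice_spacing))^2)
  expected <- integrate(f, 0, sp$lattice_spacing)$value / sp$lattice_spacing
  expect_equal(bt, expected, tolerance = 1e-8)
  # the truth polylines of full lattice-period branches actually have
  # that tortuosity (chord = lattice spacing in mm)
  # junction-to-junction branches span exactly one lattice period of the
  # sinusoid; terminal stubs carry partial periods and are excluded
  g2 <- ph2$truth$graph
  deg <- node_degrees(g2)
  span <- sp$lattice_spacing * sp$spacing
  vals <- c()
  for (br in g2$branches) {
    if (deg[br$node_a] < 3 || deg[br$node_b] < 3) next
    chord <- sqrt(sum((g2$nodes[br$node_b, ] - g2$nodes[br$node_a, ])^2))
    if (abs(chord - span) < 0.2 * span) {
      arc <- sum(sqrt(rowSums(diff(br$polyline)^2)))
      vals <- c(vals, arc / chord)
    }
  }
  expect_gt(length(vals), 10)
  expect_equal(mean(vals), expected, tolerance = 0.01)
})

test_that("blueprint connectivity comes from exhaustive degree enumeration", {
  ph <- generate_phantom(small_spec(seed = 24))
  g <- ph$truth$graph
  deg <- node_degrees(g)
  expect_equal(ph$truth$blueprint$connectivity_mean, mean(deg[deg >= 2]))
  expect_gt(ph$truth$blueprint$n_junctions, 0)
  # interior junctions of a cubic lattice have degree 6
  expect_identical(max(deg), 6L)
})

test_that("degrade is deterministic and separable intensities threshold back", {
  ph <- generate_phantom(small_spec(seed = 25))
  d1 <- degrade(ph$volume, 0.01, 1, seed = 3)
  d2 <- degrade(ph$volume, 0.01, 1, seed = 3)
  expect_identical(d1$voxels, d2$voxels)
  # no noise, no blur: thresholding recovers the phantom exactly
  d0 <- degrade(ph$volume, 0, 0, seed = 3)
  b <- otsu_threshold(d0)
  expect_identical(b$voxels, ph$volume$voxels)
  expect_error(degrade(ph$volume, 1.5), "noise_rate")
})

test_that("isolation recovers phantom compartments (clean and degraded)", {
  ph <- generate_phantom(small_spec(seed = 26))
  comp <- split_bone(ph$volume)
  expect_gte(dice(comp$cancellous, ph$truth$compartments$cancellous), 0.95)
  expect_gte(dice(comp$cortical, ph$truth$compartments$cortical), 0.95)

  gr <- degrade(ph$volume, noise_rate = 0.01, blur_sigma = 1, seed = 26)
  compd <- split_bone(otsu_threshold(gr))
  expect_gte(dice(compd$cancellous, ph$truth$compartments$cancellous), 0.90)
  expect_gte(dice(compd$cortical, ph$truth$compartments$cortical), 0.90)
})

test_that("measured graph statistics recover the blueprint", {
  ph <- generate_phantom(small_spec(seed = 27))
  comp <- split_bone(ph$volume)
  g <- extract_graph(thin_volume(comp$cancellous))
  co <- connectivity(g)
  expect_lt(abs(co$mean - ph$truth$blueprint$connectivity_mean), 0.3)
  to <- tortuosity(g)
  expect_lt(abs(to$mean - ph$truth$blueprint$tortuosity), 0.05)
  junctions <- sum(node_degrees(g) >= 3)
  expect_lt(abs(junctions - ph$truth$blueprint$n_junctions) /
              ph$truth$blueprint$n_junctions, 0.10)
})

test_that("lattice spacing sweep shifts node density as designed", {
  # doubling the lattice spacing cuts junction density by ~8x
  sp1 <- phantom_spec(dims = c(96, 96, 96), semi_axes = c(40, 40, 44),
                      lattice_spacing = 12, rod_radius = 2.5, seed = 28)
  sp2 <- phantom_spec(dims = c(96, 96, 96), semi_axes = c(40, 40, 44),
                      lattice_spacing = 24, rod_radius = 2.5, seed = 28)
  run <- function(sp) {
    ph <- generate_phantom(sp)
    g <- extract_graph(thin_volume(split_bone(ph$volume)$cancellous))
    list(f = node_density(g, grid_dims = c(40, 40, 40)),
         co = connectivity(g)$mean,
         fd = fractal_dimension(g)$fd, bp = ph$truth$blueprint)
  }
  r1 <- run(sp1); r2 <- run(sp2)
  ratio <- r2$f$summary$mean / r1$f$summary$mean
  expect_lt(abs(ratio - 1 / 8) / (1 / 8), 0.6)  # KDE boundary effects
  # connectivity is a lattice-geometry constant
  expect_lt(abs(r1$co - r2$co), 0.5)
})

test_that("the whole pipeline closes on the default test matrix", {
  for (seed in c(31, 32)) {
    ph <- generate_phantom(small_spec(seed = seed,
                                      rod_waviness = if (seed %% 2)
                                        c(0, 14) else c(1, 14)))
    gr <- degrade(ph$volume, 0.005, 0.8, seed = seed)
    bin <- otsu_threshold(gr)
    comp <- split_bone(bin)
    g <- extract_graph(thin_volume(comp$cancellous))
    expect_gt(nrow(g$nodes), 10)
    rep <- make_report(g, reference_axis(c(0, 0, 0), c(1, 0, 0)),
                       specimen = paste0("ph", seed),
                       grid_dims = c(50, 50, 50))
    expect_false(is.na(rep$mean_connectivity))
    expect_false(is.na(rep$fractal_dimension))
    expect_true(rep$mean_tortuosity >= 1)
    expect_true(rep$trabecular_angle >= 0 && rep$trabecular_angle <= 90)
  }
})
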