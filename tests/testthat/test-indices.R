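test_that("tortuosity matches closed forms", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  straight <- make_graph(nodes, rbind(c(1, 2)))
  expect_identical(tortuosity(straight)$mean, 1)

  gL <- skeleton_graph(rbind(c(0, 0, 0), c(1, 1, 0)),
                       list(list(node_a = 1, node_b = 2,
                                 polyline = rbind(c(0, 0, 0), c(1, 0, 0),
                                                  c(1, 1, 0)))))
  expect_equal(tortuosity(gL)$mean, sqrt(2), tolerance = 1e-12)

  tt <- seq(0, pi, length.out = 100)
  arc <- cbind(cos(tt), sin(tt), 0)
  gS <- skeleton_graph(rbind(c(1, 0, 0), c(-1, 0, 0)),
                       list(list(node_a = 1, node_b = 2, polyline = arc)))
  expect_equal(tortuosity(gS)$mean, pi / 2, tolerance = pi / 2 * 0.001)
})

test_that("tortuosity is >= 1 on random graphs and excludes zero chords", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 8
    nodes <- matrix(rnorm(3 * n), n, 3)
    pairs <- cbind(1:(n - 1), 2:n)
    polys <- lapply(seq_len(n - 1), function(i) {
      mid <- (nodes[i, ] + nodes[i + 1, ]) / 2 + rnorm(3, 0, 0.3)
      rbind(nodes[i, ], mid, nodes[i + 1, ])
    })
    g <- make_graph(nodes, pairs, polys)
    expect_true(all(tortuosity(g)$values >= 1 - 1e-12))
  }
  # self-loop excluded and counted
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  loop_poly <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, -0.5, 0), c(0, 0, 0))
  g2 <- skeleton_graph(nodes, list(
    list(node_a = 1, node_b = 1, polyline = loop_poly, self_loop = TRUE),
    list(node_a = 1, node_b = 2,
         polyline = rbind(c(0, 0, 0), c(1, 0, 0)))))
  tr <- tortuosity(g2)
  expect_identical(tr$n_excluded, 1L)
  expect_identical(length(tr$values), 1L)
  g3 <- skeleton_graph(nodes, list(
    list(node_a = 1, node_b = 1, polyline = loop_poly, self_loop = TRUE)))
  expect_error(tortuosity(g3), "zero chord")
})

test_that("trabecular angle reproduces closed-form cases", {
  ax <- reference_axis(c(0, 0, 0), c(1, 0, 0))
  g1 <- make_graph(rbind(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0), c(5, 0, 0)),
                   rbind(c(1, 2), c(3, 4)))
  expect_equal(trabecular_angle(g1, ax)$angle_deg, 0, tolerance = 1e-9)

  g2 <- make_graph(rbind(c(0, 0, 0), c(1, 1, 0)), rbind(c(1, 2)))
  expect_equal(trabecular_angle(g2, ax)$angle_deg, 45, tolerance = 1e-9)

  # symmetric +-30 degrees about the axis: resultant along the axis
  n3 <- rbind(c(0, 0, 0), c(cos(pi / 6), sin(pi / 6), 0),
              c(cos(pi / 6), -sin(pi / 6), 0))
  g3 <- make_graph(n3, rbind(c(1, 2), c(1, 3)))
  expect_equal(trabecular_angle(g3, ax)$angle_deg, 0, tolerance = 1e-9)

  # antiparallel branches must not cancel (axial directions)
  g4 <- make_graph(rbind(c(0, 0, 0), c(1, 0.2, 0), c(0, 0, 0),
                         c(-1, -0.2, 0))[c(1, 2, 4), ],
                   rbind(c(1, 2), c(1, 3)))
  expect_lt(trabecular_angle(g4, ax)$angle_deg, 15)
})

test_that("trabecular angle is invariant under joint rotation and scaling", {
  set.seed(9)
  nodes <- matrix(rnorm(30), 10, 3)
  pairs <- cbind(1:9, 2:10)
  g <- make_graph(nodes, pairs)
  ax <- reference_axis(c(0, 0, 0), c(1, 0.3, -0.2))
  a0 <- trabecular_angle(g, ax)$angle_deg
  for (rep in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    gr <- rotate_graph(g, R)
    axr <- reference_axis(as.vector(R %*% ax$start),
                          as.vector(R %*% ax$end))
    expect_equal(trabecular_angle(gr, axr)$angle_deg, a0,
                 tolerance = 1e-6)
  }
  expect_equal(trabecular_angle(scale_graph(g, 3.7), ax)$angle_deg, a0,
               tolerance = 1e-9)
  # percentage contributions sum to 100
  expect_equal(sum(trabecular_angle(g, ax)$percent_contrib), 100)
})

test_that("trabecular angle error paths and major-axis fallback", {
  # perfectly balanced orthogonal pair: zero resultant after hemisphere
  # orientation relative to an axis orthogonal to both
  g <- make_graph(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2), c(1, 3)))
  # major axis: elongated cloud along y
  nodes <- cbind(rnorm(20, 0, 0.1), seq(0, 10, length.out = 20),
                 rnorm(20, 0, 0.1))
  gm <- make_graph(nodes, cbind(1:19, 2:20))
  res <- trabecular_angle(gm, "major")
  expect_identical(res$axis_source, "major")
  expect_lt(res$angle_deg, 10)
})

test_that("connectivity averages non-terminal nodes only", {
  g <- extract_graph(fixture_plus(5))
  co <- connectivity(g)
  expect_identical(co$mean, 4)
  expect_identical(co$sd, 0)
  expect_identical(co$n_nodes_used, 1L)
  expect_identical(co$n_terminal, 4L)

  # single chain: no non-terminal nodes
  chain <- make_graph(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2)))
  expect_error(connectivity(chain), "no non-terminal")

  # simple cycle: every node has degree exactly 2
  expect_identical(connectivity(make_cycle_graph(6))$mean, 2)
  expect_identical(connectivity(make_cycle_graph(11))$sd, 0)

  # self-loops contribute 2
  gsl <- skeleton_graph(rbind(c(0, 0, 0), c(1, 0, 0)), list(
    list(node_a = 1, node_b = 1,
         polyline = rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0, 0, 0)),
         self_loop = TRUE),
    list(node_a = 1, node_b = 2,
         polyline = rbind(c(0, 0, 0), c(1, 0, 0)))))
  co2 <- connectivity(gsl)
  expect_identical(co2$mean, 3)
  expect_identical(co2$n_self_loops, 1L)
})

test_that("node density integrates to the node count and is non-negative", {
  set.seed(10)
  for (rep in 1:3) {
    n <- c(200, 500, 1000)[rep]
    pts <- matrix(runif(3 * n, 0, 10), ncol = 3)
    f <- node_density(skeleton_graph(pts), grid_dims = c(60, 60, 60))
    expect_true(all(f$values >= 0))
    expect_lt(abs(f$summary$integral_nodes - n) / n, 0.05)
  }
})

test_that("uniform-cube density recovers the analytic rate", {
  set.seed(11)
  n <- 1000
  pts <- matrix(runif(3 * n, 0, 10), ncol = 3)   # 1 cm^3 in mm units
  f <- node_density(skeleton_graph(pts))
  # evaluate in the occupied bulk (cells deeper than two bandwidths from
  # the cube faces), where kernel mass flux balances and the field's
  # expectation is the analytic rate N/V = 1000 nodes/cm^3
  hb <- 2 * max(f$bandwidth)
  inside <- lapply(1:3, function(a)
    f$cell_centers[[a]] >= hb & f$cell_centers[[a]] <= 10 - hb)
  bulk <- f$values[inside[[1]], inside[[2]], inside[[3]]]
  expect_lt(abs(mean(bulk) - 1000) / 1000, 0.10)
})

test_that("node density is deterministic and fails cleanly when degenerate", {
  set.seed(12)
  pts <- matrix(runif(60), 20, 3)
  g <- skeleton_graph(pts)
  f1 <- node_density(g); f2 <- node_density(g)
  expect_identical(f1$values, f2$values)
  expect_error(node_density(skeleton_graph(pts[1, , drop = FALSE])),
               "2 nodes")
  flat <- cbind(pts[, 1:2], 0.7)
  expect_error(node_density(skeleton_graph(flat)), "axis z")
})

test_that("scaled density reports the scaled frame", {
  set.seed(13)
  pts <- matrix(runif(300, 0, 10), 100, 3)
  g <- skeleton_graph(pts)
  fs <- node_density(g, grid_dims = c(40, 40, 40), scale_length = 10)
  expect_match(fs$unit, "scaled")
  expect_lt(abs(fs$summary$integral_nodes - 100) / 100, 0.05)
})

test_that("fractal dimension is calibrated on line, plane and volume", {
  line <- cbind(seq(0, 100, length.out = 10000),
                seq(0, 50, length.out = 10000),
                seq(0, 80, length.out = 10000))
  expect_lt(abs(fractal_dimension(line)$fd - 1), 0.05)

  gp <- as.matrix(expand.grid(x = 0:99, y = 0:99))
  plane <- cbind(gp, 0.5 * gp[, 1] + 0.2 * gp[, 2])
  expect_lt(abs(fractal_dimension(plane)$fd - 2), 0.1)

  vol <- as.matrix(expand.grid(x = 0:63, y = 0:63, z = 0:63))
  expect_lt(abs(fractal_dimension(vol)$fd - 3), 0.1)

  # monotone sanity
  expect_lt(fractal_dimension(line)$fd, fractal_dimension(plane)$fd)
  expect_lt(fractal_dimension(plane)$fd, fractal_dimension(vol)$fd)
})

test_that("fractal dimension is invariant under uniform scaling", {
  set.seed(14)
  g <- extract_graph(thin_volume(fixture_torus()))
  fd0 <- fractal_dimension(g)$fd
  # scales adapt to the bounding box, so the slope is scale-free up to
  # floating-point cell-boundary rounding
  expect_equal(fractal_dimension(scale_graph(g, 5))$fd, fd0,
               tolerance = 0.02)
  expect_equal(fractal_dimension(g, scale_length = 5)$fd, fd0,
               tolerance = 0.02)
  expect_error(fractal_dimension(matrix(c(1, 2, 3), 1, 3)), "degenerate")
  expect_error(fractal_dimension(g, n_scales = 2), "3 scales")
})

test_that("make_report aggregates indices and flags missing ones", {
  g <- extract_graph(fixture_plus(5))
  ax <- reference_axis(c(0, 0, 0), c(1, 0, 0))
  rep1 <- make_report(g, ax, specimen = "plus")
  expect_s3_class(rep1, "index_report")
  expect_identical(rep1$mean_connectivity, 4)
  expect_identical(rep1$n_nodes, 5L)
  df <- as.data.frame(rep1)
  expect_identical(nrow(df), 1L)
  expect_identical(df$specimen, "plus")

  # 1-branch graph: connectivity missing with reason, tortuosity computed
  chain <- make_graph(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2)))
  rep2 <- make_report(chain, ax, specimen = "chain")
  expect_true(is.na(rep2$mean_connectivity))
  expect_match(rep2$missing$connectivity, "non-terminal")
  expect_identical(rep2$mean_tortuosity, 1)

  # CSV output is deterministic
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_report_csv(rep1, f1); write_report_csv(make_report(g, ax,
                                                           specimen = "plus"),
                                               f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("density colour maps render and reject bad positions", {
  set.seed(15)
  pts <- matrix(runif(900, 0, 10), 300, 3)
  f <- node_density(skeleton_graph(pts), grid_dims = c(30, 30, 30))
  p <- tempfile(fileext = ".png")
  density_colormap_slices(f, "coronal", 0.5, p)
  expect_true(file.exists(p) && file.info(p)$size > 0)
  expect_error(density_colormap_slices(f, "axial", 1.5, p), "position")
})
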