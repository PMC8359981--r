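# Independent brute-force oracles and fixture builders shared by the suite.

# Naive per-pixel sliding-window morphology: for every pixel, take the
# max (dilation) or min (erosion) over the structuring element's active
# offsets, with explicit border padding (0 for dilation, 1 for erosion).
oracle_morph <- function(m, pattern, op = c("dilate", "erode")) {
  op <- match.arg(op)
  pad <- if (op == "dilate") 0L else 1L
  r <- (nrow(pattern) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  big <- matrix(pad, nr + 2 * r, nc + 2 * r)
  big[(r + 1):(r + nr), (r + 1):(r + nc)] <- m
  out <- matrix(0L, nr, nc)
  act <- which(pattern == 1, arr.ind = TRUE) - (r + 1L)  # offsets
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- big[cbind(i + r + act[, 1], j + r + act[, 2])]
      out[i, j] <- if (op == "dilate") max(vals) else min(vals)
    }
  }
  out
}

oracle_morph_iter <- function(m, pattern, n, op) {
  for (k in seq_len(n)) m <- oracle_morph(m, pattern, op)
  m
}

# Exhaustive Otsu: scan every candidate threshold and maximize
# between-class variance computed directly from the data.
oracle_otsu <- function(values, candidates) {
  best <- -Inf; best_t <- candidates[1]
  for (t in candidates) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    sb2 <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb2 > best) { best <- sb2; best_t <- t }
  }
  best_t
}

# --- fixtures -------------------------------------------------------------

raster_disc <- function(n, radius, ctr = (n + 1) / 2) {
  m <- matrix(0L, n, n)
  for (x in 1:n) for (y in 1:n)
    if ((x - ctr)^2 + (y - ctr)^2 <= radius^2) m[x, y] <- 1L
  m
}

# Filled disc whose contour is reachable by the protocol's own iterated
# structuring element (built as dilate^5 of a small core), so the closing
# step is exactly the identity on it.
fixture_disc_slice <- function(n = 61, core_radius = 5) {
  se <- make_structuring_element("disc", 5)
  dilate(raster_disc(n, core_radius), se, 5)
}

fixture_disc_stack <- function(n = 61, core_radius = 5, slices = 3) {
  sl <- fixture_disc_slice(n, core_radius)
  image_stack(array(sl, c(n, n, slices)), 0.03, is_binary = TRUE)
}

# Hollow annulus: dilation-built outer disc minus an inner hole small
# enough for the closing iterations to bridge (hole radius <= 2 px/iter
# growth of the disc-5 element).
fixture_annulus_stack <- function(n = 61, core_radius = 5, hole_radius = 8,
                                  slices = 3) {
  outer <- fixture_disc_slice(n, core_radius)
  hole <- raster_disc(n, hole_radius)
  sl <- outer * (1L - hole)
  list(stack = image_stack(array(sl, c(n, n, slices)), 0.03,
                           is_binary = TRUE),
       outer = image_stack(array(outer, c(n, n, slices)), 0.03,
                           is_binary = TRUE),
       hole = image_stack(array(outer * hole, c(n, n, slices)), 0.03,
                          is_binary = TRUE))
}

# annulus with isolated interior specks (pseudo-trabecular islands)
fixture_speck_stack <- function(n = 75, core_radius = 12, hole_radius = 10,
                                slices = 5) {
  outer <- fixture_disc_slice(n, core_radius)   # radius ~ core + 10
  hole <- raster_disc(n, hole_radius)
  ann <- outer * (1L - hole)
  ctr <- (n + 1) / 2
  truth_sl <- matrix(0L, n, n)
  centers <- expand.grid(x = ctr + c(-6, 0, 6), y = ctr + c(-6, 0, 6))
  keep <- (centers$x - ctr)^2 + (centers$y - ctr)^2 <= (hole_radius - 3)^2
  centers <- centers[keep, ]
  for (k in seq_len(nrow(centers)))
    truth_sl[centers$x[k] + (-1:1), centers$y[k] + (-1:1)] <- 1L
  sl <- pmax(ann, truth_sl)
  dim(sl) <- dim(ann)
  list(stack = image_stack(array(sl, c(n, n, slices)), 0.03,
                           is_binary = TRUE),
       truth = image_stack(array(truth_sl, c(n, n, slices)), 0.03,
                           is_binary = TRUE))
}

# plus sign: 4 arms of `arm` voxels meeting at one voxel, in a 1-slice-thick
# volume padded front/back
fixture_plus <- function(arm = 5) {
  n <- 2 * arm + 11
  ctr <- (n + 1) %/% 2
  v <- array(0L, c(n, n, 3))
  v[(ctr - arm):(ctr + arm), ctr, 2] <- 1L
  v[ctr, (ctr - arm):(ctr + arm), 2] <- 1L
  image_stack(v, 1, is_binary = TRUE)
}

# solid torus, major radius R, minor radius r
fixture_torus <- function(R = 12, r = 3, n = 40, nz = 16) {
  v <- array(0L, c(n, n, nz))
  cx <- (n + 1) / 2; cz <- (nz + 1) / 2
  for (z in 1:nz) for (y in 1:n) for (x in 1:n) {
    rho <- sqrt((x - cx)^2 + (y - cx)^2)
    if ((rho - R)^2 + (z - cz)^2 <= r^2) v[x, y, z] <- 1L
  }
  image_stack(v, 1, is_binary = TRUE)
}

# straight voxel chain along x
fixture_chain <- function(len = 10, n = NULL) {
  if (is.null(n)) n <- len + 6
  v <- array(0L, c(n, 7, 7))
  v[3:(2 + len), 4, 4] <- 1L
  image_stack(v, 1, is_binary = TRUE)
}

# wireframe cube: 12 edges of a cube of side `side`, 8 degree-3 corners
fixture_cube_frame <- function(side = 9, pad = 3) {
  n <- side + 2 * pad + 1
  v <- array(0L, c(n, n, n))
  a <- pad + 1; b <- pad + 1 + side
  for (x in c(a, b)) for (y in c(a, b)) v[x, y, a:b] <- 1L
  for (x in c(a, b)) for (z in c(a, b)) v[x, a:b, z] <- 1L
  for (y in c(a, b)) for (z in c(a, b)) v[a:b, y, z] <- 1L
  image_stack(v, 1, is_binary = TRUE)
}

# --- graph builders -------------------------------------------------------

straight_branch <- function(nodes, a, b) {
  list(node_a = as.integer(a), node_b = as.integer(b),
       polyline = rbind(nodes[a, ], nodes[b, ]), self_loop = a == b)
}

make_graph <- function(nodes, pairs, polylines = NULL) {
  nodes <- as.matrix(nodes)
  br <- lapply(seq_len(nrow(pairs)), function(i) {
    if (!is.null(polylines) && !is.null(polylines[[i]]))
      list(node_a = as.integer(pairs[i, 1]), node_b = as.integer(pairs[i, 2]),
           polyline = polylines[[i]], self_loop = pairs[i, 1] == pairs[i, 2])
    else straight_branch(nodes, pairs[i, 1], pairs[i, 2])
  })
  skeleton_graph(nodes, br)
}

# simple cycle graph with k nodes on a circle
make_cycle_graph <- function(k = 6, radius = 5) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  nodes <- cbind(radius * cos(th), radius * sin(th), 0)
  pairs <- cbind(1:k, c(2:k, 1))
  make_graph(nodes, pairs)
}

# Euler characteristic V - E and cycle rank E - V + C of a skeleton graph
graph_euler <- function(g) {
  V <- nrow(g$nodes); E <- length(g$branches)
  if (E == 0) return(list(chi = V, cycles = 0, components = V))
  el <- do.call(rbind, lapply(g$branches, function(b) c(b$node_a, b$node_b)))
  if (requireNamespace("igraph", quietly = TRUE)) {
    ig <- igraph::graph_from_edgelist(el, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, V - igraph::vcount(ig)))
    C <- igraph::components(ig)$no
  } else {
    parent <- seq_len(V)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(el))) {
      a <- find(el[r, 1]); b <- find(el[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    C <- length(unique(vapply(seq_len(V), find, integer(1))))
  }
  list(chi = as.integer(V - E), cycles = as.integer(E - V + C),
       components = as.integer(C))
}

# small rotation matrix about an arbitrary axis
rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rotate_graph <- function(g, R) {
  g$nodes <- g$nodes %*% t(R)
  g$branches <- lapply(g$branches, function(br) {
    br$polyline <- br$polyline %*% t(R)
    br
  })
  g
}
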