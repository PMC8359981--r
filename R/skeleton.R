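#' Construct a skeleton graph
#'
#' A skeleton graph is the topological skeleton of the cancellous lattice:
#' `nodes` are junctions and branch endpoints (3D physical points, mm),
#' `branches` connect node pairs and carry the centreline polyline.
#'
#' @param nodes n x 3 numeric matrix of node positions (mm).
#' @param branches List of `list(node_a =, node_b =, polyline =)` records;
#'   `node_a`/`node_b` are 1-based node indices, `polyline` an m x 3 matrix
#'   (m >= 2) running from `node_a`'s position to `node_b`'s.
#' @param provenance `"computed"` or `"amira_import"`.
#' @param validate Check structural invariants (default `TRUE`).
#' @return An object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, branches = list(),
                           provenance = c("computed", "amira_import"),
                           validate = TRUE) {
  provenance <- match.arg(provenance)
  nodes <- as.matrix(nodes)
  if (length(nodes) == 0) nodes <- matrix(numeric(0), 0, 3)
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 matrix")
  g <- structure(list(nodes = nodes, branches = branches,
                      provenance = provenance),
                 class = "skeleton_graph")
  if (validate) validate_skeleton_graph(g)
  g
}

validate_skeleton_graph <- function(g) {
  n <- nrow(g$nodes)
  for (br in g$branches) {
    if (br$node_a < 1 || br$node_a > n || br$node_b < 1 || br$node_b > n)
      stop("branch endpoint index out of range")
    p <- br$polyline
    if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 2)
      stop("polyline must be an m x 3 matrix with m >= 2")
    steps <- diff(p)
    if (any(rowSums(abs(steps)) == 0))
      stop("consecutive polyline points must be distinct")
  }
  invisible(g)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  deg <- node_degrees(x)
  cat(sprintf(
    "skeleton_graph (%s): %d nodes (%d terminal), %d branches\n",
    x$provenance, nrow(x$nodes), sum(deg == 1), length(x$branches)))
  invisible(x)
}

#' Node degrees of a skeleton graph
#'
#' Degree is the number of branch endpoints referencing the node;
#' self-loop branches contribute 2. Terminal nodes have degree 1.
#'
#' @param graph A [skeleton_graph()].
#' @return Integer vector, one entry per node.
#' @export
node_degrees <- function(graph) {
  deg <- integer(nrow(graph$nodes))
  for (br in graph$branches) {
    deg[br$node_a] <- deg[br$node_a] + 1L
    deg[br$node_b] <- deg[br$node_b] + 1L
  }
  deg
}

branch_arc_length <- function(polyline) {
  if (nrow(polyline) < 2) return(0)
  sum(sqrt(rowSums(diff(polyline)^2)))
}

#' Thin a binary volume to a 1-voxel-wide skeleton
#'
#' Topology-preserving 3D curve thinning: simple points (voxels whose
#' removal changes neither foreground 26-connectivity nor background
#' 6-connectivity) are peeled in six directional sub-iterations with
#' sequential re-checking, preserving endpoints, until no voxel can be
#' removed. Connected components and tunnels of the input are preserved.
#'
#' @param cancellous Binary [image_stack()] with at least one foreground
#'   voxel.
#' @return Binary [image_stack()] of the medial curve skeleton
#'   (a subset of the input).
#' @export
thin_volume <- function(cancellous) {
  stopifnot(inherits(cancellous, "image_stack"))
  if (!cancellous$is_binary) stop("thin_volume needs a binary stack")
  v <- cancellous$voxels
  if (sum(v) == 0) stop("empty input: nothing to thin")
  thin <- cpp_thin3d(as.integer(v), dim(v))
  binary_like(cancellous, array(thin, dim(v)))
}

# physical coordinates of 1-based voxel indices
voxel_to_mm <- function(ijk, spacing, origin) {
  sweep(sweep(ijk - 1, 2, spacing, `*`), 2, origin, `+`)
}

#' Extract a node/branch graph from a thinned volume
#'
#' Skeleton voxels are classified by their 26-neighbour count: 1 =
#' terminal node, 2 = branch interior, >= 3 = junction. Maximal
#' 26-connected sets of junction voxels collapse to a single node at their
#' centroid; branches are traced as voxel chains between nodes and emitted
#' as polylines in physical mm. Isolated voxels are dropped; components
#' with no node (pure cycles) get one anchor node carrying a self-loop
#' branch. Junction-junction branches with fewer than `contract_below`
#' interior voxels are contracted (their junctions merged), removing
#' 1-voxel thinning bridges.
#'
#' @param thinned Binary [image_stack()], output of [thin_volume()].
#' @param spacing Optional spacing override (mm per axis).
#' @param contract_below Minimum interior voxel count for a
#'   junction-junction branch to survive contraction (default 2).
#' @return A [skeleton_graph()] (possibly empty).
#' @export
extract_graph <- function(thinned, spacing = NULL, contract_below = 2) {
  stopifnot(inherits(thinned, "image_stack"))
  v <- thinned$voxels
  if (is.null(spacing)) spacing <- thinned$spacing
  origin <- thinned$origin
  d <- dim(v)
  storage.mode(v) <- "integer"

  for (pass in 1:10) {
    res <- trace_skeleton(v, d)
    if (is.null(res)) return(skeleton_graph(matrix(numeric(0), 0, 3)))
    contracted <- contract_short_bridges(res, contract_below)
    if (!contracted$changed) break
    res <- contracted$res
  }
  nodes_mm <- voxel_to_mm(res$node_pos, spacing, origin)
  branches <- list()
  for (br in res$branches) {
    poly <- voxel_to_mm(br$chain, spacing, origin)
    # endpoints replaced by node centroids so polyline ends coincide with
    # node positions
    poly[1, ] <- nodes_mm[br$node_a, ]
    poly[nrow(poly), ] <- nodes_mm[br$node_b, ]
    poly <- poly[c(TRUE, rowSums(abs(diff(poly))) > 0), , drop = FALSE]
    if (nrow(poly) < 2) {
      if (br$node_a == br$node_b) next   # degenerate self-loop: drop
      poly <- rbind(nodes_mm[br$node_a, ], nodes_mm[br$node_b, ])
    }
    branches[[length(branches) + 1L]] <-
      list(node_a = br$node_a, node_b = br$node_b, polyline = poly,
           self_loop = br$node_a == br$node_b)
  }
  skeleton_graph(nodes_mm, branches, provenance = "computed")
}

# Core voxel-level tracing. v: integer 0/1 array. Returns node voxel
# positions (cluster centroids, 1-based fractional indices), and branches
# as voxel chains (matrices of 1-based indices, ends at node centroids'
# representative voxels).
trace_skeleton <- function(v, d) {
  fg <- which(v == 1L)
  if (length(fg) == 0) return(NULL)
  cnt <- cpp_neighbour_counts(v, d)
  deg <- cnt[fg]
  # drop isolated voxels
  if (any(deg == 0)) {
    v[fg[deg == 0]] <- 0L
    fg <- fg[deg != 0]
    if (length(fg) == 0) return(NULL)
    cnt <- cpp_neighbour_counts(v, d)
    deg <- cnt[fg]
  }
  coord <- arrayInd(fg, d)
  node_of <- array(0L, d)         # voxel -> node id (0 = not a node voxel)

  is_junction <- deg >= 3
  is_terminal <- deg == 1
  n_nodes <- 0L
  node_pos <- list()
  node_kind <- character(0)
  node_voxsets <- list()

  if (any(is_junction)) {
    jmask <- array(0L, d); jmask[fg[is_junction]] <- 1L
    jlab <- cpp_label_components(jmask, d, 26L)
    jvox <- which(jlab > 0)
    for (vox in split(jvox, jlab[jvox])) {
      ci <- arrayInd(vox, d)
      n_nodes <- n_nodes + 1L
      node_pos[[n_nodes]] <- colMeans(ci)
      node_kind[n_nodes] <- "junction"
      node_voxsets[[n_nodes]] <- vox
      node_of[vox] <- n_nodes
    }
  }
  if (any(is_terminal)) {
    for (t in fg[is_terminal]) {
      n_nodes <- n_nodes + 1L
      node_pos[[n_nodes]] <- as.numeric(arrayInd(t, d))
      node_kind[n_nodes] <- "terminal"
      node_voxsets[[n_nodes]] <- t
      node_of[t] <- n_nodes
    }
  }

  nb_off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb_off <- nb_off[rowSums(abs(nb_off)) > 0, ]
  neighbours_of <- function(ijk) {
    nb <- sweep(nb_off, 2, ijk, `+`)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    lin[v[lin] == 1L]
  }
  lin_of <- function(ijk) ijk[1] + d[1] * (ijk[2] - 1) + d[1] * d[2] * (ijk[3] - 1)

  visited <- array(FALSE, d)      # interior voxels claimed by a branch
  branches <- list()
  nb_cache <- new.env()

  add_branch <- function(a, b, chain_lin) {
    branches[[length(branches) + 1L]] <<- list(
      node_a = a, node_b = b,
      chain = arrayInd(chain_lin, d),
      interior = length(chain_lin) - 2L)
  }

  # trace from every node voxel into each non-node neighbour
  used_direct <- new.env()
  for (nid in seq_len(n_nodes)) {
    for (nvox in node_voxsets[[nid]]) {
      for (u in neighbours_of(arrayInd(nvox, d)[1, ])) {
        uid <- node_of[u]
        if (uid == nid) next
        if (uid > 0) {
          # direct node-node adjacency; dedupe by canonical voxel pair
          key <- paste(min(nvox, u), max(nvox, u))
          if (!is.null(used_direct[[key]])) next
          used_direct[[key]] <- TRUE
          add_branch(nid, uid, c(nvox, u))
          next
        }
        if (visited[u]) next
        # walk the degree-2 chain
        chain <- c(nvox, u)
        visited[u] <- TRUE
        prev <- nvox; cur <- u
        repeat {
          nbs <- neighbours_of(arrayInd(cur, d)[1, ])
          nxt <- nbs[nbs != prev]
          if (length(nxt) > 1) {
            # prefer a node voxel, else an unvisited interior voxel;
            # diagonal shortcuts around the previous voxel are skipped
            noden <- nxt[node_of[nxt] > 0]
            if (length(noden) > 0) nxt <- noden[1]
            else {
              free <- nxt[!visited[nxt]]
              if (length(free) == 0) break
              nxt <- free[1]
            }
          }
          if (length(nxt) == 0) break      # dead end (shouldn't happen)
          nxt <- nxt[1]
          chain <- c(chain, nxt)
          if (node_of[nxt] > 0) {
            add_branch(nid, node_of[nxt], chain)
            break
          }
          if (visited[nxt]) break          # merged into an existing trace
          visited[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
      }
    }
  }

  # pure cycles: interior voxels never visited and not adjacent to nodes
  left <- fg[!visited[fg] & node_of[fg] == 0 & deg == 2]
  if (length(left) > 0) {
    left_mask <- array(0L, d); left_mask[left] <- 1L
    clab <- cpp_label_components(left_mask, d, 26L)
    cvox <- which(clab > 0)
    for (vox in split(cvox, clab[cvox])) {
      if (any(visited[vox])) next
      # skip components adjacent to node voxels (already traced territory)
      start <- min(vox)
      n_nodes <- n_nodes + 1L
      node_pos[[n_nodes]] <- as.numeric(arrayInd(start, d))
      node_kind[n_nodes] <- "cycle_anchor"
      node_voxsets[[n_nodes]] <- start
      node_of[start] <- n_nodes
      visited[start] <- TRUE
      nbs <- neighbours_of(arrayInd(start, d)[1, ])
      chain <- start
      prev <- start; cur <- nbs[1]
      repeat {
        chain <- c(chain, cur)
        if (cur == start) break
        visited[cur] <- TRUE
        nbs2 <- neighbours_of(arrayInd(cur, d)[1, ])
        nxt <- nbs2[nbs2 != prev]
        if (length(nxt) == 0) break
        prev <- cur; cur <- nxt[1]
      }
      if (chain[length(chain)] == start)
        add_branch(n_nodes, n_nodes, chain)
    }
  }

  list(node_pos = do.call(rbind, node_pos), node_kind = node_kind,
       branches = branches, dims = d)
}

# merge junction pairs connected by branches with < contract_below interior
# voxels; returns possibly-updated trace result
contract_short_bridges <- function(res, contract_below) {
  if (contract_below <= 0 || length(res$branches) == 0)
    return(list(changed = FALSE, res = res))
  kind <- res$node_kind
  n <- nrow(res$node_pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  changed <- FALSE
  for (br in res$branches) {
    if (br$node_a == br$node_b) next
    if (kind[br$node_a] != "junction" || kind[br$node_b] != "junction") next
    if (br$interior >= contract_below) next
    ra <- find(br$node_a); rb <- find(br$node_b)
    if (ra != rb) { parent[max(ra, rb)] <- min(ra, rb); changed <- TRUE }
  }
  if (!changed) return(list(changed = FALSE, res = res))
  root <- vapply(seq_len(n), find, integer(1))
  keep <- sort(unique(root))
  remap <- match(root, keep)
  new_pos <- t(vapply(keep, function(r) {
    colMeans(res$node_pos[root == r, , drop = FALSE])
  }, numeric(3)))
  new_branches <- list()
  for (br in res$branches) {
    a <- remap[br$node_a]; b <- remap[br$node_b]
    if (a == b && kind[br$node_a] == "junction" &&
        kind[br$node_b] == "junction" && br$interior < contract_below)
      next                           # the contracted bridge itself
    br$node_a <- a; br$node_b <- b
    new_branches[[length(new_branches) + 1L]] <- br
  }
  list(changed = TRUE,
       res = list(node_pos = new_pos,
                  node_kind = vapply(keep, function(r)
                    res$node_kind[r], character(1)),
                  branches = new_branches, dims = res$dims))
}

#' Scale a skeleton graph by a homologous length
#'
#' Divides all coordinates by `scale_length` (e.g. femoral-head height in
#' mm), making the skeleton dimensionless so that size effects cancel in
#' node density and fractal dimension. Topology, tortuosity, connectivity
#' and trabecular angle are unchanged.
#'
#' @param graph A [skeleton_graph()].
#' @param scale_length Positive scalar (mm).
#' @return Scaled [skeleton_graph()].
#' @export
scale_graph <- function(graph, scale_length) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (length(scale_length) != 1 || !is.finite(scale_length) ||
      scale_length <= 0)
    stop("scale_length must be a positive number")
  graph$nodes <- graph$nodes / scale_length
  graph$branches <- lapply(graph$branches, function(br) {
    br$polyline <- br$polyline / scale_length
    br
  })
  graph
}

#' Export a skeleton graph as a CSV pair
#'
#' Writes `<prefix>_nodes.csv` (id, x, y, z) and `<prefix>_branches.csv`
#' (id, node_a, node_b, arc_length, n_points).
#'
#' @param graph A [skeleton_graph()].
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_skeleton_csv <- function(graph, prefix) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nf <- paste0(prefix, "_nodes.csv")
  bf <- paste0(prefix, "_branches.csv")
  nd <- data.frame(id = seq_len(nrow(graph$nodes)),
                   x = graph$nodes[, 1], y = graph$nodes[, 2],
                   z = graph$nodes[, 3])
  utils::write.csv(nd, nf, row.names = FALSE)
  bd <- data.frame(
    id = seq_along(graph$branches),
    node_a = vapply(graph$branches, `[[`, numeric(1), "node_a"),
    node_b = vapply(graph$branches, `[[`, numeric(1), "node_b"),
    arc_length = vapply(graph$branches, function(b)
      branch_arc_length(b$polyline), numeric(1)),
    n_points = vapply(graph$branches, function(b)
      nrow(b$polyline), numeric(1)))
  utils::write.csv(bd, bf, row.names = FALSE)
  invisible(c(nf, bf))
}
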