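#' Skeletonize a binary neurite mask
#'
#' Topology-preserving 3D curve thinning. Because thinning assumes an
#' isotropic grid, the mask is first resampled (linear interpolation) along
#' any axis whose pitch differs from the x pitch — at the reference spacing
#' this means z is resampled from 0.5 to 0.33 um — and the one-voxel-wide
#' skeleton is returned on that isotropic grid with its spacing recorded,
#' so downstream coordinates remain physical.
#'
#' @param mask a [binary_mask] of the neurite channel (after hole filling).
#' @return A [binary_mask] containing the skeleton on the isotropic grid.
#'   An empty mask yields an empty skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$voxels
  sp <- mask$spacing_um
  iso <- sp[1]
  a <- m * 1.0
  for (ax in 2:3) {
    if (abs(sp[ax] - iso) > 1e-9) a <- resample_axis(a, ax, sp[ax], iso)
  }
  mi <- a >= 0.5
  d <- dim(mi)
  if (!any(mi)) return(binary_mask(mi, rep(iso, 3)))
  sk <- cpp_thin3d(mi, d)
  dim(sk) <- d
  binary_mask(sk, rep(iso, 3))
}

# Linear resampling of a numeric array along one axis from pitch `from` to
# pitch `to`, preserving the physical extent (voxel centres at (i-0.5)*pitch).
resample_axis <- function(a, axis, from, to) {
  d <- dim(a)
  n_old <- d[axis]
  extent <- n_old * from
  n_new <- max(1L, as.integer(round(extent / to)))
  dn <- d; dn[axis] <- n_new
  out <- array(0, dn)
  idx_old <- function(k) {
    i <- lapply(d, seq_len); i[[axis]] <- k
    do.call(`[`, c(list(a), i, list(drop = FALSE)))
  }
  set_new <- function(k, val) {
    i <- lapply(dn, seq_len); i[[axis]] <- k
    eval(as.call(c(list(as.name("[<-"), as.name("out")), i, list(val))))
  }
  for (k in seq_len(n_new)) {
    zc <- (k - 0.5) * to               # physical centre of new voxel
    f <- zc / from + 0.5               # fractional old index
    k0 <- floor(f)
    if (k0 < 1) { k0 <- 1L; k1 <- 1L; w <- 0 }
    else if (k0 >= n_old) { k0 <- n_old; k1 <- n_old; w <- 0 }
    else { k1 <- k0 + 1L; w <- f - k0 }
    sl <- (1 - w) * idx_old(k0) + w * idx_old(k1)
    out <- set_new(k, sl)
  }
  out
}

#' Convert a voxel skeleton to a spatial graph
#'
#' Skeleton voxels with three or more skeletal neighbours are junction
#' voxels; 26-adjacent junction voxels are clustered and collapsed to their
#' centroid as a single branch node (this prevents spurious adjacent branch
#' points). Degree-1 voxels become end nodes, and the degree-2 chains
#' between node voxels become edges carrying polylines through the voxel
#' centres. Polyline interiors are lightly smoothed (moving average) to
#' remove the voxel staircase before arclengths are computed; connected
#' components are labelled.
#'
#' @param skel a skeleton [binary_mask] from [skeletonize()].
#' @param smooth_window odd moving-average window for polyline smoothing
#'   (1 disables).
#' @return A [spatial_graph] in `skeleton` mode.
#' @export
skeleton_to_graph <- function(skel, smooth_window = 5L) {
  stopifnot(inherits(skel, "binary_mask"))
  sp <- skel$spacing_um
  d <- dim(skel$voxels)
  if (!any(skel$voxels)) return(spatial_graph(mode = "skeleton"))
  res <- cpp_skel_chains(skel$voxels, d)
  nid <- res$node_id
  nn <- res$n_nodes
  # node positions: centroid of each cluster's voxel centres
  vox <- which(nid > 0)
  co <- arrayInd(vox, d)
  pos_um <- cbind((co[, 1] - 0.5) * sp[1], (co[, 2] - 0.5) * sp[2],
                  (co[, 3] - 0.5) * sp[3])
  cl <- nid[vox]
  cx <- tapply(pos_um[, 1], cl, mean)
  cy <- tapply(pos_um[, 2], cl, mean)
  cz <- tapply(pos_um[, 3], cl, mean)
  ord <- as.integer(names(cx))
  centroid <- matrix(NA_real_, nn, 3)
  centroid[ord, ] <- cbind(cx, cy, cz)
  nodes <- data.frame(x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
                      kind = "end", stringsAsFactors = FALSE)

  chains <- res$chains
  edges <- data.frame(from = integer(0), to = integer(0))
  polylines <- list()
  for (ch in chains) {
    co <- arrayInd(ch, d)
    p <- cbind((co[, 1] - 0.5) * sp[1], (co[, 2] - 0.5) * sp[2],
               (co[, 3] - 0.5) * sp[3])
    from <- nid[ch[1]]
    to <- nid[ch[length(ch)]]
    p[1, ] <- centroid[from, ]
    p[nrow(p), ] <- centroid[to, ]
    if (smooth_window >= 3) p <- smooth_polyline(p, smooth_window)
    edges <- rbind(edges, data.frame(from = from, to = to))
    polylines[[length(polylines) + 1L]] <- p
  }
  g <- spatial_graph(nodes, edges, polylines, mode = "skeleton")
  g
}

#' Prune short terminal spurs
#'
#' Iteratively removes terminal edges shorter than `min_len_um` that attach
#' at a branch node — the small artifactual side branches created by uneven
#' neurite surfaces — and dissolves any branch node thereby reduced to a
#' through-connection, repeating to a fixpoint. `min_len_um = 0` is the
#' identity; chains with no branch nodes are never modified.
#'
#' @param g a [spatial_graph].
#' @param min_len_um spur length threshold (um).
#' @return The pruned graph.
#' @export
prune_spurs <- function(g, min_len_um = 2) {
  stopifnot(inherits(g, "spatial_graph"))
  if (min_len_um < 0) stop("min_len_um must be >= 0")
  if (min_len_um == 0 || nrow(g$edges) == 0) return(g)
  repeat {
    deg <- sg_degree(g)
    kind <- g$nodes$kind
    e_from <- g$edges$from; e_to <- g$edges$to
    tip_to <- deg[e_to] == 1 & kind[e_to] != "soma" & deg[e_from] >= 3
    tip_from <- deg[e_from] == 1 & kind[e_from] != "soma" & deg[e_to] >= 3
    spur <- which((tip_to | tip_from) & g$edges$length < min_len_um)
    if (length(spur) == 0) break
    g <- sg_remove_edges(g, spur)
    g <- sg_dissolve_slabs(g)
  }
  g
}

#' Remove soma-scale loops
#'
#' Hollow somas whose cavities survive binarization are traced as small
#' loops that add artifactual length. Cycles whose geodesic circumference
#' is at most `max_loop_len_um` are collapsed to a single node at the cycle
#' centroid; larger cycles are genuine network circuits and are kept. The
#' number of removed loops and their total length are recorded in the
#' attributes `loops_removed` and `loop_length_removed_um`.
#'
#' @param g a [spatial_graph].
#' @param max_loop_len_um circumference threshold (um); the default 40 um
#'   is about the circumference of a 12 um soma.
#' @return The graph with small loops collapsed.
#' @export
remove_loops <- function(g, max_loop_len_um = 40) {
  stopifnot(inherits(g, "spatial_graph"))
  if (max_loop_len_um <= 0) stop("max_loop_len_um must be > 0")
  n_removed <- 0L
  len_removed <- 0
  repeat {
    if (nrow(g$edges) == 0) break
    # self-loops first
    self <- which(g$edges$from == g$edges$to & g$edges$length <= max_loop_len_um)
    if (length(self)) {
      len_removed <- len_removed + sum(g$edges$length[self])
      n_removed <- n_removed + length(self)
      g <- sg_remove_edges(g, self)
      next
    }
    cyc <- find_small_cycle(g, max_loop_len_um)
    if (is.null(cyc)) break
    len_removed <- len_removed + cyc$length
    n_removed <- n_removed + 1L
    g <- collapse_cycle(g, cyc$nodes, cyc$edges)
  }
  attr(g, "loops_removed") <- n_removed
  attr(g, "loop_length_removed_um") <- len_removed
  g
}

# Find one cycle with geodesic circumference <= max_len, or NULL.
find_small_cycle <- function(g, max_len) {
  ne <- nrow(g$edges)
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
  igraph::E(ig)$weight <- g$edges$length
  igraph::E(ig)$eid <- seq_len(ne)
  for (e in seq_len(ne)) {
    if (g$edges$length[e] > max_len) next
    u <- g$edges$from[e]; v <- g$edges$to[e]
    ig2 <- igraph::delete_edges(ig, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(ig2, from = u, to = v, weights = igraph::E(ig2)$weight,
                             output = "both"))
    if (length(sp$vpath[[1]]) == 0) next
    plen <- sum(igraph::E(ig2)$weight[as.integer(sp$epath[[1]])])
    if (g$edges$length[e] + plen <= max_len) {
      path_eids <- igraph::E(ig2)$eid[as.integer(sp$epath[[1]])]
      return(list(nodes = unique(c(u, v, as.integer(sp$vpath[[1]]))),
                  edges = unique(c(e, path_eids)),
                  length = g$edges$length[e] + plen))
    }
  }
  NULL
}

# Collapse the given cycle nodes to their centroid; cycle edges vanish,
# external edges re-terminate at the centroid node.
collapse_cycle <- function(g, cyc_nodes, cyc_edges) {
  cen <- colMeans(g$nodes[cyc_nodes, c("x", "y", "z")])
  keep_kind <- if (any(g$nodes$kind[cyc_nodes] == "soma")) "soma" else "slab"
  target <- cyc_nodes[1]
  g$nodes[target, c("x", "y", "z")] <- as.list(cen)
  g$nodes$kind[target] <- keep_kind
  drop_nodes <- setdiff(cyc_nodes, target)
  # remove cycle edges
  keep_e <- setdiff(seq_len(nrow(g$edges)), cyc_edges)
  g$edges <- g$edges[keep_e, , drop = FALSE]
  g$polylines <- g$polylines[keep_e]
  # re-terminate external edges
  for (e in seq_len(nrow(g$edges))) {
    if (g$edges$from[e] %in% cyc_nodes) {
      g$edges$from[e] <- target
      g$polylines[[e]] <- rbind(cen, g$polylines[[e]])
    }
    if (g$edges$to[e] %in% cyc_nodes) {
      g$edges$to[e] <- target
      g$polylines[[e]] <- rbind(g$polylines[[e]], cen)
    }
  }
  g <- sg_keep_nodes(g, setdiff(seq_len(nrow(g$nodes)), drop_nodes))
  sg_refresh(g)
}

#' Bridge gaps between skeleton end points
#'
#' Joins pairs of end nodes whose Euclidean separation is at most
#' `max_gap_um` and whose terminal directions are each misaligned from the
#' connecting segment by at most `max_angle_deg`, restoring continuity
#' across staining or thresholding dropouts. Pairs are taken greedily by
#' ascending distance (ties by node index) and each end node is used at
#' most once; the gap limit of 4 um and the angle gate together avoid
#' creating connections between closely located but distinct neurites.
#' `max_gap_um = 0` is the identity. The number of bridges added is
#' recorded in the attribute `bridges_added`.
#'
#' @param g a [spatial_graph].
#' @param max_gap_um maximum Euclidean gap width (um).
#' @param max_angle_deg maximum terminal-direction misalignment (degrees).
#' @return The bridged graph.
#' @export
bridge_gaps <- function(g, max_gap_um = 4, max_angle_deg = 60) {
  stopifnot(inherits(g, "spatial_graph"))
  if (max_gap_um < 0) stop("max_gap_um must be >= 0")
  attr(g, "bridges_added") <- 0L
  if (max_gap_um == 0 || nrow(g$edges) == 0) return(g)
  deg <- sg_degree(g)
  ends <- which(deg == 1 & g$nodes$kind != "soma")
  if (length(ends) < 2) return(g)

  dir_out <- matrix(NA_real_, length(ends), 3)
  for (i in seq_along(ends)) {
    nd <- ends[i]
    e <- which(g$edges$from == nd | g$edges$to == nd)[1]
    p <- g$polylines[[e]]
    if (g$edges$from[e] == nd) p <- p[nrow(p):1, , drop = FALSE] # orient toward nd
    L <- polyline_length(p)
    back <- point_at_arclength(p, max(0, L - 3))
    dir_out[i, ] <- unit3(p[nrow(p), ] - back)
  }
  pos <- as.matrix(g$nodes[ends, c("x", "y", "z")])
  cosmax <- cos(max_angle_deg * pi / 180)

  cand <- list()
  for (i in seq_along(ends)) {
    for (j in seq_along(ends)) {
      if (j <= i) next
      v <- pos[j, ] - pos[i, ]
      dd <- sqrt(sum(v^2))
      if (dd > max_gap_um || dd < 1e-9) next
      u <- v / dd
      if (sum(dir_out[i, ] * u) < cosmax) next
      if (sum(dir_out[j, ] * (-u)) < cosmax) next
      cand[[length(cand) + 1L]] <- c(i, j, dd)
    }
  }
  if (length(cand) == 0) return(g)
  cm <- do.call(rbind, cand)
  cm <- cm[order(cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
  used <- logical(length(ends))
  nb <- 0L
  for (r in seq_len(nrow(cm))) {
    i <- cm[r, 1]; j <- cm[r, 2]
    if (used[i] || used[j]) next
    used[i] <- TRUE; used[j] <- TRUE
    g <- sg_add_edge(g, ends[i], ends[j])
    nb <- nb + 1L
  }
  g <- sg_refresh(g)
  attr(g, "bridges_added") <- nb
  g
}

#' Insert detected somas into the graph and select the tracing mode
#'
#' Each soma becomes a soma node at its detected centre, fused with every
#' graph node lying within the soma radius (edges re-terminate at the soma
#' centre; edges entirely inside the soma vanish). In `soma_rooted` mode —
#' the behaviour of soma-seeded tracers, where only neurites connected to a
#' soma in the imaged region are analysed — components without a soma are
#' discarded and their count is recorded in the attribute
#' `components_discarded`. In `skeleton` mode all components are kept and
#' somas are optional.
#'
#' @param g a [spatial_graph].
#' @param somas data frame with `x`, `y`, `z`, `radius` (from
#'   [detect_somas()] or ground truth).
#' @param mode `"soma_rooted"` or `"skeleton"`.
#' @param volume_um optional physical extents; somas outside error out.
#' @param fuse_radius_um fusion radius applied to every soma (default: each
#'   soma's own detected radius). Edges whose centrelines pass within this
#'   radius are split there so that through-paths fuse too.
#' @return The graph with soma nodes, `mode` set accordingly.
#' @export
assign_somas <- function(g, somas, mode = c("soma_rooted", "skeleton"),
                         volume_um = NULL, fuse_radius_um = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "spatial_graph"))
  if (!is.null(volume_um) && nrow(somas) > 0) {
    out <- somas$x < 0 | somas$y < 0 | somas$z < 0 |
      somas$x > volume_um[1] | somas$y > volume_um[2] | somas$z > volume_um[3]
    if (any(out)) stop("soma outside volume")
  }
  if (nrow(somas) > 0) {
    for (i in seq_len(nrow(somas))) {
      cen <- c(somas$x[i], somas$y[i], somas$z[i])
      r <- if (is.null(fuse_radius_um)) somas$radius[i] else fuse_radius_um
      # split edges whose centrelines pass through the soma sphere, so that
      # through-paths without a node inside still fuse
      for (e in seq_len(nrow(g$edges))) {
        p <- g$polylines[[e]]
        d2p <- (p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2 + (p[, 3] - cen[3])^2
        mv <- which.min(d2p)
        if (d2p[mv] <= r^2 && mv > 1 && mv < nrow(p)) {
          g <- sg_split_edge(g, e, mv)$g
        }
      }
      d2 <- (g$nodes$x - cen[1])^2 + (g$nodes$y - cen[2])^2 +
        (g$nodes$z - cen[3])^2
      cand <- which(d2 <= r^2 & g$nodes$kind != "soma")
      newid <- nrow(g$nodes) + 1L
      g$nodes <- rbind(g$nodes, data.frame(
        id = newid, x = cen[1], y = cen[2], z = cen[3], kind = "soma",
        stringsAsFactors = FALSE))
      if (length(cand)) {
        drop_e <- integer(0)
        for (e in seq_len(nrow(g$edges))) {
          fin <- g$edges$from[e] %in% cand
          tin <- g$edges$to[e] %in% cand
          if (fin && tin) { drop_e <- c(drop_e, e); next }
          if (fin) {
            g$edges$from[e] <- newid
            g$polylines[[e]] <- rbind(cen, g$polylines[[e]])
          }
          if (tin) {
            g$edges$to[e] <- newid
            g$polylines[[e]] <- rbind(g$polylines[[e]], cen)
          }
        }
        if (length(drop_e)) {
          keep_e <- setdiff(seq_len(nrow(g$edges)), drop_e)
          g$edges <- g$edges[keep_e, , drop = FALSE]
          g$polylines <- g$polylines[keep_e]
        }
        g <- sg_keep_nodes(g, setdiff(seq_len(nrow(g$nodes)), cand))
      }
      g <- sg_refresh(g)
    }
  }
  discarded <- 0L
  if (mode == "soma_rooted" && nrow(g$edges) > 0) {
    soma_nodes <- which(g$nodes$kind == "soma")
    soma_comps <- unique(g$node_components[soma_nodes])
    ncomp <- max(g$node_components)
    discarded <- ncomp - length(intersect(seq_len(ncomp), soma_comps))
    keep_nodes <- which(g$node_components %in% soma_comps)
    g <- sg_keep_nodes(g, keep_nodes)
    g <- sg_refresh(g)
  }
  g$mode <- mode
  attr(g, "components_discarded") <- discarded
  g
}
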