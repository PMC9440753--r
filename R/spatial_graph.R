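#' Geometric centreline graph of a neuronal network
#'
#' A spatial graph stores the reconstructed (or ground-truth) network as
#' nodes with physical positions and kinds (`soma`, `branch`, `end`, `slab`)
#' and edges carrying 3D polyline centrelines with their arclengths in
#' micrometres. Connected-component labels are maintained per edge. Node
#' kinds other than `soma` are derived from degree: 1 = `end`, 2 = `slab`,
#' 3 or more = `branch`.
#'
#' @param nodes data frame with columns `x`, `y`, `z` (micrometres) and
#'   optionally `kind` (only `soma` entries are honoured; the rest follow
#'   from degree).
#' @param edges data frame with integer columns `from`, `to` indexing rows of
#'   `nodes`.
#' @param polylines list (one per edge) of n x 3 matrices; the first row must
#'   coincide with the `from` node position, the last with the `to` node
#'   position.
#' @param mode `"skeleton"` (all components kept) or `"soma_rooted"` (every
#'   component contains a soma).
#'
#' @return An object of class `spatial_graph` with elements `nodes`, `edges`
#'   (including recomputed `length`), `polylines`, `components` (per-edge
#'   component id), `node_components` and `mode`.
#' @export
spatial_graph <- function(nodes = NULL, edges = NULL, polylines = list(),
                          mode = "skeleton") {
  if (is.null(nodes)) {
    nodes <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        kind = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(nodes$kind)) nodes$kind <- rep("end", nrow(nodes))
  if (is.null(edges)) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        length = numeric(0))
  }
  if (is.null(edges$length)) edges$length <- rep(NA_real_, nrow(edges))
  nodes$id <- seq_len(nrow(nodes))
  stopifnot(length(polylines) == nrow(edges))
  g <- structure(list(nodes = nodes[, c("id", "x", "y", "z", "kind")],
                      edges = edges[, c("from", "to", "length")],
                      polylines = polylines,
                      components = integer(nrow(edges)),
                      node_components = integer(nrow(nodes)),
                      mode = mode),
                 class = "spatial_graph")
  sg_refresh(g)
}

# Recompute edge lengths, node kinds and component labels.
sg_refresh <- function(g) {
  ne <- nrow(g$edges)
  if (ne > 0) {
    g$edges$length <- vapply(g$polylines, polyline_length, numeric(1))
  }
  deg <- sg_degree(g)
  kind <- g$nodes$kind
  nonsoma <- kind != "soma"
  kind[nonsoma & deg >= 3] <- "branch"
  kind[nonsoma & deg == 2] <- "slab"
  kind[nonsoma & deg <= 1] <- "end"
  g$nodes$kind <- kind

  nn <- nrow(g$nodes)
  if (nn == 0) {
    g$node_components <- integer(0)
    g$components <- integer(0)
    return(g)
  }
  ig <- igraph::make_empty_graph(n = nn, directed = FALSE)
  if (ne > 0)
    ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
  memb <- igraph::components(ig)$membership
  g$node_components <- as.integer(memb)
  g$components <- if (ne > 0) as.integer(memb[g$edges$from]) else integer(0)
  g
}

# Node degrees (self-loops count twice, as usual).
sg_degree <- function(g) {
  nn <- nrow(g$nodes)
  if (nn == 0) return(integer(0))
  tabulate(c(g$edges$from, g$edges$to), nbins = nn)
}

#' Total network length
#'
#' Sum of edge polyline arclengths over all components, in micrometres.
#'
#' @param g a [spatial_graph].
#' @return Total length in micrometres (0 for an empty graph).
#' @export
total_length <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  if (nrow(g$edges) == 0) return(0)
  sum(g$edges$length)
}

#' @export
print.spatial_graph <- function(x, ...) {
  ncomp <- if (length(x$node_components)) max(x$node_components) else 0
  cat(sprintf("spatial_graph (%s): %d nodes, %d edges, %d components, total length %.1f um\n",
              x$mode, nrow(x$nodes), nrow(x$edges), ncomp, total_length(x)))
  if (nrow(x$nodes)) {
    tb <- table(x$nodes$kind)
    cat("node kinds:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.spatial_graph <- function(object, ...) {
  g <- object
  out <- list(n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
              n_components = if (length(g$node_components)) max(g$node_components) else 0L,
              total_length_um = total_length(g),
              n_branch = sum(g$nodes$kind == "branch"),
              n_end = sum(g$nodes$kind == "end"),
              n_soma = sum(g$nodes$kind == "soma"))
  class(out) <- "summary.spatial_graph"
  out
}

#' @export
print.summary.spatial_graph <- function(x, ...) {
  cat(sprintf("nodes %d (soma %d, branch %d, end %d), edges %d, components %d, length %.1f um\n",
              x$n_nodes, x$n_soma, x$n_branch, x$n_end,
              x$n_edges, x$n_components, x$total_length_um))
  invisible(x)
}

# --- internal editing helpers ----------------------------------------------

# Remove edges by index, dropping non-soma nodes left with degree 0.
sg_remove_edges <- function(g, idx, drop_isolated = TRUE) {
  if (length(idx) == 0) return(sg_refresh(g))
  keep <- setdiff(seq_len(nrow(g$edges)), idx)
  g$edges <- g$edges[keep, , drop = FALSE]
  g$polylines <- g$polylines[keep]
  if (drop_isolated) g <- sg_drop_isolated(g)
  sg_refresh(g)
}

# Drop non-soma nodes with no incident edges; renumber ids.
sg_drop_isolated <- function(g) {
  deg <- sg_degree(g)
  keep <- which(deg > 0 | g$nodes$kind == "soma")
  sg_keep_nodes(g, keep)
}

# Keep only the given node indices (edges touching dropped nodes are removed).
sg_keep_nodes <- function(g, keep) {
  keep <- sort(unique(keep))
  map <- integer(nrow(g$nodes))
  map[keep] <- seq_along(keep)
  eok <- g$edges$from %in% keep & g$edges$to %in% keep
  g$edges <- g$edges[eok, , drop = FALSE]
  g$polylines <- g$polylines[eok]
  g$edges$from <- map[g$edges$from]
  g$edges$to <- map[g$edges$to]
  g$nodes <- g$nodes[keep, , drop = FALSE]
  g$nodes$id <- seq_len(nrow(g$nodes))
  rownames(g$nodes) <- NULL
  rownames(g$edges) <- NULL
  g
}

# Split edge `e` at polyline vertex `v` (1-based). Returns list(g, node):
# the id of the node at that vertex (reusing the edge's endpoints when the
# vertex is terminal). The new node starts as a slab.
sg_split_edge <- function(g, e, v) {
  p <- g$polylines[[e]]
  n <- nrow(p)
  if (v <= 1) return(list(g = g, node = g$edges$from[e]))
  if (v >= n) return(list(g = g, node = g$edges$to[e]))
  newid <- nrow(g$nodes) + 1L
  g$nodes <- rbind(g$nodes,
                   data.frame(id = newid, x = p[v, 1], y = p[v, 2], z = p[v, 3],
                              kind = "slab", stringsAsFactors = FALSE))
  to_old <- g$edges$to[e]
  g$edges$to[e] <- newid
  g$polylines[[e]] <- p[1:v, , drop = FALSE]
  g$edges <- rbind(g$edges,
                   data.frame(from = newid, to = to_old, length = NA_real_))
  g$polylines[[length(g$polylines) + 1L]] <- p[v:n, , drop = FALSE]
  list(g = g, node = newid)
}

# Add a straight edge between two existing nodes.
sg_add_edge <- function(g, a, b, poly = NULL) {
  if (is.null(poly)) {
    poly <- rbind(as.numeric(g$nodes[a, c("x", "y", "z")]),
                  as.numeric(g$nodes[b, c("x", "y", "z")]))
  }
  g$edges <- rbind(g$edges, data.frame(from = a, to = b, length = NA_real_))
  g$polylines[[length(g$polylines) + 1L]] <- poly
  g
}

# Merge the two edges meeting at every non-soma degree-2 node into single
# through-edges (repeatedly, to a fixpoint). Self-loops are left alone.
sg_dissolve_slabs <- function(g) {
  repeat {
    deg <- sg_degree(g)
    loops <- g$edges$from == g$edges$to
    loopdeg <- tabulate(g$edges$from[loops], nbins = nrow(g$nodes))
    cand <- which(deg == 2 & loopdeg == 0 & g$nodes$kind != "soma")
    if (length(cand) == 0) break
    v <- cand[1]
    inc <- which(g$edges$from == v | g$edges$to == v)
    if (length(inc) != 2) break # defensive; cannot happen with loops excluded
    e1 <- inc[1]; e2 <- inc[2]
    p1 <- g$polylines[[e1]]
    p2 <- g$polylines[[e2]]
    a <- if (g$edges$from[e1] == v) g$edges$to[e1] else g$edges$from[e1]
    b <- if (g$edges$from[e2] == v) g$edges$to[e2] else g$edges$from[e2]
    if (g$edges$to[e1] != v) p1 <- p1[nrow(p1):1, , drop = FALSE] # orient a -> v
    if (g$edges$from[e2] != v) p2 <- p2[nrow(p2):1, , drop = FALSE] # orient v -> b
    newp <- rbind(p1, p2[-1, , drop = FALSE])
    g$edges$from[e1] <- a
    g$edges$to[e1] <- b
    g$polylines[[e1]] <- newp
    g$edges <- g$edges[-e2, , drop = FALSE]
    g$polylines <- g$polylines[-e2]
    g <- sg_keep_nodes(g, setdiff(seq_len(nrow(g$nodes)), v))
  }
  sg_refresh(g)
}

# Edge indices of a node's component.
sg_component_edges <- function(g, node) {
  comp <- g$node_components[node]
  which(g$components == comp)
}
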