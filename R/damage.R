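#' Apply damage phenotypes to a ground-truth network
#'
#' Transforms a healthy ground-truth network into a damaged one by applying,
#' in order: loss of whole primary neurites at the soma, distal pruning of a
#' commanded fraction of the then-remaining total neurite length,
#' detachment of neurites from their soma, fragmentation of neurites by
#' removing gap segments along their arclength, and soma swelling. Pruning
#' removes exactly the commanded fraction of length (up to exhaustion of
#' free neurite tips), so the remaining length is `(1 - prune_fraction)`
#' times the pre-pruning length; fragmentation then splits edges and raises
#' the component count without changing soma radii; swelling changes only
#' soma radii. All-zero parameters with unit swell return the input
#' untouched.
#'
#' @param truth a ground-truth object from [generate_network()].
#' @param d a [damage_params()].
#' @param seed RNG seed for the damage draws (defaults to the generator seed
#'   plus one).
#' @return A damaged ground-truth object; its `damage_report` records the pruned
#'   length, number of introduced gaps, detached and lost neurites, and the
#'   swell factor.
#' @export
apply_damage <- function(truth, d, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(d, "damage_params"))
  if (is_identity_damage(d)) return(truth)
  if (is.null(seed)) seed <- truth$config$seed + 1L
  with_seed(seed, apply_damage_impl(truth, d))
}

apply_damage_impl <- function(truth, d) {
  g <- truth$graph
  somas <- truth$somas
  report <- list(pruned_length_um = 0, n_gaps = 0L, n_detached = 0L,
                 n_neurites_lost = 0L, soma_swell_factor = d$soma_swell_factor)

  ## 1. whole-neurite loss at the soma --------------------------------------
  if (d$neurite_loss_per_soma > 0 && nrow(somas) > 0) {
    drop <- integer(0)
    for (i in seq_len(nrow(somas))) {
      sn <- somas$node[i]
      inc <- which(g$edges$from == sn | g$edges$to == sn)
      inc <- setdiff(inc, drop)
      if (length(inc) == 0) next
      k <- min(rpois(1, d$neurite_loss_per_soma), length(inc))
      if (k > 0) {
        drop <- c(drop, sample(inc, k))
        report$n_neurites_lost <- report$n_neurites_lost + k
      }
    }
    if (length(drop)) {
      g <- sg_remove_edges(g, drop)
      somas$node <- match_soma_nodes(g, somas)
      # orphaned pieces no longer attached to any soma vanish with the neurite
      soma_comps <- unique(g$node_components[somas$node])
      orphan <- which(!(g$components %in% soma_comps))
      if (length(orphan)) {
        g <- sg_remove_edges(g, orphan)
        somas$node <- match_soma_nodes(g, somas)
      }
    }
  }

  ## 2. distal pruning of a length fraction ---------------------------------
  if (d$prune_fraction > 0 && nrow(g$edges) > 0) {
    target <- d$prune_fraction * total_length(g)
    removed <- 0
    while (target - removed > 1e-9) {
      deg <- sg_degree(g)
      term_to <- deg[g$edges$to] == 1 & g$nodes$kind[g$edges$to] != "soma"
      term_from <- deg[g$edges$from] == 1 & g$nodes$kind[g$edges$from] != "soma"
      term <- which(term_to | term_from)
      if (length(term) == 0) break
      e <- if (length(term) == 1) term else sample(term, 1)
      len <- g$edges$length[e]
      need <- target - removed
      if (len <= need + 1e-9) {
        removed <- removed + len
        g <- sg_remove_edges(g, e)
        somas$node <- match_soma_nodes(g, somas)
      } else {
        p <- g$polylines[[e]]
        if (term_to[e]) {
          q <- clip_polyline(p, len - need)
          g$polylines[[e]] <- q
          g$nodes[g$edges$to[e], c("x", "y", "z")] <- q[nrow(q), ]
        } else {
          q <- clip_polyline(p[nrow(p):1, , drop = FALSE], len - need)
          g$polylines[[e]] <- q[nrow(q):1, , drop = FALSE]
          g$nodes[g$edges$from[e], c("x", "y", "z")] <- q[nrow(q), ]
        }
        g <- sg_refresh(g)
        removed <- target
      }
    }
    report$pruned_length_um <- removed
    g <- sg_dissolve_slabs(g)
    somas$node <- match_soma_nodes(g, somas)
  }

  ## 3. detachment of neurites from their soma ------------------------------
  if (d$detach_prob > 0 && nrow(somas) > 0) {
    for (i in seq_len(nrow(somas))) {
      sn <- somas$node[i]
      inc <- which(g$edges$from == sn | g$edges$to == sn)
      for (e in inc) {
        if (runif(1) >= d$detach_prob) next
        p <- g$polylines[[e]]
        len <- g$edges$length[e]
        cut <- min(2, len / 2)
        if (g$edges$from[e] == sn) {
          q <- subseg_polyline(p, cut, len)
          newid <- nrow(g$nodes) + 1L
          g$nodes <- rbind(g$nodes, data.frame(
            id = newid, x = q[1, 1], y = q[1, 2], z = q[1, 3],
            kind = "end", stringsAsFactors = FALSE))
          g$edges$from[e] <- newid
          g$polylines[[e]] <- q
        } else {
          q <- subseg_polyline(p, 0, len - cut)
          newid <- nrow(g$nodes) + 1L
          g$nodes <- rbind(g$nodes, data.frame(
            id = newid, x = q[nrow(q), 1], y = q[nrow(q), 2], z = q[nrow(q), 3],
            kind = "end", stringsAsFactors = FALSE))
          g$edges$to[e] <- newid
          g$polylines[[e]] <- q
        }
        report$n_detached <- report$n_detached + 1L
      }
    }
    g <- sg_refresh(g)
  }

  ## 4. fragmentation: remove gap segments along edges -----------------------
  if (d$fragment_rate_per_um > 0 && nrow(g$edges) > 0) {
    frag <- fragment_graph(g, d$fragment_rate_per_um, d$gap_length_um)
    g <- frag$g
    report$n_gaps <- frag$n_gaps
    somas$node <- match_soma_nodes(g, somas)
  }

  ## 5. soma swelling --------------------------------------------------------
  somas$radius <- somas$radius * d$soma_swell_factor

  g <- sg_refresh(g)
  somas$node <- match_soma_nodes(g, somas)
  out <- new_ground_truth(g, somas, truth$nuclei, truth$config,
                          damage_report = report)
  out
}

# Soma graph-node ids can shift when nodes are renumbered; recover them by
# exact position match.
match_soma_nodes <- function(g, somas) {
  if (nrow(somas) == 0) return(integer(0))
  idx <- integer(nrow(somas))
  sn <- which(g$nodes$kind == "soma")
  for (i in seq_len(nrow(somas))) {
    d2 <- (g$nodes$x[sn] - somas$x[i])^2 + (g$nodes$y[sn] - somas$y[i])^2 +
      (g$nodes$z[sn] - somas$z[i])^2
    idx[i] <- sn[which.min(d2)]
  }
  idx
}

# Sub-polyline between arclengths a and b (from the first vertex).
subseg_polyline <- function(p, a, b) {
  q <- clip_polyline(p, b)
  if (a <= 1e-12) return(q)
  lb <- polyline_length(q)
  r <- clip_polyline(q[nrow(q):1, , drop = FALSE], lb - a)
  r[nrow(r):1, , drop = FALSE]
}

# Remove Poisson-placed gap segments along every edge; rebuilds the graph.
fragment_graph <- function(g, rate, gap_len) {
  nodes <- g$nodes
  new_edges <- list()
  new_polys <- list()
  n_gaps <- 0L
  add_break_node <- function(pos) {
    nodes <<- rbind(nodes, data.frame(id = nrow(nodes) + 1L, x = pos[1],
                                      y = pos[2], z = pos[3], kind = "end",
                                      stringsAsFactors = FALSE))
    nrow(nodes)
  }
  for (e in seq_len(nrow(g$edges))) {
    p <- g$polylines[[e]]
    len <- g$edges$length[e]
    k <- rpois(1, rate * len)
    if (k == 0 || len <= 1e-9) {
      new_edges[[length(new_edges) + 1L]] <- c(g$edges$from[e], g$edges$to[e])
      new_polys[[length(new_polys) + 1L]] <- p
      next
    }
    centers <- sort(runif(k, 0, len))
    iv <- cbind(pmax(0, centers - gap_len / 2), pmin(len, centers + gap_len / 2))
    # merge overlapping gaps
    merged <- list(iv[1, ])
    if (k > 1) for (i in 2:k) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
      else merged[[length(merged) + 1L]] <- iv[i, ]
    }
    n_gaps <- n_gaps + length(merged)
    gaps <- do.call(rbind, merged)
    kept <- list()
    pos <- 0
    for (i in seq_len(nrow(gaps))) {
      if (gaps[i, 1] - pos > 0.05) kept[[length(kept) + 1L]] <- c(pos, gaps[i, 1])
      pos <- gaps[i, 2]
    }
    if (len - pos > 0.05) kept[[length(kept) + 1L]] <- c(pos, len)
    for (i in seq_along(kept)) {
      a <- kept[[i]][1]; b <- kept[[i]][2]
      q <- subseg_polyline(p, a, b)
      from <- if (a <= 1e-9) g$edges$from[e] else add_break_node(q[1, ])
      to <- if (b >= len - 1e-9) g$edges$to[e] else add_break_node(q[nrow(q), ])
      new_edges[[length(new_edges) + 1L]] <- c(from, to)
      new_polys[[length(new_polys) + 1L]] <- q
    }
  }
  edges <- if (length(new_edges)) {
    em <- do.call(rbind, new_edges)
    data.frame(from = em[, 1], to = em[, 2])
  } else data.frame(from = integer(0), to = integer(0))
  g2 <- spatial_graph(nodes, edges, new_polys, mode = g$mode)
  g2 <- sg_drop_isolated(g2)
  list(g = sg_refresh(g2), n_gaps = n_gaps)
}
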