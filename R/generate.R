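#' Generate a ground-truthed synthetic neuronal network
#'
#' Builds the true geometry of a cultured neuronal network inside the
#' configured volume: somas placed without overlap, tortuous branched
#' neurites grown as constant-step random walks with reflective boundaries
#' and Poisson branching along arclength, and (optionally) inter-neuron
#' contact edges wherever polylines of different neurons pass within one
#' tube diameter — these contacts are what make healthy control networks
#' form one large connected component. All stochastic steps run from the
#' seed recorded in `config`, so identical configs give identical output.
#'
#' Neurite length is commanded as arclength from the soma centre, so a
#' single straight neurite of commanded length 50 contributes exactly
#' 50 um of true length.
#'
#' @param config a [sim_config()].
#' @return An object of class `ground_truth`: list with `graph` (a
#'   [spatial_graph] whose soma nodes carry the culture's true topology),
#'   `somas` (data frame: centre, radius, hollow flag, graph node id),
#'   `nuclei` (data frame of all nuclei with NeuN labels),
#'   `component_partition` (per-edge component id), `neurite_counts`
#'   (per-soma primary-neurite count) and the config echo.
#' @seealso [apply_damage()], [render_stack()]
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, generate_network_impl(config))
}

generate_network_impl <- function(config) {
  vol <- config$volume_um
  n <- config$n_neurons

  if (n == 0) {
    g <- spatial_graph(mode = "skeleton")
    return(new_ground_truth(g, empty_somas(), empty_nuclei(), config))
  }

  ## --- soma placement: rejection sampling with non-overlap ----------------
  radii <- pmax(2, rnorm(n, config$soma_diameter_um / 2,
                         config$soma_diameter_sd_um / 2))
  centers <- matrix(NA_real_, n, 3)
  max_tries <- 2000L * n
  tries <- 0L
  placed <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement failure: volume too small to place ", n,
           " non-overlapping somas")
    r <- radii[placed + 1L]
    if (any(vol < 2 * r))
      stop("placement failure: volume too small for soma of radius ", r)
    cand <- runif(3, min = r, max = vol - r)
    ok <- TRUE
    if (placed > 0) {
      d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
      ok <- all(d > radii[seq_len(placed)] + r + 1)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  hollow <- runif(n) < config$hollow_soma_fraction

  ## --- grow neurites ------------------------------------------------------
  acc <- new.env(parent = emptyenv())
  acc$npos <- list()   # node positions
  acc$nkind <- character(0)
  acc$edges <- list()  # list(from, to, poly)
  add_node <- function(pos, kind) {
    acc$npos[[length(acc$npos) + 1L]] <- pos
    acc$nkind <- c(acc$nkind, kind)
    length(acc$npos)
  }
  add_edge <- function(from, to, poly) {
    acc$edges[[length(acc$edges) + 1L]] <- list(from = from, to = to, poly = poly)
  }

  neuron_of_edge <- integer(0) # filled as edges are added
  grow <- function(from_node, start, dir, L, depth, neuron) {
    pts <- matrix(start, 1, 3)
    remaining <- L
    branch_at <- integer(0)
    branch_dir <- list()
    branch_len <- numeric(0)
    dir <- unit3(dir)
    while (remaining > 1e-9) {
      s <- min(config$step_um, remaining)
      if (config$tortuosity > 0)
        dir <- unit3(dir + config$tortuosity * rnorm(3))
      nxt <- pts[nrow(pts), ] + s * dir
      # reflective boundaries
      for (ax in 1:3) {
        if (nxt[ax] < 0) { nxt[ax] <- -nxt[ax]; dir[ax] <- -dir[ax] }
        if (nxt[ax] > vol[ax]) { nxt[ax] <- 2 * vol[ax] - nxt[ax]; dir[ax] <- -dir[ax] }
        nxt[ax] <- min(max(nxt[ax], 0), vol[ax])
      }
      pts <- rbind(pts, nxt)
      remaining <- remaining - s
      if (depth < 4 && remaining > config$step_um &&
          runif(1) < config$branch_prob_per_um * s) {
        branch_at <- c(branch_at, nrow(pts))
        # branches diverge forward at a moderate angle from the parent
        perp <- rnorm(3)
        perp <- unit3(perp - sum(perp * dir) * dir)
        ang <- runif(1, pi / 6, pi / 2.8)
        branch_dir[[length(branch_dir) + 1L]] <-
          unit3(cos(ang) * dir + sin(ang) * perp)
        branch_len <- c(branch_len, remaining * runif(1, 0.4, 0.8))
      }
    }
    # split polyline at branch vertices; spawn children
    cuts <- sort(unique(branch_at))
    cuts <- cuts[cuts > 1 & cuts < nrow(pts)]
    bounds <- c(1, cuts, nrow(pts))
    prev_node <- from_node
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]; b <- bounds[i + 1]
      endkind <- if (b == nrow(pts)) "end" else "branch"
      nd <- add_node(pts[b, ], endkind)
      add_edge(prev_node, nd, pts[a:b, , drop = FALSE])
      neuron_of_edge[length(acc$edges)] <<- neuron
      if (endkind == "branch") {
        k <- which(cuts == b)
        grow(nd, pts[b, ], branch_dir[[k]], branch_len[k], depth + 1, neuron)
      }
      prev_node <- nd
    }
  }

  soma_node <- integer(n)
  for (i in seq_len(n)) {
    soma_node[i] <- add_node(centers[i, ], "soma")
    for (k in seq_len(config$neurites_per_soma)) {
      L <- max(config$step_um,
               rnorm(1, config$neurite_length_um, config$neurite_length_sd_um))
      grow(soma_node[i], centers[i, ], unit3(rnorm(3)), L, 0L, i)
    }
  }

  nodes <- data.frame(x = vapply(acc$npos, `[`, numeric(1), 1),
                      y = vapply(acc$npos, `[`, numeric(1), 2),
                      z = vapply(acc$npos, `[`, numeric(1), 3),
                      kind = acc$nkind, stringsAsFactors = FALSE)
  edges <- data.frame(from = vapply(acc$edges, function(e) e$from, integer(1)),
                      to = vapply(acc$edges, function(e) e$to, integer(1)))
  polylines <- lapply(acc$edges, function(e) e$poly)
  g <- spatial_graph(nodes, edges, polylines, mode = "skeleton")

  ## --- inter-neuron contact edges ----------------------------------------
  if (config$connect && n > 1) {
    g <- add_contact_edges(g, neuron_of_edge, 2 * config$neurite_radius_um)
  }

  ## --- nuclei -------------------------------------------------------------
  nuc_r <- config$nucleus_diameter_um / 2
  nuclei <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                       radius = pmin(nuc_r, radii * 0.8), neun = TRUE)
  nb <- config$n_background_nuclei
  if (nb > 0) {
    bg <- matrix(NA_real_, nb, 3)
    got <- 0L
    btries <- 0L
    while (got < nb && btries < 5000L * nb) {
      btries <- btries + 1L
      cand <- runif(3, min = nuc_r, max = vol - nuc_r)
      d <- sqrt(colSums((t(centers) - cand)^2))
      if (all(d > radii + nuc_r + 1)) {
        got <- got + 1L
        bg[got, ] <- cand
      }
    }
    if (got > 0)
      nuclei <- rbind(nuclei,
                      data.frame(x = bg[1:got, 1], y = bg[1:got, 2],
                                 z = bg[1:got, 3], radius = nuc_r, neun = FALSE))
  }

  somas <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                      radius = radii, hollow = hollow, node = soma_node)
  new_ground_truth(g, somas, nuclei, config)
}

empty_somas <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             radius = numeric(0), hollow = logical(0), node = integer(0))
}

empty_nuclei <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             radius = numeric(0), neun = logical(0))
}

new_ground_truth <- function(graph, somas, nuclei, config, damage_report = NULL) {
  counts <- if (nrow(somas)) sg_degree(graph)[somas$node] else integer(0)
  structure(list(graph = graph, somas = somas, nuclei = nuclei,
                 component_partition = graph$components,
                 neurite_counts = counts,
                 config = config,
                 damage_report = damage_report),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d somas, %d nuclei, total length %.1f um, %d components\n",
              nrow(x$somas), nrow(x$nuclei), total_length(x$graph),
              if (length(x$graph$node_components)) max(x$graph$node_components) else 0))
  if (!is.null(x$damage_report)) {
    r <- x$damage_report
    cat(sprintf("damage: pruned %.1f um, %d gaps, %d detached, %d neurites lost, swell x%.2f\n",
                r$pruned_length_um, r$n_gaps, r$n_detached, r$n_neurites_lost,
                r$soma_swell_factor))
  }
  invisible(x)
}

# Insert contact edges where polyline vertices of different neurons pass
# within `thr` of each other. Grid-hashed neighbour search; greedy by
# ascending distance, at most two contacts per neuron pair.
add_contact_edges <- function(g, neuron_of_edge, thr, max_per_pair = 2L) {
  np <- lapply(seq_along(g$polylines), function(e) {
    p <- resample_polyline(g$polylines[[e]], thr / 2)
    cbind(p, e, seq_len(nrow(p)))
  })
  pts <- do.call(rbind, np)
  if (is.null(pts) || nrow(pts) < 2) return(g)
  colnames(pts) <- c("x", "y", "z", "edge", "vert")
  neuron <- neuron_of_edge[pts[, "edge"]]
  cell <- floor(pts[, 1:3] / thr)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cellmap <- split(seq_len(nrow(pts)), key)

  cand <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ci in names(cellmap)) {
    idx <- cellmap[[ci]]
    base <- as.numeric(strsplit(ci, " ")[[1]])
    neigh <- unlist(lapply(seq_len(nrow(offs)), function(o) {
      cellmap[[paste(base[1] + offs[o, 1], base[2] + offs[o, 2],
                     base[3] + offs[o, 3])]]
    }), use.names = FALSE)
    for (i in idx) {
      js <- neigh[neigh > i & neuron[neigh] != neuron[i]]
      if (length(js) == 0) next
      d <- sqrt((pts[js, 1] - pts[i, 1])^2 + (pts[js, 2] - pts[i, 2])^2 +
                (pts[js, 3] - pts[i, 3])^2)
      hit <- js[d <= thr]
      for (h in seq_along(hit))
        cand[[length(cand) + 1L]] <- c(i, hit[h], d[match(hit[h], js)])
    }
  }
  if (length(cand) == 0) return(g)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]

  pair_count <- new.env(parent = emptyenv())
  accepted <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    key <- paste(sort(c(neuron[i], neuron[j])), collapse = "-")
    cnt <- get0(key, envir = pair_count, ifnotfound = 0L)
    if (cnt >= max_per_pair) next
    assign(key, cnt + 1L, envir = pair_count)
    accepted[[length(accepted) + 1L]] <- r
  }
  if (length(accepted) == 0) return(g)
  acc <- cand[unlist(accepted), , drop = FALSE]

  # contact points are identified on resampled polylines; map back to the
  # nearest original vertex of the edge, splitting there
  contact_nodes <- integer(nrow(acc) * 2)
  ptrow <- function(k) pts[k, ]
  for (r in seq_len(nrow(acc))) {
    for (side in 1:2) {
      k <- acc[r, side]
      e <- pts[k, "edge"]
      target <- pts[k, 1:3]
      # edge indices may have changed through splits: polylines only get
      # shorter at the split edge; find current edge containing the target
      best <- find_vertex_near(g, target)
      sp <- sg_split_edge(g, best$edge, best$vertex)
      g <- sp$g
      contact_nodes[(r - 1) * 2 + side] <- sp$node
    }
  }
  for (r in seq_len(nrow(acc))) {
    a <- contact_nodes[(r - 1) * 2 + 1]
    b <- contact_nodes[(r - 1) * 2 + 2]
    if (a != b) g <- sg_add_edge(g, a, b)
  }
  sg_refresh(g)
}

# Nearest polyline vertex over all edges to a physical point.
find_vertex_near <- function(g, p) {
  best_d <- Inf; best_e <- 1L; best_v <- 1L
  for (e in seq_along(g$polylines)) {
    q <- g$polylines[[e]]
    d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2
    m <- which.min(d2)
    if (d2[m] < best_d) { best_d <- d2[m]; best_e <- e; best_v <- m }
  }
  list(edge = best_e, vertex = best_v, dist = sqrt(best_d))
}
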