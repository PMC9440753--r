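# Shared fixtures: hand-built graphs, manual ground truths and reference
# implementations used as independent oracles.

# Straight single-edge graph from a to b (defaults: the 3-4-5 style line).
line_graph <- function(a = c(0, 0, 0), b = c(50, 0, 0)) {
  nodes <- data.frame(x = c(a[1], b[1]), y = c(a[2], b[2]), z = c(a[3], b[3]),
                      kind = "end")
  spatial_graph(nodes, data.frame(from = 1, to = 2), list(rbind(a, b)))
}

# Soma at `centre` with k straight radial neurites of length `len` (xy plane).
star_graph <- function(k, centre = c(50, 50, 50), len = 20) {
  if (k == 0) {
    nodes <- data.frame(x = centre[1], y = centre[2], z = centre[3],
                        kind = "soma")
    return(spatial_graph(nodes, NULL, list()))
  }
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  tips <- cbind(centre[1] + len * cos(th), centre[2] + len * sin(th), centre[3])
  nodes <- data.frame(x = c(centre[1], tips[, 1]), y = c(centre[2], tips[, 2]),
                      z = c(centre[3], tips[, 3]),
                      kind = c("soma", rep("end", k)))
  polys <- lapply(seq_len(k), function(i) rbind(centre, tips[i, ]))
  spatial_graph(nodes, data.frame(from = 1, to = 1 + seq_len(k)), polys)
}

# Closed ring of given circumference as a single self-loop edge.
ring_graph <- function(circumference, centre = c(50, 50, 10), n_pts = 41) {
  r <- circumference / (2 * pi)
  th <- seq(0, 2 * pi, length.out = n_pts)
  p <- cbind(centre[1] + r * cos(th), centre[2] + r * sin(th), centre[3])
  nodes <- data.frame(x = p[1, 1], y = p[1, 2], z = p[1, 3], kind = "end")
  spatial_graph(nodes, data.frame(from = 1, to = 1), list(p))
}

# Ground truth assembled by hand from parts (bypasses the generator).
manual_truth <- function(graph = spatial_graph(),
                         somas = NULL, nuclei = NULL, config = NULL) {
  if (is.null(somas))
    somas <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        radius = numeric(0), hollow = logical(0),
                        node = integer(0))
  if (is.null(nuclei))
    nuclei <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         radius = numeric(0), neun = logical(0))
  structure(list(graph = graph, somas = somas, nuclei = nuclei,
                 component_partition = graph$components,
                 neurite_counts = integer(0), config = config,
                 damage_report = NULL),
            class = "ground_truth")
}

# Clean (noise- and blur-free) rendering config.
clean_config <- function(volume_um, seed = 1, ...) {
  sim_config(volume_um = volume_um, n_neurons = 0, psf_sigma_um = c(0, 0, 0),
             noise_gaussian_sd = 0, noise_poisson_scale = 0, seed = seed, ...)
}

# Minimum distance between polylines of non-adjacent edges (um). Used to
# enforce the "no crossings closer than ..." precondition of the geometry
# recovery tests.
min_edge_separation <- function(g, ds = 0.5) {
  ne <- nrow(g$edges)
  if (ne < 2) return(Inf)
  pts <- lapply(seq_len(ne), function(e)
    neurotrace3d:::resample_polyline(g$polylines[[e]], ds))
  best <- Inf
  for (i in seq_len(ne - 1)) {
    for (j in (i + 1):ne) {
      if (length(intersect(c(g$edges$from[i], g$edges$to[i]),
                           c(g$edges$from[j], g$edges$to[j])))) next
      A <- pts[[i]]; B <- pts[[j]]
      for (r in seq_len(nrow(A))) {
        d <- min(sqrt((B[, 1] - A[r, 1])^2 + (B[, 2] - A[r, 2])^2 +
                        (B[, 3] - A[r, 3])^2))
        if (d < best) best <- d
      }
    }
  }
  best
}

# Independent reference: 26-connectivity component labeling by BFS in plain R
# (used as the brute-force oracle for connectedness).
r_label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        p <- co + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# Geometry-recovery fixture: sparse single-neurite neurons, tube radius
# 1.5 um, in a 64 x 64 x 40 um volume; seeds are filtered so no two
# non-adjacent centrelines pass closer than `min_sep`.
recovery_config <- function(seed) {
  sim_config(volume_um = c(64, 64, 40), n_neurons = 4,
             neurite_radius_um = 1.5, soma_diameter_um = 3.5,
             soma_diameter_sd_um = 0, neurites_per_soma = 1,
             neurite_length_um = 50, neurite_length_sd_um = 8,
             branch_prob_per_um = 0.005, hollow_soma_fraction = 0,
             tortuosity = 0.12, connect = FALSE,
             psf_sigma_um = c(0, 0, 0), noise_gaussian_sd = 0,
             noise_poisson_scale = 0, seed = seed)
}

recovery_truths <- function(n_stacks, min_sep = 4, max_seed = 200) {
  out <- list()
  seed <- 0
  while (length(out) < n_stacks && seed < max_seed) {
    seed <- seed + 1
    cfg <- recovery_config(seed)
    tr <- generate_network(cfg)
    if (min_edge_separation(tr$graph) < min_sep) next
    out[[length(out) + 1L]] <- list(config = cfg, truth = tr)
  }
  out
}
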