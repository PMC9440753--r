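#' Count neurite branching points
#'
#' Nodes of degree 3 or more, excluding soma nodes. Branch-point counts at
#' neurite crossings are known to be inflated by tracing errors, so treat
#' this measure with care (see the package vignette).
#'
#' @param g a [spatial_graph].
#' @return Integer count.
#' @export
count_branch_points <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  deg <- sg_degree(g)
  sum(deg >= 3 & g$nodes$kind != "soma")
}

#' Count neurite ending points
#'
#' Nodes of degree 1, excluding soma nodes.
#'
#' @param g a [spatial_graph].
#' @return Integer count.
#' @export
count_end_points <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  deg <- sg_degree(g)
  sum(deg == 1 & g$nodes$kind != "soma")
}

#' Neurites per soma by Sholl sphere
#'
#' Counts the connected crossings of a sphere of radius `radius_um`
#' (default 8 um) centred on the soma by the edges of the soma's component:
#' every transition of the (densely resampled) centreline geometry between
#' the inside and the outside of the sphere counts one crossing. A neurite
#' that leaves and re-enters therefore counts twice, while branching beyond
#' the sphere adds nothing. The count is invariant to subdividing edges.
#'
#' @param g a [spatial_graph] containing the soma.
#' @param soma_node node id of a soma node in `g`.
#' @param radius_um Sholl sphere radius.
#' @param ds_um resampling step for the crossing test.
#' @return Integer crossing count (0 for an isolated soma).
#' @export
neurites_per_soma <- function(g, soma_node, radius_um = 8, ds_um = 0.25) {
  stopifnot(inherits(g, "spatial_graph"))
  if (soma_node < 1 || soma_node > nrow(g$nodes) ||
      g$nodes$kind[soma_node] != "soma")
    stop("soma_node is not a soma node of the graph")
  cen <- as.numeric(g$nodes[soma_node, c("x", "y", "z")])
  eidx <- sg_component_edges(g, soma_node)
  if (length(eidx) == 0) return(0L)
  r2 <- radius_um^2
  n_cross <- 0L
  for (e in eidx) {
    p <- resample_polyline(g$polylines[[e]], ds_um)
    inside <- (p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2 +
      (p[, 3] - cen[3])^2 < r2
    n_cross <- n_cross + sum(diff(inside) != 0)
  }
  as.integer(n_cross)
}

#' Count neurite-growing neurons
#'
#' Number of somas with at least one neurite crossing their Sholl sphere —
#' the viable, neurite-growing neurons. Cells without growing neurites are
#' excluded by definition.
#'
#' @param neurite_counts integer vector of per-soma neurite counts (see
#'   [neurites_per_soma()]).
#' @return Integer count.
#' @export
count_neurite_growing <- function(neurite_counts) {
  sum(neurite_counts >= 1)
}

#' Network volume
#'
#' Foreground voxel count times voxel volume (at the reference spacing
#' 0.33 x 0.33 x 0.5 um a voxel is 0.05445 um^3). Conventionally measured
#' on the hole-filled neurite mask.
#'
#' @param mask a [binary_mask].
#' @return Volume in cubic micrometres.
#' @export
network_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$spacing_um)
}

#' Network connectedness
#'
#' The fraction (in percent) of the network's volume or length that belongs
#' to its largest connected component — 100 exactly when the network is a
#' single component. For a [binary_mask] the basis is volume
#' (26-connectivity component labeling); for a [spatial_graph] the basis is
#' length (graph connectivity). Undefined (error) for an empty network.
#'
#' @param x a [binary_mask] or [spatial_graph].
#' @param basis `"volume"` (masks) or `"length"` (graphs); defaults to the
#'   basis matching the input.
#' @return Percentage in (0, 100].
#' @export
connectedness <- function(x, basis = NULL) {
  if (inherits(x, "binary_mask")) {
    if (!is.null(basis) && basis != "volume")
      stop("a voxel mask supports only the volume basis")
    if (!any(x$voxels)) stop("connectedness undefined for an empty network")
    labs <- cpp_label3d(x$voxels, dim(x$voxels), 26L)
    sizes <- tabulate(labs[labs > 0])
    return(100 * max(sizes) / sum(sizes))
  }
  if (inherits(x, "spatial_graph")) {
    if (!is.null(basis) && basis != "length")
      stop("a spatial graph supports only the length basis")
    if (nrow(x$edges) == 0) stop("connectedness undefined for an empty network")
    lens <- tapply(x$edges$length, x$components, sum)
    return(100 * max(lens) / sum(lens))
  }
  stop("x must be a binary_mask or spatial_graph")
}

#' Percent reduction between group means
#'
#' `100 (control - treated) / control`, rounded half away from zero to an
#' integer — the convention behind reported figures such as a 56% length
#' reduction from mean 10,500 to 4600 um.
#'
#' @param control_mean control group mean (> 0).
#' @param treated_mean treated group mean.
#' @return Integer-valued percentage.
#' @export
percent_reduction <- function(control_mean, treated_mean) {
  if (!is.finite(control_mean) || control_mean <= 0)
    stop("control_mean must be positive")
  round_half_away(100 * (control_mean - treated_mean) / control_mean)
}

#' Assemble the per-sample network metrics record
#'
#' Gathers every quantified measure for one sample into a one-row data
#' frame: total length, branch and end point counts, soma count, per-soma
#' neurite statistics, neurite-growing neuron count, nuclei count, network
#' volume, and connectedness on both bases.
#'
#' @param g a traced [spatial_graph] (after [assign_somas()]).
#' @param mask the hole-filled neurite [binary_mask] (optional; volume and
#'   volume-basis connectedness become `NA` without it).
#' @param n_nuclei total nuclei count (optional).
#' @param sholl_radius_um Sholl sphere radius for neurites per soma.
#' @return A one-row data frame of class `network_metrics`.
#' @export
network_metrics <- function(g, mask = NULL, n_nuclei = NA_integer_,
                            sholl_radius_um = 8) {
  stopifnot(inherits(g, "spatial_graph"))
  soma_nodes <- which(g$nodes$kind == "soma")
  counts <- vapply(soma_nodes, function(s)
    neurites_per_soma(g, s, sholl_radius_um), integer(1))
  out <- data.frame(
    total_length_um = total_length(g),
    n_branch_points = count_branch_points(g),
    n_end_points = count_end_points(g),
    n_somas = length(soma_nodes),
    neurites_per_soma_mean = if (length(counts)) mean(counts) else NA_real_,
    n_neurite_growing_neurons = count_neurite_growing(counts),
    n_nuclei = n_nuclei,
    volume_um3 = if (is.null(mask)) NA_real_ else network_volume(mask),
    connectedness_volume_pct = if (is.null(mask) || !any(mask$voxels))
      NA_real_ else connectedness(mask),
    connectedness_length_pct = if (nrow(g$edges) == 0) NA_real_
      else connectedness(g),
    mode = g$mode,
    sholl_radius_um = sholl_radius_um,
    stringsAsFactors = FALSE)
  class(out) <- c("network_metrics", "data.frame")
  attr(out, "neurites_per_soma") <- counts
  out
}
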