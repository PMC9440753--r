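#' Trace a neuronal network from a multichannel stack
#'
#' Runs the full reconstruction chain on an [image_stack]: channel merge
#' (neurite + NeuN) in soma-rooted mode or curvature-driven diffusion in
#' skeleton mode, Gaussian smoothing, binarization, 3D hole filling,
#' skeletonization, graph extraction, spur pruning, loop removal, gap
#' bridging (soma-rooted mode only, emulating seed-based tracers) and soma
#' assignment from the NeuN-masked DAPI channel.
#'
#' The two modes reproduce the contract of the two tracing philosophies
#' compared in the workflow: `soma_rooted` keeps only components that
#' contain a soma and bridges small gaps; `skeleton` keeps every component
#' including disconnected fragments and does not bridge.
#'
#' @param stack an [image_stack] with channels `neurite`, `NeuN`, `DAPI`
#'   (names configurable).
#' @param mode `"soma_rooted"` or `"skeleton"`.
#' @param neurite_channel,neun_channel,dapi_channel channel names.
#' @param smooth_sigma_um Gaussian smoothing sigma (default 0.33 um, one xy
#'   voxel at the reference spacing).
#' @param threshold binarization threshold; `NULL` uses Otsu.
#' @param cdd_iter curvature-driven-diffusion iterations applied in
#'   skeleton mode before smoothing (0 disables).
#' @param spur_um spur-pruning threshold.
#' @param loop_um loop-collapse circumference threshold.
#' @param max_gap_um gap-bridging limit (soma-rooted mode).
#' @param max_angle_deg gap-bridging angle gate.
#' @param detect use [detect_somas()] on the NeuN-masked DAPI channel
#'   (`TRUE`), or pass `somas` explicitly.
#' @param somas optional soma data frame overriding detection.
#' @param soma_diameter_um expected soma diameter for detection.
#' @param neun_threshold NeuN masking threshold.
#' @return List of class `trace_result`: `graph` (a [spatial_graph]),
#'   `mask` (hole-filled [binary_mask]), `somas`, and the processed
#'   `stack`.
#' @export
trace_network <- function(stack, mode = c("soma_rooted", "skeleton"),
                          neurite_channel = "neurite",
                          neun_channel = "NeuN", dapi_channel = "DAPI",
                          smooth_sigma_um = 0.33, threshold = NULL,
                          cdd_iter = 0L, spur_um = 2, loop_um = 40,
                          max_gap_um = 4, max_angle_deg = 60,
                          detect = TRUE, somas = NULL,
                          soma_diameter_um = 12, neun_threshold = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))

  work <- "trace_input"
  if (mode == "soma_rooted" && neun_channel %in% names(stack$channels)) {
    stack <- merge_channels(stack, neurite_channel, neun_channel, name = work)
  } else {
    stack <- set_channel(stack, work,
                         rescale01(get_channel(stack, neurite_channel)))
    if (mode == "skeleton" && cdd_iter > 0)
      stack <- cdd_filter(stack, work, n_iter = cdd_iter)
  }
  if (smooth_sigma_um > 0)
    stack <- gaussian_smooth(stack, work, smooth_sigma_um)

  mask <- if (is.null(threshold)) binarize(stack, work, "otsu")
          else binarize(stack, work, "fixed", threshold = threshold)
  mask <- fill_holes(mask)

  skel <- skeletonize(mask)
  g <- skeleton_to_graph(skel)
  g <- prune_spurs(g, spur_um)
  g <- remove_loops(g, loop_um)
  if (mode == "soma_rooted") g <- bridge_gaps(g, max_gap_um, max_angle_deg)

  if (is.null(somas) && detect && mode == "soma_rooted" &&
      all(c(neun_channel, dapi_channel) %in% names(stack$channels))) {
    stack <- mask_nuclear_channel(stack, dapi_channel, neun_channel,
                                  neun_threshold)
    somas <- detect_somas(stack, "DAPI_masked", soma_diameter_um)
  }
  if (is.null(somas)) somas <- data.frame(x = numeric(0), y = numeric(0),
                                          z = numeric(0), radius = numeric(0))
  g <- assign_somas(g, somas, mode, fuse_radius_um = soma_diameter_um / 2)

  structure(list(graph = g, mask = mask, somas = somas, stack = stack),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat("trace_result\n")
  print(x$graph)
  cat(sprintf("somas: %d detected\n", nrow(x$somas)))
  invisible(x)
}

#' Trace and measure one sample
#'
#' Convenience wrapper running [trace_network()] followed by
#' [network_metrics()] (including the nuclei count from the DAPI channel
#' when present).
#'
#' @inheritParams trace_network
#' @param count_nuclei_channel DAPI channel used for the nuclei count
#'   (`NULL` skips the count).
#' @param nucleus_diameter_um expected nuclear diameter for the count.
#' @param sholl_radius_um Sholl sphere radius.
#' @param ... passed to [trace_network()].
#' @return A one-row [network_metrics()] data frame; the trace result is
#'   attached as attribute `trace`.
#' @export
analyze_stack <- function(stack, mode = "soma_rooted",
                          count_nuclei_channel = "DAPI",
                          nucleus_diameter_um = 8, sholl_radius_um = 8, ...) {
  tr <- trace_network(stack, mode = mode, ...)
  nn <- NA_integer_
  if (!is.null(count_nuclei_channel) &&
      count_nuclei_channel %in% names(stack$channels)) {
    nn <- count_nuclei(stack, count_nuclei_channel, nucleus_diameter_um)
  }
  m <- network_metrics(tr$graph, tr$mask, n_nuclei = nn,
                       sholl_radius_um = sholl_radius_um)
  attr(m, "trace") <- tr
  m
}
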