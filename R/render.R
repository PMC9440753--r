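#' Render a ground-truth network into a multichannel image stack
#'
#' Rasterizes the true geometry into the three channels of the emulated
#' staining: `neurite` (cytoskeletal marker; constant-radius tubes swept
#' along every centreline plus soma spheres, with the hollow fraction of
#' somas rendered as shells enclosing a dark cavity), `NeuN` (neuronal
#' nuclei only) and `DAPI` (all nuclei). A Gaussian PSF blur is applied per
#' channel, followed by signal-scaled Poisson noise and additive Gaussian
#' read noise. Rendering is deterministic given the config seed.
#'
#' @param truth a ground-truth object from [generate_network()] or [apply_damage()].
#' @param config a [sim_config()]; its volume must contain the geometry and
#'   normally matches the config the truth was generated with.
#' @return An [image_stack] with channels `neurite`, `NeuN`, `DAPI`.
#' @export
render_stack <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  validate_sim_config(config)
  dims <- pmax(1L, as.integer(round(config$volume_um / config$spacing_um)))
  g <- truth$graph
  if (nrow(g$nodes) > 0) {
    pos <- as.matrix(g$nodes[, c("x", "y", "z")])
    if (any(t(pos) < -1e-6) || any(t(pos) > config$volume_um + 1e-6))
      stop("extent mismatch: ground truth does not fit inside config volume")
  }
  sp <- config$spacing_um
  zero <- array(0, dims)

  ## neurite channel: tube sweep + soma spheres (shells when hollow)
  neurite <- zero
  if (nrow(g$edges) > 0) {
    ds <- min(sp) / 2
    samp <- do.call(rbind, lapply(g$polylines, resample_polyline, ds = ds))
    neurite <- cpp_stamp_spheres(neurite, dims, sp, samp,
                                 rep(config$neurite_radius_um, nrow(samp)),
                                 1.0, FALSE)
    dim(neurite) <- dims
  }
  if (nrow(truth$somas) > 0) {
    sc <- as.matrix(truth$somas[, c("x", "y", "z")])
    neurite <- cpp_stamp_spheres(neurite, dims, sp, sc, truth$somas$radius,
                                 1.0, FALSE)
    dim(neurite) <- dims
    hol <- which(truth$somas$hollow)
    if (length(hol)) {
      inner <- pmax(0, truth$somas$radius[hol] - config$shell_thickness_um)
      neurite <- cpp_stamp_spheres(neurite, dims, sp,
                                   sc[hol, , drop = FALSE], inner, 0, TRUE)
      dim(neurite) <- dims
    }
  }

  ## nuclear channels
  neun <- zero
  dapi <- zero
  if (nrow(truth$nuclei) > 0) {
    nc <- as.matrix(truth$nuclei[, c("x", "y", "z")])
    dapi <- cpp_stamp_spheres(dapi, dims, sp, nc, truth$nuclei$radius, 1.0, FALSE)
    dim(dapi) <- dims
    pos <- which(truth$nuclei$neun)
    if (length(pos)) {
      neun <- cpp_stamp_spheres(neun, dims, sp, nc[pos, , drop = FALSE],
                                truth$nuclei$radius[pos], 1.0, FALSE)
      dim(neun) <- dims
    }
  }

  chans <- list(neurite = neurite, NeuN = neun, DAPI = dapi)

  if (any(config$psf_sigma_um > 0)) {
    sig_vox <- config$psf_sigma_um / sp
    chans <- lapply(chans, function(a) {
      out <- cpp_gauss3d(a, dims, sig_vox)
      dim(out) <- dims
      out
    })
  }

  if (config$noise_poisson_scale > 0 || config$noise_gaussian_sd > 0) {
    chans <- with_seed(config$seed + 1009L, {
      lapply(chans, function(a) {
        if (config$noise_poisson_scale > 0) {
          a <- array(rpois(length(a), a * config$noise_poisson_scale) /
                       config$noise_poisson_scale, dims)
        }
        if (config$noise_gaussian_sd > 0) {
          a <- a + array(rnorm(length(a), 0, config$noise_gaussian_sd), dims)
        }
        pmax(a, 0)
      })
    })
  }

  stack <- image_stack(chans, sp)
  log_op(stack, "render_stack",
         list(seed = config$seed, volume_um = config$volume_um))
}
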