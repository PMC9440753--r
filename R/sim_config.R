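#' Configuration for the synthetic network generator
#'
#' Defines the virtual culture, staining and imaging conditions emulated by
#' [generate_network()] and [render_stack()]: a 255 x 255 x 100 um analysis
#' volume sampled at 0.33 x 0.33 x 0.5 um (the cropped confocal field the
#' workflow was designed around), ~12 um somas a fraction of which appear as
#' hollow shells in the neurite channel (cytoskeletal markers do not fill the
#' soma), tube-like neurites of roughly 1 um diameter growing as tortuous
#' branched random walks, NeuN-positive neuronal nuclei plus a few
#' NeuN-negative background nuclei in DAPI, and confocal-like PSF blur with
#' Gaussian read noise plus signal-scaled Poisson noise.
#'
#' @param volume_um physical extents (x, y, z) in micrometres.
#' @param spacing_um voxel spacing (x, y, z) in micrometres.
#' @param n_neurons number of neurons (somas) to place.
#' @param soma_diameter_um mean soma diameter.
#' @param soma_diameter_sd_um between-soma s.d. of the diameter.
#' @param hollow_soma_fraction fraction of somas rendered as shells in the
#'   neurite channel (0-1).
#' @param neurite_radius_um constant tube radius of rendered neurites.
#' @param neurites_per_soma number of primary neurites per soma.
#' @param neurite_length_um mean commanded neurite length (arclength from the
#'   soma centre).
#' @param neurite_length_sd_um s.d. of the commanded length.
#' @param branch_prob_per_um probability per micrometre of arclength that a
#'   growing neurite spawns a side branch.
#' @param tortuosity s.d. of the random direction perturbation per step
#'   (radians); 0 gives straight neurites.
#' @param step_um random-walk step length.
#' @param connect logical; create inter-neuron contact edges where polylines
#'   of different neurons pass within one tube diameter (drives the high
#'   connectedness of control networks).
#' @param n_background_nuclei number of NeuN-negative nuclei.
#' @param nucleus_diameter_um nuclear diameter (DAPI/NeuN spheres).
#' @param shell_thickness_um wall thickness of hollow soma shells.
#' @param psf_sigma_um Gaussian PSF sigma per axis in micrometres.
#' @param noise_gaussian_sd additive Gaussian read-noise s.d. (intensity
#'   units; 0 disables).
#' @param noise_poisson_scale photons per unit intensity for the Poisson
#'   component (0 disables).
#' @param seed RNG seed; identical seed and config give bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_network()], [render_stack()], [damage_params()]
#' @export
sim_config <- function(volume_um = c(255, 255, 100),
                       spacing_um = c(0.33, 0.33, 0.5),
                       n_neurons = 30,
                       soma_diameter_um = 12,
                       soma_diameter_sd_um = 1,
                       hollow_soma_fraction = 0.5,
                       neurite_radius_um = 0.5,
                       neurites_per_soma = 5,
                       neurite_length_um = 80,
                       neurite_length_sd_um = 20,
                       branch_prob_per_um = 0.02,
                       tortuosity = 0.25,
                       step_um = 2,
                       connect = TRUE,
                       n_background_nuclei = 5,
                       nucleus_diameter_um = 8,
                       shell_thickness_um = 1.5,
                       psf_sigma_um = c(0.2, 0.2, 0.6),
                       noise_gaussian_sd = 0.02,
                       noise_poisson_scale = 100,
                       seed = 1L) {
  cfg <- list(volume_um = as.numeric(volume_um),
              spacing_um = as.numeric(spacing_um),
              n_neurons = as.integer(n_neurons),
              soma_diameter_um = soma_diameter_um,
              soma_diameter_sd_um = soma_diameter_sd_um,
              hollow_soma_fraction = hollow_soma_fraction,
              neurite_radius_um = neurite_radius_um,
              neurites_per_soma = as.integer(neurites_per_soma),
              neurite_length_um = neurite_length_um,
              neurite_length_sd_um = neurite_length_sd_um,
              branch_prob_per_um = branch_prob_per_um,
              tortuosity = tortuosity,
              step_um = step_um,
              connect = isTRUE(connect),
              n_background_nuclei = as.integer(n_background_nuclei),
              nucleus_diameter_um = nucleus_diameter_um,
              shell_thickness_um = shell_thickness_um,
              psf_sigma_um = as.numeric(psf_sigma_um),
              noise_gaussian_sd = noise_gaussian_sd,
              noise_poisson_scale = noise_poisson_scale,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$volume_um) != 3 || any(cfg$volume_um <= 0))
    stop("volume_um must be 3 positive extents")
  if (length(cfg$spacing_um) != 3 || any(cfg$spacing_um <= 0))
    stop("spacing_um must be 3 positive values")
  if (cfg$n_neurons < 0) stop("n_neurons must be >= 0")
  if (cfg$hollow_soma_fraction < 0 || cfg$hollow_soma_fraction > 1)
    stop("hollow_soma_fraction must lie in [0, 1]")
  pos <- c(soma_diameter_um = cfg$soma_diameter_um,
           neurite_radius_um = cfg$neurite_radius_um,
           neurite_length_um = cfg$neurite_length_um,
           step_um = cfg$step_um,
           nucleus_diameter_um = cfg$nucleus_diameter_um,
           shell_thickness_um = cfg$shell_thickness_um)
  if (any(pos <= 0))
    stop("physical quantities must be positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  nonneg <- c(cfg$soma_diameter_sd_um, cfg$neurite_length_sd_um,
              cfg$branch_prob_per_um, cfg$tortuosity,
              cfg$n_background_nuclei, cfg$psf_sigma_um,
              cfg$noise_gaussian_sd, cfg$noise_poisson_scale,
              cfg$neurites_per_soma)
  if (any(nonneg < 0)) stop("rates, sigmas and counts must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %g x %g x %g um at %g x %g x %g um/voxel, %d neurons, seed %d\n",
              x$volume_um[1], x$volume_um[2], x$volume_um[3],
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
              x$n_neurons, x$seed))
  invisible(x)
}

#' Damage model parameters
#'
#' Parametrizes the morphological phenotypes of damaged networks applied by
#' [apply_damage()]: distal pruning of neurite length, fragmentation of
#' neurites into disconnected pieces, full detachment of neurites from their
#' soma, soma swelling, and loss of whole neurites at the soma. The all-zero /
#' unit-swell setting is the identity transform.
#'
#' @param prune_fraction fraction (0-1) of total neurite length removed from
#'   distal ends.
#' @param fragment_rate_per_um Poisson rate of introduced gaps per micrometre
#'   of neurite.
#' @param gap_length_um length of neurite removed at each introduced gap.
#' @param detach_prob probability that a soma-attached neurite is severed at
#'   the soma.
#' @param soma_swell_factor multiplicative soma radius scaling (>= 1).
#' @param neurite_loss_per_soma expected number of whole primary neurites
#'   deleted per soma (Poisson).
#'
#' @return An object of class `damage_params`.
#' @export
damage_params <- function(prune_fraction = 0,
                          fragment_rate_per_um = 0,
                          gap_length_um = 2,
                          detach_prob = 0,
                          soma_swell_factor = 1,
                          neurite_loss_per_soma = 0) {
  if (prune_fraction < 0 || prune_fraction > 1)
    stop("prune_fraction must lie in [0, 1]")
  if (detach_prob < 0 || detach_prob > 1)
    stop("detach_prob must lie in [0, 1]")
  if (soma_swell_factor < 1)
    stop("soma_swell_factor must be >= 1")
  if (fragment_rate_per_um < 0 || gap_length_um < 0 || neurite_loss_per_soma < 0)
    stop("rates and lengths must be >= 0")
  structure(list(prune_fraction = prune_fraction,
                 fragment_rate_per_um = fragment_rate_per_um,
                 gap_length_um = gap_length_um,
                 detach_prob = detach_prob,
                 soma_swell_factor = soma_swell_factor,
                 neurite_loss_per_soma = neurite_loss_per_soma),
            class = "damage_params")
}

is_identity_damage <- function(d) {
  d$prune_fraction == 0 && d$fragment_rate_per_um == 0 &&
    d$detach_prob == 0 && d$soma_swell_factor == 1 &&
    d$neurite_loss_per_soma == 0
}
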