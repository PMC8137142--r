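#' Simulation configuration
#'
#' Bundles every parameter of the synthetic microscopy world: field layout,
#' cell/nucleus geometry, spot statistics, optics, and noise. Defaults are
#' chosen to mimic spinning-disk confocal smFISH in budding yeast: ~50
#' spots per cell for a highly expressed transcript (down to ~7 for lowly
#' expressed ones), a 100x oil objective PSF, and 3D stacks with 0.2 um
#' z-steps over 0.1 um pixels.
#'
#' @param n_cells number of cells in the field.
#' @param spots_per_cell_mean mean spot count per cell and channel
#'   (Poisson-distributed across cells).
#' @param true_rho fraction in `[0, 1]` of reference-channel (A) spots that
#'   have a co-localized channel-B partner; this is the parameter the
#'   matching pipeline is meant to recover.
#' @param jitter_sigma isotropic localization error (um) applied to the
#'   channel-B partner of each true pair.
#' @param voxel_size voxel edge lengths in um, `(z, y, x)`.
#' @param psf_sigma Gaussian PSF sigma in um per axis, `(z, y, x)`.
#' @param cell_radius,nucleus_radius ellipsoid semi-axes in um, `(z, y, x)`.
#'   The default mother-cell ellipsoid (3.5 x 3.5 x 2.25 um semi-axes,
#'   ~115 um^3) keeps the background spot density low enough that chance
#'   pairings stay well below the localization signal at a 0.3 um gate
#'   (see [chance_coloc_expectation()]).
#' @param nuclear_fraction optional fraction in `[0, 1]` of spots forced
#'   into the nucleus mask; `NULL` (default) places spots uniformly over
#'   the whole cell so the nuclear share follows the volume ratio.
#' @param background_level,peak_intensity background and per-spot peak
#'   amplitude in photon counts.
#' @param noise_model one of `"poisson"`, `"gaussian"`, `"poisson+gaussian"`,
#'   or `"none"`.
#' @param gaussian_sd read-noise standard deviation used by the Gaussian
#'   noise models.
#' @param rng_seed integer seed; all randomness derives from it via
#'   per-cell seed spawning, so results are independent of iteration order.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells = 4, spots_per_cell_mean = 20, true_rho = 0.5)
#' cfg$true_rho
#' @export
sim_config <- function(n_cells = 25L,
                       spots_per_cell_mean = 50,
                       true_rho = 0.5,
                       jitter_sigma = 0.1,
                       voxel_size = c(z = 0.2, y = 0.1, x = 0.1),
                       psf_sigma = c(z = 0.30, y = 0.13, x = 0.13),
                       cell_radius = c(z = 2.25, y = 3.5, x = 3.5),
                       nucleus_radius = c(z = 0.9, y = 1.2, x = 1.2),
                       nuclear_fraction = NULL,
                       background_level = 10,
                       peak_intensity = 200,
                       noise_model = c("poisson", "gaussian",
                                       "poisson+gaussian", "none"),
                       gaussian_sd = 2,
                       rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 0L)
    stop_mod("sim_config", "n_cells", "must be a non-negative integer")
  if (spots_per_cell_mean < 0)
    stop_mod("sim_config", "spots_per_cell_mean", "must be >= 0")
  if (!is.numeric(true_rho) || true_rho < 0 || true_rho > 1)
    stop_mod("sim_config", "true_rho", "must lie in [0, 1]")
  if (jitter_sigma < 0)
    stop_mod("sim_config", "jitter_sigma", "must be >= 0")
  voxel_size <- check_axis_triple(voxel_size, "voxel_size", "sim_config")
  psf_sigma <- check_axis_triple(psf_sigma, "psf_sigma", "sim_config")
  cell_radius <- check_axis_triple(cell_radius, "cell_radius", "sim_config")
  nucleus_radius <- check_axis_triple(nucleus_radius, "nucleus_radius",
                                      "sim_config")
  if (any(voxel_size <= 0))
    stop_mod("sim_config", "voxel_size", "must be > 0")
  if (any(psf_sigma <= 0))
    stop_mod("sim_config", "psf_sigma", "must be > 0")
  if (any(nucleus_radius >= cell_radius))
    stop_mod("sim_config", "nucleus_radius",
             "nucleus must fit strictly inside the cell")
  if (!is.null(nuclear_fraction) &&
      (nuclear_fraction < 0 || nuclear_fraction > 1))
    stop_mod("sim_config", "nuclear_fraction", "must lie in [0, 1]")
  if (background_level < 0 || peak_intensity < 0)
    stop_mod("sim_config", "intensity", "levels must be >= 0")

  structure(list(
    n_cells = n_cells,
    spots_per_cell_mean = spots_per_cell_mean,
    true_rho = true_rho,
    jitter_sigma = jitter_sigma,
    voxel_size = voxel_size,
    psf_sigma = psf_sigma,
    cell_radius = cell_radius,
    nucleus_radius = nucleus_radius,
    nuclear_fraction = nuclear_fraction,
    background_level = background_level,
    peak_intensity = peak_intensity,
    noise_model = noise_model,
    gaussian_sd = gaussian_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells,",
      x$spots_per_cell_mean, "spots/cell/channel, true_rho =", x$true_rho,
      "\n  jitter", x$jitter_sigma, "um, voxel (z,y,x) =",
      paste(x$voxel_size, collapse = " x "), "um, noise =", x$noise_model,
      "\n")
  invisible(x)
}
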