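#' Render a spot field into a multi-channel 3D intensity stack
#'
#' Each spot becomes a 3D Gaussian of per-axis sigma `psf_sigma` (um,
#' converted to voxels) and amplitude `peak_intensity`, summed onto a
#' constant `background_level`; the nuclear-stain channel is the nucleus
#' mask at `peak_intensity / 2` over background. Noise is applied per
#' `config$noise_model`. Rendering is deterministic given `rng_seed`.
#'
#' Spots whose centre falls outside the region's bounding box are clipped
#' (their in-box tail is still rendered) with a warning.
#'
#' @param truth a `spot_field` from [simulate_spot_pair_field()].
#' @param region the matching `cell_region`.
#' @param config a [sim_config()].
#' @param rng_seed seed for the noise draw (default `config$rng_seed`).
#' @return named list of 3D arrays `a`, `b`, `nucleus` (dim `(z, y, x)`)
#'   with attributes `voxel_size` and `offset` (global voxel offset).
#' @examples
#' cfg <- sim_config(n_cells = 1, spots_per_cell_mean = 5,
#'                   noise_model = "none")
#' geom <- generate_cell_geometry(cfg)
#' fld <- simulate_spot_pair_field(geom$regions[[1]], cfg)
#' img <- render_image(fld, geom$regions[[1]], cfg)
#' dim(img$a)
#' @export
render_image <- function(truth, region, config,
                         rng_seed = config$rng_seed) {
  stopifnot(inherits(truth, "spot_field"), inherits(region, "cell_region"),
            inherits(config, "sim_config"))
  if (any(config$voxel_size <= 0) || any(config$psf_sigma <= 0))
    stop_mod("render_image", "voxel_size/psf_sigma", "must be > 0")
  dims <- dim(region$cell)
  ch_a <- render_channel(truth$spots_a, dims, region$offset, config)
  ch_b <- render_channel(truth$spots_b, dims, region$offset, config)
  ch_n <- array(config$background_level, dims) +
    region$nucleus * (config$peak_intensity / 2)

  set.seed(rng_seed)
  out <- lapply(list(a = ch_a, b = ch_b, nucleus = ch_n),
                apply_noise, config = config)
  attr(out, "voxel_size") <- config$voxel_size
  attr(out, "offset") <- region$offset
  out
}

# sum of 3D Gaussians over a background; positions in global um
render_channel <- function(spots_um, dims, offset, config) {
  img <- array(config$background_level, dims)
  if (nrow(spots_um) == 0L) return(img)
  vs <- config$voxel_size
  sig <- config$psf_sigma / vs                  # sigma in voxel units
  half <- ceiling(4 * sig)
  # continuous 0-based local index of the spot centre: voxel i has its
  # centre at (i + 0.5) * vs, so centre index = um/vs - 0.5 - offset
  ctr <- sweep(sweep(spots_um, 2L, vs, `/`), 2L, offset + 0.5, `-`)
  clipped <- 0L
  for (s in seq_len(nrow(ctr))) {
    c0 <- ctr[s, ]
    if (any(c0 < -0.5) || any(c0 > dims - 0.5)) clipped <- clipped + 1L
    lo <- pmax(floor(c0 - half), 0)
    hi <- pmin(ceiling(c0 + half), dims - 1)
    if (any(hi < lo)) next
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    gz <- exp(-((iz - c0[1])^2) / (2 * sig[["z"]]^2))
    gy <- exp(-((iy - c0[2])^2) / (2 * sig[["y"]]^2))
    gx <- exp(-((ix - c0[3])^2) / (2 * sig[["x"]]^2))
    blob <- config$peak_intensity * outer(outer(gz, gy), gx)
    img[iz + 1, iy + 1, ix + 1] <- img[iz + 1, iy + 1, ix + 1] + blob
  }
  if (clipped > 0L)
    warning(sprintf("render_image: %d spot(s) outside the field of view were clipped",
                    clipped), call. = FALSE)
  img
}

apply_noise <- function(img, config) {
  out <- switch(config$noise_model,
    none = img,
    poisson = array(rpois(length(img), img), dim(img)),
    gaussian = img + array(rnorm(length(img), sd = config$gaussian_sd),
                           dim(img)),
    `poisson+gaussian` = array(rpois(length(img), img), dim(img)) +
      array(rnorm(length(img), sd = config$gaussian_sd), dim(img)))
  out
}

#' Render a whole cohort into one global field
#'
#' Stitches per-cell renderings into global arrays of `field_dim`,
#' rendering each cell's box independently (cells do not overlap). Voxels
#' outside every cell's bounding box stay at the noiseless background.
#'
#' @param cohort result of [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return named list of global 3D arrays `a`, `b`, `nucleus`.
#' @export
render_field <- function(cohort, config) {
  geometry <- cohort$geometry
  fd <- geometry$field_dim
  out <- list(a = array(config$background_level, fd),
              b = array(config$background_level, fd),
              nucleus = array(config$background_level, fd))
  seeds <- spawn_seeds(config$rng_seed + 1L, length(geometry$regions))
  for (k in seq_along(geometry$regions)) {
    region <- geometry$regions[[k]]
    img <- render_image(cohort$fields[[k]], region, config,
                        rng_seed = seeds[k])
    o <- region$offset; d <- dim(region$cell)
    for (ch in names(out))
      out[[ch]][o[1] + seq_len(d[1]), o[2] + seq_len(d[2]),
                o[3] + seq_len(d[3])] <- img[[ch]]
  }
  attr(out, "voxel_size") <- config$voxel_size
  out
}
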