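#' Simulate a two-channel spot field with known pairing for one cell
#'
#' Draws channel-A spot positions uniformly over the cell mask, duplicates
#' a `round(true_rho * nA)` subset into channel B with isotropic Gaussian
#' localization jitter (`jitter_sigma`, um), and fills channel B up with
#' unpaired spots placed uniformly over the mask. The ground-truth pairing
#' is recorded, so the downstream matching estimate can be compared with
#' the generating `true_rho`.
#'
#' Spot counts are Poisson across cells: `nA ~ Pois(spots_per_cell_mean)`
#' and the unpaired channel-B count `~ Pois(spots_per_cell_mean *
#' (1 - true_rho))`, keeping the expected density equal in both channels.
#' Rounding of the pair count is deterministic half-up.
#'
#' @param region a `cell_region` from [generate_cell_geometry()].
#' @param config a [sim_config()].
#' @param rng_seed seed for this cell's private stream; defaults to
#'   `config$rng_seed`. [simulate_cohort()] spawns one per cell.
#' @return An object of class `spot_field`: list with `cell_id`,
#'   `spots_a`, `spots_b` (matrices with columns `z_um, y_um, x_um`),
#'   `pairing` (two-column index matrix into A and B), `true_rho`,
#'   `jitter_sigma`.
#' @examples
#' geom <- generate_cell_geometry(sim_config(n_cells = 1))
#' fld <- simulate_spot_pair_field(geom$regions[[1]],
#'                                 sim_config(spots_per_cell_mean = 10))
#' nrow(fld$pairing) / nrow(fld$spots_a)
#' @export
simulate_spot_pair_field <- function(region, config,
                                     rng_seed = config$rng_seed) {
  stopifnot(inherits(region, "cell_region"), inherits(config, "sim_config"))
  rho <- config$true_rho
  if (rho < 0 || rho > 1)
    stop_mod("simulate_spot_pair_field", "true_rho", "must lie in [0, 1]")
  set.seed(rng_seed)

  n_a <- rpois(1L, config$spots_per_cell_mean)
  spots_a <- sample_uniform_in_mask(region, n_a, config$nuclear_fraction)
  n_pair <- as.integer(round_half_up(rho * n_a))
  idx_a <- if (n_pair > 0L) sort(sample.int(n_a, n_pair)) else integer(0)

  paired_b <- spots_a[idx_a, , drop = FALSE]
  if (n_pair > 0L && config$jitter_sigma > 0)
    paired_b <- paired_b +
      matrix(rnorm(3L * n_pair, sd = config$jitter_sigma), ncol = 3L)

  n_b_extra <- rpois(1L, config$spots_per_cell_mean * (1 - rho))
  extra_b <- sample_uniform_in_mask(region, n_b_extra,
                                    config$nuclear_fraction)
  spots_b <- rbind(paired_b, extra_b)
  # shuffle channel B so pair indices carry no positional information
  perm <- sample.int(nrow(spots_b))
  spots_b <- spots_b[perm, , drop = FALSE]
  pos_b <- order(perm)[seq_len(n_pair)]     # where each paired spot landed

  pairing <- cbind(index_a = idx_a, index_b = pos_b)
  colnames(spots_a) <- colnames(spots_b) <- c("z_um", "y_um", "x_um")
  structure(list(cell_id = region$cell_id,
                 spots_a = spots_a, spots_b = spots_b,
                 pairing = pairing,
                 true_rho = rho, jitter_sigma = config$jitter_sigma),
            class = "spot_field")
}

# uniform positions (um, global frame) over the cell mask; optionally a
# fixed fraction constrained to the nucleus mask
sample_uniform_in_mask <- function(region, n, nuclear_fraction = NULL) {
  out <- matrix(numeric(0), ncol = 3L,
                dimnames = list(NULL, c("z_um", "y_um", "x_um")))
  if (n == 0L) return(out)
  draw <- function(mask, k) {
    vox <- which(mask)
    if (length(vox) == 0L)
      stop_mod("simulate_spot_pair_field", "mask", "mask is empty")
    pick <- vox[sample.int(length(vox), k, replace = TRUE)]
    ind <- arrayInd(pick, dim(mask)) - 1L          # 0-based local voxel
    ind <- sweep(ind, 2L, region$offset, `+`)      # global voxel
    (ind + matrix(runif(3L * k), ncol = 3L)) *
      rep(region$voxel_size, each = k)             # uniform within voxel
  }
  if (is.null(nuclear_fraction)) {
    pos <- draw(region$cell, n)
  } else {
    k_nuc <- as.integer(round_half_up(nuclear_fraction * n))
    pos <- rbind(if (k_nuc > 0L) draw(region$nucleus, k_nuc),
                 if (n - k_nuc > 0L) draw(region$cell, n - k_nuc))
  }
  colnames(pos) <- c("z_um", "y_um", "x_um")
  pos
}

#' Simulate a whole cohort of cells
#'
#' Generates geometry and one `spot_field` per cell, each from a child
#' seed spawned from `config$rng_seed`, so results do not depend on the
#' order in which cells are processed.
#'
#' @param config a [sim_config()].
#' @param geometry optional pre-built [generate_cell_geometry()] result
#'   (re-used across conditions to save time).
#' @return list with `geometry` and `fields` (list of `spot_field`).
#' @export
simulate_cohort <- function(config, geometry = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(geometry)) geometry <- generate_cell_geometry(config)
  seeds <- spawn_seeds(config$rng_seed, length(geometry$regions))
  fields <- mapply(function(region, s)
    simulate_spot_pair_field(region, config, rng_seed = s),
    geometry$regions, seeds, SIMPLIFY = FALSE)
  list(geometry = geometry, fields = fields)
}

#' Ground-truth paired fraction of a cohort
#'
#' @param fields list of `spot_field`.
#' @return total pairs / total channel-A spots.
#' @export
truth_paired_fraction <- function(fields) {
  n_pair <- sum(vapply(fields, function(f) nrow(f$pairing), numeric(1)))
  n_a <- sum(vapply(fields, function(f) nrow(f$spots_a), numeric(1)))
  if (n_a == 0) return(NA_real_)
  n_pair / n_a
}

#' Convert simulated spot fields to a spot table
#'
#' Flattens `spot_field` objects into the package's standard spot table
#' (one row per spot) with ground-truth `pair_id` carried along.
#'
#' @param fields list of `spot_field`.
#' @return data.frame with columns `channel, cell_id, z_um, y_um, x_um,
#'   pair_id`.
#' @export
fields_to_spot_table <- function(fields) {
  rows <- lapply(fields, function(f) {
    pa <- rep(NA_character_, nrow(f$spots_a))
    pb <- rep(NA_character_, nrow(f$spots_b))
    if (nrow(f$pairing) > 0L) {
      ids <- sprintf("%d_%d", f$cell_id, seq_len(nrow(f$pairing)))
      pa[f$pairing[, 1L]] <- ids
      pb[f$pairing[, 2L]] <- ids
    }
    rbind(
      data.frame(channel = "a", cell_id = f$cell_id, f$spots_a,
                 pair_id = pa, stringsAsFactors = FALSE),
      data.frame(channel = "b", cell_id = f$cell_id, f$spots_b,
                 pair_id = pb, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
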