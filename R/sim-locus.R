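#' Simulate a two-channel tagged-locus image pair
#'
#' Places two disk-shaped locus signals (equal radii) in a 2D frame so
#' their area overlap — intersection over the smaller disk — equals
#' `overlap_target`. The centre distance is solved analytically from the
#' circle-intersection area, the pair is dropped at a random position and
#' orientation, and each disk is rasterized into its own channel.
#'
#' @param overlap_target desired overlap fraction in `[0, 1]`.
#' @param rng_seed integer seed (position/orientation, noise).
#' @param img_size frame edge in pixels (square).
#' @param radius_px disk radius in pixels.
#' @param pixel_size_um physical pixel edge (um), used only for reporting
#'   centroid distances downstream.
#' @param intensity peak intensity of each disk over zero background.
#' @param noise_sd Gaussian noise sd added to both channels (0 = none).
#' @return list with 2D matrices `image_a`, `image_b`, the analytic
#'   `overlap_true`, the rasterized `overlap_raster` (pixel-counted,
#'   within one pixel's area of the target), `centers` (2 x 2, rows a/b,
#'   columns y/x in pixels) and `pixel_size_um`.
#' @examples
#' lp <- simulate_locus_pair(0.15, rng_seed = 7)
#' abs(lp$overlap_raster - 0.15) < 0.05
#' @export
simulate_locus_pair <- function(overlap_target, rng_seed = 1L,
                                img_size = 64L, radius_px = 10,
                                pixel_size_um = 0.1,
                                intensity = 100, noise_sd = 0) {
  if (overlap_target < 0 || overlap_target > 1)
    stop_mod("simulate_locus_pair", "overlap_target", "must lie in [0, 1]")
  set.seed(rng_seed)
  r <- radius_px

  d <- distance_for_overlap(overlap_target, r)
  # margin: both full disks (or the disjoint pair) must fit in the frame
  need <- d + 2 * r + 2
  if (need > img_size)
    stop_mod("simulate_locus_pair", "radius_px",
             sprintf("disks of radius %g at separation %.2f px do not fit a %d px frame",
                     r, d, img_size))
  theta <- runif(1, 0, 2 * pi)
  wiggle <- (img_size - need) / 2
  mid <- img_size / 2 + runif(2, -wiggle / 2, wiggle / 2)
  ca <- mid + (d / 2) * c(sin(theta), cos(theta))
  cb <- mid - (d / 2) * c(sin(theta), cos(theta))

  rasterize <- function(ctr) {
    yy <- matrix(seq_len(img_size) - 0.5, img_size, img_size)
    xx <- t(yy)
    disk <- ((yy - ctr[1])^2 + (xx - ctr[2])^2) <= r^2
    img <- disk * intensity
    if (noise_sd > 0) img <- img + matrix(rnorm(img_size^2, sd = noise_sd),
                                          img_size)
    img
  }
  image_a <- rasterize(ca)
  image_b <- rasterize(cb)
  inter <- sum(image_a >= intensity / 2 & image_b >= intensity / 2)
  area_a <- sum(image_a >= intensity / 2)
  area_b <- sum(image_b >= intensity / 2)
  list(image_a = image_a, image_b = image_b,
       overlap_true = overlap_target,
       overlap_raster = inter / min(area_a, area_b),
       centers = rbind(a = ca, b = cb),
       pixel_size_um = pixel_size_um)
}

# centre distance giving a prescribed intersection-over-smaller-disk for
# two equal circles of radius r (closed-form lens area, solved by uniroot)
distance_for_overlap <- function(frac, r) {
  if (frac >= 1) return(0)
  if (frac <= 0) return(2 * r + 2)   # disjoint with a margin
  lens_frac <- function(d) {
    a <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
    a / (pi * r^2)
  }
  uniroot(function(d) lens_frac(d) - frac, c(1e-9, 2 * r - 1e-9),
          tol = 1e-10)$root
}

#' Simulate a cohort of locus pairs from class probabilities
#'
#' Draws each cell's class from `(co-localized, adjacent, not
#' co-localized)` probabilities and generates the matching image pair:
#' co-localized cells get fully overlapping disks (overlap 1), adjacent
#' cells a partial overlap drawn uniformly from `adjacent_range`, and
#' non-co-localized cells disjoint disks.
#'
#' @param n_cells number of cells.
#' @param class_probs length-3 probabilities, in the order above.
#' @param adjacent_range overlap range for the adjacent class; default
#'   0.10-0.25, the partial-overlap band reported for apposed loci.
#' @param rng_seed integer seed.
#' @param ... passed to [simulate_locus_pair()].
#' @return list with `pairs` (list of locus-pair objects), `true_class`
#'   (factor), `class_probs`.
#' @export
simulate_locus_cohort <- function(n_cells, class_probs = c(0.1, 0.7, 0.2),
                                  adjacent_range = c(0.10, 0.25),
                                  rng_seed = 1L, ...) {
  stopifnot(length(class_probs) == 3L, abs(sum(class_probs) - 1) < 1e-8)
  lv <- c("co-localized", "adjacent", "not co-localized")
  set.seed(rng_seed)
  cls <- sample(lv, n_cells, replace = TRUE, prob = class_probs)
  targets <- vapply(cls, function(cl) switch(cl,
    "co-localized" = 1,
    "adjacent" = runif(1, adjacent_range[1], adjacent_range[2]),
    "not co-localized" = 0), numeric(1))
  seeds <- spawn_seeds(rng_seed + 1L, n_cells)
  pairs <- lapply(seq_len(n_cells), function(i)
    simulate_locus_pair(targets[i], rng_seed = seeds[i], ...))
  list(pairs = pairs, true_class = factor(cls, levels = lv),
       class_probs = class_probs)
}
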