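test_that("cell geometry: containment, disjointness, edge cases", {
  cfg <- sim_config(n_cells = 1)
  geom <- generate_cell_geometry(cfg)
  expect_length(geom$regions, 1L)
  r <- geom$regions[[1]]
  expect_true(all(r$cell[r$nucleus]))          # nucleus strictly inside cell
  expect_gt(sum(r$cell), sum(r$nucleus))

  expect_length(generate_cell_geometry(sim_config(n_cells = 0))$regions, 0L)

  geom12 <- generate_cell_geometry(sim_config(n_cells = 12))
  expect_length(geom12$regions, 12L)
  # disjointness checked against a stitched global occupancy count
  occ <- array(0L, geom12$field_dim)
  for (r in geom12$regions) {
    o <- r$offset; d <- dim(r$cell)
    sl <- list(o[1] + seq_len(d[1]), o[2] + seq_len(d[2]),
               o[3] + seq_len(d[3]))
    occ[sl[[1]], sl[[2]], sl[[3]]] <- occ[sl[[1]], sl[[2]], sl[[3]]] +
      r$cell
  }
  expect_lte(max(occ), 1L)
  expect_true(validate_geometry(geom12))

  expect_error(generate_cell_geometry(
    sim_config(cell_radius = c(0.01, 0.01, 0.01),
               nucleus_radius = c(0.005, 0.005, 0.005))),
    "cell_radius")
})

test_that("spot fields honour true_rho, masks, and determinism", {
  cfg <- sim_config(n_cells = 1, spots_per_cell_mean = 30)
  geom <- generate_cell_geometry(cfg)
  region <- geom$regions[[1]]

  # rho = 1, no jitter: channel B contains exact copies of channel A
  cfg1 <- sim_config(n_cells = 1, spots_per_cell_mean = 30, true_rho = 1,
                     jitter_sigma = 0)
  f1 <- simulate_spot_pair_field(region, cfg1, rng_seed = 5)
  expect_equal(nrow(f1$pairing), nrow(f1$spots_a))
  expect_equal(f1$spots_b[f1$pairing[, 2], , drop = FALSE],
               f1$spots_a[f1$pairing[, 1], , drop = FALSE],
               ignore_attr = TRUE)

  # zero-intensity world: no spots
  f0 <- simulate_spot_pair_field(
    region, sim_config(n_cells = 1, spots_per_cell_mean = 0), rng_seed = 5)
  expect_equal(nrow(f0$spots_a), 0L)
  expect_equal(nrow(f0$spots_b), 0L)
  expect_equal(nrow(f0$pairing), 0L)

  # pair-count bookkeeping: |pairing| = round-half-up(rho * nA) per cell,
  # and every spot lies inside the cell mask
  for (s in seeds_for(8)) {
    for (rho in c(0, 0.25, 0.5, 0.77)) {
      cfgr <- sim_config(n_cells = 1, spots_per_cell_mean = 20,
                         true_rho = rho)
      f <- simulate_spot_pair_field(region, cfgr, rng_seed = s)
      expect_equal(nrow(f$pairing), floor(rho * nrow(f$spots_a) + 0.5))
      vox <- floor(sweep(f$spots_a, 2, region$voxel_size, `/`))
      loc <- sweep(vox, 2, region$offset, `-`) + 1
      expect_true(all(region$cell[loc]))
    }
  }

  # determinism: identical seed, identical field
  fa <- simulate_spot_pair_field(region, cfg, rng_seed = 99)
  fb <- simulate_spot_pair_field(region, cfg, rng_seed = 99)
  expect_identical(fa, fb)

  expect_error(sim_config(true_rho = 1.2), "true_rho")
})

test_that("rendering: background, localization, photometry, determinism", {
  cfg <- sim_config(n_cells = 1, spots_per_cell_mean = 0,
                    noise_model = "none")
  geom <- generate_cell_geometry(cfg)
  region <- geom$regions[[1]]
  f0 <- simulate_spot_pair_field(region, cfg, rng_seed = 1)
  img0 <- render_image(f0, region, cfg)
  expect_true(all(img0$a == cfg$background_level))
  expect_true(all(img0$b == cfg$background_level))

  # one spot, no noise: arg-max voxel within one voxel of the truth,
  # and integrated intensity matches the Gaussian integral within 5%
  for (s in seeds_for(5)) {
    set.seed(s)
    pos <- region$center_um + runif(3, -0.3, 0.3)
    truth <- structure(list(cell_id = 1L,
                            spots_a = matrix(pos, 1,
                              dimnames = list(NULL, c("z_um", "y_um", "x_um"))),
                            spots_b = matrix(numeric(0), ncol = 3),
                            pairing = cbind(integer(0), integer(0)),
                            true_rho = 0, jitter_sigma = 0),
                       class = "spot_field")
    img <- render_image(truth, region, cfg)
    amax <- arrayInd(which.max(img$a), dim(img$a)) - 1L
    vox_true <- floor(pos / cfg$voxel_size) - region$offset
    expect_true(all(abs(amax - vox_true) <= 1))
    integral <- sum(img$a - cfg$background_level)
    expected <- cfg$peak_intensity * (2 * pi)^1.5 *
      prod(cfg$psf_sigma) / prod(cfg$voxel_size)
    expect_lt(abs(integral / expected - 1), 0.05)
  }

  # identical seed => bit-identical noisy render
  cfgn <- sim_config(n_cells = 1, spots_per_cell_mean = 10,
                     noise_model = "poisson+gaussian")
  fn <- simulate_spot_pair_field(region, cfgn, rng_seed = 3)
  r1 <- render_image(fn, region, cfgn, rng_seed = 42)
  r2 <- render_image(fn, region, cfgn, rng_seed = 42)
  expect_identical(r1, r2)

  # out-of-view spot is clipped with a warning
  far <- structure(list(cell_id = 1L,
                        spots_a = matrix(c(-5, -5, -5), 1,
                          dimnames = list(NULL, c("z_um", "y_um", "x_um"))),
                        spots_b = matrix(numeric(0), ncol = 3),
                        pairing = cbind(integer(0), integer(0)),
                        true_rho = 0, jitter_sigma = 0),
                   class = "spot_field")
  expect_warning(render_image(far, region, cfg), "clipped")
})

test_that("count matrices: library size, Poisson limit, validation", {
  em <- simulate_count_matrix(2000, rng_seed = 2)
  expect_s3_class(em, "expression_matrix")
  cs <- colSums(em$values)
  expect_true(all(abs(cs / (100 * 2000) - 1) < 0.05))

  # dispersion 0 -> Poisson: standardized residuals have unit variance
  em0 <- simulate_count_matrix(10000, dispersion = 0, rng_seed = 3)
  tr <- attr(em0, "truth")
  z <- (em0$values[, "control1"] - tr$mu_control) / sqrt(tr$mu_control)
  expect_lt(abs(var(z) - 1), 0.1)
  # and dispersion 0.1 is visibly overdispersed
  em1 <- simulate_count_matrix(10000, dispersion = 0.1, rng_seed = 3)
  tr1 <- attr(em1, "truth")
  z1 <- (em1$values[, "control1"] - tr1$mu_control) / sqrt(tr1$mu_control)
  expect_gt(var(z1), 2)

  # enriched genes have the requested fold in their generating means
  emf <- simulate_count_matrix(100, enriched_ids = "gene00007", fold = 6,
                               rng_seed = 4)
  trf <- attr(emf, "truth")
  expect_equal(trf$mu_pulldown[7] / trf$mu_control[7], 6)
  expect_equal(trf$mu_pulldown[8] / trf$mu_control[8], 1)

  expect_error(simulate_count_matrix(10, enriched_ids = "nope"),
               "enriched_ids")
  expect_error(simulate_count_matrix(10, fold = 0.5), "fold")
})

test_that("locus pairs: overlap targets are realized in the raster", {
  lp1 <- simulate_locus_pair(1, rng_seed = 1)
  expect_identical(lp1$image_a >= 50, lp1$image_b >= 50)
  expect_equal(lp1$overlap_raster, 1)

  lp0 <- simulate_locus_pair(0, rng_seed = 2)
  expect_equal(lp0$overlap_raster, 0)

  for (s in seeds_for(6)) {
    lp <- simulate_locus_pair(0.15, rng_seed = s)
    expect_lt(abs(lp$overlap_raster - 0.15), 0.02)
  }

  expect_error(simulate_locus_pair(0.5, img_size = 16, radius_px = 10),
               "radius_px")
  expect_error(simulate_locus_pair(1.4), "overlap_target")
})
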