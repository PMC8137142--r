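make_region <- function(cfg = sim_config(n_cells = 1)) {
  generate_cell_geometry(cfg)$regions[[1]]
}

# hand-built spot_field at given positions (um, global frame)
field_at <- function(pos_um, cell_id = 1L) {
  m <- matrix(pos_um, ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("z_um", "y_um", "x_um")))
  structure(list(cell_id = cell_id, spots_a = m,
                 spots_b = matrix(numeric(0), ncol = 3),
                 pairing = cbind(integer(0), integer(0)),
                 true_rho = 0, jitter_sigma = 0),
            class = "spot_field")
}

test_that("detection on blank, single- and two-spot images", {
  cfg <- sim_config(n_cells = 1, noise_model = "none")
  region <- make_region(cfg)
  vs <- cfg$voxel_size

  blank <- array(cfg$background_level, dim(region$cell))
  expect_equal(nrow(detect_spots(blank, vs)), 0L)

  bad <- blank; bad[1] <- NA
  expect_error(detect_spots(bad, vs), "non-finite")

  # one rendered Gaussian, no noise: found within 0.5 voxel
  ctr <- region$center_um
  img <- render_image(field_at(ctr), region, cfg)$a
  spots <- detect_spots(img, vs)
  expect_equal(nrow(spots), 1L)
  # detection positions are local to the rendered array
  pos <- c(spots$z_um, spots$y_um, spots$x_um)
  err_vox <- abs(pos - (ctr - region$offset * vs)) / vs
  expect_true(all(err_vox <= 0.5))

  # two Gaussians 4 x psf apart: both found
  sep <- 4 * max(cfg$psf_sigma)
  img2 <- render_image(field_at(c(ctr, ctr + c(0, sep, 0))), region,
                       cfg)$a
  expect_equal(nrow(detect_spots(img2, vs)), 2L)

  # idempotence: identical tables on repeat runs
  expect_identical(detect_spots(img2, vs), detect_spots(img2, vs))
})

test_that("noise-free localization error is well below 0.2 voxel RMS", {
  cfg <- sim_config(n_cells = 1, noise_model = "none")
  region <- make_region(cfg)
  vs <- cfg$voxel_size
  errs <- NULL
  for (s in seeds_for(12)) {
    set.seed(s)
    truth <- region$center_um + runif(3, -0.4, 0.4)
    img <- render_image(field_at(truth), region, cfg)$a
    spots <- detect_spots(img, vs)
    expect_equal(nrow(spots), 1L)
    local_truth <- truth - region$offset * vs
    errs <- rbind(errs,
                  (c(spots$z_um, spots$y_um, spots$x_um) - local_truth) / vs)
  }
  expect_lt(sqrt(mean(errs^2)), 0.2)
})

test_that("cell assignment matches the brute-force point-in-mask oracle", {
  cfg <- sim_config(n_cells = 6)
  geom <- generate_cell_geometry(cfg)
  set.seed(17)
  n <- 100
  spots <- data.frame(
    z_um = runif(n, 0, geom$field_dim[1] * cfg$voxel_size[1]),
    y_um = runif(n, 0, geom$field_dim[2] * cfg$voxel_size[2]),
    x_um = runif(n, 0, geom$field_dim[3] * cfg$voxel_size[3]))
  got <- assign_spots_to_cells(spots, geom)
  expect_identical(got$cell_id, assign_oracle(spots, geom))
  expect_true(any(is.na(got$cell_id)))     # background spots stay flagged
  expect_true(any(!is.na(got$cell_id)))
})

test_that("compartment classification follows the inclusive nuclear rule", {
  cfg <- sim_config(n_cells = 1)
  geom <- generate_cell_geometry(cfg)
  region <- geom$regions[[1]]
  vs <- cfg$voxel_size

  mk <- function(pos) data.frame(z_um = pos[1], y_um = pos[2],
                                 x_um = pos[3], cell_id = 1L)
  # nucleus centroid -> nuclear
  got <- classify_compartment(mk(region$center_um), geom)
  expect_equal(got$compartment, "nuclear")

  # far lateral edge of the cell -> cytoplasmic
  edge <- region$center_um + c(0, cfg$cell_radius[["y"]] - 0.3, 0)
  expect_equal(classify_compartment(mk(edge), geom)$compartment,
               "cytoplasmic")

  # boundary voxel of the nucleus mask (outermost mask voxel) -> nuclear
  nuc <- which(region$nucleus, arr.ind = TRUE)
  boundary <- nuc[which.max(nuc[, 2]), ]         # largest-y nucleus voxel
  pos <- (boundary - 1 + region$offset + 0.5) * vs
  expect_equal(classify_compartment(mk(pos), geom)$compartment, "nuclear")

  # unassigned spots stay unassigned
  bg <- mk(c(0.01, 0.01, 0.01)); bg$cell_id <- NA_integer_
  expect_equal(classify_compartment(bg, geom)$compartment, "unassigned")
})
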