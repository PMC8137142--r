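rand_pts <- function(n, scale = 1) {
  matrix(runif(3 * n, 0, scale), ncol = 3,
         dimnames = list(NULL, c("z_um", "y_um", "x_um")))
}

test_that("match_spots basics: identity, empties, validation", {
  a <- rand_pts(5)
  m <- match_spots(a, a, gate_radius = 0.5)
  expect_equal(nrow(m$pairs), 5L)
  expect_equal(m$pairs$distance, rep(0, 5))
  expect_equal(m$pairs$index_a, m$pairs$index_b)

  m0 <- match_spots(a, matrix(numeric(0), ncol = 3), gate_radius = 0.5)
  expect_equal(nrow(m0$pairs), 0L)
  expect_equal(m0$unmatched_a, 1:5)

  expect_error(match_spots(a, a, gate_radius = -1), "gate_radius")
})

test_that("match_spots equals exhaustive enumeration on small instances", {
  set.seed(101)
  for (rep in 1:200) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    pa <- rand_pts(na); pb <- rand_pts(nb)
    gate <- runif(1, 0.1, 1.2)
    m <- match_spots(pa, pb, gate)
    oracle <- brute_force_match(pa, pb, gate)
    expect_equal(nrow(m$pairs), oracle$cardinality)
    expect_lt(abs(sum(m$pairs$distance) - oracle$cost), 1e-9)
    # structural invariants
    expect_true(all(m$pairs$distance <= gate))
    expect_setequal(c(m$pairs$index_a, m$unmatched_a), seq_len(na))
    expect_setequal(c(m$pairs$index_b, m$unmatched_b), seq_len(nb))
    expect_lte(nrow(m$pairs), min(na, nb))
  }
})

test_that("channel swap symmetry and gate monotonicity", {
  set.seed(7)
  for (rep in 1:25) {
    pa <- rand_pts(sample(2:8, 1)); pb <- rand_pts(sample(2:8, 1))
    m_ab <- match_spots(pa, pb, 0.6)
    m_ba <- match_spots(pb, pa, 0.6)
    # continuous random distances: optimum a.s. unique -> same pair set
    expect_equal(
      m_ab$pairs[order(m_ab$pairs$index_a), c("index_a", "index_b")],
      setNames(m_ba$pairs[order(m_ba$pairs$index_b),
                          c("index_b", "index_a")],
               c("index_a", "index_b")),
      ignore_attr = TRUE)
    # enlarging the gate never loses pairs
    cards <- vapply(c(0.1, 0.3, 0.6, 1, 5), function(g)
      nrow(match_spots(pa, pb, g)$pairs), numeric(1))
    expect_true(all(diff(cards) >= 0))
  }
})

test_that("coloc_fraction arithmetic and undefined marker", {
  a <- rand_pts(5)
  m <- match_spots(a, a, 0.5)
  expect_equal(coloc_fraction(m, 5), 1)
  expect_equal(coloc_fraction(m, 8), 0.625)
  m0 <- match_spots(matrix(numeric(0), ncol = 3),
                    matrix(numeric(0), ncol = 3), 0.5)
  expect_true(is.na(coloc_fraction(m0, 0)))
  expect_error(coloc_fraction(m, 3), "reference")
})

test_that("summarize_coloc mean/SEM and compartment shares", {
  s <- summarize_coloc(c(0.2, 0.4, 0.6))
  expect_equal(s$mean, 0.4)
  expect_equal(s$sem, 0.2 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n_cells, 3L)

  s1 <- summarize_coloc(0.4)
  expect_true(is.na(s1$sem))
  expect_equal(summarize_coloc(rep(0.3, 5))$sem, 0)

  sc <- summarize_coloc(c(0.5, 0.5),
                        compartments = c(nuclear = 6, cytoplasmic = 4))
  expect_equal(sc$nuclear_share, 0.6)
  expect_equal(sc$nuclear_share + sc$cytoplasmic_share, 1)

  expect_error(summarize_coloc(numeric(0)), "per_cell")
  expect_error(summarize_coloc(c(NA, NA)), "per_cell")
})

test_that("compare_groups is a Welch t-test with stated degenerate rules", {
  g <- c(0.1, 0.2, 0.3)
  same <- compare_groups(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  degen <- compare_groups(c(0, 0, 0), c(1, 1, 1))
  expect_true(is.infinite(degen$t))
  expect_equal(degen$p_value, 0)

  got <- compare_groups(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  oracle <- welch_oracle(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(got$t, oracle$t, tolerance = 1e-12)
  expect_equal(got$df, oracle$df, tolerance = 1e-12)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-12)

  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("chance co-localization expectation", {
  expect_equal(chance_coloc_expectation(0, 0.3), 0)
  expect_equal(chance_coloc_expectation(0.1, 0), 0)
  # frozen from direct evaluation of 1 - exp(-0.1 * (4/3) pi 0.3^3),
  # cross-checked by Monte Carlo during development
  expect_equal(chance_coloc_expectation(0.1, 0.3), 0.01124602,
               tolerance = 1e-6)
  expect_error(chance_coloc_expectation(-1, 0.3), "density")
})

test_that("rho ordering is preserved (low vs high co-localization)", {
  cfg_lo <- sim_config(n_cells = 25, spots_per_cell_mean = 30,
                       true_rho = 0.30, rng_seed = 21)
  cfg_hi <- sim_config(n_cells = 25, spots_per_cell_mean = 30,
                       true_rho = 0.77, rng_seed = 22)
  geom <- generate_cell_geometry(cfg_lo)
  est <- function(cfg) {
    co <- simulate_cohort(cfg, geom)
    coloc_cohort(co$fields, gate_radius = 0.3)$summary$mean
  }
  e_lo <- est(cfg_lo); e_hi <- est(cfg_hi)
  expect_gt(e_hi, e_lo)
  expect_gt(e_hi - e_lo, 0.3)
})
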