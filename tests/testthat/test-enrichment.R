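toy_em <- function(values, roles, unit = "TPM") {
  expression_matrix(values, roles = roles, unit = unit)
}

test_that("log_enrichment: identities, arithmetic, antisymmetry", {
  v <- cbind(p1 = c(7, 0, 10), ctrl = c(3, 0, 10))
  em <- toy_em(v, c("pulldown", "control"))
  le <- log_enrichment(em)
  expect_equal(le[1, 1], log2(8) - log2(4))   # = 1 exactly
  expect_equal(le[2, 1], 0)                   # 0 vs 0 pseudo-count
  expect_equal(le[3, 1], 0)                   # sample == control

  # x vs x is identically zero
  em_same <- toy_em(cbind(p1 = c(5, 2), ctrl = c(5, 2)),
                    c("pulldown", "control"))
  expect_true(all(log_enrichment(em_same) == 0))

  # swapping sample and control flips the sign
  em_sw <- toy_em(v[, 2:1], c("pulldown", "control"))
  expect_equal(unname(log_enrichment(em_sw)), unname(-le))

  # multiple controls averaged on the log scale
  em_mc <- toy_em(cbind(p = 7, c1 = 3, c2 = 15),
                  c("pulldown", "control", "control"))
  expect_equal(unname(log_enrichment(em_mc)[1, 1]),
               log2(8) - mean(c(log2(4), log2(16))))

  expect_error(log_enrichment(toy_em(v, c("pulldown", "control"),
                                     unit = "counts")), "TPM")
})

test_that("nb_exact_test: symmetry, Poisson limit, validation", {
  expect_equal(nb_exact_test(10, 10), 1)
  expect_equal(nb_exact_test(0, 0), 1)

  # dispersion 0 reduces to the conditional binomial exact test; base R's
  # binom.test is the independent oracle
  for (ab in list(c(5, 0), c(8, 2), c(30, 12), c(1, 1))) {
    expect_equal(nb_exact_test(ab[1], ab[2], dispersion = 0),
                 binom.test(ab[1], sum(ab), 0.5)$p.value,
                 tolerance = 1e-12)
  }

  # size factors: doubling one library halves its effective count
  expect_equal(nb_exact_test(20, 10, size_factor_a = 2, size_factor_b = 1,
                             dispersion = 0.1),
               nb_exact_test(15, 15, dispersion = 0.1))

  expect_error(nb_exact_test(5, 5, dispersion = -1), "dispersion")
  expect_error(nb_exact_test(-1, 5), "counts")
  expect_error(nb_exact_test(5, 5, size_factor_a = 0), "size_factor")
})

test_that("nb_exact_test matches the closed-form conditional oracle", {
  # every split of every total <= 50, fixed dispersion 0.1
  for (s in c(1, 2, 5, 17, 50)) {
    for (a in 0:s) {
      expect_lt(abs(nb_exact_test(a, s - a, dispersion = 0.1) -
                    nb_conditional_oracle(a, s - a, 0.1)), 1e-10)
    }
  }
  # replicate-aware variant against the same oracle
  for (a in c(0, 3, 11, 20)) {
    expect_lt(abs(nb_exact_test(a, 25 - a, dispersion = 0.1,
                                n_rep_a = 3, n_rep_b = 3) -
                  nb_conditional_oracle(a, 25 - a, 0.1, 3, 3)), 1e-10)
  }
})

test_that("bh_fdr: worked examples, permutation invariance, oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  # hand application of the step-up formula
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))

  set.seed(33)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
  perm <- sample.int(200)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))

  expect_error(bh_fdr(c(0.5, 1.2)), "p_values")
})

test_that("enrichment filter honours its boundaries and finds plants", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    fold_change = c(4.0, 3.99, 8, 10),
                    fdr = c(5e-4, 1e-6, 1e-3, 1e-5))
  # fold exactly 4 is "at least fourfold" (inclusive); fdr must be < max
  expect_setequal(apply_enrichment_filter(tab), c("g1", "g4"))
  expect_equal(apply_enrichment_filter(tab[0, ]), character(0))

  # one strongly enriched gene among nulls is found, exactly
  em <- simulate_count_matrix(300, enriched_ids = "gene00042", fold = 8,
                              dispersion = 0.1, rng_seed = 8, n_reps = 3)
  found <- apply_enrichment_filter(score_enrichment(em))
  expect_identical(found, "gene00042")
})

test_that("heatmap_matrix restricts and orders", {
  m <- matrix(1:12, 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_identical(heatmap_matrix(m, rownames(m)), m)
  sub <- heatmap_matrix(m, c("g3", "g1"))
  expect_identical(rownames(sub), c("g3", "g1"))
  expect_identical(dim(sub), c(2L, 3L))
  expect_error(heatmap_matrix(m, character(0)), "non-empty")
  expect_error(heatmap_matrix(m, c("g1", "nope")), "unknown")
})
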