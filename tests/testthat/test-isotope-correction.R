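test_that("correction matrix matches the binomial convolution", {
  cm1 <- build_correction_matrix(1, 0.0107)
  expect_equal(unname(cm1$matrix),
               rbind(c(0.9893, 0), c(0.0107, 1)), tolerance = 1e-12)
  cm0 <- build_correction_matrix(5, 0)
  expect_equal(unname(cm0$matrix), diag(6))
  cm2 <- build_correction_matrix(2, 0.5)
  expect_equal(unname(cm2$matrix[, 1]), c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_error(build_correction_matrix(3, 1), "natural_abundance")
  expect_error(build_correction_matrix(3, -0.1), "natural_abundance")
})

test_that("correction matrix columns are probability distributions and lower-triangular", {
  for (n in c(1, 3, 6, 11, 30)) {
    for (p in c(0, 0.0107, 0.1, 0.5)) {
      cm <- build_correction_matrix(n, p)$matrix
      expect_true(all(cm >= 0))
      expect_equal(unname(colSums(cm)), rep(1, n + 1), tolerance = 1e-12)
      expect_true(all(cm[upper.tri(cm)] == 0))
    }
  }
})

test_that("correction inverts the forward convolution exactly on noise-free input", {
  set.seed(42)
  for (n in c(3, 5, 6, 11)) {
    cm <- build_correction_matrix(n, 0.0107)
    x <- runif(n + 1); x <- x / sum(x)
    raw <- as.numeric(cm$matrix %*% x) * 5e5
    iv <- correct_distribution(raw, cm)
    expect_lt(max(abs(iv$corrected - x)), 1e-8)
    expect_lt(abs(iv$mean_enrichment - mean_enrichment(x, n)), 1e-8)
  }
})

test_that("a natural-abundance-only sample corrects to pure M+0", {
  cm <- build_correction_matrix(1, 0.0107)
  iv <- correct_distribution(c(0.9893, 0.0107), cm)
  expect_equal(iv$corrected, c(1, 0), tolerance = 1e-9)
  expect_equal(iv$mean_enrichment, 0, tolerance = 1e-9)
  cm6 <- build_correction_matrix(6, 0.0107)
  iv6 <- correct_distribution(as.numeric(cm6$matrix[, 1]), cm6)
  expect_equal(isotopologue_fraction(iv6$corrected, 0), 1, tolerance = 1e-8)
})

test_that("correction handles errors and scaling invariance", {
  cm <- build_correction_matrix(3, 0.0107)
  expect_error(correct_distribution(c(1, 0, 0), cm), "length")
  expect_error(correct_distribution(rep(0, 4), cm), "zero")
  raw <- as.numeric(cm$matrix %*% c(0.1, 0.2, 0.3, 0.4))
  a <- correct_distribution(raw, cm)
  b <- correct_distribution(raw * 1e4, cm)
  expect_equal(a$mean_enrichment, b$mean_enrichment, tolerance = 1e-10)
})

test_that("mean enrichment follows its definition", {
  expect_identical(mean_enrichment(c(0, 0, 0, 1), 3), 1)
  expect_identical(mean_enrichment(c(1, 0, 0, 0), 3), 0)
  expect_equal(mean_enrichment(c(0.25, 0.5, 0.25), 2), 0.5)
  expect_error(mean_enrichment(c(-0.1, 1.1), 1), "negative")
  expect_error(mean_enrichment(c(0.5, 0.5), 2), "length")
})

test_that("planted UDP-glucose M+6 and M+11 fractions are recovered under noise", {
  n <- 11
  x <- rep(0.5 / 10, n + 1)
  x[7] <- 0.4; x[12] <- 0.1  # M+6 = 0.4, M+11 = 0.1
  x <- x / sum(x)
  mets <- data.frame(name = "UDP_glucose", n_atoms = n)
  cfg <- isotope_sim_config(metabolites = mets, days = 1L,
                            true_distributions = list(UDP_glucose = list("1" = x)),
                            noise_cv = 0.02, n_replicates = 3L, seed = 7)
  sim <- simulate_isotopologues(cfg)
  res <- correct_isotopologue_table(sim$intensities)
  for (r in 1:3) {
    got <- res$corrected$fraction[res$corrected$replicate == r]
    expect_lt(abs(isotopologue_fraction(got, 6) - x[7]), 0.02)
    expect_lt(abs(isotopologue_fraction(got, 11) - x[12]), 0.02)
  }
  expect_error(isotopologue_fraction(x, 12), "out of range")
})

test_that("protein normalization is proportional", {
  expect_identical(normalize_by_protein(100, 10), 10)
  expect_identical(normalize_by_protein(0, 5), 0)
  expect_equal(normalize_by_protein(80, 5) / normalize_by_protein(80, 10), 2)
  expect_error(normalize_by_protein(1, 0), "protein_ug")
})
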