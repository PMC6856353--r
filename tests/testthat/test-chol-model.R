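test_that("expected covariance assembles within- and cross-twin blocks", {
  # no familial variance: E identity only
  m <- chol_model(2)
  m <- set_paths(m, A = matrix(0, 2, 2), E = diag(2))
  S <- expected_covariance(m, "MZ")
  expect_equal(S, diag(4))

  # worked bivariate AE example (explicit matrix products)
  m <- demo_ae_model()
  A <- matrix(c(0.6, 0.3, 0, 0.4), 2)
  E <- matrix(c(0.8, 0.1, 0, 0.5), 2)
  W <- tcrossprod(A) + tcrossprod(E)
  expect_equal(W, matrix(c(1.00, 0.26, 0.26, 0.51), 2))
  Smz <- expected_covariance(m, "MZ")
  expect_equal(Smz[1:2, 3:4], matrix(c(0.36, 0.18, 0.18, 0.25), 2))
  expect_equal(Smz[1:2, 1:2], W)
  expect_true(isSymmetric(Smz))

  Sdz <- expected_covariance(m, "DZ")
  expect_equal(Sdz[1:2, 3:4], matrix(c(0.18, 0.09, 0.09, 0.125), 2))
  expect_equal(Sdz[1:2, 3:4], 0.5 * Smz[1:2, 3:4])

  # MZ cross-twin A block equals the within-twin A block exactly; C adds to both
  mc <- chol_model(2, C = "free")
  mc <- set_paths(mc, A = A, C = matrix(c(0.3, 0.2, 0, 0.25), 2), E = E)
  Smzc <- expected_covariance(mc, "MZ")
  Sdzc <- expected_covariance(mc, "DZ")
  CC <- tcrossprod(matrix(c(0.3, 0.2, 0, 0.25), 2))
  expect_equal(Smzc[1:2, 3:4], tcrossprod(A) + CC)
  expect_equal(Sdzc[1:2, 3:4], 0.5 * tcrossprod(A) + CC)

  m_bad <- set_paths(m, A = matrix(c(NaN, 0, 0, 0), 2))
  expect_error(expected_covariance(m_bad, "MZ"), "non-finite")
})

test_that("genetic correlation follows the path formula and a latent-simulation oracle", {
  base <- function(a21, a22) {
    set_paths(chol_model(2), A = matrix(c(0.6, a21, 0, a22), 2),
              E = matrix(c(0.8, 0.1, 0, 0.5), 2))
  }
  expect_equal(genetic_correlation(base(0, 0.4)), 0)
  expect_equal(genetic_correlation(base(0.3, 0)), 1)
  expect_equal(genetic_correlation(base(0.3, 0.4)), 0.18 / sqrt(0.36 * 0.25))

  # oracle: correlate the simulated latent genetic components directly
  set.seed(7)
  z1 <- rnorm(1e6); z2 <- rnorm(1e6)
  A1 <- 0.6 * z1
  A2 <- 0.3 * z1 + 0.4 * z2
  expect_equal(genetic_correlation(base(0.3, 0.4)), cor(A1, A2),
               tolerance = 0.005)

  # zero genetic variance in a trait: undefined
  m0 <- set_paths(chol_model(2), A = matrix(0, 2, 2),
                  E = matrix(c(1, 0, 0, 1), 2))
  expect_true(is.na(genetic_correlation(m0)))
})

test_that("bivariate heritability decomposes the implied phenotypic correlation", {
  m <- demo_ae_model()
  expect_equal(bivariate_heritability(m), 0.18 / sqrt(0.51))
  expect_equal(bivariate_heritability(m, "E"), 0.08 / sqrt(0.51))
  expect_equal(bivariate_heritability(m) + bivariate_heritability(m, "E"),
               0.26 / sqrt(0.51))
  m0 <- set_paths(chol_model(2), A = matrix(c(0.6, 0, 0, 0.4), 2),
                  E = matrix(c(0.8, 0.1, 0, 0.5), 2))
  expect_equal(bivariate_heritability(m0), 0)
})

test_that("model degrees of freedom count free parameters against the saturated model", {
  expect_identical(model_df(chol_model(2)), 20L)          # bivariate AE
  uni <- chol_model(1)
  expect_identical(model_df(uni), 2L * (2L + 3L) - 3L)    # univariate AE: 7
  expect_identical(model_df(chol_model(2, C = "free")), 17L)
  # C loading on variable 1 only adds one parameter
  expect_identical(model_df(vertex_model_spec()), 19L)
})

test_that("component specifications parse and fixed entries persist", {
  m <- chol_model(2, C = matrix(c(NA, 0, 0, 0), 2, 2))
  expect_true(m$comps$C$free[1, 1])
  expect_false(any(m$comps$C$free[-1]))
  expect_identical(n_free_params(m), 6L + 1L + 2L)
  expect_error(chol_model(2, A = matrix(c(1, 1, 1, 1), 2, 2)),
               "lower triangular")
  expect_error(chol_model(2, E = "none"), "residual variance")
  m2 <- fix_path(chol_model(2), "A", 2, 1, at = 0)
  expect_false(m2$comps$A$free[2, 1])
  expect_identical(n_free_params(m2), 7L)
})
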