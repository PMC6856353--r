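test_that("simulated cross-twin covariance converges to its expectation", {
  # Falconer-style check: MZ cross-twin covariance -> AA' + CC',
  # DZ -> 0.5 AA' + CC' (elementwise, within 3 standard errors at n = 10^4)
  m <- chol_model(2, C = "free")
  A <- matrix(c(0.6, 0.3, 0, 0.4), 2)
  C <- matrix(c(0.35, 0.15, 0, 0.3), 2)
  E <- matrix(c(0.7, 0.1, 0, 0.5), 2)
  m <- set_paths(m, A = A, C = C, E = E)
  coh <- simulate_from_model(m, 10000, 10000, seed = 81)
  mz <- coh$data[coh$zygosity == "MZ", ]
  dz <- coh$data[coh$zygosity == "DZ", ]
  cross_mz <- cov(mz[, 1:2], mz[, 3:4])
  cross_dz <- cov(dz[, 1:2], dz[, 3:4])
  se <- 3 * 1.2 / sqrt(10000)  # conservative elementwise bound
  expect_true(all(abs(cross_mz - (tcrossprod(A) + tcrossprod(C))) < se))
  expect_true(all(abs(cross_dz - (0.5 * tcrossprod(A) + tcrossprod(C))) < se))
  # within-twin covariance matches the full ACE variance
  expect_true(all(abs(cov(mz[, 1:2]) -
                        (tcrossprod(A) + tcrossprod(C) + tcrossprod(E))) < se))
})

test_that("identical seeds reproduce cohorts bit for bit", {
  mesh <- make_mesh("sphere", 42, scale_mm = 50)
  s1 <- simulate_twin_cohort(mesh, n_mz = 50, n_dz = 50,
                             singleton_fraction = 0.1, seed = 7)
  s2 <- simulate_twin_cohort(mesh, n_mz = 50, n_dz = 50,
                             singleton_fraction = 0.1, seed = 7)
  expect_identical(s1$thickness, s2$thickness)
  expect_identical(s1$behavior, s2$behavior)
  s3 <- simulate_twin_cohort(mesh, n_mz = 50, n_dz = 50, seed = 8)
  expect_false(identical(s1$thickness, s3$thickness))
})

test_that("singleton deletion removes whole co-twins at the requested rate", {
  mesh <- make_mesh("sphere", 12, scale_mm = 50)
  s <- simulate_twin_cohort(mesh, n_mz = 400, n_dz = 400,
                            singleton_fraction = 0.25, seed = 9)
  n_single <- sum(is.na(s$pairing$row2))
  expect_gt(n_single, 800 * 0.15); expect_lt(n_single, 800 * 0.35)
  # deleted co-twins are missing across all vertices and traits
  gone <- which(s$truth$singleton)
  expect_true(all(is.na(s$thickness[800 + gone, ])))
  expect_true(all(is.na(s$behavior[800 + gone, ])))
})

test_that("planted clusters share genetic variance with behavior, elsewhere none", {
  mesh <- make_mesh("sphere", 162, scale_mm = 50)
  patch <- geodesic_patch(mesh, 1, 20)
  truth <- list(
    clusters = list(list(vertices = patch, loading = 0.55)),
    traits = list(list(name = "beh", a = sqrt(0.4), e = sqrt(0.6),
                       cross = 0.5)))
  s <- simulate_twin_cohort(mesh, truth, n_mz = 4000, n_dz = 4000, seed = 10)
  # within-person correlation of thickness with behavior, inside vs outside
  r_in <- mean(abs(cor(s$thickness[, patch], s$behavior[, 1])))
  out_v <- setdiff(seq_len(162), patch)
  r_out <- mean(abs(cor(s$thickness[, out_v], s$behavior[, 1])))
  expect_gt(r_in, 0.2)
  expect_lt(r_out, 0.05)
  # vertex total variance is preserved when loading is carved out of A
  v_in <- mean(apply(s$thickness[, patch], 2, var))
  expect_equal(v_in, 1, tolerance = 0.05)
})
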