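test_that("FIML log-likelihood matches the direct density oracle on complete data", {
  m <- demo_ae_model(means = c(0.3, -0.1))
  coh <- simulate_from_model(m, 40, 40, seed = 11)
  expect_equal(fiml_loglik(m, coh), ref_fiml_loglik(m, coh), tolerance = 1e-10)
})

test_that("singletons contribute marginal densities only", {
  m <- demo_ae_model()
  coh <- simulate_from_model(m, 60, 60, singleton_fraction = 0.3, seed = 12)
  expect_gt(sum(rowSums(is.na(coh$data)) > 0), 0)
  expect_equal(fiml_loglik(m, coh), ref_fiml_loglik(m, coh), tolerance = 1e-10)

  # scattered item-level missingness too
  d <- coh$data
  set.seed(13)
  holes <- cbind(sample(nrow(d), 25), sample(4, 25, replace = TRUE))
  d[holes] <- NA
  keep <- rowSums(!is.na(d)) > 0
  coh2 <- twin_cohort(d[keep, ], coh$zygosity[keep], coh$variables)
  expect_equal(fiml_loglik(m, coh2), ref_fiml_loglik(m, coh2),
               tolerance = 1e-10)
})

test_that("non-positive-definite implied covariance gives -Inf, not an error", {
  m <- set_paths(chol_model(2), A = matrix(0, 2, 2), E = matrix(0, 2, 2))
  coh <- simulate_from_model(demo_ae_model(), 10, 10, seed = 1)
  expect_identical(fiml_loglik(m, coh), -Inf)
})

test_that("the likelihood prefers the generating parameters over perturbed ones", {
  m <- demo_ae_model()
  pert <- demo_ae_model(a = c(0.8, 0.5, 0.6), e = c(1.0, 0.3, 0.7))
  wins <- 0L
  for (r in 1:100) {
    coh <- simulate_from_model(m, 500, 500, seed = 1000 + r)
    if (fiml_loglik(m, coh) > fiml_loglik(pert, coh)) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("fitting recovers generating paths and standardized shares", {
  m <- demo_ae_model()
  coh <- simulate_from_model(m, 1500, 1500, seed = 21)
  fit <- fit_model(coh, chol_model(2), n_starts = 3, seed = 2)
  expect_true(fit$converged)
  est <- fit$model$comps$A$values
  expect_equal(est[lower.tri(est, diag = TRUE)], c(0.6, 0.3, 0.4),
               tolerance = 0.08)
  # per-variable standardized shares sum to one
  expect_equal(unname(rowSums(fit$shares)), c(1, 1), tolerance = 1e-6)
  # E diagonals strictly positive, fixed entries untouched
  expect_true(all(diag(fit$model$comps$E$values) > 0))
  expect_identical(fit$model$comps$A$values[1, 2], 0)
  # bivariate decomposition identity
  expect_equal(sum(fit$bivariate), fit$implied_phenotypic_correlation,
               tolerance = 1e-6)
})

test_that("a true-null constraint costs almost no likelihood", {
  m <- demo_ae_model(a = c(0.6, 0, 0.5))  # no genetic cross path
  coh <- simulate_from_model(m, 400, 400, seed = 31)
  full <- fit_model(coh, chol_model(2), n_starts = 3, seed = 3)
  red <- fit_model(coh, fix_path(chol_model(2), "A", 2, 1), n_starts = 3,
                   seed = 3)
  lr <- lr_test(full, red)
  expect_identical(lr$df, 1L)
  expect_lt(lr$chi2, qchisq(0.999, 1))
  expect_gte(full$loglik, red$loglik - 1e-4)
})

test_that("likelihood-ratio test handles identical and non-nested models", {
  coh <- simulate_from_model(demo_ae_model(), 150, 150, seed = 41)
  fit <- fit_model(coh, chol_model(2), n_starts = 2, seed = 4)
  same <- lr_test(fit, fit)
  expect_equal(same$chi2, 0)
  expect_identical(same$df, 0L)
  expect_equal(same$p_value, 1)

  ace <- fit_model(coh, chol_model(2, C = "free"), n_starts = 2, seed = 4)
  expect_error(lr_test(fit, ace), "not nested")
  # and the saturated model dominates any nested fit
  sat <- fit_saturated(coh)
  expect_gte(sat$loglik, fit$loglik - 1e-4)
  expect_gte(sat$loglik, ace$loglik - 1e-4)
})

test_that("saturated model handles missingness patterns", {
  coh <- simulate_from_model(demo_ae_model(), 150, 150,
                             singleton_fraction = 0.2, seed = 43)
  sat <- fit_saturated(coh)
  fit <- fit_model(coh, chol_model(2), n_starts = 2, seed = 5)
  expect_gte(sat$loglik, fit$loglik - 1e-4)
})

test_that("fit indices follow their formulas", {
  # formula oracle on synthetic chi-square values
  fake_fit <- structure(list(loglik = -1000, model = chol_model(2)),
                        class = "twin_fit")
  sat <- list(loglik = -1000 + 30.264 / 2)
  base_model <- chol_model(2, A = "none", C = "none", E = "diag")
  fake_base <- structure(list(loglik = -1000 + 30.264 / 2 - 200 / 2,
                              model = base_model),
                         class = "twin_fit")
  fi <- fit_indices(fake_fit, sat, fake_base, n = 225)
  expect_equal(fi$chi2, 30.264)
  expect_identical(fi$df, 20L)
  expect_equal(fi$rmsea, sqrt(10.264 / (20 * 224)), tolerance = 1e-10)
  expect_equal(fi$cfi, 1 - 10.264 / (200 - 24), tolerance = 1e-10)
  expect_equal(fi$tli, ((200 / 24) - (30.264 / 20)) / ((200 / 24) - 1),
               tolerance = 1e-10)

  # perfect fit: chi2 = 0, RMSEA = 0, CFI = 1
  perfect <- structure(list(loglik = sat$loglik, model = chol_model(2)),
                       class = "twin_fit")
  fi0 <- fit_indices(perfect, sat, fake_base, n = 225)
  expect_equal(fi0$chi2, 0)
  expect_equal(fi0$rmsea, 0)
  expect_equal(fi0$cfi, 1)

  # degenerate baseline: TLI/CFI absent
  degen <- structure(list(loglik = sat$loglik - 1, model = base_model),
                     class = "twin_fit")
  fid <- fit_indices(fake_fit, sat, degen, n = 225)
  expect_true(is.na(fid$tli) && is.na(fid$cfi))

  # end to end on simulated data: true model fits acceptably
  coh <- simulate_from_model(demo_ae_model(), 300, 300, seed = 51)
  fit <- fit_model(coh, chol_model(2), n_starts = 2, seed = 6)
  fi2 <- fit_indices(fit, fit_saturated(coh), fit_independence(coh),
                     n = nrow(coh$data))
  expect_identical(fi2$df, 20L)
  expect_gt(fi2$p_value, 0.001)
  expect_lt(fi2$rmsea, 0.1)
})

test_that("fit summaries tabulate estimates and round-trip to TSV", {
  coh <- simulate_from_model(demo_ae_model(), 120, 120, seed = 61)
  fit <- fit_model(coh, chol_model(2), n_starts = 2, seed = 7)
  sm <- fit_summary(fit)
  expect_setequal(unique(sm$component), c("A", "E", "mean"))
  expect_equal(sum(sm$free), 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fit_summary(fit, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(sm))
  expect_equal(back$estimate, sm$estimate, tolerance = 1e-12)
})
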