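test_that("gene filtering removes excluded and unavailable genes", {
  sim <- simulate_expression(120, 10, k_true = 3, seed = 5)
  x <- sim$matrix
  expect_identical(suppressMessages(filter_genes(x))$genes, x$genes)
  flagged <- x$genes[1:20]
  expect_message(f <- filter_genes(x, exclusion_list = flagged),
                 "100 of 120 genes retained")
  expect_length(f$genes, 100)
  expect_false(any(flagged %in% f$genes))
  # availability mask composes with the exclusion list
  avail <- x$genes[1:60]
  f2 <- suppressMessages(filter_genes(x, flagged, avail))
  expect_length(f2$genes, 40)
  expect_error(suppressMessages(filter_genes(x, x$genes)), "no genes left")
})

test_that("elbow selection recovers planted cluster counts", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_expression(100, 10, k_true = 3, separation = 3,
                               noise_sd = 0.5, seed = 200 + s)
    res <- kmeans_elbow(sim$matrix, k_range = 1:8, n_init = 10, seed = s)
    if (res$chosen_k == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # labels at the chosen k match the planted partition (up to permutation)
  sim <- simulate_expression(100, 10, k_true = 3, separation = 3,
                             noise_sd = 0.5, seed = 300)
  res <- kmeans_elbow(sim$matrix, seed = 1)
  tab <- table(res$labels, sim$labels)
  expect_equal(sum(apply(tab, 1, max)), 100)
})

test_that("degenerate and single-cluster matrices choose k = 1", {
  flat <- expression_matrix(matrix(rep(1:10, each = 50), 50, 10,
                                   byrow = FALSE))
  res <- kmeans_elbow(flat, k_range = 1:5, seed = 1)
  expect_identical(res$chosen_k, 1L)
  expect_true(all(res$wss < 1e-8))

  one <- simulate_expression(80, 10, k_true = 1, seed = 9)
  expect_identical(kmeans_elbow(one$matrix, seed = 2)$chosen_k, 1L)
})

test_that("the WSS curve starts at the total sum of squares and never increases", {
  sim <- simulate_expression(60, 8, k_true = 2, seed = 17)
  res <- kmeans_elbow(sim$matrix, k_range = 1:6, n_init = 10, seed = 3)
  vals <- res$wss
  expect_true(all(diff(vals) <= 1e-8))
  # k = 1 WSS equals total SS about the grand centroid of the z-scored rows
  z <- t(scale(t(sim$matrix$values)))
  tot <- sum(sweep(z, 2, colMeans(z))^2)
  expect_equal(unname(vals[1]), tot, tolerance = 1e-8)
})

test_that("cluster labels are invariant to gene order up to permutation", {
  sim <- simulate_expression(90, 10, k_true = 3, separation = 4,
                             noise_sd = 0.4, seed = 23)
  res1 <- kmeans_elbow(sim$matrix, seed = 4)
  set.seed(5)
  ord <- sample(90)
  shuffled <- expression_matrix(sim$matrix$values[ord, ],
                                sim$matrix$genes[ord], sim$matrix$regions)
  res2 <- kmeans_elbow(shuffled, seed = 4)
  expect_identical(res2$chosen_k, res1$chosen_k)
  tab <- table(res1$labels[ord], res2$labels)
  expect_equal(sum(apply(tab, 1, max)), 90)
})

test_that("expression matrices round-trip through TSV", {
  sim <- simulate_expression(20, 6, k_true = 2, seed = 31)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$matrix, f)
  back <- read_expression_matrix(f)
  expect_identical(back$genes, sim$matrix$genes)
  expect_identical(back$regions, sim$matrix$regions)
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-10,
               ignore_attr = TRUE)
})
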