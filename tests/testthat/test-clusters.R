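test_that("cluster extraction respects significance, connectivity, and sign", {
  mesh <- make_mesh("sphere", 642, scale_mm = 50)
  nv <- nrow(mesh$coords)

  # nothing significant -> empty table
  null_map <- manual_vertex_map(nv, p_genetic = rep(0.5, nv),
                                effect = rep(0.1, nv))
  empty <- extract_clusters(null_map, mesh)
  expect_identical(nrow(empty), 0L)

  # one planted patch of ~40 mm extent
  patch <- geodesic_patch(mesh, 10, 20)
  p <- rep(0.5, nv); p[patch] <- 0.001
  eff <- rep(0.01, nv); eff[patch] <- 0.3
  map <- manual_vertex_map(nv, p, eff)
  tab <- extract_clusters(map, mesh, alpha = 0.05, extent_mm = 20)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$sign, "positive")
  expect_gt(jaccard(cluster_members(tab)[[1]], patch), 0.99)
  expect_gte(tab$extent_mm, 20)

  # a too-small patch is dropped by extent correction
  tiny <- geodesic_patch(mesh, 400, 8)
  p2 <- rep(0.5, nv); p2[tiny] <- 0.001
  map2 <- manual_vertex_map(nv, p2, eff)
  expect_identical(nrow(extract_clusters(map2, mesh, extent_mm = 20)), 0L)
  expect_identical(nrow(extract_clusters(map2, mesh, extent_mm = 2)), 1L)

  # area mode uses mm^2 against the same threshold argument
  tab_area <- extract_clusters(map, mesh, extent_mm = 100,
                               extent_mode = "area")
  expect_identical(nrow(tab_area), 1L)

  # invalid vertices are excluded even when nominally significant
  map3 <- map
  map3$valid[patch[1:5]] <- FALSE
  tab3 <- extract_clusters(map3, mesh)
  expect_false(any(patch[1:5] %in% cluster_members(tab3)[[1]]))
})

test_that("clusters split across sign and across broken connectivity", {
  mesh <- make_mesh("grid", 400, scale_mm = 100)
  nv <- nrow(mesh$coords)
  k <- sqrt(nv)
  # two horizontal significant bands joined only through a non-significant row
  idx <- matrix(seq_len(nv), k, k)  # column-major grid layout
  band1 <- as.vector(idx[, 3:5]); band2 <- as.vector(idx[, 7:9])
  p <- rep(0.5, nv); p[c(band1, band2)] <- 0.001
  eff <- rep(0.2, nv)
  map <- manual_vertex_map(nv, p, eff)
  tab <- extract_clusters(map, mesh, extent_mm = 5)
  expect_identical(nrow(tab), 2L)

  # opposite signs break an otherwise contiguous patch
  eff2 <- eff; eff2[band1] <- -0.2
  p3 <- rep(0.5, nv); p3[as.vector(idx[, 3:9])] <- 0.001
  map2 <- manual_vertex_map(nv, p3, eff2)
  tab2 <- extract_clusters(map2, mesh, extent_mm = 5)
  expect_identical(sort(tab2$sign), c("negative", "positive"))

  # lowering alpha never increases the significant vertex count
  n_sig <- function(alpha) sum(map$p_genetic < alpha)
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  expect_true(all(diff(vapply(alphas, n_sig, numeric(1))) <= 0))
})

test_that("cluster tables are invariant to vertex relabeling", {
  mesh <- make_mesh("sphere", 162, scale_mm = 50)
  nv <- nrow(mesh$coords)
  patch <- geodesic_patch(mesh, 42, 18)
  p <- rep(0.5, nv); p[patch] <- 0.01
  map <- manual_vertex_map(nv, p, rep(0.2, nv))
  tab <- extract_clusters(map, mesh, extent_mm = 10)

  set.seed(99)
  perm <- sample(nv)  # new index of old vertex i is perm[i]
  inv <- order(perm)
  mesh2 <- surface_mesh(mesh$coords[inv, ],
                        matrix(perm[mesh$triangles], ncol = 3),
                        mesh$hemisphere)
  map2 <- map[inv, ]; map2$vertex <- seq_len(nv)
  class(map2) <- class(map)
  tab2 <- extract_clusters(map2, mesh2, extent_mm = 10)
  expect_identical(nrow(tab2), nrow(tab))
  expect_setequal(perm[cluster_members(tab)[[1]]], cluster_members(tab2)[[1]])
  expect_equal(sort(tab2$extent_mm), sort(tab$extent_mm), tolerance = 1e-9)
  expect_equal(tab2$cog_x, tab$cog_x, tolerance = 1e-9)
})

test_that("cluster center of gravity is the unweighted member mean", {
  mesh <- make_mesh("sphere", 162, scale_mm = 50)
  expect_equal(cluster_cog(5, mesh), unname(mesh$coords[5, ]))
  m2 <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0)),
                     matrix(c(1, 2, 3), 1))
  expect_equal(cluster_cog(c(1, 2), m2), c(1, 0, 0))
  # a geodesic patch's COG sits near its seed (spherical cap centroid is
  # pulled inward along the axis, never sideways)
  patch <- geodesic_patch(mesh, 20, 15)
  cog <- cluster_cog(patch, mesh)
  seed_dir <- mesh$coords[20, ] / 50
  expect_lt(sqrt(sum((cog - sum(cog * seed_dir) * seed_dir)^2)), 2)
})

test_that("conjunction overlays intersect surviving clusters", {
  mesh <- make_mesh("sphere", 642, scale_mm = 50)
  nv <- nrow(mesh$coords)
  mk <- function(vs, effect_sign = 1) {
    p <- rep(0.5, nv); p[vs] <- 0.001
    extract_clusters(manual_vertex_map(nv, p, rep(0.2 * effect_sign, nv)),
                     mesh, extent_mm = 5)
  }
  pa <- geodesic_patch(mesh, 1, 18)
  pb <- geodesic_patch(mesh, 300, 18)
  # disjoint cluster sets -> empty overlay
  expect_identical(nrow(conjunction_overlay(mk(pa), mk(pb), mesh)), 0L)
  # identical sets -> overlay equals input
  ov_same <- conjunction_overlay(mk(pa), mk(pa), mesh)
  expect_identical(nrow(ov_same), 1L)
  expect_setequal(cluster_members(ov_same)[[1]], pa)
  # partial overlap -> exactly the intersected vertex set
  shift <- geodesic_patch(mesh, pa[length(pa)], 18)
  ov <- conjunction_overlay(mk(pa), mk(shift), mesh)
  expect_identical(nrow(ov), 1L)
  expect_setequal(cluster_members(ov)[[1]], intersect(pa, shift))
  # discordant signs are flagged, not silently merged
  ovd <- conjunction_overlay(mk(pa), mk(pa, effect_sign = -1), mesh)
  expect_true(all(ovd$discordant))
  # mesh mismatch rejected
  other <- make_mesh("sphere", 162, scale_mm = 50)
  expect_error(conjunction_overlay(mk(pa), mk(pa), other), "different mesh")
})

test_that("sign concordance measures directional agreement", {
  mesh <- make_mesh("sphere", 162, scale_mm = 50)
  nv <- nrow(mesh$coords)
  patch <- geodesic_patch(mesh, 1, 25)
  p <- rep(0.5, nv); p[patch] <- 0.001
  g <- manual_vertex_map(nv, p, rep(0.3, nv), effect_env = rep(0.1, nv))
  tab <- extract_clusters(g, mesh, extent_mm = 5)
  expect_equal(sign_concordance(g, g, tab)$concordance, 1)
  g_neg <- g; g_neg$bivariate_environmentality <- -g$bivariate_environmentality
  expect_equal(sign_concordance(g, g_neg, tab)$concordance, 0)
  set.seed(3)
  g_rand <- g
  g_rand$bivariate_environmentality <- sample(c(-1, 1), nv, TRUE) * 0.1
  cc <- sign_concordance(g, g_rand, tab)$concordance
  expect_gt(cc, 0.3); expect_lt(cc, 0.7)
})
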