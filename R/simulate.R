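#' Simulate a twin cohort with vertex-wise thickness and behavioral traits
#'
#' Generates MZ/DZ twin pairs under the generative mirror of the fitted
#' model: per-pair latent additive-genetic scores correlate 1.0 across MZ
#' co-twins and 0.5 across DZ co-twins, shared-environment scores are
#' identical within a pair, and non-shared environment is independent. Each
#' vertex's thickness is assembled from its own A/C/E paths; spatially
#' contiguous "planted" clusters receive part of their genetic variance from
#' a cluster-level genetic factor on which the behavioral trait(s) also
#' load, so that vertices inside a cluster share genetic variance with
#' behavior at a controlled cross-path magnitude while vertices outside are
#' genetically unrelated to it.
#'
#' The \code{truth} list has elements:
#' \describe{
#'   \item{vertex}{list \code{a}, \code{c}, \code{e}: unstandardized path
#'     scalars (or per-vertex vectors) for thickness. Defaults
#'     \code{a = sqrt(0.5)}, \code{c = sqrt(0.2)}, \code{e = sqrt(0.3)}:
#'     moderately heritable cortex with some shared environment.}
#'   \item{clusters}{list of planted clusters, each
#'     \code{list(vertices, loading)}: member vertex indices (a connected
#'     patch, e.g. from [geodesic_patch()]) and the loading of each member
#'     on the cluster genetic factor (carved out of the vertex's genetic
#'     variance, so total vertex variance is unchanged).}
#'   \item{traits}{list of behavioral traits, each
#'     \code{list(name, a, e, cross)}: total genetic and environmental path
#'     scalars and a vector of cross paths onto each cluster factor (0 =
#'     unrelated). Trait-specific genetic variance is reduced to keep
#'     \code{a^2} total.}
#' }
#'
#' @param mesh a [surface_mesh()] (only its vertex count is used here; the
#'   mesh carries the geometry for later cluster extraction).
#' @param truth generating parameters, see Details; missing parts get the
#'   defaults above.
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param singleton_fraction fraction of pairs whose second twin is deleted
#'   completely at random (matching the FIML missingness assumption).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list: \code{thickness} (individuals x vertices; twin 1 rows then
#'   twin 2 rows, deleted co-twins are \code{NA}), \code{behavior} (matrix
#'   individuals x traits), \code{pairing} ([twin_pairing()] rows aligned to
#'   the matrices), \code{cohorts} (list of behavioral [twin_cohort()]s, one
#'   per trait pair combination is left to the caller; here one cohort with
#'   all traits), and \code{truth} (the completed generating record).
#' @export
simulate_twin_cohort <- function(mesh, truth = list(), n_mz = 100, n_dz = 100,
                                 singleton_fraction = 0, seed = 1) {
  set.seed(seed)
  nv <- n_vertices(mesh)
  np <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  rA <- ifelse(zyg == "MZ", 1.0, 0.5)

  vt <- truth$vertex
  if (is.null(vt)) vt <- list()
  a_v <- rep_len(if (is.null(vt$a)) sqrt(0.5) else vt$a, nv)
  c_v <- rep_len(if (is.null(vt$c)) sqrt(0.2) else vt$c, nv)
  e_v <- rep_len(if (is.null(vt$e)) sqrt(0.3) else vt$e, nv)
  clusters <- if (is.null(truth$clusters)) list() else truth$clusters
  traits <- if (is.null(truth$traits))
    list(list(name = "trait", a = sqrt(0.4), e = sqrt(0.6),
              cross = rep(0.3, length(clusters)))) else truth$traits

  # correlated standard-normal pair draws: x2 = r x1 + sqrt(1-r^2) z
  twin_pair_normal <- function(n_col) {
    z1 <- matrix(stats::rnorm(np * n_col), np)
    z2 <- matrix(stats::rnorm(np * n_col), np)
    list(t1 = z1, t2 = rA * z1 + sqrt(1 - rA^2) * z2)
  }

  nc <- length(clusters)
  Fg <- twin_pair_normal(max(1, nc))  # cluster genetic factors
  Av <- twin_pair_normal(nv)          # vertex-specific genetic
  Cv <- matrix(stats::rnorm(np * nv), np)  # shared within pair
  E1 <- matrix(stats::rnorm(np * nv), np)
  E2 <- matrix(stats::rnorm(np * nv), np)

  load_v <- numeric(nv)
  cluster_of <- integer(nv)
  for (j in seq_len(nc)) {
    cl <- clusters[[j]]
    load_v[cl$vertices] <- rep_len(cl$loading, length(cl$vertices))
    cluster_of[cl$vertices] <- j
  }
  a_spec <- sqrt(pmax(0, a_v^2 - load_v^2))
  shared_term <- function(tw) {
    out <- matrix(0, np, nv)
    idx <- which(cluster_of > 0)
    if (length(idx))
      out[, idx] <- Fg[[tw]][, cluster_of[idx], drop = FALSE] *
        rep(load_v[idx], each = np)
    out
  }
  th1 <- Av$t1 * rep(a_spec, each = np) + shared_term("t1") +
    Cv * rep(c_v, each = np) + E1 * rep(e_v, each = np)
  th2 <- Av$t2 * rep(a_spec, each = np) + shared_term("t2") +
    Cv * rep(c_v, each = np) + E2 * rep(e_v, each = np)

  nt <- length(traits)
  Ab <- twin_pair_normal(nt)
  beh1 <- matrix(0, np, nt); beh2 <- matrix(0, np, nt)
  tnames <- character(nt)
  for (k in seq_len(nt)) {
    tr <- traits[[k]]
    tnames[k] <- if (is.null(tr$name)) paste0("trait", k) else tr$name
    cross <- if (nc == 0) numeric(0) else
      if (is.null(tr$cross)) numeric(nc) else rep_len(tr$cross, nc)
    a_tot <- tr$a; e_tot <- tr$e
    a_sp <- sqrt(max(0, a_tot^2 - sum(cross^2)))
    cr1 <- if (nc > 0) Fg$t1[, seq_len(nc), drop = FALSE] %*% cross else 0
    cr2 <- if (nc > 0) Fg$t2[, seq_len(nc), drop = FALSE] %*% cross else 0
    beh1[, k] <- a_sp * Ab$t1[, k] + cr1 + e_tot * stats::rnorm(np)
    beh2[, k] <- a_sp * Ab$t2[, k] + cr2 + e_tot * stats::rnorm(np)
  }

  # stack individuals: twin-1 rows then twin-2 rows; delete singleton co-twins
  singleton <- stats::runif(np) < singleton_fraction
  th2[singleton, ] <- NA_real_
  beh2[singleton, ] <- NA_real_
  thickness <- rbind(th1, th2)
  behavior <- rbind(beh1, beh2)
  colnames(behavior) <- tnames
  pairing <- data.frame(family_id = paste0("fam", seq_len(np)),
                        zygosity = zyg,
                        row1 = seq_len(np),
                        row2 = ifelse(singleton, NA_integer_, np + seq_len(np)))
  cohort <- twin_cohort(cbind(beh1, beh2), zyg, tnames,
                        family_id = pairing$family_id)
  truth_out <- list(vertex = list(a = a_v, c = c_v, e = e_v),
                    clusters = clusters, traits = traits,
                    singleton = singleton)
  list(thickness = thickness, behavior = behavior, pairing = pairing,
       cohort = cohort, truth = truth_out)
}

#' Simulate a behavioral-only twin cohort from a bivariate Cholesky model
#'
#' Direct generative form of the bivariate model: per pair, latent A vectors
#' with MZ/DZ cross-twin correlation 1.0/0.5 (and C shared, E independent)
#' are scaled through the Cholesky path matrices.
#'
#' @param model a [chol_model()] with path values populated (the generating
#'   truth).
#' @param n_mz,n_dz pair counts.
#' @param singleton_fraction completely-at-random co-twin deletion rate.
#' @param seed integer seed.
#' @return a [twin_cohort()].
#' @export
simulate_from_model <- function(model, n_mz, n_dz, singleton_fraction = 0,
                                seed = 1) {
  stopifnot(inherits(model, "chol_model"))
  set.seed(seed)
  p <- model$p
  np <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  rA <- ifelse(zyg == "MZ", 1.0, 0.5)
  A <- model$comps$A$values
  C <- if (is.null(model$comps$C)) NULL else model$comps$C$values
  E <- model$comps$E$values
  z1 <- matrix(stats::rnorm(np * p), np)
  z2 <- matrix(stats::rnorm(np * p), np)
  A1 <- z1; A2 <- rA * z1 + sqrt(1 - rA^2) * z2
  Cz <- matrix(stats::rnorm(np * p), np)
  x1 <- tcrossprod(A1, A) + tcrossprod(matrix(stats::rnorm(np * p), np), E)
  x2 <- tcrossprod(A2, A) + tcrossprod(matrix(stats::rnorm(np * p), np), E)
  if (!is.null(C)) {
    x1 <- x1 + tcrossprod(Cz, C)
    x2 <- x2 + tcrossprod(Cz, C)
  }
  x1 <- sweep(x1, 2, model$means, "+")
  x2 <- sweep(x2, 2, model$means, "+")
  singleton <- stats::runif(np) < singleton_fraction
  x2[singleton, ] <- NA_real_
  twin_cohort(cbind(x1, x2), zyg, model$variables)
}

#' Construct a populated bivariate AE model from correlations and heritabilities
#'
#' Builds the Cholesky path values of a two-trait AE model with unit total
#' variance per trait (so paths equal standardized paths), given each trait's
#' heritability and the target genetic and environmental correlations:
#' \eqn{a_{11} = \sqrt{h^2_1}}, \eqn{a_{21} = r_G \sqrt{h^2_2}},
#' \eqn{a_{22} = \sqrt{h^2_2 - a_{21}^2}}, and analogously for E with
#' \eqn{1 - h^2}. Useful as a generating model for simulation studies of
#' behavioral trait pairs (e.g. a depression scale and a callous-unemotional
#' trait scale with \eqn{r_G = 0.40}, \eqn{r_E = 0.04}).
#'
#' @param h2 length-2 heritabilities in (0, 1).
#' @param rG,rE genetic and non-shared environmental correlations in
#'   \eqn{[-1, 1]}.
#' @param variables trait names.
#' @return a populated [chol_model()] (AE, p = 2, zero means).
#' @export
bivariate_ae_model <- function(h2 = c(0.40, 0.48), rG = 0.40, rE = 0.04,
                               variables = c("trait1", "trait2")) {
  stopifnot(length(h2) == 2, all(h2 > 0), all(h2 < 1),
            abs(rG) <= 1, abs(rE) <= 1)
  u2 <- 1 - h2
  A <- matrix(c(sqrt(h2[1]), rG * sqrt(h2[2]), 0,
                sqrt(h2[2] * (1 - rG^2))), 2)
  E <- matrix(c(sqrt(u2[1]), rE * sqrt(u2[2]), 0,
                sqrt(u2[2] * (1 - rE^2))), 2)
  set_paths(chol_model(2, variables = variables), A = A, E = E)
}

#' Simulate a gene-by-region expression matrix with planted clusters
#'
#' Rows are drawn from \code{k_true} mean profiles (standard-normal centers
#' scaled by \code{separation}) plus independent Gaussian noise.
#'
#' @param n_genes,n_regions dimensions.
#' @param k_true number of planted profiles (\eqn{\le} n_genes).
#' @param separation scale of the profile centers relative to unit noise.
#' @param noise_sd per-entry noise standard deviation.
#' @param seed integer seed.
#' @return list: \code{matrix} (an [expression_matrix()]) and \code{labels}
#'   (true profile assignment per gene).
#' @export
simulate_expression <- function(n_genes = 100, n_regions = 10, k_true = 3,
                                separation = 3, noise_sd = 1, seed = 1) {
  stopifnot(k_true <= n_genes, k_true >= 1)
  set.seed(seed)
  centers <- matrix(stats::rnorm(k_true * n_regions, sd = separation),
                    k_true)
  labels <- rep_len(seq_len(k_true), n_genes)
  vals <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_regions, sd = noise_sd), n_genes)
  list(matrix = expression_matrix(vals), labels = labels)
}
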