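# Independent oracles, kept deliberately separate from the package's
# computation paths.

# direct multivariate-normal log-density via determinant() and solve()
dmvnorm_log <- function(x, mu, Sigma) {
  k <- length(mu)
  ld <- determinant(Sigma, logarithm = TRUE)
  stopifnot(ld$sign > 0)
  d <- x - mu
  -0.5 * (k * log(2 * pi) + as.numeric(ld$modulus) +
            drop(t(d) %*% solve(Sigma, d)))
}

# pair-by-pair FIML log-likelihood: loops observations, deletes missing
# rows/columns, sums direct densities
ref_fiml_loglik <- function(model, cohort) {
  total <- 0
  mu <- rep(model$means, 2)
  for (i in seq_len(nrow(cohort$data))) {
    x <- cohort$data[i, ]
    obs <- which(!is.na(x))
    Sigma <- expected_covariance(model, cohort$zygosity[i])
    total <- total + dmvnorm_log(x[obs], mu[obs],
                                 Sigma[obs, obs, drop = FALSE])
  }
  total
}

# populated bivariate AE generating model used across tests
demo_ae_model <- function(a = c(0.6, 0.3, 0.4), e = c(0.8, 0.1, 0.5),
                          means = c(0, 0)) {
  m <- chol_model(2)
  set_paths(m,
            A = matrix(c(a[1], a[2], 0, a[3]), 2),
            E = matrix(c(e[1], e[2], 0, e[3]), 2),
            means = means)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# hand-built vertex map (the structure fit_vertexwise returns)
manual_vertex_map <- function(nv, p_genetic, effect,
                              p_env = rep(0.5, nv),
                              effect_env = rep(0.1, nv),
                              valid = rep(TRUE, nv)) {
  out <- data.frame(vertex = seq_len(nv),
                    bivariate_heritability = effect,
                    bivariate_environmentality = effect_env,
                    p_genetic = p_genetic, p_environmental = p_env,
                    valid = valid)
  class(out) <- c("vertex_map", "data.frame")
  out
}
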