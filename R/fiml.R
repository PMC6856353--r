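# Parameter vector layout: free A entries, free C entries, free E entries
# (column-major within each component), then the p means.

build_cpp_spec <- function(model) {
  p <- model$p
  comp_mat <- function(cc) if (is.null(cc)) matrix(0, p, p) else cc$values
  comp_idx <- function(cc) {
    if (is.null(cc) || !any(cc$free)) return(matrix(0L, 0, 2))
    which(cc$free, arr.ind = TRUE)
  }
  list(p = as.integer(p),
       A = comp_mat(model$comps$A), C = comp_mat(model$comps$C),
       E = comp_mat(model$comps$E), hasC = !is.null(model$comps$C),
       idxA = comp_idx(model$comps$A), idxC = comp_idx(model$comps$C),
       idxE = comp_idx(model$comps$E), means = model$means)
}

pack_theta <- function(model) {
  th <- numeric(0)
  for (nm in c("A", "C", "E")) {
    cc <- model$comps[[nm]]
    if (!is.null(cc)) th <- c(th, cc$values[cc$free])
  }
  c(th, model$means)
}

unpack_theta <- function(model, theta) {
  k <- 0
  for (nm in c("A", "C", "E")) {
    cc <- model$comps[[nm]]
    if (is.null(cc)) next
    nf <- sum(cc$free)
    if (nf > 0) {
      cc$values[cc$free] <- theta[k + seq_len(nf)]
      k <- k + nf
      model$comps[[nm]] <- cc
    }
  }
  model$means <- theta[k + seq_len(model$p)]
  model
}

#' Full-information maximum-likelihood log-likelihood of a twin cohort
#'
#' Sums, over twin pairs, the multivariate-normal log-density of each pair's
#' observed sub-vector under the model-implied, zygosity-specific expected
#' covariance and the equated means. Missing entries (including whole absent
#' co-twins) are marginalized out by row/column deletion, so singletons
#' contribute a p-dimensional density term.
#'
#' @param model a [chol_model()] with path and mean values populated.
#' @param cohort a [twin_cohort()].
#' @return scalar log-likelihood; \code{-Inf} if the implied covariance of
#'   any observed pattern is not positive definite.
#' @export
fiml_loglik <- function(model, cohort) {
  stopifnot(inherits(model, "chol_model"), inherits(cohort, "twin_cohort"))
  if (model$p != cohort$p) stop("model and cohort dimension mismatch")
  groups <- fiml_stats(cohort)
  .fiml_eval_cpp(pack_theta(model), build_cpp_spec(model), groups)
}

# data-driven starting values: pooled within-twin covariance split across the
# model's components
start_theta <- function(model, cohort) {
  p <- model$p
  d <- cohort$data
  S1 <- stats::cov(d[, seq_len(p), drop = FALSE], use = "pairwise.complete.obs")
  S2 <- stats::cov(d[, p + seq_len(p), drop = FALSE], use = "pairwise.complete.obs")
  Sw <- (S1 + S2) / 2
  Sw[!is.finite(Sw)] <- 0
  Sw <- Sw + diag(1e-3 + 0.05 * mean(diag(Sw)), p)
  hasC <- !is.null(model$comps$C)
  shares <- if (hasC) c(A = 0.35, C = 0.15, E = 0.5) else c(A = 0.4, C = 0, E = 0.6)
  m <- model
  for (nm in c("A", "C", "E")) {
    cc <- m$comps[[nm]]
    if (is.null(cc)) next
    L <- t(chol(shares[[nm]] * Sw))
    cc$values[cc$free] <- L[cc$free]
    m$comps[[nm]] <- cc
  }
  mu <- colMeans(rbind(d[, seq_len(p), drop = FALSE],
                       d[, p + seq_len(p), drop = FALSE]), na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  m$means <- mu
  pack_theta(m)
}

#' Fit a twin Cholesky model by FIML
#'
#' Maximizes [fiml_loglik()] over the free paths and means with multi-start
#' quasi-Newton (BFGS) optimization. Paths are parameterized directly on the
#' real line; after fitting, the sign of each component's diagonal entries is
#' normalized nonnegative (sign flips of a path-matrix column leave the
#' implied covariance unchanged). Starting values are data driven (pooled
#' within-twin covariance split across components); additional starts are
#' jittered.
#'
#' @param cohort a [twin_cohort()] containing both zygosity groups (a single
#'   group is allowed but leaves A and C unidentified).
#' @param model a [chol_model()] free/fixed specification; default full
#'   bivariate/multivariate AE.
#' @param n_starts number of optimization starts (first is data driven).
#' @param seed optional seed for the start jitter.
#' @param start optional numeric parameter vector used as the first start
#'   (warm start), e.g. from a neighboring vertex's fit.
#' @param max_iter BFGS iteration cap per start.
#' @return An object of class \code{"twin_fit"}: the model with estimates,
#'   \code{loglik}, standardized path matrices, variance shares, and (for
#'   p = 2) genetic/environmental correlations and bivariate heritability.
#'   \code{converged} is \code{FALSE} when every start failed; estimates are
#'   then from the best non-converged start and downstream callers should
#'   treat the fit as invalid.
#' @seealso [genetic_correlation()], [bivariate_heritability()], [lr_test()]
#' @export
fit_model <- function(cohort, model = chol_model(cohort$p, variables = cohort$variables),
                      n_starts = 5, seed = NULL, start = NULL, max_iter = 500) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (n_free_params(model) < 1 + model$p) stop("model has no free paths")
  groups <- fiml_stats(cohort)
  cspec <- build_cpp_spec(model)
  negll <- function(th) {
    v <- .fiml_eval_cpp(th, cspec, groups)
    if (!is.finite(v)) 1e10 else -v
  }
  if (!is.null(seed)) set.seed(seed)
  theta0 <- if (!is.null(start)) as.numeric(start) else start_theta(model, cohort)
  npar <- length(pack_theta(model))
  stopifnot(length(theta0) == npar)
  p <- model$p
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    th <- theta0
    if (s > 1) {
      jit <- stats::rnorm(npar, 0, 0.2)
      jit[npar - p + seq_len(p)] <- stats::rnorm(p, 0, 0.1)  # means
      th <- theta0 + jit * pmax(abs(theta0), 0.5)
    }
    opt <- tryCatch(
      stats::optim(th, negll, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) next
    conv <- opt$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    warning("all optimization starts failed")
    fit <- finalize_fit(model, rep(NA_real_, npar), NA_real_, cohort, FALSE)
    return(fit)
  }
  if (!any_conv) warning("no optimization start reported convergence")
  finalize_fit(model, best$par, -best$value, cohort, any_conv)
}

finalize_fit <- function(model, theta, loglik, cohort, converged) {
  m <- unpack_theta(model, theta)
  # normalize diagonal path signs (column flips leave the model invariant)
  if (all(is.finite(theta))) {
    for (nm in c("A", "C", "E")) {
      cc <- m$comps[[nm]]
      if (is.null(cc)) next
      for (j in seq_len(m$p)) {
        if (cc$values[j, j] < 0) cc$values[, j] <- -cc$values[, j]
      }
      m$comps[[nm]] <- cc
    }
  }
  fit <- list(model = m, loglik = loglik,
              n_free_params = n_free_params(m),
              converged = converged,
              n_pairs = nrow(cohort$data),
              n_families = nrow(cohort$data),
              variables = cohort$variables)
  fit <- c(fit, derived_quantities(m))
  class(fit) <- "twin_fit"
  fit
}

derived_quantities <- function(model) {
  p <- model$p
  vals <- lapply(model$comps, function(cc) if (is.null(cc)) NULL else cc$values)
  if (any(vapply(Filter(Negate(is.null), vals),
                 function(x) any(!is.finite(x)), logical(1)))) {
    return(list(shares = NULL, std = NULL, rG = NA_real_, rC = NA_real_,
                rE = NA_real_, bivariate = NULL,
                implied_phenotypic_correlation = NA_real_))
  }
  cov_of <- function(v) if (is.null(v)) matrix(0, p, p) else tcrossprod(v)
  Acov <- cov_of(vals$A); Ccov <- cov_of(vals$C); Ecov <- cov_of(vals$E)
  S <- Acov + Ccov + Ecov
  dS <- diag(S)
  shares <- cbind(A = diag(Acov) / dS, C = diag(Ccov) / dS, E = diag(Ecov) / dS)
  rownames(shares) <- model$variables
  Dinv <- diag(1 / sqrt(dS), p)
  std <- list(A = if (is.null(vals$A)) NULL else Dinv %*% vals$A,
              C = if (is.null(vals$C)) NULL else Dinv %*% vals$C,
              E = if (is.null(vals$E)) NULL else Dinv %*% vals$E)
  out <- list(shares = shares, std = std)
  latent_cor <- function(M) {
    if (M[1, 1] <= 1e-12 || M[2, 2] <= 1e-12) return(NA_real_)
    max(-1, min(1, M[1, 2] / sqrt(M[1, 1] * M[2, 2])))
  }
  if (p == 2) {
    denom <- sqrt(S[1, 1] * S[2, 2])
    out$rG <- latent_cor(Acov)
    out$rC <- if (is.null(vals$C)) NA_real_ else latent_cor(Ccov)
    out$rE <- latent_cor(Ecov)
    out$bivariate <- c(A = Acov[1, 2] / denom, C = Ccov[1, 2] / denom,
                       E = Ecov[1, 2] / denom)
    out$implied_phenotypic_correlation <- S[1, 2] / denom
  } else {
    out$rG <- NA_real_; out$rC <- NA_real_; out$rE <- NA_real_
    out$bivariate <- NULL
    out$implied_phenotypic_correlation <- NA_real_
  }
  out
}

#' @export
print.twin_fit <- function(x, digits = 4, ...) {
  cat("Twin Cholesky FIML fit (", x$n_pairs, " pairs, ",
      x$n_free_params, " free parameters)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 10),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  if (!is.null(x$shares)) {
    cat("  standardized variance shares:\n")
    print(round(x$shares, digits))
  }
  if (!is.null(x$bivariate)) {
    cat("  rG =", round(x$rG, digits), " rE =", round(x$rE, digits),
        if (!is.na(x$rC)) paste(" rC =", round(x$rC, digits)) else "", "\n")
    cat("  bivariate heritability =", round(x$bivariate["A"], digits),
        "; bivariate environmentality =", round(x$bivariate["E"], digits), "\n")
    cat("  implied phenotypic r =",
        round(x$implied_phenotypic_correlation, digits), "\n")
  }
  invisible(x)
}

#' Genetic (or environmental) correlation from a bivariate fit
#'
#' The correlation of the two traits' latent additive-genetic components,
#' \eqn{r_G = a_{11} a_{21} / \sqrt{a_{11}^2 (a_{21}^2 + a_{22}^2)}}, i.e.
#' the off-diagonal of the genetic component covariance \eqn{AA'} scaled by
#' its variances. With \code{component = "E"} the same formula on the E paths
#' gives the non-shared environmental correlation \eqn{r_E}, and
#' \code{"C"} the shared-environmental correlation.
#'
#' @param fit a \code{"twin_fit"} from [fit_model()] (or a populated
#'   [chol_model()]), with p = 2.
#' @param component \code{"A"} (default), \code{"C"}, or \code{"E"}.
#' @return correlation in \eqn{[-1, 1]}; \code{NA} when either trait has zero
#'   variance for the component (the correlation is then undefined).
#' @export
genetic_correlation <- function(fit, component = c("A", "C", "E")) {
  component <- match.arg(component)
  model <- if (inherits(fit, "twin_fit")) fit$model else fit
  stopifnot(inherits(model, "chol_model"), model$p == 2)
  cc <- model$comps[[component]]
  if (is.null(cc)) return(NA_real_)
  M <- tcrossprod(cc$values)
  if (M[1, 1] <= 1e-12 || M[2, 2] <= 1e-12) return(NA_real_)
  max(-1, min(1, M[1, 2] / sqrt(M[1, 1] * M[2, 2])))
}

#' Bivariate heritability (genetic part of the phenotypic correlation)
#'
#' The portion of the implied phenotypic correlation attributable to a
#' component: the product of the standardized paths
#' \eqn{a_{11} \times a_{21}}, equal to the component's cross-trait
#' covariance divided by \eqn{\sqrt{S_{11} S_{22}}} with \eqn{S} the
#' within-twin phenotypic covariance. With \code{component = "E"} this is the
#' bivariate environmentality. The components' bivariate shares sum to the
#' implied phenotypic correlation.
#'
#' @inheritParams genetic_correlation
#' @return signed real; \code{NA} if total variance of either trait is zero.
#' @export
bivariate_heritability <- function(fit, component = c("A", "C", "E")) {
  component <- match.arg(component)
  model <- if (inherits(fit, "twin_fit")) fit$model else fit
  stopifnot(inherits(model, "chol_model"), model$p == 2)
  q <- derived_quantities(model)
  if (is.null(q$bivariate)) return(NA_real_)
  unname(q$bivariate[component])
}

free_pattern_matrix <- function(model, component) {
  cc <- model$comps[[component]]
  if (is.null(cc)) matrix(FALSE, model$p, model$p) else cc$free
}

#' Likelihood-ratio (chi-square difference) test of nested twin models
#'
#' @param full,reduced \code{"twin_fit"} objects on the same cohort; the
#'   reduced model's free pattern must be a subset of the full model's.
#' @return list with \code{chi2} (clipped at 0), \code{df} (difference in
#'   free-parameter counts) and \code{p_value} from the upper chi-square tail.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "twin_fit"), inherits(reduced, "twin_fit"))
  for (nm in c("A", "C", "E")) {
    ff <- free_pattern_matrix(full$model, nm)
    fr <- free_pattern_matrix(reduced$model, nm)
    if (any(fr & !ff))
      stop("models are not nested: reduced frees a ", nm,
           " path fixed in the full model")
  }
  df <- as.integer(full$n_free_params - reduced$n_free_params)
  if (df < 0) stop("reduced model has more free parameters than the full model")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) as.numeric(chi2 < 1e-6) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

#' Saturated (unstructured) multigroup model
#'
#' Per zygosity group, free means and an unstructured covariance for the
#' stacked twin-pair vector. When a group's data share one missingness
#' pattern the MLE is closed form (sample mean and MLE scatter); otherwise
#' the group likelihood is maximized numerically over a Cholesky
#' parameterization of its covariance.
#'
#' @param cohort a [twin_cohort()].
#' @return list with \code{loglik}, \code{n_free_params} (the conventional
#'   \eqn{n_{groups}(2p + 2p(2p+1)/2)} count), class \code{"twin_fit_sat"}.
#' @export
fit_saturated <- function(cohort) {
  p <- cohort$p
  k <- 2 * p
  ll <- 0
  for (z in unique(cohort$zygosity)) {
    rows <- which(cohort$zygosity == z)
    d <- cohort$data[rows, , drop = FALSE]
    obs <- !is.na(d)
    pats <- apply(obs, 1, paste, collapse = "")
    if (length(unique(pats)) == 1) {
      idx <- which(obs[1, ])
      x <- d[, idx, drop = FALSE]
      n <- nrow(x)
      xbar <- colMeans(x)
      S <- crossprod(sweep(x, 2, xbar)) / n
      ld <- determinant(S, logarithm = TRUE)
      if (ld$sign <= 0) stop("singular saturated covariance in group ", z)
      ll <- ll - 0.5 * n * (length(idx) * log(2 * pi) +
                              as.numeric(ld$modulus) + length(idx))
    } else {
      groups <- fiml_stats(twin_cohort(d, rep(z, nrow(d)), cohort$variables))
      S0 <- stats::cov(d, use = "pairwise.complete.obs")
      S0[!is.finite(S0)] <- 0
      S0 <- S0 + diag(1e-2 + 0.05 * mean(diag(S0), na.rm = TRUE), k)
      mu0 <- colMeans(d, na.rm = TRUE)
      L0 <- t(chol(S0))
      th0 <- c(mu0, L0[lower.tri(L0, diag = TRUE)])
      negll <- function(th) {
        v <- .mvn_sat_eval_cpp(th, k, groups)
        if (!is.finite(v)) 1e10 else -v
      }
      opt <- stats::optim(th0, negll, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-12))
      if (opt$value >= 1e9) stop("saturated fit failed in group ", z)
      ll <- ll - opt$value
    }
  }
  structure(list(loglik = ll,
                 n_free_params = length(unique(cohort$zygosity)) *
                   (k + k * (k + 1) / 2)),
            class = "twin_fit_sat")
}

#' Independence (baseline) model
#'
#' Diagonal within-twin covariance, no familial covariance: an E-only model
#' with diagonal E, means and variances equated across twin order and
#' zygosity. Used as the null baseline for incremental fit indices.
#'
#' @param cohort a [twin_cohort()].
#' @return a \code{"twin_fit"}.
#' @export
fit_independence <- function(cohort) {
  m <- chol_model(cohort$p, A = "none", C = "none", E = "diag",
                  variables = cohort$variables)
  fit_model(cohort, m, n_starts = 1)
}

#' Chi-square, RMSEA, TLI and CFI for a fitted twin model
#'
#' \eqn{\chi^2 = 2(\ell_{sat} - \ell_{model})} with degrees of freedom from
#' [model_df()]; \eqn{RMSEA = \sqrt{\max(0, (\chi^2 - df)/(df\,(n-1)))}} with
#' \eqn{n} the number of families (the independent sampling units);
#' \eqn{CFI = 1 - \max(0, \chi^2_m - df_m)/\max(0, \chi^2_b - df_b)} and
#' \eqn{TLI = ((\chi^2_b/df_b) - (\chi^2_m/df_m)) / ((\chi^2_b/df_b) - 1)}
#' against the independence baseline.
#'
#' @param fit a \code{"twin_fit"} for the substantive model.
#' @param saturated result of [fit_saturated()] on the same cohort.
#' @param independence result of [fit_independence()] on the same cohort.
#' @param n number of families.
#' @return list of class \code{"twin_fit_indices"}: \code{chi2}, \code{df},
#'   \code{p_value}, \code{rmsea}, \code{tli}, \code{cfi} (TLI/CFI are
#'   \code{NA} when the baseline is degenerate, i.e.
#'   \eqn{\chi^2_b \le df_b} or \eqn{df_b = 0}).
#' @export
fit_indices <- function(fit, saturated, independence, n) {
  chi2 <- max(0, 2 * (saturated$loglik - fit$loglik))
  df <- model_df(fit$model)
  chi2_b <- max(0, 2 * (saturated$loglik - independence$loglik))
  df_b <- model_df(independence$model)
  rmsea <- if (df > 0) sqrt(max(0, (chi2 - df) / (df * (n - 1)))) else 0
  if (df_b == 0 || chi2_b <= df_b) {
    tli <- NA_real_; cfi <- NA_real_
  } else {
    cfi <- 1 - max(0, chi2 - df) / max(0, chi2_b - df_b)
    cfi <- max(0, min(1, cfi))
    rb <- chi2_b / df_b
    rm <- if (df > 0) chi2 / df else NA_real_
    tli <- if (is.na(rm)) NA_real_ else (rb - rm) / (rb - 1)
  }
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(list(chi2 = chi2, df = df, p_value = p,
                 rmsea = rmsea, tli = tli, cfi = cfi),
            class = "twin_fit_indices")
}

#' @export
print.twin_fit_indices <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f, p = %.3f, RMSEA = %.3f, TLI = %.3f, CFI = %.3f\n",
              x$df, x$chi2, x$p_value, x$rmsea, x$tli, x$cfi))
  invisible(x)
}

#' Tabulate a fitted model's path estimates
#'
#' @param fit a \code{"twin_fit"}.
#' @return data frame with one row per path (component, row, col, free flag,
#'   estimate, standardized estimate) plus the means.
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  m <- fit$model
  rows <- list()
  for (nm in c("A", "C", "E")) {
    cc <- m$comps[[nm]]
    if (is.null(cc)) next
    idx <- which(lower.tri(cc$values, diag = TRUE), arr.ind = TRUE)
    rows[[nm]] <- data.frame(
      component = nm, row = idx[, 1], col = idx[, 2],
      variable = m$variables[idx[, 1]],
      free = cc$free[idx],
      estimate = cc$values[idx],
      standardized = if (is.null(fit$std)) NA_real_ else fit$std[[nm]][idx])
  }
  paths <- do.call(rbind, rows)
  means <- data.frame(component = "mean", row = seq_len(m$p), col = NA,
                      variable = m$variables, free = TRUE,
                      estimate = m$means, standardized = NA_real_)
  out <- rbind(paths, means)
  rownames(out) <- NULL
  out
}

#' @rdname fit_summary
#' @param path output TSV path.
#' @export
write_fit_summary <- function(fit, path) {
  utils::write.table(fit_summary(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
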