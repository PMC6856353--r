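#' Pair individual-level rows into twin families
#'
#' Builds the pairing structure [fit_vertexwise()] needs to assemble, per
#' vertex, the (vertex, behavior) observation vectors of both co-twins.
#'
#' @param family_id vector of family identifiers, one per individual (row of
#'   the thickness matrix / behavior vector).
#' @param twin_order 1 or 2 per individual.
#' @param zygosity \code{"MZ"}/\code{"DZ"} per individual (constant within
#'   family).
#' @return data frame with one row per family: \code{family_id},
#'   \code{zygosity}, \code{row1}, \code{row2} (\code{NA} for singletons).
#' @export
twin_pairing <- function(family_id, twin_order, zygosity) {
  stopifnot(length(family_id) == length(twin_order),
            length(family_id) == length(zygosity))
  fams <- split(seq_along(family_id), family_id)
  rows <- lapply(names(fams), function(f) {
    idx <- fams[[f]]
    if (length(idx) > 2) stop("family ", f, " has more than two individuals")
    zy <- unique(as.character(zygosity[idx]))
    if (length(zy) != 1) stop("zygosity differs within family ", f)
    r1 <- idx[twin_order[idx] == 1]
    r2 <- idx[twin_order[idx] == 2]
    data.frame(family_id = f, zygosity = zy,
               row1 = if (length(r1)) r1 else NA_integer_,
               row2 = if (length(r2)) r2 else NA_integer_)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$row1) & is.na(out$row2))) stop("family with no members")
  out
}

#' Model specification for per-vertex brain-behavior Cholesky fits
#'
#' Bivariate Cholesky with the vertex as the first variable and the
#' behavioral trait as the second: full A and E, and a C component with only
#' the vertex-specific loading free (the C cross path and the trait-specific
#' C loading fixed at zero), for use when the behavioral trait itself shows
#' no shared-environment variance but the cortex does.
#'
#' @param with_c if \code{FALSE}, drop C entirely (plain AE).
#' @return a [chol_model()] with variables \code{c("vertex", "trait")}.
#' @export
vertex_model_spec <- function(with_c = TRUE) {
  C <- if (with_c) matrix(c(NA, 0, 0, 0), 2, 2) else "none"
  chol_model(2, A = "free", C = C, E = "free",
             variables = c("vertex", "trait"))
}

#' Fit the bivariate twin model at every vertex
#'
#' For each vertex, fits the (vertex, behavior) Cholesky model by FIML and
#' tests the genetic and environmental cross paths by chi-square difference
#' tests against the same model with that path fixed at zero. Returns signed
#' standardized bivariate heritability (product of the standardized a11 and
#' a21 paths), bivariate environmentality, and their likelihood-ratio
#' p-values. The trait's own fit to the first vertex seeds warm starts that
#' propagate across vertices for stability and speed; optimizer failures and
#' zero-variance vertices are marked invalid, never silently zeroed.
#'
#' Thickness columns and the behavior vector are assumed already residualized
#' on nuisance covariates (see [residualize()]).
#'
#' @param thickness numeric matrix, individuals x vertices.
#' @param behavior numeric vector, one value per individual.
#' @param pairing output of [twin_pairing()] aligning rows to families.
#' @param spec the per-vertex [chol_model()] (default [vertex_model_spec()]).
#' @param seed seed for optimizer start jitter.
#' @param n_starts optimization starts per vertex (warm starts make a small
#'   number adequate; raise for difficult data).
#' @param components which cross-path tests to run; dropping
#'   \code{"environmental"} skips one refit per vertex.
#' @param verbose print progress every 500 vertices.
#' @return data frame of class \code{"vertex_map"} with one row per vertex:
#'   \code{vertex}, \code{bivariate_heritability},
#'   \code{bivariate_environmentality}, \code{p_genetic},
#'   \code{p_environmental}, \code{valid}.
#' @export
fit_vertexwise <- function(thickness, behavior, pairing,
                           spec = vertex_model_spec(), seed = 1,
                           n_starts = 2,
                           components = c("genetic", "environmental"),
                           verbose = FALSE) {
  thickness <- as.matrix(thickness)
  stopifnot(nrow(thickness) == length(behavior))
  components <- match.arg(components, several.ok = TRUE)
  nv <- ncol(thickness)
  nfam <- nrow(pairing)
  set.seed(seed)

  spec_g0 <- fix_path(spec, "A", 2, 1, at = 0)
  spec_e0 <- fix_path(spec, "E", 2, 1, at = 0)

  r1 <- pairing$row1; r2 <- pairing$row2
  get_col <- function(x, rows) ifelse(is.na(rows), NA_real_, x[ifelse(is.na(rows), 1L, rows)])
  b1 <- get_col(behavior, r1); b2 <- get_col(behavior, r2)

  out <- data.frame(vertex = seq_len(nv),
                    bivariate_heritability = NA_real_,
                    bivariate_environmentality = NA_real_,
                    p_genetic = NA_real_, p_environmental = NA_real_,
                    valid = FALSE)
  warm <- NULL
  for (v in seq_len(nv)) {
    tv <- thickness[, v]
    d <- cbind(get_col(tv, r1), b1, get_col(tv, r2), b2)
    tvals <- as.vector(d[, c(1, 3)])
    if (all(is.na(tvals)) || stats::sd(tvals, na.rm = TRUE) < 1e-10) next
    keep <- rowSums(!is.na(d)) > 0
    cohort <- twin_cohort(d[keep, , drop = FALSE], pairing$zygosity[keep],
                          c("vertex", "trait"))
    fit <- tryCatch(
      suppressWarnings(fit_model(cohort, spec, n_starts = n_starts,
                                 start = warm)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$loglik)) next
    warm <- pack_theta(fit$model)
    row_ok <- TRUE
    if ("genetic" %in% components) {
      w0 <- zero_path_start(fit$model, spec_g0)
      fg <- tryCatch(
        suppressWarnings(fit_model(cohort, spec_g0, n_starts = 1, start = w0)),
        error = function(e) NULL)
      if (is.null(fg) || !fg$converged) row_ok <- FALSE
      else out$p_genetic[v] <- lr_test(fit, fg)$p_value
    }
    if ("environmental" %in% components && row_ok) {
      w0 <- zero_path_start(fit$model, spec_e0)
      fe <- tryCatch(
        suppressWarnings(fit_model(cohort, spec_e0, n_starts = 1, start = w0)),
        error = function(e) NULL)
      if (is.null(fe) || !fe$converged) row_ok <- FALSE
      else out$p_environmental[v] <- lr_test(fit, fe)$p_value
    }
    if (!row_ok) next
    out$bivariate_heritability[v] <- fit$bivariate["A"]
    out$bivariate_environmentality[v] <- fit$bivariate["E"]
    out$valid[v] <- TRUE
    if (verbose && v %% 500 == 0)
      message("vertex ", v, "/", nv)
  }
  class(out) <- c("vertex_map", "data.frame")
  out
}

# warm start for a reduced model: the full fit's estimates with the
# newly-fixed paths dropped from the parameter vector
zero_path_start <- function(full_model, reduced_spec) {
  m <- reduced_spec
  for (nm in c("A", "C", "E")) {
    cc <- m$comps[[nm]]
    if (is.null(cc)) next
    est <- full_model$comps[[nm]]$values
    est[!cc$free & cc$values == 0] <- 0
    vals <- cc$values
    vals[cc$free] <- est[cc$free]
    m$comps[[nm]]$values <- vals
  }
  m$means <- full_model$means
  pack_theta(m)
}
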