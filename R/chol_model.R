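#' Specify a twin Cholesky (ACE/AE) model
#'
#' Builds the path-matrix specification of a multivariate twin model in which
#' each variance component's covariance matrix is parameterized as the product
#' of a lower-triangular path matrix and its transpose: additive genetic
#' \eqn{AA'}, shared (common) environmental \eqn{CC'}, and non-shared
#' environmental \eqn{EE'}. Additive genetic latent factors correlate 1.0
#' across monozygotic co-twins and 0.5 across dizygotic co-twins; C factors
#' correlate 1.0 and E factors 0.0 in both zygosity groups. Means are equated
#' across twin order and zygosity (one mean per variable).
#'
#' Each component argument is one of:
#' \itemize{
#'   \item \code{"free"}: all lower-triangular entries free;
#'   \item \code{"none"}: component absent (all paths fixed at zero);
#'   \item \code{"diag"}: diagonal entries free, off-diagonals fixed at zero;
#'   \item a numeric lower-triangular \code{p x p} matrix where \code{NA}
#'     marks a free entry and numbers are fixed values.
#' }
#' The matrix form expresses constrained models, e.g. for per-vertex
#' brain-behavior fits a C component loading only on the vertex:
#' \code{C = matrix(c(NA, 0, 0, 0), 2, 2)}.
#'
#' @param p number of phenotypes per twin.
#' @param A,C,E component specifications (see Details). Defaults give a full
#'   AE model (\code{C = "none"}), the common choice when shared-environment
#'   paths on the behavioral traits are not supported by the data.
#' @param variables character vector of variable names (length \code{p}).
#' @param means optional numeric vector of starting/fixed mean values
#'   (default zeros). Means are always free parameters during fitting.
#' @return An object of class \code{"chol_model"}: the free/fixed pattern and
#'   current path values for each component.
#' @examples
#' chol_model(2)                          # bivariate AE
#' chol_model(2, C = "free")              # bivariate ACE
#' chol_model(2, C = matrix(c(NA, 0, 0, 0), 2, 2))  # C on variable 1 only
#' @export
chol_model <- function(p, A = "free", C = "none", E = "free",
                       variables = paste0("V", seq_len(p)), means = NULL) {
  stopifnot(p >= 1, length(variables) == p)
  comps <- list(A = parse_component(A, p, "A"),
                C = parse_component(C, p, "C"),
                E = parse_component(E, p, "E"))
  if (is.null(comps$E))
    stop("the E component cannot be 'none': every variable needs residual variance")
  if (is.null(means)) means <- rep(0, p)
  stopifnot(length(means) == p)
  structure(list(p = p, variables = variables, comps = comps,
                 means = as.numeric(means)),
            class = "chol_model")
}

parse_component <- function(x, p, name) {
  if (is.character(x)) {
    x <- match.arg(x, c("free", "none", "diag"))
    if (x == "none") return(NULL)
    free <- matrix(FALSE, p, p)
    if (x == "free") free[lower.tri(free, diag = TRUE)] <- TRUE
    if (x == "diag") diag(free) <- TRUE
    return(list(values = matrix(0, p, p), free = free))
  }
  if (is.matrix(x)) {
    stopifnot(nrow(x) == p, ncol(x) == p)
    if (any(!is.na(x[upper.tri(x)]) & x[upper.tri(x)] != 0))
      stop(name, " path matrix must be lower triangular")
    free <- is.na(x) & lower.tri(x, diag = TRUE)
    values <- x
    values[is.na(values)] <- 0
    return(list(values = values, free = free))
  }
  stop("component spec must be a keyword or a numeric matrix")
}

#' Set path values on a model specification
#'
#' Fills in numeric path values (both free and fixed positions) so the model
#' can be used as a generating model or evaluated directly, e.g. with
#' [expected_covariance()] or [fiml_loglik()].
#'
#' @param model a [chol_model()] specification.
#' @param A,C,E optional \code{p x p} lower-triangular numeric matrices.
#' @param means optional length-\code{p} numeric vector.
#' @return The model with values replaced.
#' @export
set_paths <- function(model, A = NULL, C = NULL, E = NULL, means = NULL) {
  stopifnot(inherits(model, "chol_model"))
  p <- model$p
  put <- function(slot, m) {
    stopifnot(is.matrix(m), nrow(m) == p, ncol(m) == p)
    if (any(m[upper.tri(m)] != 0)) stop("path matrices must be lower triangular")
    if (is.null(model$comps[[slot]]))
      stop("component ", slot, " is absent from this model")
    model$comps[[slot]]$values <<- m
  }
  if (!is.null(A)) put("A", A)
  if (!is.null(C)) put("C", C)
  if (!is.null(E)) put("E", E)
  if (!is.null(means)) {
    stopifnot(length(means) == p)
    model$means <- as.numeric(means)
  }
  model
}

#' Fix a single path at a value
#'
#' Convenience for nested-model tests: returns a copy of the model in which
#' one path entry is removed from the free pattern and held at \code{at}.
#'
#' @param model a [chol_model()].
#' @param component \code{"A"}, \code{"C"} or \code{"E"}.
#' @param row,col 1-based entry position (must be lower-triangular).
#' @param at fixed value (default 0).
#' @export
fix_path <- function(model, component, row, col, at = 0) {
  stopifnot(inherits(model, "chol_model"), row >= col)
  comp <- model$comps[[component]]
  if (is.null(comp)) stop("component ", component, " is absent")
  comp$free[row, col] <- FALSE
  comp$values[row, col] <- at
  model$comps[[component]] <- comp
  model
}

#' Number of free parameters (paths + means)
#' @param model a [chol_model()].
#' @return integer count; means (one per variable) are always counted free.
#' @export
n_free_params <- function(model) {
  as.integer(sum(vapply(model$comps,
                        function(cc) if (is.null(cc)) 0L else sum(cc$free),
                        integer(1))) + model$p)
}

#' Degrees of freedom of a twin model against the saturated model
#'
#' The saturated multigroup model has, per zygosity group, \eqn{2p} means and
#' \eqn{2p(2p+1)/2} covariances for the stacked twin-pair observation vector.
#' With means equated across twin order and zygosity, the fitted model spends
#' its free paths plus \eqn{p} means, so
#' \deqn{df = n_{groups}(2p + 2p(2p+1)/2) - (n_{free\ paths} + p).}
#' A bivariate AE model (6 free paths, 2 means) against 2 zygosity groups of
#' 4 observed variables gives \eqn{2(4+10) - 8 = 20}.
#'
#' @param model a [chol_model()].
#' @param n_groups number of zygosity groups (default 2: MZ and DZ).
#' @return integer degrees of freedom.
#' @export
model_df <- function(model, n_groups = 2) {
  p <- model$p
  k <- 2 * p
  df <- n_groups * (k + k * (k + 1) / 2) - n_free_params(model)
  if (df < 0) stop("model has more free parameters than the saturated model")
  as.integer(df)
}

#' @export
print.chol_model <- function(x, ...) {
  cat("Twin Cholesky model:", x$p, "phenotype(s);",
      paste(names(Filter(Negate(is.null), x$comps)), collapse = ""),
      "components;", n_free_params(x), "free parameters\n")
  invisible(x)
}

#' Expected twin-pair covariance matrix under a Cholesky model
#'
#' Assembles the model-implied \eqn{2p \times 2p} covariance of the stacked
#' (twin 1, twin 2) observation vector. The within-twin block is
#' \eqn{AA' + CC' + EE'}; the cross-twin block is \eqn{f\,AA' + CC'}, where
#' the genetic cross-twin factor \eqn{f} is 1.0 for monozygotic and 0.5 for
#' dizygotic pairs.
#'
#' @param model a [chol_model()] with path values populated.
#' @param zygosity \code{"MZ"} or \code{"DZ"}.
#' @return symmetric \code{2p x 2p} numeric matrix, variables ordered
#'   (twin-1 variables, then twin-2 variables).
#' @export
expected_covariance <- function(model, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(model, "chol_model"))
  zygosity <- match.arg(zygosity)
  f <- zygosity_factor(zygosity)
  vals <- lapply(model$comps, function(cc) if (is.null(cc)) NULL else cc$values)
  if (any(vapply(Filter(Negate(is.null), vals),
                 function(m) any(!is.finite(m)), logical(1))))
    stop("non-finite path values")
  AAt <- tcrossprod(vals$A)
  CCt <- if (is.null(vals$C)) matrix(0, model$p, model$p) else tcrossprod(vals$C)
  EEt <- tcrossprod(vals$E)
  W <- AAt + CCt + EEt
  X <- f * AAt + CCt
  rbind(cbind(W, X), cbind(X, W))
}

zygosity_factor <- function(zygosity) {
  unname(c(MZ = 1.0, DZ = 0.5)[zygosity])
}
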