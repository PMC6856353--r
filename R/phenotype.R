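#' Define a Likert scale for scoring
#'
#' @param name scale label (e.g. \code{"CESD"}, \code{"ICU"}).
#' @param n_items number of items.
#' @param reverse_coded integer indices of reverse-coded items.
#' @param min_completion minimum fraction of items that must be answered for
#'   a score to be computed (default 0.8).
#' @param likert_min,likert_max admissible response range (default 0..3, the
#'   usual 4-point Likert coding).
#' @return list of class \code{"scale_definition"}.
#' @export
scale_definition <- function(name, n_items, reverse_coded = integer(0),
                             min_completion = 0.8, likert_min = 0,
                             likert_max = 3) {
  stopifnot(n_items >= 1, min_completion > 0, min_completion <= 1,
            likert_max > likert_min)
  if (length(reverse_coded) &&
      (min(reverse_coded) < 1 || max(reverse_coded) > n_items))
    stop("reverse-coded indices out of range")
  structure(list(name = name, n_items = as.integer(n_items),
                 reverse_coded = as.integer(reverse_coded),
                 min_completion = min_completion,
                 likert_min = likert_min, likert_max = likert_max),
            class = "scale_definition")
}

#' Score a Likert scale with a completion rule
#'
#' The score is the mean of the answered items (reverse-coded items mapped as
#' \code{likert_max + likert_min - response} first) multiplied by the number
#' of items, provided at least \code{min_completion} of the items were
#' answered; otherwise the score is missing.
#'
#' @param responses numeric vector of item responses (length
#'   \code{def$n_items}), \code{NA} for unanswered items.
#' @param def a [scale_definition()].
#' @return scalar score, or \code{NA} under the completion threshold.
#' @examples
#' d <- scale_definition("demo", 20)
#' score_scale(rep(1, 20), d)  # 20
#' @export
score_scale <- function(responses, def) {
  stopifnot(inherits(def, "scale_definition"))
  if (length(responses) != def$n_items)
    stop("expected ", def$n_items, " responses, got ", length(responses))
  obs <- !is.na(responses)
  r <- responses[obs]
  if (any(r < def$likert_min | r > def$likert_max))
    stop("responses outside the Likert range [", def$likert_min, ", ",
         def$likert_max, "]")
  x <- responses
  if (length(def$reverse_coded))
    x[def$reverse_coded] <- def$likert_max + def$likert_min - x[def$reverse_coded]
  if (mean(obs) < def$min_completion) return(NA_real_)
  mean(x[obs]) * def$n_items
}

#' Square-root transform a nonnegative score
#'
#' Used to improve the normality of right-skewed symptom-count scores before
#' twin modeling.
#'
#' @param score numeric vector, nonnegative (\code{NA} passed through).
#' @return \code{sqrt(score)}.
#' @export
sqrt_transform <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("scores must be nonnegative")
  sqrt(score)
}

#' Residualize a variable on covariates
#'
#' Ordinary-least-squares residuals of \code{y} on an intercept plus the
#' covariates (e.g. sex and mean cortical thickness), computed over rows with
#' observed \code{y}; missing \code{y} stays missing. Residuals are exactly
#' orthogonal to the covariate columns.
#'
#' @param y numeric vector (may contain \code{NA}).
#' @param covariates numeric matrix or data frame, one row per element of
#'   \code{y}; must be complete for rows with observed \code{y}.
#' @return residual vector of the same length as \code{y}.
#' @export
residualize <- function(y, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y))
  obs <- !is.na(y)
  if (any(!stats::complete.cases(X[obs, , drop = FALSE])))
    stop("covariates missing for rows with observed y")
  # collinearity among covariates is rejected; a covariate collinear with the
  # intercept (constant) is harmless and simply centers y
  if (qr(X[obs, , drop = FALSE])$rank < ncol(X))
    stop("rank-deficient covariate matrix")
  Xf <- cbind(`(Intercept)` = 1, X[obs, , drop = FALSE])
  fit <- stats::lm.fit(Xf, y[obs])
  out <- rep(NA_real_, length(y))
  out[obs] <- fit$residuals
  out
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the OLS residuals of \code{x} and \code{y} on the
#' covariates, over jointly complete rows.
#'
#' @param x,y numeric vectors.
#' @param covariates matrix/data frame of controls.
#' @return scalar correlation; \code{NA} (with a warning) if either residual
#'   vector is degenerate (zero variance).
#' @export
partial_correlation <- function(x, y, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  stopifnot(length(x) == length(y), nrow(X) == length(x))
  ok <- !is.na(x) & !is.na(y) & stats::complete.cases(X)
  if (sum(ok) < 3 + ncol(X))
    stop("need at least ", 3 + ncol(X), " complete rows, have ", sum(ok))
  rx <- residualize(x[ok], X[ok, , drop = FALSE])
  ry <- residualize(y[ok], X[ok, , drop = FALSE])
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    warning("degenerate residuals; partial correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}
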