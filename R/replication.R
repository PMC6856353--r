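#' Split family identifiers into two halves
#'
#' @param family_ids vector of unique family identifiers.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @param mode \code{"balanced"} (default): a random partition into halves
#'   whose sizes differ by at most one; \code{"bernoulli"}: each family is
#'   assigned independently with probability 1/2, so half sizes vary
#'   (mirroring split-half draws such as 132/126 out of 258).
#' @return logical vector, \code{TRUE} for half 1.
#' @export
split_families <- function(family_ids, seed, mode = c("balanced", "bernoulli")) {
  mode <- match.arg(mode)
  n <- length(family_ids)
  stopifnot(n >= 2)
  set.seed(seed)
  if (mode == "balanced") {
    h1 <- sample(n, ceiling(n / 2))
    out <- seq_len(n) %in% h1
  } else {
    out <- stats::runif(n) < 0.5
    if (all(out) || !any(out)) out[sample(n, 1)] <- !out[1]  # avoid empty half
  }
  out
}

#' Family-preserving split-half of a twin cohort
#'
#' Partitions families (twin pairs stay together) randomly into two
#' sub-cohorts for split-half replication.
#'
#' @param cohort a [twin_cohort()].
#' @param seed integer seed.
#' @param mode see [split_families()].
#' @return list with \code{half1}, \code{half2} (twin cohorts) and
#'   \code{assignment} (logical per family, \code{TRUE} = half 1).
#' @export
split_by_family <- function(cohort, seed, mode = c("balanced", "bernoulli")) {
  stopifnot(inherits(cohort, "twin_cohort"))
  h1 <- split_families(cohort$family_id, seed, mode)
  sub <- function(keep) {
    twin_cohort(cohort$data[keep, , drop = FALSE], cohort$zygosity[keep],
                cohort$variables, cohort$family_id[keep])
  }
  list(half1 = sub(h1), half2 = sub(!h1), assignment = h1)
}

#' Triple conjunction of full-sample and split-half cluster tables
#'
#' A full-sample cluster is flagged replicated when it shares at least one
#' vertex with a same-sign surviving cluster in each half-sample analysis.
#' The returned table is the full-sample table with the \code{replicated}
#' column filled; the replicated subset is the high-confidence set.
#'
#' @param full,half1,half2 cluster tables on the same mesh (the halves fitted
#'   at their own vertex alpha, conventionally 0.05, with the same extent
#'   correction).
#' @param mesh the shared [surface_mesh()].
#' @return the full table with \code{replicated} logical per cluster.
#' @export
triple_conjunction <- function(full, half1, half2, mesh) {
  for (tb in list(full, half1, half2))
    if (!isTRUE(all.equal(attr(tb, "mesh_id"), mesh_id(mesh))))
      stop("cluster table was built on a different mesh")
  hits <- function(vs, sgn, tb) {
    mem <- cluster_members(tb)
    any(vapply(seq_along(mem), function(i) {
      tb$sign[i] == sgn && length(intersect(mem[[i]], vs)) > 0
    }, logical(1)))
  }
  memf <- cluster_members(full)
  rep_flag <- vapply(seq_along(memf), function(i) {
    hits(memf[[i]], full$sign[i], half1) && hits(memf[[i]], full$sign[i], half2)
  }, logical(1))
  full$replicated <- rep_flag
  full
}
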