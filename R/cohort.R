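#' Construct a twin cohort
#'
#' A twin cohort holds one row per family (twin pair), with the observation
#' vectors of both co-twins side by side: columns are ordered
#' (variable 1 twin 1, ..., variable p twin 1, variable 1 twin 2, ...,
#' variable p twin 2). Missing entries are \code{NA}; a singleton is a pair
#' whose second twin's entries are all \code{NA}. Singletons still contribute
#' to the likelihood through the marginal density of their observed entries,
#' so they inform means and variances.
#'
#' @param data numeric matrix or data frame, \code{n_pairs x 2p}.
#' @param zygosity character/factor of \code{"MZ"}/\code{"DZ"} per pair.
#' @param variables names of the \code{p} phenotypes.
#' @param family_id optional identifiers (default \code{1:n}).
#' @return An object of class \code{"twin_cohort"}.
#' @export
twin_cohort <- function(data, zygosity, variables, family_id = NULL) {
  data <- as.matrix(data)
  p <- length(variables)
  stopifnot(ncol(data) == 2 * p, nrow(data) == length(zygosity))
  zygosity <- as.character(zygosity)
  if (!all(zygosity %in% c("MZ", "DZ")))
    stop("zygosity entries must be 'MZ' or 'DZ'")
  if (any(rowSums(!is.na(data)) == 0))
    stop("every pair must have at least one observed value")
  if (is.null(family_id)) family_id <- seq_len(nrow(data))
  colnames(data) <- c(paste0(variables, "_t1"), paste0(variables, "_t2"))
  structure(list(data = data, zygosity = zygosity, variables = variables,
                 family_id = family_id, p = p),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("Twin cohort:", nrow(x$data), "pairs (",
      sum(x$zygosity == "MZ"), "MZ,", sum(x$zygosity == "DZ"), "DZ ),",
      x$p, "phenotype(s):", paste(x$variables, collapse = ", "), "\n")
  ns <- sum(rowSums(!is.na(x$data[, x$p + seq_len(x$p), drop = FALSE])) == 0)
  if (ns > 0) cat("  ", ns, "singleton(s)\n")
  invisible(x)
}

#' Build a twin cohort from an individual-level phenotype table
#'
#' Reshapes a long table (one row per individual) into paired form. The table
#' must carry \code{family_id}, \code{twin} (1 or 2), and \code{zygosity}
#' columns; zygosity must be constant within family and families must contain
#' at most two individuals.
#'
#' @param df data frame, one row per individual.
#' @param variables character vector of phenotype column names.
#' @return A [twin_cohort()].
#' @export
as_twin_cohort <- function(df, variables) {
  need <- c("family_id", "twin", "zygosity", variables)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  fams <- split(df, df$family_id)
  p <- length(variables)
  rows <- lapply(fams, function(fd) {
    if (nrow(fd) > 2) stop("family ", fd$family_id[1], " has >2 individuals")
    if (length(unique(fd$zygosity)) != 1)
      stop("zygosity differs within family ", fd$family_id[1])
    out <- rep(NA_real_, 2 * p)
    for (i in seq_len(nrow(fd))) {
      tw <- fd$twin[i]
      if (!tw %in% c(1, 2)) stop("twin must be 1 or 2")
      out[(tw - 1) * p + seq_len(p)] <- as.numeric(fd[i, variables])
    }
    out
  })
  data <- do.call(rbind, rows)
  zyg <- vapply(fams, function(fd) as.character(fd$zygosity[1]), character(1))
  twin_cohort(data, zyg, variables, family_id = names(fams))
}

# Sufficient statistics for FIML: pairs grouped by zygosity x missingness
# pattern; per group the count, mean vector and MLE scatter matrix of the
# observed entries.  The likelihood of a group is then a closed function of
# the model-implied covariance restricted to its observed entries.
fiml_stats <- function(cohort) {
  data <- cohort$data
  obs <- !is.na(data)
  key <- paste(cohort$zygosity, apply(obs, 1, paste, collapse = ""))
  idx_by_group <- split(seq_len(nrow(data)), key)
  lapply(idx_by_group, function(rows) {
    pat <- which(obs[rows[1], ])
    x <- data[rows, pat, drop = FALSE]
    n <- nrow(x)
    xbar <- colMeans(x)
    xc <- sweep(x, 2, xbar)
    S <- crossprod(xc) / n
    list(idx = as.integer(pat), n = as.numeric(n), xbar = xbar, S = S,
         factor = zygosity_factor(cohort$zygosity[rows[1]]))
  })
}

#' Read / write an individual-level phenotype table
#'
#' Delimited text with a header; required columns \code{family_id},
#' \code{twin}, \code{zygosity} plus any covariate, item, or score columns.
#'
#' @param path file path.
#' @return data frame (read) or invisible path (write).
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("family_id", "twin", "zygosity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_phenotype_table
#' @param df data frame to write.
#' @export
write_phenotype_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
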