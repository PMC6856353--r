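#' Construct a gene-by-region expression matrix
#'
#' @param values numeric matrix, genes in rows, regions in columns.
#' @param genes,regions unique labels (defaults from dimnames).
#' @return object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              regions = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(values)))
  if (is.null(regions)) regions <- paste0("region", seq_len(ncol(values)))
  stopifnot(length(genes) == nrow(values), length(regions) == ncol(values))
  if (anyDuplicated(genes) || anyDuplicated(regions))
    stop("gene and region labels must be unique")
  if (anyNA(values)) stop("expression matrix must have no missing entries")
  dimnames(values) <- list(genes, regions)
  structure(list(values = values, genes = genes, regions = regions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", length(x$genes), "genes x",
      length(x$regions), "regions\n")
  invisible(x)
}

#' Filter genes by an exclusion list and an availability mask
#'
#' Removes genes named in \code{exclusion_list} (e.g. the major
#' histocompatibility complex, whose apparent associations can be spurious
#' under long-range linkage disequilibrium) and genes without expression
#' data available (\code{availability_mask}).
#'
#' @param x an [expression_matrix()].
#' @param exclusion_list character vector of gene labels to drop.
#' @param availability_mask logical per gene (\code{TRUE} = keep), or a
#'   character vector of available gene labels; default keeps all.
#' @return filtered [expression_matrix()]; a message reports the count.
#' @export
filter_genes <- function(x, exclusion_list = character(0),
                         availability_mask = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  keep <- !(x$genes %in% exclusion_list)
  if (!is.null(availability_mask)) {
    if (is.character(availability_mask))
      availability_mask <- x$genes %in% availability_mask
    stopifnot(length(availability_mask) == length(x$genes))
    keep <- keep & availability_mask
  }
  if (!any(keep)) stop("no genes left after filtering")
  message(sum(keep), " of ", length(x$genes), " genes retained")
  expression_matrix(x$values[keep, , drop = FALSE], x$genes[keep], x$regions)
}

#' K-means clustering of expression profiles with elbow selection of k
#'
#' Rows are z-scored across regions (zero-variance rows left at zero), then
#' k-means is run for each candidate k with \code{n_init} restarts, keeping
#' the best within-cluster sum of squares (WSS). The number of clusters is
#' chosen at the elbow of the WSS curve, operationalized as the k with the
#' maximum curvature — the maximum second difference of log(WSS) over k. The
#' log scale makes the criterion invariant to the overall variance and
#' sharpens the flattening after the true cluster count, which the raw
#' second difference can blur when two planted profiles lie close together.
#' When no candidate's curvature exceeds \code{min_curvature} — the
#' signature of a structureless (single-cluster) matrix whose WSS declines
#' smoothly — \code{chosen_k = 1}, as it does for a degenerate matrix (all
#' profiles identical, WSS near zero everywhere).
#'
#' @param x an [expression_matrix()] or plain numeric matrix.
#' @param k_range candidate cluster counts (default 1:8); must lie within
#'   \code{[1, n_genes]}.
#' @param n_init k-means restarts per k.
#' @param seed integer seed; results are deterministic given the seed.
#' @param standardize z-score rows first (default TRUE).
#' @param min_curvature minimum elbow curvature (second difference of
#'   log WSS, dimensionless) below which no elbow is declared and
#'   \code{chosen_k = 1}.
#' @return list: \code{labels} (cluster assignment at \code{chosen_k}),
#'   \code{chosen_k}, \code{wss} (named curve over \code{k_range}),
#'   \code{centers}.
#' @export
kmeans_elbow <- function(x, k_range = 1:8, n_init = 10, seed = 1,
                         standardize = TRUE, min_curvature = 0.1) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 1, max(k_range) <= nrow(vals))
  if (standardize) {
    mu <- rowMeans(vals)
    sdr <- apply(vals, 1, stats::sd)
    sdr[sdr < 1e-12] <- 1
    vals <- (vals - mu) / sdr
  }
  set.seed(seed)
  tot_ss <- sum(sweep(vals, 2, colMeans(vals))^2)
  distinct <- unique(vals)
  wss <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      wss[i] <- tot_ss
      fits[[i]] <- list(cluster = rep(1L, nrow(vals)),
                        centers = matrix(colMeans(vals), 1))
    } else if (k >= nrow(distinct)) {
      # as many centers as distinct profiles: each pattern is its own cluster
      lab <- match(apply(vals, 1, paste, collapse = ","),
                   apply(distinct, 1, paste, collapse = ","))
      wss[i] <- 0
      fits[[i]] <- list(cluster = lab, centers = distinct)
    } else {
      fit <- stats::kmeans(vals, centers = k, nstart = n_init,
                           iter.max = 100)
      wss[i] <- fit$tot.withinss
      fits[[i]] <- fit
    }
  }
  names(wss) <- k_range
  if (wss[1] < 1e-8 * max(1, abs(tot_ss))) {
    chosen <- 1L
  } else if (length(k_range) < 3) {
    chosen <- k_range[which.min(wss)]
  } else {
    floor_w <- pmax(wss, 1e-12 * wss[1])
    d2 <- diff(diff(log(floor_w)))  # curvature at interior k
    if (max(d2) < min_curvature) chosen <- 1L
    else chosen <- k_range[which.max(d2) + 1L]
  }
  ci <- match(chosen, k_range)
  if (is.na(ci)) {  # no-elbow verdict with k = 1 outside the candidate range
    return(list(labels = rep(1L, nrow(vals)), chosen_k = 1L, wss = wss,
                centers = matrix(colMeans(vals), 1)))
  }
  list(labels = fits[[ci]]$cluster, chosen_k = as.integer(chosen),
       wss = wss, centers = fits[[ci]]$centers)
}

#' Read / write a delimited expression matrix
#'
#' Tab-separated, genes in rows (first column = gene label), regions in
#' columns (header row).
#'
#' @param path file path.
#' @return an [expression_matrix()] (read) or invisible path (write).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(vals, genes, colnames(vals))
}

#' @rdname read_expression_matrix
#' @param x an [expression_matrix()] to write.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
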