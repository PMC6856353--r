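# Readers and writers for the per-vertex overlay and mesh formats the
# pipeline touches.  FreeSurfer binary formats are big-endian.

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

write_int3 <- function(con, value) {
  writeBin(as.integer(c(value %/% 65536, (value %/% 256) %% 256, value %% 256)),
           con, size = 1)
}

#' Read / write FreeSurfer curv (scalar overlay) files
#'
#' New-format curv: per-vertex float32 scalars (thickness, curvature, or any
#' statistic) in big-endian binary.
#'
#' @param path file path.
#' @return numeric vector of per-vertex values.
#' @export
read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 16777215L) stop("not a new-format curv file: ", path)
  vnum <- readBin(con, "integer", size = 4, endian = "big")
  readBin(con, "integer", size = 4, endian = "big")  # fnum, unused
  vpv <- readBin(con, "integer", size = 4, endian = "big")
  if (vpv != 1L) stop("curv files with ", vpv, " values per vertex unsupported")
  readBin(con, "numeric", n = vnum, size = 4, endian = "big")
}

#' @rdname read_curv
#' @param values numeric vector to write.
#' @param fnum face count recorded in the header (informational).
#' @export
write_curv <- function(values, path, fnum = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, 16777215L)
  writeBin(as.integer(c(length(values), fnum, 1L)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write MGH scalar volumes as vertex overlays
#'
#' Supports the common overlay layout: an MGH volume of width n_vertices,
#' height/depth 1, one or more frames, float32 data. (MGZ, the gzipped
#' variant, can be read by passing a \code{gzfile} path ending in .mgz.)
#'
#' @param path file path (.mgh, or .mgz read via gzip).
#' @return numeric vector (one frame) or matrix (vertices x frames).
#' @export
read_mgh <- function(path) {
  con <- if (grepl("\\.mgz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 7, size = 4, endian = "big")
  if (hdr[1] != 1L) stop("unsupported MGH version ", hdr[1])
  width <- hdr[2]; height <- hdr[3]; depth <- hdr[4]; nframes <- hdr[5]
  type <- hdr[6]
  readBin(con, "integer", size = 2, endian = "big")  # goodRAS flag
  readBin(con, "raw", n = 284 - 30)                  # pad to data offset
  n <- width * height * depth * nframes
  vals <- switch(as.character(type),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "big")),
    "3" = readBin(con, "numeric", n = n, size = 4, endian = "big"),
    "4" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "big")),
    stop("unsupported MGH data type ", type))
  if (nframes > 1) matrix(vals, ncol = nframes) else vals
}

#' @rdname read_mgh
#' @param values numeric vector or (vertices x frames) matrix.
#' @export
write_mgh <- function(values, path) {
  values <- as.matrix(values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(1L, nrow(values), 1L, 1L, ncol(values), 3L, 0L)),
           con, size = 4, endian = "big")
  writeBin(0L, con, size = 2, endian = "big")
  writeBin(raw(284 - 30), con)
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write FreeSurfer binary triangle surfaces
#'
#' @param path file path.
#' @param hemisphere label attached to the mesh on read.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, hemisphere = "lh") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != 16777214L) stop("not a binary triangle surface: ", path)
  # created-by comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop("truncated surface file")
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  vnum <- readBin(con, "integer", size = 4, endian = "big")
  fnum <- readBin(con, "integer", size = 4, endian = "big")
  coords <- matrix(readBin(con, "numeric", n = 3 * vnum, size = 4,
                           endian = "big"), ncol = 3, byrow = TRUE)
  tris <- matrix(readBin(con, "integer", n = 3 * fnum, size = 4,
                         endian = "big"), ncol = 3, byrow = TRUE) + 1L
  surface_mesh(coords, tris, hemisphere)
}

#' @rdname read_surface
#' @param mesh a [surface_mesh()] to write.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  write_int3(con, 16777214L)
  writeBin(charToRaw("created by twinmap\n\n"), con)
  writeBin(as.integer(c(nrow(mesh$coords), nrow(mesh$triangles))), con,
           size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$coords)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$triangles) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write GIFTI files (ASCII encoding)
#'
#' Minimal GIFTI support for functional overlays (one float data array) and
#' surfaces (a POINTSET and a TRIANGLE array). Only ASCII-encoded data are
#' handled; binary encodings are rejected with an error.
#'
#' @param path file path (.gii).
#' @return for functional files a numeric vector/matrix; for surface files a
#'   [surface_mesh()].
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0) stop("no DataArray in ", path)
  parsed <- lapply(arrays, function(a) {
    enc <- xml2::xml_attr(a, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("only ASCII-encoded GIFTI supported, got ", enc)
    intent <- xml2::xml_attr(a, "Intent")
    txt <- xml2::xml_text(xml2::xml_find_first(a, "./Data"))
    vals <- scan(text = txt, quiet = TRUE)
    dim0 <- as.integer(xml2::xml_attr(a, "Dim0"))
    dim1 <- suppressWarnings(as.integer(xml2::xml_attr(a, "Dim1")))
    if (!is.na(dim1) && dim1 > 1)
      vals <- matrix(vals, nrow = dim0, ncol = dim1, byrow = TRUE)
    list(intent = intent, values = vals)
  })
  intents <- vapply(parsed, `[[`, character(1), "intent")
  if ("NIFTI_INTENT_POINTSET" %in% intents && "NIFTI_INTENT_TRIANGLE" %in% intents) {
    coords <- parsed[[which(intents == "NIFTI_INTENT_POINTSET")[1]]]$values
    tris <- parsed[[which(intents == "NIFTI_INTENT_TRIANGLE")[1]]]$values + 1L
    return(surface_mesh(coords, tris))
  }
  if (length(parsed) == 1) return(parsed[[1]]$values)
  do.call(cbind, lapply(parsed, `[[`, "values"))
}

gifti_array_xml <- function(values, intent, datatype) {
  values <- as.matrix(values)
  dims <- if (ncol(values) > 1)
    sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"', nrow(values), ncol(values))
  else sprintf('Dimensionality="1" Dim0="%d"', nrow(values))
  body <- apply(values, 1, paste, collapse = " ")
  sprintf(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" %s Encoding="ASCII" Endian="LittleEndian">\n<Data>%s</Data>\n</DataArray>',
    intent, datatype, dims, paste(body, collapse = "\n"))
}

#' @rdname read_gifti
#' @param x numeric vector/matrix (functional data) or a [surface_mesh()].
#' @export
write_gifti <- function(x, path) {
  arrays <- if (inherits(x, "surface_mesh")) {
    c(gifti_array_xml(x$coords, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
      gifti_array_xml(x$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                      "NIFTI_TYPE_INT32"))
  } else {
    gifti_array_xml(x, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32")
  }
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="', length(arrays),
                '">\n', paste(arrays, collapse = "\n"), '\n</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Read per-vertex data in any supported format
#'
#' Dispatches on \code{format} (or the file extension when \code{"auto"}):
#' \code{.mgh}/\code{.mgz} to [read_mgh()], \code{.gii} to [read_gifti()],
#' \code{.tsv}/\code{.txt}/\code{.csv} to a delimited reader (header row
#' preserved as column labels), anything else to [read_curv()]. When a mesh
#' is supplied the vector length is checked against its vertex count.
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"curv"}, \code{"mgh"}, \code{"gifti"},
#'   or \code{"tsv"}.
#' @param mesh optional [surface_mesh()] for length validation.
#' @return numeric vector or matrix of per-vertex values.
#' @export
read_vertex_data <- function(path, format = c("auto", "curv", "mgh", "gifti",
                                              "tsv"), mesh = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgh$|\\.mgz$", path)) "mgh"
    else if (grepl("\\.gii$", path)) "gifti"
    else if (grepl("\\.tsv$|\\.txt$|\\.csv$", path)) "tsv"
    else "curv"
  }
  x <- switch(format,
              curv = read_curv(path),
              mgh = read_mgh(path),
              gifti = read_gifti(path),
              tsv = {
                sep <- if (grepl("\\.csv$", path)) "," else "\t"
                df <- utils::read.delim(path, sep = sep, check.names = FALSE)
                m <- as.matrix(df)
                if (ncol(m) == 1) setNames(m[, 1], NULL) else m
              })
  if (!is.null(mesh)) {
    nvals <- if (is.matrix(x)) nrow(x) else length(x)
    if (nvals != n_vertices(mesh))
      stop("overlay has ", nvals, " values but mesh has ",
           n_vertices(mesh), " vertices")
  }
  x
}

#' @rdname read_vertex_data
#' @param x numeric vector/matrix to write.
#' @export
write_vertex_data <- function(x, path, format = c("auto", "curv", "mgh",
                                                  "gifti", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgh$", path)) "mgh"
    else if (grepl("\\.gii$", path)) "gifti"
    else if (grepl("\\.tsv$|\\.txt$|\\.csv$", path)) "tsv"
    else "curv"
  }
  switch(format,
         curv = write_curv(x, path),
         mgh = write_mgh(x, path),
         gifti = write_gifti(x, path),
         tsv = {
           df <- as.data.frame(as.matrix(x))
           if (is.null(colnames(x))) names(df) <- paste0("value",
                                                         seq_along(df))
           sep <- if (grepl("\\.csv$", path)) "," else "\t"
           utils::write.table(df, path, sep = sep, quote = FALSE,
                              row.names = FALSE)
         })
  invisible(path)
}

#' Write a cluster table as TSV
#'
#' Columns: Cluster, COG X, COG Y, COG Z, Number of vertices, sign,
#' replicated. Coordinates are reported to 2 decimals in mm. An empty table
#' yields a header-only file.
#'
#' @param table a cluster table.
#' @param path output path.
#' @export
write_cluster_table <- function(table, path) {
  df <- data.frame(Cluster = table$cluster,
                   `COG X` = round(table$cog_x, 2),
                   `COG Y` = round(table$cog_y, 2),
                   `COG Z` = round(table$cog_z, 2),
                   `Number of vertices` = table$n_vertices,
                   sign = table$sign,
                   replicated = table$replicated,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @return \code{read_cluster_table} returns the data frame as written
#'   (member vertex sets are not serialized).
#' @export
read_cluster_table <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE)
}
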