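#' Construct a triangulated surface mesh
#'
#' @param coords numeric \code{n x 3} matrix of vertex coordinates in mm.
#' @param triangles integer \code{m x 3} matrix of 1-based vertex indices.
#' @param hemisphere label, e.g. \code{"lh"} or \code{"rh"}.
#' @return object of class \code{"surface_mesh"}. Isolated vertices (in no
#'   triangle) are permitted but flagged with a warning; they can never join
#'   a cluster.
#' @export
surface_mesh <- function(coords, triangles, hemisphere = "lh") {
  coords <- as.matrix(coords)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(coords) == 3, ncol(triangles) == 3)
  n <- nrow(coords)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle indices out of range (1..", n, ")")
  used <- unique(as.vector(triangles))
  if (length(used) < n)
    warning(n - length(used), " isolated vertex/vertices not in any triangle")
  structure(list(coords = coords, triangles = triangles,
                 hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("Surface mesh (", x$hemisphere, "): ", nrow(x$coords), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$coords)

# unique undirected edges (two-column matrix) and their Euclidean lengths
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$coords[e[, 1], , drop = FALSE] -
                       mesh$coords[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = d)
}

mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_vertices(mesh) - igraph::vcount(g)))
  igraph::E(g)$weight <- ed$lengths
  g
}

# per-vertex surface area: one third of each incident triangle's area
vertex_areas <- function(mesh) {
  tr <- mesh$triangles
  a <- mesh$coords[tr[, 1], , drop = FALSE]
  b <- mesh$coords[tr[, 2], , drop = FALSE]
  cc <- mesh$coords[tr[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  va <- numeric(n_vertices(mesh))
  for (j in 1:3) {
    acc <- tapply(tri_area / 3, tr[, j], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va
}

# loose fingerprint used to reject cross-mesh operations
mesh_id <- function(mesh) {
  c(n_vertices(mesh), nrow(mesh$triangles), round(sum(mesh$coords), 6))
}

same_mesh <- function(a, b) isTRUE(all.equal(mesh_id(a), mesh_id(b)))

#' Generate a synthetic surface mesh
#'
#' \code{"sphere"} builds a subdivided icosahedron projected onto a sphere of
#' radius \code{scale_mm} (the smallest subdivision level with at least
#' \code{n_vertices} vertices: 12, 42, 162, 642, 2562, ...).
#' \code{"grid"} builds a regular planar triangulation of a
#' \code{scale_mm x scale_mm} square with approximately \code{n_vertices}
#' vertices (a \code{k x k} grid has \eqn{2(k-1)^2} triangles).
#'
#' @param kind \code{"sphere"} or \code{"grid"}.
#' @param n_vertices requested minimum vertex count (\eqn{\ge 4}).
#' @param scale_mm sphere radius / grid side length in mm (default 50, the
#'   order of a hemisphere's radius).
#' @param seed unused (generation is deterministic); kept so mesh creation
#'   shares the generator calling convention.
#' @return a [surface_mesh()].
#' @export
make_mesh <- function(kind = c("sphere", "grid"), n_vertices = 162,
                      scale_mm = 50, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_vertices >= 4)
  if (kind == "sphere") {
    mesh <- icosphere_mesh(n_vertices, scale_mm)
  } else {
    k <- max(2L, ceiling(sqrt(n_vertices)))
    mesh <- grid_mesh(k, scale_mm)
  }
  mesh
}

icosphere_mesh <- function(n_target, radius) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)
  while (nrow(v) < n_target) {
    midpoint_cache <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    vlist <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[i, ] + vlist[j, ]) / 2
      vlist <<- rbind(vlist, m / sqrt(sum(m^2)))
      idx <- nrow(vlist)
      midpoint_cache[[key]] <- idx
      idx
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vlist
    f <- nf
  }
  surface_mesh(v * radius, f, hemisphere = "sphere")
}

grid_mesh <- function(k, side) {
  xs <- seq(0, side, length.out = k)
  coords <- cbind(rep(xs, each = k), rep(xs, times = k), 0)
  idx <- function(i, j) (i - 1L) * k + j
  tris <- matrix(0L, 0, 3)
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - 1)) {
      tris <- rbind(tris,
                    c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                    c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  surface_mesh(coords, tris, hemisphere = "grid")
}

#' Vertices within a geodesic radius of a seed vertex
#'
#' Helper for planting spatially contiguous clusters on a mesh: all vertices
#' whose shortest edge-path distance (Euclidean edge weights) from the seed
#' is at most \code{radius_mm}.
#'
#' @param mesh a [surface_mesh()].
#' @param seed_vertex 1-based vertex index.
#' @param radius_mm geodesic radius.
#' @return integer vector of vertex indices (always includes the seed).
#' @export
geodesic_patch <- function(mesh, seed_vertex, radius_mm) {
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = seed_vertex)[1, ]
  which(d <= radius_mm)
}
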