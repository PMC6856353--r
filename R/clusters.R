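# A cluster table is a data frame (one row per cluster: cluster, sign,
# n_vertices, extent_mm, cog_x/y/z, trait, component, replicated) carrying
# the member vertex sets in attr(, "members") and a mesh fingerprint in
# attr(, "mesh_id").

new_cluster_table <- function(members, signs, mesh, trait = NA_character_,
                              component = NA_character_,
                              discordant = rep(FALSE, length(members))) {
  n <- length(members)
  if (n == 0) {
    df <- data.frame(cluster = integer(0), sign = character(0),
                     n_vertices = integer(0), extent_mm = numeric(0),
                     cog_x = numeric(0), cog_y = numeric(0),
                     cog_z = numeric(0), trait = character(0),
                     component = character(0), replicated = logical(0),
                     discordant = logical(0))
  } else {
    cogs <- t(vapply(members, function(vs) cluster_cog(vs, mesh), numeric(3)))
    df <- data.frame(cluster = seq_len(n), sign = signs,
                     n_vertices = vapply(members, length, integer(1)),
                     extent_mm = NA_real_,
                     cog_x = cogs[, 1], cog_y = cogs[, 2], cog_z = cogs[, 3],
                     trait = trait, component = component,
                     replicated = NA, discordant = discordant)
  }
  attr(df, "members") <- members
  attr(df, "mesh_id") <- mesh_id(mesh)
  class(df) <- c("cluster_table", "data.frame")
  df
}

#' Member vertex sets of a cluster table
#' @param table a cluster table from [extract_clusters()] or
#'   [conjunction_overlay()].
#' @return list of integer vertex-index vectors, one per row.
#' @export
cluster_members <- function(table) attr(table, "members")

# connected components of a vertex subset under mesh edge adjacency
components_of <- function(vertices, mesh) {
  if (length(vertices) == 0) return(list())
  ed <- mesh_edges(mesh)
  keep <- ed$edges[, 1] %in% vertices & ed$edges[, 2] %in% vertices
  sub <- igraph::graph_from_edgelist(
    matrix(match(ed$edges[keep, , drop = FALSE], vertices),
           ncol = 2), directed = FALSE)
  sub <- igraph::add_vertices(sub, max(0, length(vertices) - igraph::vcount(sub)))
  comp <- igraph::components(sub)$membership
  unname(split(vertices, comp))
}

# maximum pairwise edge-path distance (geodesic diameter) within a cluster
cluster_extent_geodesic <- function(vertices, mesh) {
  if (length(vertices) < 2) return(0)
  ed <- mesh_edges(mesh)
  keep <- ed$edges[, 1] %in% vertices & ed$edges[, 2] %in% vertices
  g <- igraph::graph_from_edgelist(
    matrix(match(ed$edges[keep, , drop = FALSE], vertices), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- ed$lengths[keep]
  d <- igraph::distances(g)
  max(d[is.finite(d)])
}

cluster_extent_area <- function(vertices, mesh) {
  sum(vertex_areas(mesh)[vertices])
}

#' Extract significant clusters from a vertex map with extent correction
#'
#' Vertices with \code{p < alpha} (on the chosen component's p field) are
#' partitioned into connected components under mesh edge adjacency, after
#' splitting by the sign of the component's bivariate effect so each cluster
#' is monotone in direction. Components whose spatial extent falls below
#' \code{extent_mm} are discarded. Extent is, by default, the geodesic
#' diameter: the maximum pairwise shortest-path distance along mesh edges
#' (Euclidean edge weights), in mm; \code{extent_mode = "area"} instead uses
#' total vertex-assigned surface area in mm^2 against the same threshold
#' value.
#'
#' @param map a vertex map from [fit_vertexwise()].
#' @param mesh the [surface_mesh()] the map lives on.
#' @param alpha vertex-level significance threshold (default 0.05).
#' @param extent_mm minimum cluster extent (default 20 mm, twice a typical
#'   10 mm surface smoothing kernel).
#' @param component \code{"genetic"} (default) uses \code{p_genetic} and the
#'   sign of bivariate heritability; \code{"environmental"} the E analogues.
#' @param extent_mode \code{"geodesic"} (default) or \code{"area"}.
#' @param trait label stored with the clusters.
#' @return a cluster table (empty when nothing survives); member vertex sets
#'   via [cluster_members()].
#' @export
extract_clusters <- function(map, mesh, alpha = 0.05, extent_mm = 20,
                             component = c("genetic", "environmental"),
                             extent_mode = c("geodesic", "area"),
                             trait = NA_character_) {
  component <- match.arg(component)
  extent_mode <- match.arg(extent_mode)
  stopifnot(inherits(map, "vertex_map"))
  if (nrow(map) != n_vertices(mesh))
    stop("map has ", nrow(map), " vertices but mesh has ", n_vertices(mesh))
  pfield <- if (component == "genetic") map$p_genetic else map$p_environmental
  efield <- if (component == "genetic") map$bivariate_heritability else
    map$bivariate_environmentality
  sig <- which(map$valid & !is.na(pfield) & pfield < alpha)
  members <- list(); signs <- character(0)
  for (sgn in c(1, -1)) {
    vs <- sig[sign(efield[sig]) == sgn]
    for (comp in components_of(vs, mesh)) {
      members[[length(members) + 1L]] <- sort(comp)
      signs <- c(signs, if (sgn > 0) "positive" else "negative")
    }
  }
  extent_fun <- if (extent_mode == "geodesic") cluster_extent_geodesic else
    cluster_extent_area
  extents <- vapply(members, extent_fun, numeric(1), mesh = mesh)
  keep <- extents >= extent_mm
  tab <- new_cluster_table(members[keep], signs[keep], mesh, trait = trait,
                           component = if (component == "genetic") "A" else "E")
  if (nrow(tab) > 0) tab$extent_mm <- extents[keep]
  tab
}

#' Center of gravity of a cluster
#'
#' Unweighted mean of the member vertices' mm coordinates.
#'
#' @param cluster integer vector of vertex indices (or a one-row cluster
#'   table's member set).
#' @param mesh a [surface_mesh()].
#' @return length-3 numeric xyz in mm.
#' @export
cluster_cog <- function(cluster, mesh) {
  stopifnot(length(cluster) >= 1)
  colMeans(mesh$coords[cluster, , drop = FALSE])
}

#' Conjunction (overlay) of two traits' cluster tables
#'
#' Intersects the vertex sets covered by the surviving clusters of each
#' trait, then re-partitions the intersection into connected components.
#' Components where the two traits' cluster signs disagree are kept but
#' flagged \code{discordant}; concordant components carry the shared sign.
#'
#' @param clusters_a,clusters_b cluster tables on the same mesh.
#' @param mesh the shared [surface_mesh()].
#' @return a cluster table of overlay regions.
#' @export
conjunction_overlay <- function(clusters_a, clusters_b, mesh) {
  for (tb in list(clusters_a, clusters_b))
    if (!isTRUE(all.equal(attr(tb, "mesh_id"), mesh_id(mesh))))
      stop("cluster table was built on a different mesh")
  sign_of <- function(tb) {
    s <- integer(n_vertices(mesh))
    mem <- cluster_members(tb)
    for (i in seq_along(mem))
      s[mem[[i]]] <- if (tb$sign[i] == "positive") 1L else -1L
    s
  }
  sa <- sign_of(clusters_a); sb <- sign_of(clusters_b)
  inter <- which(sa != 0L & sb != 0L)
  members <- list(); signs <- character(0); disc <- logical(0)
  for (concordant in c(TRUE, FALSE)) {
    vs <- if (concordant) inter[sa[inter] == sb[inter]] else
      inter[sa[inter] != sb[inter]]
    if (concordant) {
      for (sgn in c(1L, -1L)) {
        for (comp in components_of(vs[sa[vs] == sgn], mesh)) {
          members[[length(members) + 1L]] <- sort(comp)
          signs <- c(signs, if (sgn > 0) "positive" else "negative")
          disc <- c(disc, FALSE)
        }
      }
    } else {
      for (comp in components_of(vs, mesh)) {
        members[[length(members) + 1L]] <- sort(comp)
        signs <- c(signs, "discordant")
        disc <- c(disc, TRUE)
      }
    }
  }
  tr <- paste(unique(c(clusters_a$trait, clusters_b$trait)), collapse = "&")
  new_cluster_table(members, signs, mesh, trait = tr,
                    component = "A", discordant = disc)
}

#' Genetic/environmental sign concordance within clusters
#'
#' For each cluster, the fraction of member vertices where the sign of the
#' bivariate heritability matches the sign of the bivariate
#' environmentality. Same-direction genetic and environmental association is
#' consistent with (though not sufficient for) a causal brain-behavior
#' interpretation; discordant directions argue against it.
#'
#' @param genetic,environmental vertex maps from the same fit (the E map may
#'   be the same object as the genetic map, which carries both fields).
#' @param clusters a cluster table.
#' @return data frame: cluster, concordance fraction, and a
#'   \code{same_direction} verdict at threshold 0.5.
#' @export
sign_concordance <- function(genetic, environmental, clusters) {
  mem <- cluster_members(clusters)
  conc <- vapply(mem, function(vs) {
    mean(sign(genetic$bivariate_heritability[vs]) ==
           sign(environmental$bivariate_environmentality[vs]))
  }, numeric(1))
  data.frame(cluster = clusters$cluster, concordance = conc,
             same_direction = conc > 0.5)
}
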