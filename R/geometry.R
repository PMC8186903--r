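#' Vertex-wise surface areas
#'
#' Each vertex receives one third of the area of every triangle incident
#' to it, so the vertex areas sum exactly to the total mesh area.
#'
#' @param patch A `cortex_patch` (or any list with `vertices`, `faces`).
#' @param warn_degenerate Warn on zero-area faces (default TRUE).
#' @return Numeric vector of per-vertex areas in mm^2.
#' @export
vertex_areas <- function(patch, warn_degenerate = TRUE) {
  V <- patch$vertices; FF <- patch$faces
  a <- V[FF[, 2], , drop = FALSE] - V[FF[, 1], , drop = FALSE]
  b <- V[FF[, 3], , drop = FALSE] - V[FF[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  if (warn_degenerate && any(tri_area < 1e-12))
    warning(sum(tri_area < 1e-12), " degenerate zero-area face(s)")
  out <- numeric(nrow(V))
  for (j in 1:3) {
    acc <- tapply(tri_area / 3, FF[, j], sum)
    idx <- as.integer(names(acc))
    out[idx] <- out[idx] + as.numeric(acc)
  }
  out
}

#' ROI surface area
#'
#' Summed vertex-wise area over a vertex mask.
#'
#' @param patch A `cortex_patch`.
#' @param mask Logical mask or integer vertex indices.
#' @return Area in mm^2.
#' @export
roi_surface_area <- function(patch, mask) {
  areas <- vertex_areas(patch, warn_degenerate = FALSE)
  if (is.logical(mask)) {
    stopifnot(length(mask) == length(areas))
    sum(areas[mask])
  } else {
    stopifnot(all(mask >= 1), all(mask <= length(areas)))
    sum(areas[mask])
  }
}

#' Representative location of a digit ROI
#'
#' Either the coordinates of the peak-statistic vertex (ties to the
#' lowest vertex index) or the statistic-weighted centroid of the ROI.
#'
#' @param patch A `cortex_patch`.
#' @param vertices Integer vertex indices of the ROI.
#' @param stat Per-ROI-vertex statistic values (t or F).
#' @param mode `"peak"` or `"center"`.
#' @return Length-3 coordinates in mm; for `"peak"`, attribute
#'   `vertex` carries the peak vertex index.
#' @export
digit_location <- function(patch, vertices, stat,
                           mode = c("peak", "center")) {
  mode <- match.arg(mode)
  stopifnot(length(vertices) >= 1, length(stat) == length(vertices))
  if (mode == "peak") {
    v <- vertices[which.max(stat)]
    structure(patch$vertices[v, ], vertex = v)
  } else {
    w <- stat / sum(stat)
    colSums(patch$vertices[vertices, , drop = FALSE] * w)
  }
}

#' Cortical distance between two locations
#'
#' Euclidean: straight-line 3D distance between two coordinate triples.
#' Geodesic: shortest path along mesh edges (Dijkstra) between two
#' vertices, with edge weights equal to edge lengths.
#'
#' @param patch A `cortex_patch` (needed for geodesic; optional for
#'   euclidean when coordinates are given directly).
#' @param a,b For `"euclidean"`, coordinate triples or vertex indices;
#'   for `"geodesic"`, vertex indices.
#' @param kind `"euclidean"` or `"geodesic"`.
#' @return Distance in mm; `Inf` with a warning for disconnected
#'   vertices.
#' @export
#' @examples
#' cortical_distance(NULL, c(0, 0, 0), c(3, 4, 0))  # 5
cortical_distance <- function(patch, a, b,
                              kind = c("euclidean", "geodesic")) {
  kind <- match.arg(kind)
  to_coord <- function(u) {
    if (length(u) == 1) patch$vertices[u, ] else u
  }
  if (kind == "euclidean") {
    pa <- to_coord(a); pb <- to_coord(b)
    return(sqrt(sum((pa - pb)^2)))
  }
  stopifnot(length(a) == 1, length(b) == 1)
  e <- mesh_edges(patch$faces)
  w <- sqrt(rowSums((patch$vertices[e[, 1], , drop = FALSE] -
                       patch$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(patch$vertices) -
                                     igraph::vcount(g)))
  d <- igraph::distances(g, v = a, to = b, weights = w,
                         algorithm = "dijkstra")[1, 1]
  if (is.infinite(d))
    warning("vertices ", a, " and ", b, " are not connected on the mesh")
  d
}

#' Dice overlap coefficient of two vertex masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 0 for disjoint digit
#' representations, 1 for perfectly overlapping ones.
#'
#' @param maskA,maskB Logical masks over the same vertex set.
#' @return Dice coefficient; `NaN` with a warning when both masks are
#'   empty.
#' @export
dice_coefficient <- function(maskA, maskB) {
  stopifnot(is.logical(maskA), is.logical(maskB))
  if (length(maskA) != length(maskB))
    stop("masks must be over the same vertex set")
  denom <- sum(maskA) + sum(maskB)
  if (denom == 0) {
    warning("both masks empty; dice undefined")
    return(NaN)
  }
  2 * sum(maskA & maskB) / denom
}

#' Connected-component ROI extraction
#'
#' Splits a supra-threshold vertex mask into edge-connected components
#' and keeps those with more than `min_vertices` vertices, the
#' cluster-extent rule used for GLM-derived digit ROIs.
#'
#' @param patch A `cortex_patch`.
#' @param mask Logical vertex mask.
#' @param min_vertices Minimum component size, exclusive (default 3,
#'   i.e. components of 4+ vertices survive).
#' @return Logical mask of surviving vertices.
#' @export
extent_filter <- function(patch, mask, min_vertices = 3) {
  stopifnot(length(mask) == nrow(patch$vertices))
  if (!any(mask)) return(mask)
  g <- igraph::graph_from_edgelist(mesh_edges(patch$faces),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(patch$vertices) -
                                     igraph::vcount(g)))
  sub <- igraph::induced_subgraph(g, which(mask))
  comp <- igraph::components(sub)
  keep <- comp$csize[comp$membership] > min_vertices
  out <- rep(FALSE, length(mask))
  out[which(mask)[keep]] <- TRUE
  out
}
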