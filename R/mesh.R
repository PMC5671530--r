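#' Unstructured 2D mesh container
#'
#' Shared mesh representation for the macro-scale (axisymmetric r,z) and
#' meso-scale (plane x,y) structural and diffusion solves. Elements are
#' bilinear quadrilaterals with counter-clockwise connectivity; boundary and
#' interface facets are stored as oriented node pairs so that the referenced
#' region lies to the left of the edge direction (outward normal of the
#' region is then the right-hand rotation of the edge tangent).
#'
#' @param nodes numeric matrix (n x 2), coordinates in metres. Columns are
#'   (r, z) for axisymmetric meshes and (x, y) for plane meshes.
#' @param elems integer matrix (ne x 4), CCW quad connectivity.
#' @param region character vector of length ne, one region label per element.
#' @param edges data.frame with integer columns `n1`, `n2` and character
#'   column `tag`; oriented boundary/interface facets.
#' @param axisymmetric logical; if `TRUE` integrals carry the 2*pi*r factor
#'   and column 1 of `nodes` is the radius.
#' @return an object of class `npwt_mesh`.
#' @export
npwt_mesh <- function(nodes, elems, region, edges, axisymmetric = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(ncol(nodes) == 2, ncol(elems) == 4)
  if (length(region) != nrow(elems))
    stop("region must have one label per element")
  if (any(elems < 1L) || any(elems > nrow(nodes)))
    stop("element connectivity references missing nodes")
  if (axisymmetric && any(nodes[, 1] < -1e-12))
    stop("axisymmetric mesh has nodes with negative radius")
  mesh <- structure(
    list(nodes = nodes, elems = elems, region = as.character(region),
         edges = edges, axisymmetric = isTRUE(axisymmetric)),
    class = "npwt_mesh")
  a <- element_areas(mesh)
  if (any(a <= 0))
    stop("mesh contains inverted (non-positive area) elements")
  mesh
}

#' @export
print.npwt_mesh <- function(x, ...) {
  cat(sprintf("<npwt_mesh> %s, %d nodes, %d quad elements\n",
              if (x$axisymmetric) "axisymmetric (r,z)" else "plane (x,y)",
              nrow(x$nodes), nrow(x$elems)))
  cat("  regions: ",
      paste(sprintf("%s (%d)", names(table(x$region)), table(x$region)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$edges))
    cat("  edge tags: ",
        paste(sprintf("%s (%d)", names(table(x$edges$tag)), table(x$edges$tag)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Element cross-sectional areas
#'
#' Shoelace area of each quadrilateral (in the meridian/cross-section plane,
#' i.e. without any axisymmetric revolution factor).
#'
#' @param mesh an [npwt_mesh()].
#' @return numeric vector of areas (m^2).
#' @export
element_areas <- function(mesh) {
  el <- mesh$elems
  x <- matrix(mesh$nodes[el, 1], ncol = 4)
  y <- matrix(mesh$nodes[el, 2], ncol = 4)
  x2 <- x[, c(2, 3, 4, 1), drop = FALSE]
  y2 <- y[, c(2, 3, 4, 1), drop = FALSE]
  0.5 * rowSums(x * y2 - x2 * y)
}

#' Element centroids
#'
#' Exact polygon (area-weighted) centroids of the quad elements.
#'
#' @param mesh an [npwt_mesh()].
#' @return numeric matrix (ne x 2).
#' @export
element_centroids <- function(mesh) {
  el <- mesh$elems
  x <- matrix(mesh$nodes[el, 1], ncol = 4)
  y <- matrix(mesh$nodes[el, 2], ncol = 4)
  x2 <- x[, c(2, 3, 4, 1), drop = FALSE]
  y2 <- y[, c(2, 3, 4, 1), drop = FALSE]
  cr <- x * y2 - x2 * y
  a <- 0.5 * rowSums(cr)
  cx <- rowSums((x + x2) * cr) / (6 * a)
  cy <- rowSums((y + y2) * cr) / (6 * a)
  cbind(cx, cy)
}

#' Solid-of-revolution volume of mesh regions
#'
#' For axisymmetric meshes, revolves each element cross-section about the
#' symmetry axis (Pappus: V = 2*pi*r_centroid*A). For plane meshes returns
#' the plain area.
#'
#' @param mesh an [npwt_mesh()].
#' @param region optional region label; default all elements.
#' @return volume in m^3 (axisymmetric) or area in m^2 (plane).
#' @export
mesh_volume <- function(mesh, region = NULL) {
  keep <- if (is.null(region)) rep(TRUE, nrow(mesh$elems)) else mesh$region == region
  if (!any(keep)) return(0)
  a <- element_areas(mesh)[keep]
  if (!mesh$axisymmetric) return(sum(a))
  r <- element_centroids(mesh)[keep, 1]
  sum(2 * pi * r * a)
}

#' Graded 1D node spacing
#'
#' Node coordinates from `a` to `b` with element size grading geometrically
#' from about `h0` (at `a`) to about `h1` (at `b`). Used to refine the mesh
#' towards the wound--filler interface.
#'
#' @param a,b interval ends (b > a).
#' @param h0,h1 target element sizes at the two ends.
#' @return numeric vector of node positions including both ends.
#' @export
seq_graded <- function(a, b, h0, h1) {
  L <- b - a
  stopifnot(L > 0, h0 > 0, h1 > 0)
  if (abs(h1 - h0) < 1e-12 * (h0 + h1)) {
    n <- max(1L, as.integer(ceiling(L / h0 - 1e-9)))
    return(seq(a, b, length.out = n + 1L))
  }
  n <- max(1L, as.integer(ceiling(L * log(h1 / h0) / (h1 - h0) - 1e-9)))
  g <- (h1 / h0)^(1 / n)
  sizes <- h0 * g^(seq_len(n) - 1)
  sizes <- sizes * (L / sum(sizes))
  a + c(0, cumsum(sizes))
}

# internal: structured tensor-product quad grid
# returns list(nodes, elems, ir, iz) with node index (i,j) -> (j-1)*nr + i
.grid_mesh <- function(rc, zc) {
  nr <- length(rc)
  nz <- length(zc)
  nodes <- cbind(rep(rc, times = nz), rep(zc, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  elems <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  list(nodes = nodes, elems = elems, nr = nr, nz = nz,
       ei = i, ej = j)
}

# internal: oriented edges of CCW quads; local edges (1,2),(2,3),(3,4),(4,1)
.elem_edges <- function(elems) {
  rbind(elems[, c(1, 2)], elems[, c(2, 3)], elems[, c(3, 4)], elems[, c(4, 1)])
}

# internal: for a set of elements (subset of mesh), find oriented edges that
# are on the boundary of that set (appear in exactly one element of the set).
.region_boundary_edges <- function(elems) {
  ed <- .elem_edges(elems)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tab <- table(key)
  ed[tab[key] == 1L, , drop = FALSE]
}

# internal: simple tagged rectangle mesh (verification fixtures)
.rect_mesh <- function(xc, yc, axisymmetric = TRUE, region = "body") {
  g <- .grid_mesh(xc, yc)
  ed <- .region_boundary_edges(g$elems)
  mx <- (g$nodes[ed[, 1], 1] + g$nodes[ed[, 2], 1]) / 2
  my <- (g$nodes[ed[, 1], 2] + g$nodes[ed[, 2], 2]) / 2
  tol <- 1e-12
  tag <- rep("outer", nrow(ed))
  tag[abs(mx - min(xc)) < tol] <- "left"
  tag[abs(mx - max(xc)) < tol] <- "right"
  tag[abs(my - min(yc)) < tol] <- "bottom"
  tag[abs(my - max(yc)) < tol] <- "top"
  npwt_mesh(g$nodes, g$elems, rep(region, nrow(g$elems)),
            data.frame(n1 = ed[, 1], n2 = ed[, 2], tag = tag,
                       stringsAsFactors = FALSE),
            axisymmetric = axisymmetric)
}
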