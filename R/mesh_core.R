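#' Construct a triangle mesh
#'
#' A `triangle_mesh` is the basic container of the package: an epithelial
#' sheet (open patch) or a closed primordium surface represented by many
#' small triangular plates.
#'
#' @param vertices numeric matrix with one row per vertex and 3 columns
#'   (x, y, z), in dimensionless length units.
#' @param facets integer matrix with one row per triangular facet and 3
#'   columns of 1-based vertex indices, in consistent (counter-clockwise
#'   seen from outside / above) orientation.
#'
#' @details Vertex indices are 1-based throughout the package; file readers
#'   and writers convert to the 0-based (OFF, PLY) or 1-based (OBJ)
#'   conventions of each format. Every facet must reference three distinct
#'   valid vertices.
#'
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `facets`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1, 2, 3)))
#' facet_area(m, 1)   # 0.5
#' @seealso [build_topology()], [enclosed_volume()], [read_mesh()]
#' @export
triangle_mesh <- function(vertices, facets) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(facets) != 3L) stop("facets must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  n <- nrow(vertices)
  if (any(facets < 1L) || any(facets > n)) {
    stop("facet indices out of range [1, ", n, "]")
  }
  if (any(facets[, 1L] == facets[, 2L] | facets[, 2L] == facets[, 3L] |
            facets[, 1L] == facets[, 3L])) {
    stop("facets must reference 3 distinct vertices")
  }
  structure(list(vertices = vertices, facets = facets),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  topo <- build_topology(x)
  cat(sprintf("triangle_mesh: %d vertices, %d facets, %d edges (%d boundary)\n",
              nrow(x$vertices), nrow(x$facets), nrow(topo$edges),
              sum(topo$boundary)))
  invisible(x)
}

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) stop("not a triangle_mesh")
  invisible(mesh)
}

#' Edge topology of a triangle mesh
#'
#' Partitions the edge set into interior edges (shared by exactly two
#' facets) and boundary edges (one facet), and records, for each interior
#' edge, the two adjacent facets and their opposite vertices. This is the
#' connectivity every dihedral-angle computation consumes.
#'
#' @param mesh a [triangle_mesh()].
#'
#' @return an object of class `edge_topology` with:
#'   \describe{
#'     \item{edges}{k x 2 integer matrix of canonical edges
#'       (min index, max index), sorted lexicographically.}
#'     \item{boundary}{logical vector, `TRUE` for boundary edges.}
#'     \item{interior}{integer matrix with one row per interior edge and
#'       columns `v1`, `v2` (edge endpoints in the traversal order of the
#'       first adjacent facet), `o1`, `o2` (opposite vertices in the first
#'       and second facet), `f1`, `f2` (facet indices), `edge` (row in
#'       `edges`).}
#'     \item{opposing}{logical per interior edge: `TRUE` when the two
#'       facets traverse the edge in opposite order (consistent
#'       orientation).}
#'   }
#' @export
build_topology <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$facets
  m <- nrow(f)
  # three directed half-edges per facet
  he_a <- c(f[, 1L], f[, 2L], f[, 3L])
  he_b <- c(f[, 2L], f[, 3L], f[, 1L])
  he_f <- rep.int(seq_len(m), 3L)
  he_o <- c(f[, 3L], f[, 1L], f[, 2L])   # opposite vertex of each half-edge
  lo <- pmin(he_a, he_b)
  hi <- pmax(he_a, he_b)
  key <- paste(lo, hi)
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[which(cnt > 2L)[1L]]
    stop("non-manifold edge (", gsub(" ", "-", bad),
         ") shared by more than 2 facets")
  }
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  he_a <- he_a[ord]; he_b <- he_b[ord]; he_f <- he_f[ord]; he_o <- he_o[ord]
  first <- !duplicated(cbind(lo, hi))
  edges <- cbind(lo[first], hi[first])
  colnames(edges) <- c("a", "b")
  eid <- cumsum(first)               # edge id per half-edge
  mult <- tabulate(eid)
  boundary <- mult == 1L
  if (any(mult == 2L)) {
    i1 <- which(first & !boundary[eid])
    i2 <- i1 + 1L
    interior <- cbind(v1 = he_a[i1], v2 = he_b[i1],
                      o1 = he_o[i1], o2 = he_o[i2],
                      f1 = he_f[i1], f2 = he_f[i2],
                      edge = eid[i1])
    # consistent orientation: second facet traverses the edge reversed
    opposing <- he_a[i2] == he_b[i1] & he_b[i2] == he_a[i1]
  } else {
    interior <- matrix(integer(0), 0L, 7L,
                       dimnames = list(NULL, c("v1", "v2", "o1", "o2",
                                               "f1", "f2", "edge")))
    opposing <- logical(0)
  }
  structure(list(edges = edges, boundary = boundary,
                 interior = interior, opposing = opposing,
                 # cached 0-based index matrices for the compiled core
                 edges0 = edges - 1L,
                 ie0 = interior[, c("v1", "v2", "o1", "o2", "f1", "f2"),
                                drop = FALSE] - 1L),
            class = "edge_topology")
}

#' Is a mesh closed (watertight)?
#'
#' @param mesh a [triangle_mesh()].
#' @param topology optional precomputed [build_topology()] result.
#' @return `TRUE` when the mesh has no boundary edges.
#' @export
is_closed_mesh <- function(mesh, topology = NULL) {
  if (is.null(topology)) topology <- build_topology(mesh)
  !any(topology$boundary)
}

row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

facet_normals_raw <- function(mesh) {
  v <- mesh$vertices; f <- mesh$facets
  row_cross(v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE],
            v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE])
}

#' Facet areas
#'
#' Area of each triangular facet: half the magnitude of the cross product
#' of two edge vectors. Degenerate (collinear) facets return area 0.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of nonnegative areas, one per facet.
#' @export
facet_areas <- function(mesh) {
  stopifnot_mesh(mesh)
  n <- facet_normals_raw(mesh)
  0.5 * sqrt(rowSums(n * n))
}

#' @rdname facet_areas
#' @param facet_index facet row index.
#' @export
facet_area <- function(mesh, facet_index) {
  facet_areas(mesh)[facet_index]
}

#' Edge lengths
#'
#' @param mesh a [triangle_mesh()].
#' @param topology a [build_topology()] result for `mesh`.
#' @return numeric vector of edge lengths in the order of `topology$edges`.
#' @export
edge_lengths <- function(mesh, topology) {
  v <- mesh$vertices; e <- topology$edges
  d <- v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Inter-facet (dihedral) angles
#'
#' The angle between the two facets meeting at each interior edge, measured
#' on the inner side of the surface, in (0, 2*pi). Coplanar consistently
#' oriented facets give exactly pi ("locally flat"); on a convex closed
#' surface with outward orientation every angle is < pi; reflex folds give
#' angles > pi.
#'
#' @details The convention is `theta = pi - phi` where `phi` is the signed
#'   angle between the facet normals, its sign taken from the orientation
#'   of the shared edge in the first adjacent facet. This makes the furrow
#'   flattening protocol's rest angle of pi mean "flat sheet".
#'
#' @param mesh a [triangle_mesh()].
#' @param topology a [build_topology()] result for `mesh`.
#' @return numeric vector, one angle (radians) per interior edge, in the
#'   row order of `topology$interior`.
#' @export
dihedral_angles <- function(mesh, topology) {
  stopifnot_mesh(mesh)
  ie <- topology$interior
  if (nrow(ie) == 0L) return(numeric(0))
  if (!all(topology$opposing)) {
    stop("inconsistently oriented interior edge: dihedral sign undefined")
  }
  v <- mesh$vertices
  nraw <- facet_normals_raw(mesh)
  n1 <- nraw[ie[, "f1"], , drop = FALSE]
  n2 <- nraw[ie[, "f2"], , drop = FALSE]
  a1 <- sqrt(rowSums(n1 * n1)); a2 <- sqrt(rowSums(n2 * n2))
  if (any(a1 == 0) || any(a2 == 0)) {
    stop("degenerate (zero-area) facet adjacent to an interior edge")
  }
  n1 <- n1 / a1; n2 <- n2 / a2
  e <- v[ie[, "v2"], , drop = FALSE] - v[ie[, "v1"], , drop = FALSE]
  e <- e / sqrt(rowSums(e * e))
  s <- rowSums(row_cross(n1, n2) * e)
  c_ <- rowSums(n1 * n2)
  pi - atan2(s, c_)
}

#' @rdname dihedral_angles
#' @param interior_edge row index into `topology$interior`.
#' @export
dihedral_angle <- function(mesh, topology, interior_edge) {
  dihedral_angles(mesh, topology)[interior_edge]
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem: the sum of signed tetrahedra
#' spanned by each facet and the origin. Positive for a closed surface with
#' outward orientation, and invariant under translation.
#'
#' @param mesh a closed, consistently outward-oriented [triangle_mesh()].
#' @param topology optional precomputed topology.
#' @return the enclosed volume (scalar).
#' @export
enclosed_volume <- function(mesh, topology = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(topology)) topology <- build_topology(mesh)
  if (any(topology$boundary)) stop("volume undefined for open surface")
  v <- mesh$vertices; f <- mesh$facets
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  sum(rowSums(p1 * row_cross(p2, p3))) / 6
}

#' Validate a triangle mesh
#'
#' Reports closedness, orientation consistency, degenerate facets,
#' non-manifold edges and the Euler characteristic.
#'
#' @param mesh a [triangle_mesh()].
#' @return a list with elements `valid`, `closed`, `oriented`,
#'   `n_degenerate_facets`, `euler_characteristic`, `n_vertices`,
#'   `n_facets`, `n_edges`, `n_boundary_edges`, and `problems` (character
#'   vector; empty when valid).
#' @export
validate_mesh <- function(mesh) {
  stopifnot_mesh(mesh)
  problems <- character(0)
  topo <- tryCatch(build_topology(mesh), error = function(e) e)
  if (inherits(topo, "error")) {
    return(list(valid = FALSE, closed = NA, oriented = NA,
                n_degenerate_facets = NA_integer_,
                euler_characteristic = NA_integer_,
                n_vertices = nrow(mesh$vertices),
                n_facets = nrow(mesh$facets), n_edges = NA_integer_,
                n_boundary_edges = NA_integer_,
                problems = conditionMessage(topo)))
  }
  oriented <- all(topo$opposing)
  if (!oriented) {
    bad <- topo$interior[which(!topo$opposing)[1L], , drop = TRUE]
    problems <- c(problems, sprintf(
      "inconsistent orientation at edge (%d-%d)", bad[["v1"]], bad[["v2"]]))
  }
  ndeg <- sum(facet_areas(mesh) == 0)
  if (ndeg > 0) problems <- c(problems, sprintf("%d degenerate facets", ndeg))
  chi <- nrow(mesh$vertices) - nrow(topo$edges) + nrow(mesh$facets)
  list(valid = length(problems) == 0L,
       closed = !any(topo$boundary),
       oriented = oriented,
       n_degenerate_facets = ndeg,
       euler_characteristic = chi,
       n_vertices = nrow(mesh$vertices),
       n_facets = nrow(mesh$facets),
       n_edges = nrow(topo$edges),
       n_boundary_edges = sum(topo$boundary),
       problems = problems)
}
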