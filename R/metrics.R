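#' Shape metrics of an unfolded patch
#'
#' Turns "how did the sheet change shape" into numbers: in-plane expansion
#' ratios along the initial patch's principal axes, their anisotropy,
#' planarity of the final sheet, and the relative change in total facet
#' area. The final mesh is first rigidly aligned to the initial one
#' (rotation + translation, Kabsch on the shared vertex correspondence),
#' so all metrics are invariant under rigid motion of either mesh.
#'
#' @param initial,final two [triangle_mesh()]es with identical topology
#'   (same facet list), before and after unfolding.
#' @return an object of class `shape_metrics`: list with `extent_x`,
#'   `extent_y`, `extent_z` (final extents in the initial principal
#'   frame), `expansion_ratio_x`, `expansion_ratio_y` (final/initial
#'   in-plane extents), `anisotropy` (max/min of the two ratios, >= 1),
#'   `planarity` (max deviation of the final sheet from its best-fit
#'   plane, divided by its diameter) and `area_change_fraction`.
#' @export
patch_metrics <- function(initial, final) {
  stopifnot_mesh(initial); stopifnot_mesh(final)
  if (!identical(dim(initial$vertices), dim(final$vertices)) ||
        !identical(initial$facets, final$facets)) {
    stop("initial and final meshes must share the same topology")
  }
  # each sheet is measured in its own frame: the patch normal is the
  # area-weighted mean facet normal (corrugation tilts cancel, unlike
  # the smallest PCA axis, which leans whenever height correlates with
  # position), and the two in-plane frames are paired through the SVD of
  # the best-fit in-plane deformation map, so no vertex-level rigid
  # alignment is needed and the axes stay well defined even for square
  # or radially symmetric patches
  sheet_frame <- function(mesh) {
    x <- scale(mesh$vertices, scale = FALSE)
    nsum <- colSums(facet_normals_raw(mesh))
    nn <- sqrt(sum(nsum^2))
    normal <- if (nn > 1e-8 * sum(facet_areas(mesh))) {
      nsum / nn
    } else {
      eigen(crossprod(x), symmetric = TRUE)$vectors[, 3L]
    }
    inplane <- svd(diag(3) - tcrossprod(normal))$u[, 1:2]
    list(x = x, normal = normal, inplane = inplane, P = x %*% inplane)
  }
  fi <- sheet_frame(initial)
  ff <- sheet_frame(final)
  m2 <- qr.solve(fi$P, ff$P)          # 2x2 in-plane deformation gradient
  sv <- svd(m2)
  ui <- fi$inplane %*% sv$u           # strain directions, initial plane
  vf <- ff$inplane %*% sv$v           # corresponding final directions
  ext <- function(x, dir) diff(range(x %*% dir))
  ei1 <- ext(fi$x, ui[, 1L]); ei2 <- ext(fi$x, ui[, 2L])
  ef1 <- ext(ff$x, vf[, 1L]); ef2 <- ext(ff$x, vf[, 2L])
  ez <- ext(ff$x, ff$normal)
  rx <- ef1 / ei1; ry <- ef2 / ei2
  ef <- c(ef1, ef2, ez)
  zf <- ff$x %*% ff$normal
  diam <- sqrt(ef1^2 + ef2^2)
  planarity <- max(abs(zf - mean(zf))) / diam
  a0 <- sum(facet_areas(initial)); a1 <- sum(facet_areas(final))
  structure(list(extent_x = ef[1L], extent_y = ef[2L], extent_z = ef[3L],
                 expansion_ratio_x = rx, expansion_ratio_y = ry,
                 anisotropy = max(rx, ry) / min(rx, ry),
                 planarity = planarity,
                 area_change_fraction = (a1 - a0) / a0),
            class = "shape_metrics")
}

#' Angle-deficit curvature signature
#'
#' Discrete Gaussian-curvature proxy: for each interior vertex the angle
#' deficit `2*pi - sum(incident corner angles)`. Positive deficits mark
#' dome-like (elliptic) regions, negative deficits saddle / horseback
#' (hyperbolic) regions; a flat sheet has deficit 0 everywhere. On a
#' closed mesh the deficits sum to `2*pi*chi` (Gauss-Bonnet).
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `deficit` (per vertex; `NA` for boundary vertices),
#'   `interior` (logical), `total_deficit` (sum over interior vertices)
#'   and `fraction_negative` (share of interior vertices with deficit
#'   < -`tol`).
#' @param tol deficits within `tol` of zero count as flat, not negative.
#' @export
curvature_signature <- function(mesh, tol = 1e-9) {
  stopifnot_mesh(mesh)
  topo <- build_topology(mesh)
  v <- mesh$vertices; f <- mesh$facets
  corner_angle <- function(a, b, c_) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c_, , drop = FALSE] - v[a, , drop = FALSE]
    cu <- rowSums(u * w) /
      (sqrt(rowSums(u * u)) * sqrt(rowSums(w * w)))
    acos(pmin(pmax(cu, -1), 1))
  }
  n <- nrow(v)
  acc <- numeric(n)
  for (k in 1:3) {
    a <- f[, k]; b <- f[, k %% 3L + 1L]; c_ <- f[, (k + 1L) %% 3L + 1L]
    ang <- corner_angle(a, b, c_)
    s <- rowsum(ang, a)
    ids <- as.integer(rownames(s))
    acc[ids] <- acc[ids] + s[, 1L]
  }
  interior <- rep(TRUE, n)
  if (any(topo$boundary)) {
    bv <- unique(as.vector(topo$edges[topo$boundary, , drop = FALSE]))
    interior[bv] <- FALSE
  }
  used <- tabulate(f, n) > 0L
  deficit <- ifelse(interior & used, 2 * pi - acc, NA_real_)
  ivals <- deficit[interior & used]
  list(deficit = deficit, interior = interior & used,
       total_deficit = sum(ivals),
       fraction_negative = mean(ivals < -tol))
}

#' Arc-length expansion oracle for a sinusoidal furrow profile
#'
#' The factor by which a sinusoidal profile `z = a sin(2*pi*x/lambda)`
#' lengthens relative to its baseline: the mean of
#' `sqrt(1 + (2*pi*a/lambda)^2 cos^2(2*pi*x/lambda))` over one period,
#' computed by numerical quadrature. When parallel furrows flatten, the
#' sheet's cross-furrow extent should grow by this factor (and the
#' along-furrow extent stay ~1).
#'
#' @param amplitude profile amplitude `a`.
#' @param wavelength profile wavelength `lambda` (same units).
#' @return the arc-length ratio (>= 1).
#' @examples
#' profile_arclength_ratio(0, 10)      # flat profile: 1
#' profile_arclength_ratio(3, 2 * pi)  # deep furrows store length
#' @export
profile_arclength_ratio <- function(amplitude, wavelength) {
  k <- 2 * pi * amplitude / wavelength
  stats::integrate(function(u) sqrt(1 + k^2 * cos(u)^2), 0, 2 * pi,
                   rel.tol = 1e-10)$value / (2 * pi)
}
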