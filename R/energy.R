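#' Elastic stiffness parameters
#'
#' Stiffness constants of the four quadratic energy terms and the friction
#' coefficient of the steepest-descent dynamics. The defaults encode the
#' "almost fixed plate size" regime used for whole-primordium inflation:
#' facet-area and edge-length terms much stiffer than the bending (angle)
#' term, with a moderate volume stiffness driving the inflation.
#'
#' @param k_volume stiffness of the enclosed-volume term (0 disables it;
#'   open patches must have it disabled).
#' @param k_area stiffness of the facet-area term.
#' @param k_edge stiffness of the edge-length term.
#' @param k_angle stiffness of the inter-facet (dihedral) angle term.
#' @param gamma friction coefficient of the overdamped dynamics
#'   `gamma dr/dt = -dU/dr`; only `dt/gamma` is observable, so `gamma` is
#'   kept at 1 by default.
#' @return an object of class `elastic_parameters`.
#' @export
elastic_parameters <- function(k_volume = 10, k_area = 100, k_edge = 100,
                               k_angle = 1, gamma = 1) {
  p <- list(k_volume = k_volume, k_area = k_area, k_edge = k_edge,
            k_angle = k_angle, gamma = gamma)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop(nm, " must be a finite scalar")
    }
  }
  if (any(unlist(p[1:4]) < 0)) stop("stiffness constants must be nonnegative")
  if (gamma <= 0) stop("gamma must be positive")
  structure(p, class = "elastic_parameters")
}

#' Capture the stress-free reference state
#'
#' Reads the rest quantities (facet areas, edge lengths, inter-facet
#' angles, optionally enclosed volume) off the current geometry. Every
#' elastic term is exactly zero when the mesh equals its reference.
#'
#' @param mesh a [triangle_mesh()].
#' @param include_volume capture the enclosed volume as rest volume
#'   (requires a closed mesh).
#' @param topology optional precomputed [build_topology()].
#' @param rest_angle if non-`NULL`, overrides all rest dihedral angles with
#'   this value (radians). The furrow-flattening protocol uses `pi`.
#' @return an object of class `reference_state` with `V0` (or `NA`), `A0`,
#'   `L0` (per edge), `Theta0` and `L0_interior` (rest length per interior
#'   edge, the weight of the angle term).
#' @export
capture_reference <- function(mesh, include_volume = FALSE, topology = NULL,
                              rest_angle = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(topology)) topology <- build_topology(mesh)
  A0 <- facet_areas(mesh)
  if (any(A0 <= 0)) stop("degenerate (zero-area) facet: no valid reference")
  L0 <- edge_lengths(mesh, topology)
  Theta0 <- dihedral_angles(mesh, topology)
  if (!is.null(rest_angle)) {
    if (rest_angle <= 0 || rest_angle >= 2 * pi) {
      stop("rest_angle must lie in (0, 2*pi)")
    }
    Theta0 <- rep(rest_angle, length(Theta0))
  }
  V0 <- NA_real_
  if (include_volume) {
    if (any(topology$boundary)) {
      stop("include_volume requires a closed mesh")
    }
    V0 <- enclosed_volume(mesh, topology)
    if (V0 <= 0) stop("rest volume must be positive (check orientation)")
  }
  ie <- topology$interior[, "edge"]
  structure(list(V0 = V0, A0 = A0, L0 = L0, Theta0 = Theta0,
                 L0_interior = L0[ie]),
            class = "reference_state")
}

check_ref_sizes <- function(mesh, topology, ref) {
  if (!inherits(ref, "reference_state")) stop("ref must be a reference_state")
  if (length(ref$A0) != nrow(mesh$facets) ||
        length(ref$L0) != nrow(topology$edges) ||
        length(ref$Theta0) != nrow(topology$interior)) {
    stop("reference state does not match mesh size")
  }
}

energy_call <- function(mesh, topology, ref, params, want_grad) {
  stopifnot_mesh(mesh)
  check_ref_sizes(mesh, topology, ref)
  if (!inherits(params, "elastic_parameters")) {
    params <- do.call(elastic_parameters, as.list(params))
  }
  kv <- params$k_volume
  if (kv > 0 && is.na(ref$V0)) kv <- 0  # volume term off for open patches
  if (kv > 0 && any(topology$boundary)) {
    stop("volume term requires a closed mesh")
  }
  .energy_gradient_cpp(
    mesh$vertices, mesh$facets - 1L, topology$edges0, topology$ie0,
    if (kv > 0) ref$V0 else 1.0,
    ref$A0, ref$L0, ref$L0_interior, ref$Theta0,
    kv, params$k_area, params$k_edge, params$k_angle, want_grad)
}

#' Total elastic energy
#'
#' The total energy U is the sum of elastic energies stored by changes in
#' polygon volume, facet area, edge length, and inter-facet angle relative
#' to the stress-free reference:
#' \deqn{U = \frac{k_V}{2}\frac{(V-V_0)^2}{V_0}
#'   + \sum_f \frac{k_A}{2}\frac{(A_f-A_{0f})^2}{A_{0f}}
#'   + \sum_e \frac{k_L}{2}\frac{(L_e-L_{0e})^2}{L_{0e}}
#'   + \sum_{e\,\mathrm{int}} \frac{k_\Theta}{2}(\Theta_e-\Theta_{0e})^2
#'     L_{0e}}
#' Each penalty is normalised by its rest quantity (the angle term weighted
#' by rest edge length) so the energy is size-consistent.
#'
#' @param mesh a [triangle_mesh()].
#' @param topology a [build_topology()] result for `mesh`.
#' @param ref a [capture_reference()] state sized for this mesh.
#' @param params an [elastic_parameters()] object.
#' @return an `energy_breakdown`: list with `total`, `volume`, `area`,
#'   `edge`, `angle` (all nonnegative; `total` is their sum) and
#'   `enclosed_volume` (NA when the volume term is off).
#' @export
total_energy <- function(mesh, topology, ref, params) {
  r <- energy_call(mesh, topology, ref, params, want_grad = FALSE)
  structure(r, class = "energy_breakdown")
}

#' Analytic energy gradient
#'
#' The exact derivative `dU/dr_i` of [total_energy()] with respect to every
#' vertex position; the steepest-descent dynamics moves vertices against
#' it. Verified against [finite_difference_gradient()].
#'
#' @inheritParams total_energy
#' @return an n x 3 numeric matrix, row i holding `dU/dr_i`.
#' @export
energy_gradient <- function(mesh, topology, ref, params) {
  energy_call(mesh, topology, ref, params, want_grad = TRUE)$gradient
}

#' Central finite-difference gradient (verification oracle)
#'
#' Second-order central differences of [total_energy()] per vertex
#' coordinate; an independent numerical route used to check the analytic
#' gradient.
#'
#' @inheritParams total_energy
#' @param step central-difference step (> 0).
#' @return an n x 3 numeric matrix approximating `dU/dr_i`.
#' @export
finite_difference_gradient <- function(mesh, topology, ref, params,
                                       step = 1e-6) {
  if (step <= 0) stop("step must be positive")
  v <- mesh$vertices
  g <- matrix(0, nrow(v), 3L)
  m2 <- mesh
  for (i in seq_len(nrow(v))) {
    for (d in 1:3) {
      m2$vertices[i, d] <- v[i, d] + step
      up <- energy_call(m2, topology, ref, params, want_grad = FALSE)$total
      m2$vertices[i, d] <- v[i, d] - step
      dn <- energy_call(m2, topology, ref, params, want_grad = FALSE)$total
      m2$vertices[i, d] <- v[i, d]
      g[i, d] <- (up - dn) / (2 * step)
    }
  }
  g
}
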