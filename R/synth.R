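#' Furrow-pattern height map
#'
#' A grayscale grid interpreted as a height map: the position of each mesh
#' vertex is determined by the location and tone of the corresponding
#' pixel. Tone 255 maps to `height_scale`, tone 0 to height 0.
#'
#' @param grid numeric H x W matrix of tones in [0, 255]; row 1 is the top
#'   of the image.
#' @param height_scale physical height of tone 255 (same length units as
#'   the in-plane pitch).
#' @param pixel_pitch in-plane spacing between neighbouring pixels.
#' @return an object of class `furrow_pattern`.
#' @export
furrow_pattern <- function(grid, height_scale = 1, pixel_pitch = 1) {
  grid <- as.matrix(grid)
  if (nrow(grid) < 2L || ncol(grid) < 2L) stop("grid must be at least 2 x 2")
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 255)) {
    stop("tones must be finite and in [0, 255]")
  }
  if (height_scale < 0) stop("height_scale must be >= 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  structure(list(grid = grid, height_scale = height_scale,
                 pixel_pitch = pixel_pitch),
            class = "furrow_pattern")
}

#' Procedural furrow archetypes
#'
#' Renders the characteristic furrow patterns of horn primordia as
#' grayscale height maps: `parallel` (straight furrows, a sinusoid in one
#' axis), `zigzag` (herringbone bands whose furrow direction alternates
#' between +45 and -45 degrees), `concentric` (radial sinusoid around a
#' centre), and `dome_concentric` (a dome base with concentric rings, the
#' horn-tip analogue). Accordion corrugation of a closed stalk is produced
#' by [make_virtual_primordium()] instead.
#'
#' @param archetype one of `"parallel"`, `"zigzag"`, `"concentric"`,
#'   `"dome_concentric"`.
#' @param H,W grid size in pixels.
#' @param wavelength furrow wavelength in pixels.
#' @param amplitude tone amplitude of the furrows (0..127.5 keeps tones in
#'   range around the mid-gray base).
#' @param phase phase offset in radians.
#' @param center c(row, col) centre for the concentric archetypes
#'   (defaults to the image centre).
#' @param band_height band height in pixels for `zigzag` (default one
#'   wavelength).
#' @param jitter tone amplitude of uniform pixel noise (default 0).
#' @param seed RNG seed for the jitter; same spec + same seed renders
#'   identical grids.
#' @inheritParams furrow_pattern
#' @return a [furrow_pattern()].
#' @export
render_pattern <- function(archetype, H = 100L, W = 100L, wavelength = 20,
                           amplitude = 60, phase = 0, center = NULL,
                           band_height = NULL, jitter = 0, seed = 1L,
                           height_scale = 1, pixel_pitch = 1) {
  archetype <- match.arg(archetype, c("parallel", "zigzag", "concentric",
                                      "dome_concentric"))
  if (wavelength <= 0) stop("wavelength must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  i <- matrix(seq_len(H), H, W)        # row index
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  base <- 127.5
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  g <- switch(archetype,
    parallel = base + amplitude * sin(2 * pi * (j - 1) / wavelength + phase),
    zigzag = {
      bh <- if (is.null(band_height)) wavelength else band_height
      band <- ((i - 1) %/% bh) %% 2L
      u <- ifelse(band == 0L, (j + i) / sqrt(2), (j - i) / sqrt(2))
      base + amplitude * sin(2 * pi * u / wavelength + phase)
    },
    concentric = {
      r <- sqrt((i - center[1])^2 + (j - center[2])^2)
      base + amplitude * sin(2 * pi * r / wavelength + phase)
    },
    dome_concentric = {
      r <- sqrt((i - center[1])^2 + (j - center[2])^2)
      rmax <- max(r)
      dome <- (255 - 2 * amplitude) * pmax(0, cos(pi * r / (2 * rmax)))
      dome + amplitude * (1 + sin(2 * pi * r / wavelength + phase))
    })
  if (jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    g <- g + matrix(stats::runif(H * W, -jitter, jitter), H, W)
  }
  g <- pmin(pmax(g, 0), 255)
  furrow_pattern(g, height_scale = height_scale, pixel_pitch = pixel_pitch)
}

#' Convert a height map to an open grid mesh
#'
#' Vertex (i, j) (row-major order, row 1 at the top) sits at
#' `((j-1) * pitch, (H-i) * pitch, tone/255 * height_scale)`; each grid
#' cell is split into two consistently oriented triangles along the same
#' diagonal. An H x W image yields H*W vertices and 2(H-1)(W-1) facets.
#'
#' @param pattern a [furrow_pattern()].
#' @return an open [triangle_mesh()] with attributes `grid_dim = c(H, W)`
#'   and `pixel_pitch`, facing +z.
#' @export
heightmap_to_mesh <- function(pattern) {
  if (!inherits(pattern, "furrow_pattern")) stop("not a furrow_pattern")
  g <- pattern$grid
  H <- nrow(g); W <- ncol(g); pitch <- pattern$pixel_pitch
  # row-major vertex ids: id = (i-1)*W + j
  id <- matrix(seq_len(H * W), H, W, byrow = TRUE)
  v <- matrix(0, H * W, 3L)
  ii <- rep(seq_len(H), each = W)
  jj <- rep(seq_len(W), times = H)
  v[, 1L] <- (jj - 1) * pitch
  v[, 2L] <- (H - ii) * pitch
  v[, 3L] <- t(g)[cbind(jj, ii)] / 255 * pattern$height_scale
  a <- id[seq_len(H - 1), seq_len(W - 1)]
  b <- id[seq_len(H - 1), 2:W]
  c_ <- id[2:H, seq_len(W - 1)]
  d <- id[2:H, 2:W]
  f <- rbind(cbind(as.vector(a), as.vector(c_), as.vector(d)),
             cbind(as.vector(a), as.vector(d), as.vector(b)))
  mesh <- triangle_mesh(v, f)
  attr(mesh, "grid_dim") <- c(H, W)
  attr(mesh, "pixel_pitch") <- pitch
  mesh
}

#' Coarsen a grid mesh
#'
#' Resolution control for height-map meshes: keeps every `factor`-th grid
#' vertex in each direction and re-triangulates the coarser grid with the
#' same diagonal convention. (A simple stand-in for general decimation.)
#'
#' @param mesh a mesh produced by [heightmap_to_mesh()].
#' @param factor positive integer dividing both H-1 and W-1.
#' @return the coarsened grid mesh.
#' @export
coarsen_grid_mesh <- function(mesh, factor) {
  gd <- attr(mesh, "grid_dim")
  if (is.null(gd)) stop("not a grid mesh (missing grid_dim attribute)")
  H <- gd[1L]; W <- gd[2L]
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(mesh)
  if ((H - 1L) %% factor != 0L || (W - 1L) %% factor != 0L) {
    stop("factor must divide both H-1 and W-1")
  }
  keep_i <- seq(1L, H, by = factor)
  keep_j <- seq(1L, W, by = factor)
  id <- matrix(seq_len(H * W), H, W, byrow = TRUE)
  old_ids <- as.vector(t(id[keep_i, keep_j]))  # row-major again
  v <- mesh$vertices[old_ids, , drop = FALSE]
  H2 <- length(keep_i); W2 <- length(keep_j)
  id2 <- matrix(seq_len(H2 * W2), H2, W2, byrow = TRUE)
  a <- id2[seq_len(H2 - 1), seq_len(W2 - 1)]
  b <- id2[seq_len(H2 - 1), 2:W2]
  c_ <- id2[2:H2, seq_len(W2 - 1)]
  d <- id2[2:H2, 2:W2]
  f <- rbind(cbind(as.vector(a), as.vector(c_), as.vector(d)),
             cbind(as.vector(a), as.vector(d), as.vector(b)))
  out <- triangle_mesh(v, f)
  attr(out, "grid_dim") <- c(H2, W2)
  attr(out, "pixel_pitch") <- attr(mesh, "pixel_pitch") * factor
  out
}

#' HC Laplacian smoothing
#'
#' Humphrey's Classes (Vollmer et al.) smoothing: a uniform Laplacian step
#' followed by a correction that pushes vertices back towards their
#' original positions, curbing the volume shrinkage of plain Laplacian
#' smoothing. Boundary vertices are held fixed, so a planar grid is an
#' exact fixed point.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of smoothing passes (>= 0).
#' @param alpha weight of the original (vs current) position in the
#'   correction anchor.
#' @param beta weight of a vertex's own correction vs its neighbours'.
#' @param plain if `TRUE` performs plain Laplacian smoothing (no
#'   correction step) for comparison.
#' @return the smoothed mesh (same topology).
#' @export
hc_laplacian_smooth <- function(mesh, iterations = 2L, alpha = 0.1,
                                beta = 0.6, plain = FALSE) {
  stopifnot_mesh(mesh)
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0L) return(mesh)
  topo <- build_topology(mesh)
  e <- topo$edges
  nb_from <- c(e[, 1L], e[, 2L])
  nb_to <- c(e[, 2L], e[, 1L])
  n <- nrow(mesh$vertices)
  deg <- tabulate(nb_from, n)
  interior_v <- rep(TRUE, n)
  if (any(topo$boundary)) {
    bverts <- unique(as.vector(e[topo$boundary, , drop = FALSE]))
    interior_v[bverts] <- FALSE
  }
  o <- mesh$vertices  # originals
  q <- o
  for (it in seq_len(iterations)) {
    lap <- rowsum(q[nb_to, , drop = FALSE], nb_from) / deg
    p <- q
    p[interior_v, ] <- lap[interior_v, ]
    if (!plain) {
      b <- p - (alpha * o + (1 - alpha) * q)
      bn <- rowsum(b[nb_to, , drop = FALSE], nb_from) / deg
      corr <- beta * b + (1 - beta) * bn
      p[interior_v, ] <- p[interior_v, ] - corr[interior_v, ]
    }
    q <- p
  }
  out <- mesh
  out$vertices <- q
  out
}

#' Icosphere fixture
#'
#' A geodesic sphere obtained by repeated subdivision of an icosahedron and
#' projection to the sphere; closed, consistently outward-oriented.
#'
#' @param subdivisions number of 4-to-1 subdivision rounds (0 gives the
#'   icosahedron).
#' @param radius sphere radius.
#' @return a closed [triangle_mesh()].
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ekey <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- ekey[[k]]
      if (is.null(id)) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        id <- nrow(v)
        ekey[[k]] <- id
      }
      id
    }
    f2 <- matrix(0L, 0L, 3L)
    f2 <- vector("list", nrow(f))
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1L]; b <- f[r, 2L]; c_ <- f[r, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      f2[[r]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                       c(ab, bc, ca))
    }
    f <- do.call(rbind, f2)
  }
  v <- v / sqrt(rowSums(v * v)) * radius
  triangle_mesh(v, f)
}

#' Wrinkled-sphere fixture
#'
#' An icosphere with sinusoidal radial corrugation: latitudinal rings
#' `r = radius * (1 + amplitude * sin(2 * frequency * theta))` with
#' `theta` the polar angle, giving `frequency` full corrugation periods
#' from pole to pole. This stores substantial extra surface area at nearly
#' unchanged enclosed volume — the furrowed-primordium analogue used by the
#' inflation protocol.
#'
#' @param subdivisions icosphere subdivision rounds (resolution).
#' @param amplitude relative corrugation amplitude (fraction of radius).
#' @param frequency corrugation periods from pole to pole.
#' @param radius base radius.
#' @return a closed [triangle_mesh()].
#' @export
wrinkled_icosphere <- function(subdivisions = 4L, amplitude = 0.15,
                               frequency = 8, radius = 1) {
  m <- icosphere(subdivisions, radius = 1)
  v <- m$vertices
  r <- sqrt(rowSums(v * v))
  theta <- acos(pmin(pmax(v[, 3L] / r, -1), 1))
  fac <- radius * (1 + amplitude * sin(2 * frequency * theta))
  m$vertices <- v / r * (r * fac)
  m
}

#' Ring-corrugated sphere fixture (latitude-aligned mesh)
#'
#' A closed sphere-like surface with latitudinal accordion corrugation,
#' `r = radius * (1 + amplitude * sin(2 * frequency * theta))`, meshed on
#' a latitude-longitude grid so that the mesh edges follow the meridians
#' and parallels of the corrugation. On such an aligned mesh the
#' accordion can open by near-isometric bending (meridian and parallel
#' lengths preserved), which is how a furrowed primordium stores
#' unfoldable area; on a triangulation whose edges cross the furrows
#' obliquely (e.g. an icosphere) the same motion would strain edges and
#' the stiff membrane terms lock the folds shut.
#'
#' @param amplitude relative corrugation amplitude (fraction of radius).
#' @param frequency corrugation periods from pole to pole.
#' @param n_theta vertices per ring (around the axis).
#' @param n_rings latitude bands pole to pole.
#' @param radius base radius.
#' @return a closed [triangle_mesh()].
#' @export
corrugated_sphere <- function(amplitude = 0.15, frequency = 8,
                              n_theta = 64L, n_rings = 64L, radius = 1) {
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  th <- seq(0, pi, length.out = n_rings + 1L)
  inner <- th[2:n_rings]
  r <- radius * (1 + amplitude * sin(2 * frequency * inner))
  ang <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  v <- matrix(0, 2L + (n_rings - 1L) * n_theta, 3L)
  v[1L, ] <- c(0, 0, radius)
  v[2L, ] <- c(0, 0, -radius)
  for (k in seq_along(inner)) {
    rows <- 2L + (k - 1L) * n_theta + seq_len(n_theta)
    v[rows, ] <- cbind(r[k] * sin(inner[k]) * cos(ang),
                       r[k] * sin(inner[k]) * sin(ang),
                       r[k] * cos(inner[k]))
  }
  rid <- function(k, t) 2L + (k - 1L) * n_theta + ((t - 1L) %% n_theta) + 1L
  t <- seq_len(n_theta)
  f <- vector("list", n_rings)
  f[[1L]] <- cbind(1L, rid(1L, t), rid(1L, t + 1L))
  for (k in seq_len(n_rings - 2L)) {
    a <- rid(k, t); b <- rid(k, t + 1L)
    c_ <- rid(k + 1L, t); d <- rid(k + 1L, t + 1L)
    f[[k + 1L]] <- rbind(cbind(a, d, b), cbind(a, c_, d))
  }
  f[[n_rings]] <- cbind(2L, rid(n_rings - 1L, t + 1L), rid(n_rings - 1L, t))
  m <- triangle_mesh(v, do.call(rbind, f))
  if (enclosed_volume(m) < 0) m$facets <- m$facets[, c(1L, 3L, 2L)]
  m
}

#' Virtual primordium fixture
#'
#' A closed, outward-oriented mushroom-shaped surface of revolution
#' emulating a folded horn primordium: a dome cap with concentric
#' (ring-shaped) corrugation sitting on a cylindrical stalk with
#' circumferential accordion corrugation, closed by a flat bottom disk.
#' With `furrow_amplitude = 0` the surface is the smooth capsule-like
#' generator (cylinder + flat annulus + hemispherical cap), whose volume
#' has the closed form `pi * stalk_radius^2 * stalk_length +
#' (2/3) * pi * cap_radius^3`.
#'
#' @param stalk_radius,stalk_length cylinder dimensions.
#' @param cap_radius hemisphere radius (>= stalk_radius).
#' @param furrow_wavelength corrugation wavelength along the profile.
#' @param furrow_amplitude corrugation amplitude (< stalk_radius).
#' @param resolution number of vertices around the axis of revolution;
#'   profile sampling scales with it.
#' @return a closed [triangle_mesh()].
#' @export
make_virtual_primordium <- function(stalk_radius = 1, stalk_length = 3,
                                    cap_radius = 1.5,
                                    furrow_wavelength = 0.6,
                                    furrow_amplitude = 0, resolution = 64L) {
  if (stalk_radius <= 0 || stalk_length <= 0 || cap_radius <= 0 ||
        furrow_wavelength <= 0) {
    stop("dimensions must be positive")
  }
  if (cap_radius < stalk_radius) stop("cap_radius must be >= stalk_radius")
  if (furrow_amplitude < 0 || furrow_amplitude >= stalk_radius) {
    stop("furrow_amplitude must be in [0, stalk_radius)")
  }
  rs <- stalk_radius; L <- stalk_length; rc <- cap_radius
  # profile in (rho, z), parametrised by arc length s, pole to pole:
  # bottom disk, stalk wall, annulus, hemispherical cap
  s_disk <- rs; s_stalk <- L; s_ann <- rc - rs; s_cap <- pi * rc / 2
  stot <- s_disk + s_stalk + s_ann + s_cap
  ds_target <- stot / max(16L, round(resolution * stot / (2 * pi * rs)))
  profile_point <- function(s) {
    if (s <= s_disk) {
      c(rho = s, z = 0, nr = 0, nz = -1)        # bottom disk, normal down
    } else if (s <= s_disk + s_stalk) {
      c(rho = rs, z = s - s_disk, nr = 1, nz = 0)
    } else if (s <= s_disk + s_stalk + s_ann) {
      c(rho = rs + (s - s_disk - s_stalk), z = L, nr = 0, nz = 1)
    } else {
      psi <- (s - s_disk - s_stalk - s_ann) / rc  # 0 at rim, pi/2 at apex
      c(rho = rc * cos(psi), z = L + rc * sin(psi),
        nr = cos(psi), nz = sin(psi))
    }
  }
  ns <- max(16L, ceiling(stot / ds_target))
  ss <- seq(0, stot, length.out = ns + 1L)
  prof <- t(vapply(ss, profile_point, numeric(4)))
  # corrugation along the profile normal, tapered off at the bottom disk
  # and near the apex so poles stay regular
  if (furrow_amplitude > 0) {
    win <- rep(1, length(ss))
    win[ss <= s_disk] <- 0
    ramp <- function(u) pmin(pmax(u, 0), 1)
    win <- win * ramp((ss - s_disk) / (0.5 * furrow_wavelength))
    win <- win * ramp((stot - ss) / (0.5 * pi * rc / 2))
    disp <- furrow_amplitude *
      sin(2 * pi * (ss - s_disk) / furrow_wavelength) * win
    prof[, "rho"] <- prof[, "rho"] + disp * prof[, "nr"]
    prof[, "z"] <- prof[, "z"] + disp * prof[, "nz"]
    if (any(prof[-c(1, nrow(prof)), "rho"] <= 0)) {
      stop("corrugation parameters produce a self-intersecting profile")
    }
  }
  nt <- as.integer(resolution)
  ang <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  inner <- 2:(nrow(prof) - 1L)
  nv_ring <- length(inner)
  v <- matrix(0, 2L + nv_ring * nt, 3L)
  v[1L, ] <- c(0, 0, prof[1L, "z"])                       # bottom pole
  v[2L, ] <- c(0, 0, prof[nrow(prof), "z"])               # apex
  for (k in seq_along(inner)) {
    rho <- prof[inner[k], "rho"]; z <- prof[inner[k], "z"]
    rows <- 2L + (k - 1L) * nt + seq_len(nt)
    v[rows, ] <- cbind(rho * cos(ang), rho * sin(ang), z)
  }
  ring_id <- function(k, t) 2L + (k - 1L) * nt + ((t - 1L) %% nt) + 1L
  f <- vector("list", nv_ring + 1L)
  # bottom fan: pole at z=0 center of disk; disk normal points down (-z),
  # so traversal must be clockwise seen from +z
  f[[1L]] <- cbind(1L, ring_id(1L, seq_len(nt)), ring_id(1L, seq_len(nt) + 1L))
  for (k in seq_len(nv_ring - 1L)) {
    t <- seq_len(nt)
    a <- ring_id(k, t); b <- ring_id(k, t + 1L)
    c_ <- ring_id(k + 1L, t); d <- ring_id(k + 1L, t + 1L)
    f[[k + 1L]] <- rbind(cbind(a, d, b), cbind(a, c_, d))
  }
  t <- seq_len(nt)
  f[[nv_ring + 1L]] <- cbind(2L, ring_id(nv_ring, t + 1L), ring_id(nv_ring, t))
  mesh <- triangle_mesh(v, do.call(rbind, f))
  if (enclosed_volume(mesh) < 0) mesh$facets <- mesh$facets[, c(1L, 3L, 2L)]
  vol <- enclosed_volume(mesh)
  if (vol <= 0) stop("generation error: degenerate primordium surface")
  mesh
}
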