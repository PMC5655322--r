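# mesh fixtures built in code, shared across test files

# regular tetrahedron (alternate cube corners), outward-oriented
regular_tetrahedron <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v / (2 * sqrt(2)) * edge          # native edge length is 2*sqrt(2)
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  m <- triangle_mesh(v, f)
  if (enclosed_volume(m) < 0) m$facets <- m$facets[, c(1L, 3L, 2L)]
  m
}

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * side
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0, normal -z
             c(5, 6, 8), c(5, 8, 7),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = 1
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = 1
  triangle_mesh(v, f)
}

# two triangles sharing the edge (1,2) along the x-axis, flap angle `fold`
# measured as the dihedral: fold = pi is flat
folded_quad <- function(fold = pi) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
             c(0.5, -cos(pi - fold), -sin(pi - fold)))
  triangle_mesh(v, rbind(c(1, 2, 3), c(2, 1, 4)))
}

random_rotation <- function() {
  a <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(a))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(mesh, rot = random_rotation(),
                        shift = stats::rnorm(3, 0, 5)) {
  mesh$vertices <- mesh$vertices %*% t(rot) +
    matrix(shift, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# independent Monte-Carlo volume oracle: fraction of random points of a
# bounding box that fall inside the closed mesh (ray parity along +z)
mc_volume <- function(mesh, n = 20000L) {
  v <- mesh$vertices; f <- mesh$facets
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  inside <- vapply(seq_len(n), function(i) {
    p <- pts[i, ]
    # 2D point-in-triangle in (x, y), count crossings above p
    d1 <- (b[, 1] - a[, 1]) * (p[2] - a[, 2]) -
      (b[, 2] - a[, 2]) * (p[1] - a[, 1])
    d2 <- (c_[, 1] - b[, 1]) * (p[2] - b[, 2]) -
      (c_[, 2] - b[, 2]) * (p[1] - b[, 1])
    d3 <- (a[, 1] - c_[, 1]) * (p[2] - c_[, 2]) -
      (a[, 2] - c_[, 2]) * (p[1] - c_[, 1])
    hit <- which((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0))
    if (!length(hit)) return(FALSE)
    cross <- 0L
    for (k in hit) {
      # barycentric z at (p1, p2)
      m <- rbind(c(b[k, 1] - a[k, 1], c_[k, 1] - a[k, 1]),
                 c(b[k, 2] - a[k, 2], c_[k, 2] - a[k, 2]))
      if (abs(det(m)) < 1e-14) next
      uv <- solve(m, p[1:2] - a[k, 1:2])
      z <- a[k, 3] + uv[1] * (b[k, 3] - a[k, 3]) + uv[2] * (c_[k, 3] - a[k, 3])
      if (z > p[3]) cross <- cross + 1L
    }
    cross %% 2L == 1L
  }, logical(1))
  box <- prod(hi - lo)
  est <- mean(inside) * box
  se <- stats::sd(inside) / sqrt(n) * box
  list(volume = est, se = se)
}

expect_same_mesh <- function(a, b, tol = 0) {
  expect_identical(a$facets, b$facets)
  if (tol == 0) {
    expect_identical(unname(a$vertices), unname(b$vertices))
  } else {
    expect_lt(max(abs(a$vertices - b$vertices)), tol)
  }
}
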