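test_that("edge topology partitions interior and boundary edges", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(1:3))
  t1 <- build_topology(tri)
  expect_equal(nrow(t1$interior), 0L)
  expect_equal(sum(t1$boundary), 3L)

  quad <- folded_quad(pi)
  t2 <- build_topology(quad)
  expect_equal(nrow(t2$interior), 1L)
  expect_equal(sum(t2$boundary), 4L)
  expect_true(all(t2$opposing))

  tet <- regular_tetrahedron()
  t3 <- build_topology(tet)
  expect_equal(nrow(t3$interior), 6L)
  expect_equal(sum(t3$boundary), 0L)
  expect_true(is_closed_mesh(tet, t3))

  # canonical deterministic edge ordering: sorted (min, max) pairs
  e <- t3$edges
  expect_true(all(e[, 1] < e[, 2]))
  expect_identical(order(e[, 1], e[, 2]), seq_len(nrow(e)))
})

test_that("non-manifold edges are rejected with the edge named", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  fan <- triangle_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(build_topology(fan), "non-manifold.*1-2")
})

test_that("facet areas match closed forms and degenerate facets give 0", {
  right <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                         rbind(1:3))
  expect_equal(facet_area(right, 1), 0.5)
  equi <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                        rbind(1:3))
  expect_equal(facet_area(equi, 1), sqrt(3), tolerance = 1e-12)
  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                         rbind(1:3))
  expect_equal(facet_area(degen, 1), 0)
})

test_that("dihedral angles follow the flat = pi convention", {
  flat <- folded_quad(pi)
  tf <- build_topology(flat)
  expect_equal(dihedral_angle(flat, tf, 1), pi, tolerance = 1e-12)

  ninety <- folded_quad(pi / 2)
  expect_equal(dihedral_angle(ninety, build_topology(ninety), 1), pi / 2,
               tolerance = 1e-12)

  reflex <- folded_quad(3 * pi / 2)
  expect_equal(dihedral_angle(reflex, build_topology(reflex), 1), 3 * pi / 2,
               tolerance = 1e-12)

  tet <- regular_tetrahedron()
  th <- dihedral_angles(tet, build_topology(tet))
  expect_equal(th, rep(acos(1 / 3), 6), tolerance = 1e-12)
})

test_that("convex closed surfaces are everywhere < pi, planar grids are pi", {
  ico <- icosphere(2)
  th <- dihedral_angles(ico, build_topology(ico))
  expect_true(all(th < pi))
  grid <- heightmap_to_mesh(furrow_pattern(matrix(80, 7, 9)))
  thg <- dihedral_angles(grid, build_topology(grid))
  expect_equal(max(abs(thg - pi)), 0, tolerance = 1e-12)
})

test_that("degenerate facets poison dihedral evaluation", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0), c(0.5, -1, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3), c(2, 1, 4)))
  expect_error(dihedral_angles(m, build_topology(m)), "degenerate")
})

test_that("enclosed volume matches closed forms, is translation and rotation invariant", {
  for (s in c(0.5, 1, 2)) {
    expect_equal(enclosed_volume(cube_mesh(s)), s^3, tolerance = 1e-12)
  }
  tet <- regular_tetrahedron(edge = 1)
  expect_equal(enclosed_volume(tet), 1 / (6 * sqrt(2)), tolerance = 1e-12)

  cube <- cube_mesh(1)
  cube$vertices <- cube$vertices +
    matrix(c(100, -50, 7), 8, 3, byrow = TRUE)
  expect_equal(enclosed_volume(cube), 1, tolerance = 1e-10)

  set.seed(11)
  ico <- icosphere(2)
  v0 <- enclosed_volume(ico)
  for (k in 1:5) {
    rot <- apply_rigid(ico)
    expect_equal(enclosed_volume(rot), v0, tolerance = 1e-10 * v0)
  }
})

test_that("volume is undefined for open surfaces", {
  grid <- heightmap_to_mesh(furrow_pattern(matrix(0, 3, 3)))
  expect_error(enclosed_volume(grid), "open surface")
})

test_that("Monte-Carlo point-in-mesh oracle agrees with divergence-theorem volume", {
  set.seed(7)
  for (m in list(icosphere(2), wrinkled_icosphere(3, 0.1, 3))) {
    mc <- mc_volume(m, n = 20000L)
    expect_lt(abs(mc$volume - enclosed_volume(m)), 3 * mc$se)
  }
})

test_that("meshes survive OFF/OBJ/PLY round trips", {
  cube <- cube_mesh(1)
  cube$vertices <- cube$vertices + pi * 1e-3   # non-trivial digits
  for (fmt in c("off", "obj", "ply")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    write_mesh(cube, path)
    back <- read_mesh(path)
    expect_identical(back$facets, cube$facets)
    expect_lt(max(abs(back$vertices - cube$vertices)),
              1e-12 * max(abs(cube$vertices)))
  }
})

test_that("OBJ 1-based indices and OFF 0-based indices map to the same mesh", {
  off <- c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2")
  obj <- c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3")
  poff <- file.path(tempdir(), "a.off"); writeLines(off, poff)
  pobj <- file.path(tempdir(), "a.obj"); writeLines(obj, pobj)
  expect_same_mesh(read_mesh(poff), read_mesh(pobj))
})

test_that("malformed mesh files raise parse errors with a line number", {
  p <- file.path(tempdir(), "trunc.off")
  writeLines(c("OFF", "8 12 0", "0 0 0"), p)
  expect_error(read_mesh(p), "line")
  p2 <- file.path(tempdir(), "bad.ply")
  writeLines(c("ply", "format binary_little_endian 1.0"), p2)
  expect_error(read_mesh(p2), "ascii")
  expect_error(read_mesh(file.path(tempdir(), "nope.off")), "no such file")
})

test_that("mesh validation reports closedness, orientation and Euler characteristic", {
  ok <- validate_mesh(icosphere(1))
  expect_true(ok$valid && ok$closed && ok$oriented)
  expect_equal(ok$euler_characteristic, 2L)

  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  vr <- validate_mesh(tri)
  expect_true(vr$valid)
  expect_false(vr$closed)
  expect_equal(vr$euler_characteristic, 1L)

  # flip one facet of a tetrahedron: inconsistent orientation
  tet <- regular_tetrahedron()
  tet$facets[1, ] <- tet$facets[1, c(1, 3, 2)]
  vb <- validate_mesh(tet)
  expect_false(vb$valid)
  expect_match(paste(vb$problems, collapse = " "), "orientation")
})
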