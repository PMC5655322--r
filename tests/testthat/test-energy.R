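test_that("energy is zero at the reference and positive away from it", {
  ico <- icosphere(1)
  topo <- build_topology(ico)
  ref <- capture_reference(ico, include_volume = TRUE, topology = topo)
  par <- elastic_parameters()
  e <- total_energy(ico, topo, ref, par)
  expect_equal(e$total, 0)
  expect_equal(e$total, e$volume + e$area + e$edge + e$angle)

  ico2 <- ico
  ico2$vertices <- ico2$vertices * 1.1
  e2 <- total_energy(ico2, topo, ref, par)
  expect_gt(e2$total, 0)
  expect_true(all(unlist(e2[c("volume", "area", "edge", "angle")]) >= 0))
})

test_that("hand-computed term values are reproduced", {
  # equilateral triangle side 1 scaled to side 2, only edges active:
  # three edges each contribute (1/2) * (2-1)^2 / 1
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                       rbind(1:3))
  tt <- build_topology(tri)
  rr <- capture_reference(tri)
  tri2 <- tri
  tri2$vertices <- tri2$vertices * 2
  expect_equal(total_energy(tri2, tt, rr,
                            elastic_parameters(0, 0, 1, 0))$total,
               1.5, tolerance = 1e-12)

  # flat quad folded to pi/2 with rest angle pi, shared rest edge length 1:
  # U = (1/2) * (pi/2)^2
  flat <- folded_quad(pi)
  qt <- build_topology(flat)
  qr <- capture_reference(flat, rest_angle = pi)
  folded <- folded_quad(pi / 2)
  expect_equal(total_energy(folded, qt, qr,
                            elastic_parameters(0, 0, 0, 1))$total,
               0.5 * (pi / 2)^2, tolerance = 1e-12)
})

test_that("each term scales linearly in its stiffness", {
  fx <- random_fixture(4)
  for (k in c("k_volume", "k_area", "k_edge", "k_angle")) {
    if (fx$params[[k]] == 0) next
    p2 <- unclass(fx$params)
    p2[[k]] <- p2[[k]] * 3
    p2 <- do.call(elastic_parameters, p2)
    term <- c(k_volume = "volume", k_area = "area", k_edge = "edge",
              k_angle = "angle")[[k]]
    e1 <- total_energy(fx$mesh, fx$topo, fx$ref, fx$params)
    e2 <- total_energy(fx$mesh, fx$topo, fx$ref, p2)
    expect_equal(e2[[term]], 3 * e1[[term]], tolerance = 1e-12)
  }
})

test_that("energy is invariant under rigid motion", {
  fx <- random_fixture(3)
  u0 <- total_energy(fx$mesh, fx$topo, fx$ref, fx$params)$total
  set.seed(99)
  for (k in 1:5) {
    m2 <- apply_rigid(fx$mesh)
    u <- total_energy(m2, fx$topo, fx$ref, fx$params)$total
    expect_equal(u, u0, tolerance = 1e-10)
  }
})

test_that("analytic gradient matches the finite-difference oracle on 50 fixtures", {
  worst <- 0
  for (seed in 1:50) {
    fx <- random_fixture(seed)
    g <- energy_gradient(fx$mesh, fx$topo, fx$ref, fx$params)
    fd <- finite_difference_gradient(fx$mesh, fx$topo, fx$ref, fx$params,
                                     step = 1e-6)
    rel <- max(abs(g - fd)) / max(abs(fd))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient is zero at the reference and sums to zero (translation invariance)", {
  ico <- icosphere(1)
  topo <- build_topology(ico)
  ref <- capture_reference(ico, include_volume = TRUE, topology = topo)
  g0 <- energy_gradient(ico, topo, ref, elastic_parameters())
  expect_equal(max(abs(g0)), 0, tolerance = 1e-12)

  fx <- random_fixture(8)
  g <- energy_gradient(fx$mesh, fx$topo, fx$ref, fx$params)
  expect_lt(max(abs(colSums(g))), 1e-10 * max(abs(g)))
})

test_that("finite differences converge at second order", {
  fx <- random_fixture(6)
  g <- energy_gradient(fx$mesh, fx$topo, fx$ref, fx$params)
  e1 <- max(abs(finite_difference_gradient(fx$mesh, fx$topo, fx$ref,
                                           fx$params, step = 1e-3) - g))
  e2 <- max(abs(finite_difference_gradient(fx$mesh, fx$topo, fx$ref,
                                           fx$params, step = 5e-4) - g))
  expect_lt(e2, e1 / 2.5)   # ~4x reduction expected; allow slack
})

test_that("degenerate facets and size mismatches are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0, 0), c(0.5, -1, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3), c(2, 1, 4)))
  topo <- build_topology(m)
  expect_error(capture_reference(m, topology = topo), "degenerate")

  flat <- folded_quad(pi)
  qt <- build_topology(flat)
  qr <- capture_reference(flat)
  m2 <- flat
  m2$vertices[3, ] <- c(0.5, 0, 0)   # collapse onto the shared edge
  expect_error(total_energy(m2, qt, qr, elastic_parameters(0, 1, 1, 1)),
               "degenerate")

  tet <- regular_tetrahedron()
  expect_error(total_energy(tet, build_topology(tet), qr,
                            elastic_parameters()),
               "does not match")
})

test_that("capture_reference honours the protocol variants", {
  grid <- heightmap_to_mesh(furrow_pattern(matrix(10, 4, 4)))
  topo <- build_topology(grid)
  ref <- capture_reference(grid, topology = topo)
  expect_equal(ref$Theta0, rep(pi, nrow(topo$interior)), tolerance = 1e-12)
  expect_true(is.na(ref$V0))
  expect_error(capture_reference(grid, include_volume = TRUE,
                                 topology = topo), "closed")

  ico <- icosphere(1)
  ri <- capture_reference(ico, include_volume = TRUE)
  expect_equal(ri$V0, enclosed_volume(ico))

  wr <- wrinkled_icosphere(2, 0.1, 3)
  rw <- capture_reference(wr, rest_angle = pi)
  expect_equal(rw$Theta0, rep(pi, length(rw$Theta0)))
})
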