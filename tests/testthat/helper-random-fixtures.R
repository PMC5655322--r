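# random non-degenerate fixtures for gradient checks: open wrinkled
# patches and closed perturbed spheres
random_fixture <- function(seed) {
  set.seed(seed)
  if (seed %% 2 == 0) {
    p <- furrow_pattern(matrix(runif(30, 0, 255), 5, 6), height_scale = 2)
    m <- heightmap_to_mesh(p)
    m$vertices <- m$vertices + matrix(rnorm(length(m$vertices), 0, 0.08),
                                      ncol = 3)
    closed <- FALSE
  } else {
    m <- icosphere(1)
    m$vertices <- m$vertices * runif(1, 0.9, 1.2) +
      matrix(rnorm(length(m$vertices), 0, 0.03), ncol = 3)
    closed <- TRUE
  }
  topo <- build_topology(m)
  ref <- capture_reference(m, include_volume = closed, topology = topo)
  # deform away from the reference so every term is active
  m2 <- m
  m2$vertices <- m2$vertices * (1 + rnorm(1, 0, 0.05)) +
    matrix(rnorm(length(m$vertices), 0, 0.05), ncol = 3)
  params <- elastic_parameters(k_volume = if (closed) runif(1, 1, 5) else 0,
                               k_area = runif(1, 1, 5),
                               k_edge = runif(1, 1, 5),
                               k_angle = runif(1, 0.5, 2))
  list(mesh = m2, topo = topo, ref = ref, params = params)
}

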