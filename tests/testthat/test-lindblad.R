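empty_h <- function(sites) {
  hamiltonian_spec(protein_graph(
    data.frame(from = character(), to = character()),
    vertices = sites
  ))
}

test_that("Liouvillian construction: zero generator, dephasing spectrum, trace preservation", {
  sp <- composite_space("A")
  lv0 <- build_liouvillian(empty_h("A"), list(), sp)
  expect_equal(max(Mod(lv0)), 0)

  gam <- 0.35
  lv <- build_liouvillian(
    empty_h("A"), list(lindblad_channel("dephasing", "A", gam)), sp
  )
  expect_equal(
    sort(Re(eigen(lv, only.values = TRUE)$values)),
    c(-2 * gam, -2 * gam, 0, 0),
    tolerance = 1e-10
  )

  set.seed(30)
  for (rep in 1:5) {
    g <- random_graph(2, p = 1)
    sp2 <- composite_space(g$vertices)
    h <- hamiltonian_spec(
      extended_laplacian_spec(g, omegas = stats::setNames(rnorm(2), g$vertices)),
      coupling = stats::runif(1, 0.2, 2)
    )
    chans <- list(
      lindblad_channel("dephasing", g$vertices[1], stats::runif(1)),
      lindblad_channel("binding", g$vertices[2], stats::runif(1)),
      lindblad_channel("thermal", g$vertices[1], stats::runif(1))
    )
    lv <- build_liouvillian(h, chans, sp2)
    # vec(I) is a left null vector: the dual generator annihilates the identity
    vec_id <- as.vector(diag(4) + 0i)
    expect_lt(max(Mod(Conj(vec_id) %*% lv)), 1e-10)
  }
})

test_that("non-Hermitian potentials are rejected", {
  g <- protein_graph(data.frame(from = "A", to = "B"))
  v <- matrix(c(0, 1i, 1i, 0), 2, 2)
  expect_error(hamiltonian_spec(g, potential = kronecker(v, diag(2))), "Hermitian")
})

test_that("free evolution is the identity and closed-form decoherence is exact", {
  sp <- composite_space("A")
  rho0 <- pure_density(plus_state(sp))
  ev <- evolve(rho0, empty_h("A"), list(), times = c(0, 1, 5))
  for (s in ev$states) expect_equal(s$matrix, rho0$matrix, tolerance = 1e-12)

  ts <- c(0.2, 0.7, 1.9, 4)
  for (gam in c(0.05, 0.6)) {
    evd <- evolve(rho0, empty_h("A"),
      list(lindblad_channel("dephasing", "A", gam)),
      times = ts
    )
    coh <- vapply(evd$states, function(s) Mod(s$matrix[1, 2]), numeric(1))
    expect_equal(coh, 0.5 * exp(-2 * gam * ts), tolerance = 1e-8)

    rho1 <- density_matrix(diag(c(0, 1)) + 0i, sp)
    evb <- evolve(rho1, empty_h("A"),
      list(lindblad_channel("binding", "A", gam)),
      times = ts
    )
    pop <- vapply(evb$states, function(s) Re(s$matrix[2, 2]), numeric(1))
    expect_equal(pop, exp(-gam * ts), tolerance = 1e-8)
  }
})

test_that("evolution is CPTP on random specs", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:3, 1)
    g <- random_graph(n, p = 0.7)
    sp <- composite_space(g$vertices)
    h <- hamiltonian_spec(
      extended_laplacian_spec(g, omegas = stats::setNames(rnorm(n, sd = 0.5), g$vertices)),
      coupling = stats::runif(1, 0.1, 1.5)
    )
    chans <- lapply(g$vertices, function(v) {
      lindblad_channel(sample(c("dephasing", "binding", "thermal"), 1), v, stats::runif(1, 0, 0.5))
    })
    ev <- evolve(random_density(sp), h, chans, times = c(0.5, 2, 10))
    expect_lte(ev$trace_drift, 1e-10)
    expect_gte(ev$min_eigenvalue, -1e-9)
  }
})

test_that("RK4 and exact propagation agree to 1e-7 in Frobenius norm", {
  set.seed(32)
  for (rep in 1:6) {
    n <- 2
    g <- random_graph(n, p = 1)
    sp <- composite_space(g$vertices)
    h <- hamiltonian_spec(
      extended_laplacian_spec(g, omegas = stats::setNames(rnorm(n), g$vertices)),
      coupling = stats::runif(1, 0.2, 1.5)
    )
    chans <- list(
      lindblad_channel("dephasing", g$vertices[1], stats::runif(1, 0, 0.8)),
      lindblad_channel("binding", g$vertices[2], stats::runif(1, 0, 0.8))
    )
    rho0 <- random_density(sp)
    times <- c(0.4, 1)
    ex <- evolve(rho0, h, chans, times, method = "exact")
    rk <- evolve(rho0, h, chans, times, method = "rk4")
    expect_lt(
      max(mapply(function(a, b) frob(a$matrix, b$matrix), ex$states, rk$states)),
      1e-7
    )
  }
})

test_that("purity never increases under pure dephasing with H = 0", {
  set.seed(33)
  sp <- qubit_space(2)
  chans <- list(
    lindblad_channel("dephasing", "q1", 0.4),
    lindblad_channel("dephasing", "q2", 0.2)
  )
  ev <- evolve(
    random_density(sp), empty_h(c("q1", "q2")), chans,
    seq(0.2, 3, by = 0.2)
  )
  pur <- vapply(ev$states, purity, numeric(1))
  expect_true(all(diff(pur) <= 1e-10))
})

test_that("closed evolution preserves the spectrum", {
  set.seed(34)
  g <- random_graph(2, p = 1)
  sp <- composite_space(g$vertices)
  h <- hamiltonian_spec(
    extended_laplacian_spec(g, omegas = c(0.3, -0.2)),
    coupling = 0.9
  )
  rho0 <- random_density(sp)
  ev <- evolve(rho0, h, list(), times = c(1, 2.5), method = "rk4")
  ref <- sort(eigen(rho0$matrix, symmetric = TRUE, only.values = TRUE)$values)
  for (s in ev$states) {
    drift <- max(abs(
      sort(eigen(s$matrix, symmetric = TRUE, only.values = TRUE)$values) - ref
    ))
    expect_lt(drift, 1e-9)
  }
})

test_that("steady states: damping fixed point, degenerate kernels, thermal mixing", {
  sp <- composite_space("A")
  ss <- steady_state(
    empty_h("A"), list(lindblad_channel("binding", "A", 0.4)), sp
  )
  expect_equal(ss$matrix, diag(c(1, 0)) + 0i, tolerance = 1e-9)

  expect_error(
    steady_state(empty_h("A"), list(lindblad_channel("dephasing", "A", 0.4)), sp),
    "kernel dimension is 2"
  )

  g1 <- protein_graph(data.frame(from = character(), to = character()), vertices = "A")
  h_w <- hamiltonian_spec(extended_laplacian_spec(g1, omegas = c(A = 1)))
  ss2 <- steady_state(h_w, list(lindblad_channel("thermal", "A", 0.4)), sp)
  expect_equal(ss2$matrix, diag(2) / 2 + 0i, tolerance = 1e-9)
})

test_that("physicality breaches raise diagnostics instead of silent clipping", {
  sp <- composite_space("A")
  bad0 <- structure(
    list(matrix = diag(c(0.7, 0.31)) + 0i, space = sp),
    class = "density_matrix"
  ) # trace 1.01, injected around the validator on purpose
  expect_error(
    evolve(bad0, empty_h("A"), list(), times = c(0, 1)),
    "trace drift"
  )
})
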