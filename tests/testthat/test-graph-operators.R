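test_that("vertex-space quantum-enhanced Laplacian shifts the classical spectrum", {
  g <- protein_graph(data.frame(from = "A", to = "B"))
  expect_equal(
    quantum_enhanced_laplacian(g, omegas = 1, hbar = 0),
    classical_laplacian(g)
  )
  expect_equal(
    unname(quantum_enhanced_laplacian(g, omegas = 1, hbar = 1)),
    matrix(c(2, -1, -1, 2), 2, 2)
  )
  set.seed(20)
  g2 <- random_graph(6)
  w <- 0.37
  expect_equal(
    sort(eigen(quantum_enhanced_laplacian(g2, omegas = w))$values),
    sort(eigen(classical_laplacian(g2))$values) + w,
    tolerance = 1e-10
  )
})

test_that("swap operator permutes basis states and is involutive on qutrits too", {
  sp <- qubit_space(2)
  p <- swap_operator(sp, "q1", "q2")
  s01 <- basis_state(c(0, 1), sp)$amplitudes
  s10 <- basis_state(c(1, 0), sp)$amplitudes
  expect_equal(as.vector(p %*% s01), s10)
  set.seed(21)
  psi <- random_pure(composite_space("x"))$amplitudes
  prod_state <- as.vector(kronecker(psi, psi))
  expect_equal(as.vector(p %*% prod_state), prod_state, tolerance = 1e-12)

  spq <- composite_space(c("a", "b"), dims = 3)
  pq <- swap_operator(spq, "a", "b")
  expect_equal(pq %*% pq, diag(9) + 0i)
  expect_equal(pq, Conj(t(pq))) # Hermitian
  expect_error(
    swap_operator(composite_space(c("a", "b"), dims = c(2, 3)), "a", "b"),
    "equal local dimensions"
  )
})

test_that("extended Laplacian annihilates symmetric product states and acts as I - P on |01>", {
  sp <- qubit_space(2)
  g <- protein_graph(data.frame(from = "q1", to = "q2"))
  h <- extended_quantum_laplacian(g, sp)
  set.seed(22)
  psi <- random_pure(composite_space("x"))$amplitudes
  expect_lt(max(Mod(h %*% kronecker(psi, psi))), 1e-10)

  s01 <- basis_state(c(0, 1), sp)$amplitudes
  s10 <- basis_state(c(1, 0), sp)$amplitudes
  expect_equal(as.vector(h %*% s01), s01 - s10, tolerance = 1e-12)
})

test_that("on-site frequency term gives |00> eigenvalue 2*omega with no edges", {
  sp <- qubit_space(2)
  g <- protein_graph(data.frame(from = character(), to = character()),
    vertices = c("q1", "q2")
  )
  w <- 0.8
  h <- extended_quantum_laplacian(
    extended_laplacian_spec(g, omegas = c(q1 = w, q2 = w)), sp
  )
  s00 <- basis_state(c(0, 0), sp)$amplitudes
  expect_equal(as.vector(h %*% s00), 2 * w * s00, tolerance = 1e-12)
  # nonzero omega on a qutrit site is flagged
  spq <- composite_space(c("q1", "q2"), dims = c(3, 2))
  expect_error(
    extended_quantum_laplacian(
      extended_laplacian_spec(g, omegas = c(q1 = 1)), spq
    ),
    "two-level"
  )
})

test_that("extended Laplacian equals the nested-loop basis oracle and is PSD", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(2:3, 1)
    g <- random_graph(n, p = 0.8)
    sp <- composite_space(g$vertices)
    omg <- stats::setNames(stats::rnorm(n), g$vertices)
    got <- extended_quantum_laplacian(extended_laplacian_spec(g, omegas = omg), sp)
    want <- ext_laplacian_oracle(g, sp, omegas = as.list(omg))
    expect_equal(got, want, tolerance = 1e-12)

    topo <- extended_quantum_laplacian(g, sp)
    ev <- eigen(topo, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10) # PSD, ground energy 0
    expect_lt(min(abs(ev)), 1e-10)
  }
})

test_that("symmetric product states span part of the topological kernel (n = 4)", {
  set.seed(24)
  g <- random_graph(4, p = 0.9)
  sp <- composite_space(g$vertices)
  h <- extended_quantum_laplacian(g, sp)
  for (rep in 1:5) {
    psi <- random_pure(composite_space("x"))$amplitudes
    state <- Reduce(kronecker, rep(list(psi), 4))
    expect_lt(max(Mod(h %*% state)), 1e-10)
  }
})

test_that("quantum gradient is the weighted commutator, antisymmetric and linear", {
  g <- protein_graph(data.frame(from = "A", to = "B", weight = 1))
  f <- list(A = pauli("x"), B = pauli("z"))
  grad <- quantum_gradient(f, g)
  expect_equal(grad[["A -> B"]], 2i * pauli("y"), tolerance = 1e-12) # [Z, X] = 2iY
  expect_equal(grad[["B -> A"]], -grad[["A -> B"]])

  # same operator on both ends commutes with itself
  grad0 <- quantum_gradient(list(A = pauli("x"), B = pauli("x")), g)
  expect_equal(max(Mod(grad0[["A -> B"]])), 0)

  g4 <- protein_graph(data.frame(from = "A", to = "B", weight = 4))
  grad4 <- quantum_gradient(f, g4)
  expect_equal(grad4[["A -> B"]], 2 * grad[["A -> B"]]) # sqrt(W) scaling

  set.seed(25)
  rmat <- function() matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  f1 <- list(A = rmat(), B = rmat())
  f2 <- list(A = rmat(), B = rmat())
  lin <- quantum_gradient(list(A = f1$A + 2 * f2$A, B = f1$B + 2 * f2$B), g)
  # linear terms plus the expected cross terms: check bilinearity structure
  direct <- quantum_gradient(f1, g)[["A -> B"]] +
    2 * quantum_gradient(list(A = f2$A, B = f1$B), g)[["A -> B"]] +
    2 * quantum_gradient(list(A = f1$A, B = f2$B), g)[["A -> B"]] +
    4 * quantum_gradient(f2, g)[["A -> B"]]
  expect_equal(lin[["A -> B"]], direct, tolerance = 1e-10)

  expect_error(quantum_gradient(list(A = pauli("x")), g), "missing")
})

test_that("quantum divergence anticommutes with the local state and handles edge cases", {
  g <- protein_graph(data.frame(from = c("A", "A"), to = c("B", "C"), weight = c(1, 4)),
    vertices = c("A", "B", "C", "D")
  )
  rho <- list(
    A = diag(2) / 2 + 0i, B = diag(2) / 2 + 0i,
    C = diag(2) / 2 + 0i, D = diag(2) / 2 + 0i
  )
  Fz <- list()
  Fz[["A -> B"]] <- pauli("z")
  Fz[["B -> A"]] <- -pauli("z")
  Fz[["A -> C"]] <- pauli("x")
  Fz[["C -> A"]] <- -pauli("x")
  div <- quantum_divergence(Fz, g, rho)
  # rho = I/d: divergence reduces to (2/d) * sum sqrt(W) F
  expect_equal(div[["A"]], pauli("z") + 2 * pauli("x"), tolerance = 1e-12)
  expect_equal(div[["D"]], matrix(0 + 0i, 2, 2)) # isolated vertex
  expect_equal(div[["A"]], Conj(t(div[["A"]]))) # Hermitian output
  # zero field gives zero divergence
  F0 <- lapply(Fz, function(m) m * 0)
  expect_equal(max(Mod(quantum_divergence(F0, g, rho)[["A"]])), 0)
  expect_error(quantum_divergence(Fz[1], g, rho), "missing")
})
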