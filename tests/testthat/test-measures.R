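bell_density <- function() {
  pure_density(pure_state(c(1, 0, 0, 1) / sqrt(2), qubit_space(2)))
}

test_that("von Neumann entropy: pure states, maximal mixing, scalar oracle", {
  sp <- composite_space("A")
  set.seed(40)
  expect_equal(von_neumann_entropy(pure_density(random_pure(qubit_space(2)))), 0,
    tolerance = 1e-9
  )
  expect_equal(von_neumann_entropy(density_matrix(diag(2) / 2 + 0i, sp)), 1)
  rho <- density_matrix(diag(c(0.25, 0.75)) + 0i, sp)
  expect_equal(von_neumann_entropy(rho), shannon_oracle(c(0.25, 0.75)),
    tolerance = 1e-12
  )
  # natural-log option
  expect_equal(
    von_neumann_entropy(rho, entropy_options(log_base = exp(1))),
    shannon_oracle(c(0.25, 0.75), base = exp(1)),
    tolerance = 1e-12
  )
  expect_error(von_neumann_entropy(diag(c(0.6, 0.6)) + 0i), "invalid")
})

test_that("interaction entropy follows the printed sign convention", {
  sp <- qubit_space(2)
  set.seed(41)
  prod_pure <- pure_density(pure_state(
    kronecker(
      random_pure(composite_space("q1"))$amplitudes,
      random_pure(composite_space("q2"))$amplitudes
    ), sp
  ))
  expect_equal(interaction_entropy(prod_pure), 0, tolerance = 1e-9)

  expect_equal(interaction_entropy(bell_density()), -2, tolerance = 1e-9)
  expect_equal(interaction_entropy(bell_density(), conventional = TRUE), 2,
    tolerance = 1e-9
  )

  # additivity: mixed product states carry no correlations
  ra <- random_density(composite_space("q1"))
  rb <- random_density(composite_space("q2"))
  mixed_prod <- density_matrix(kronecker(ra$matrix, rb$matrix), sp)
  expect_equal(interaction_entropy(mixed_prod), 0, tolerance = 1e-9)

  expect_error(interaction_entropy(random_density(qubit_space(3))), "two-site")
})

test_that("l1 coherence: diagonal states, |+>, loop oracle, basis dependence", {
  sp <- composite_space("A")
  expect_equal(l1_coherence(density_matrix(diag(c(0.3, 0.7)) + 0i, sp)), 0)
  expect_equal(l1_coherence(pure_density(plus_state(sp))), 1, tolerance = 1e-12)
  set.seed(42)
  rho <- random_density(qubit_space(2))
  loop <- 0
  for (i in 1:4) {
    for (j in 1:4) if (i != j) loop <- loop + Mod(rho$matrix[i, j])
  }
  expect_equal(l1_coherence(rho), loop, tolerance = 1e-12)
  # Hadamard rotation changes the coherence of |+><+| (to 0)
  had <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  rotated <- had %*% pure_density(plus_state(sp))$matrix %*% t(had)
  expect_equal(l1_coherence(rotated), 0, tolerance = 1e-12)
})

test_that("entanglement entropy: products, Bell, pure-state symmetry, local unitaries", {
  sp <- qubit_space(2)
  set.seed(43)
  ra <- random_density(composite_space("q1"))
  rb <- random_density(composite_space("q2"))
  prod <- density_matrix(kronecker(ra$matrix, rb$matrix), sp)
  expect_equal(entanglement_entropy(prod, list("q1", "q2")), 0, tolerance = 1e-9)

  expect_equal(entanglement_entropy(bell_density(), list("q1", "q2")), 2,
    tolerance = 1e-9
  )

  for (rep in 1:5) {
    psi <- pure_density(random_pure(sp))
    s_ab <- entanglement_entropy(psi, list("q1", "q2"))
    s_a <- von_neumann_entropy(partial_trace(psi, "q1"))
    expect_equal(s_ab, 2 * s_a, tolerance = 1e-9)

    # invariance under U_A (x) U_B
    ua <- qr.Q(qr(matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)))
    ub <- qr.Q(qr(matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)))
    u <- kronecker(ua, ub)
    rot <- density_matrix(u %*% psi$matrix %*% Conj(t(u)), sp, validate = FALSE)
    expect_equal(entanglement_entropy(rot, list("q1", "q2")), s_ab,
      tolerance = 1e-9
    )
  }
  expect_error(entanglement_entropy(bell_density(), list("q1", "q1")), "disjoint")
})

test_that("interaction entropy is minus the mutual information on pairs", {
  set.seed(44)
  for (rep in 1:5) {
    rho <- random_density(qubit_space(2))
    expect_equal(
      interaction_entropy(rho),
      -entanglement_entropy(rho, list("q1", "q2")),
      tolerance = 1e-10
    )
  }
})

test_that("subadditivity holds on random bipartite states", {
  set.seed(45)
  for (rep in 1:40) {
    nsites <- sample(2:4, 1) # dims up to 16
    sp <- qubit_space(nsites)
    rho <- random_density(sp)
    cut <- sample(seq_len(nsites - 1), 1)
    a <- sp$site_order[1:cut]
    b <- sp$site_order[(cut + 1):nsites]
    s_ab <- von_neumann_entropy(rho)
    s_a <- von_neumann_entropy(partial_trace(rho, a))
    s_b <- von_neumann_entropy(partial_trace(rho, b))
    expect_lte(s_ab, s_a + s_b + 1e-9)
  }
})

test_that("cooperativity factor is 1 + alpha * S with validation", {
  expect_equal(cooperativity_factor(0, 2), 1) # independent binding
  expect_equal(cooperativity_factor(5, 0), 1)
  s_bell <- entanglement_entropy(bell_density(), list("q1", "q2"))
  expect_equal(cooperativity_factor(s_bell, 0.5), 2, tolerance = 1e-9)
  expect_error(cooperativity_factor(-1, 1), "nonnegative")
})

test_that("modular entanglement bounds: arithmetic and degenerate cases", {
  part <- module_partition(list(m1 = c("a", "b"), m2 = c("c", "d", "e")))
  eb <- entanglement_bound(part)
  expect_equal(eb$pairwise$bound, 2) # min(2, 3) * log2(2)
  single <- entanglement_bound(module_partition(list(m = c("a", "b"))))
  expect_equal(nrow(single$pairwise), 0)
  tiny <- entanglement_bound(module_partition(list(m1 = "a", m2 = "b")))
  expect_equal(tiny$pairwise$bound, 1)
  # total sums supplied intra terms and all inter bounds
  expect_equal(entanglement_bound(part, e_intra = c(0.5, 1.5))$total, 4)
})

test_that("marginal-entropy reading of the bound holds on random pure 2|2 states", {
  set.seed(46)
  sp <- qubit_space(4)
  part <- module_partition(list(m1 = c("q1", "q2"), m2 = c("q3", "q4")))
  worst <- Inf
  for (rep in 1:200) {
    res <- check_bound(pure_density(random_pure(sp)), part)
    expect_true(res$holds)
    worst <- min(worst, res$worst_margin)
  }
  expect_gte(worst, 0)

  # product state: margin equals the full bound
  prod <- pure_density(basis_state(c(0, 1, 0, 1), sp))
  expect_equal(check_bound(prod, part)$worst_margin, 2, tolerance = 1e-9)

  # two Bell pairs across the cut: mutual information reaches twice the
  # bound while the marginal entropy saturates it exactly
  bell <- c(1, 0, 0, 1) / sqrt(2)
  amps <- kronecker(bell, bell)
  # amps orders (q1 q2)(q3 q4); rearrange so pairs are (q1 q3) and (q2 q4)
  perm <- sapply(0:15, function(i) {
    b <- as.integer(intToBits(i))[4:1]
    sum(c(b[1], b[3], b[2], b[4]) * c(8, 4, 2, 1))
  })
  max_ent <- rep(0 + 0i, 16)
  max_ent[perm + 1] <- amps
  rho_me <- pure_density(pure_state(max_ent, sp))
  res <- check_bound(rho_me, part)
  expect_equal(res$detail$s_mutual, 4, tolerance = 1e-9)
  expect_equal(res$detail$s_marginal, 2, tolerance = 1e-9)
  expect_true(res$holds)
})
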