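featureless_pair_graph <- function() {
  protein_graph(data.frame(from = "A", to = "B"))
}

const_trajectory <- function(rho, spec) {
  times <- seq(0, spec$horizon, by = spec$grid_step)
  structure(
    list(
      times = times, states = rep(list(rho), length(times)),
      trace_drift = 0, min_eigenvalue = 0, method = "exact",
      space = rho$space
    ),
    class = "qpin_evolution"
  )
}

test_that("interaction operator is the similarity-weighted binding projector", {
  proj <- diag(c(0, 0, 0, 1)) + 0i
  g0 <- featureless_pair_graph()
  expect_equal(interaction_operator(g0, "A", "B"), proj) # no features -> s = 1

  feats <- rbind(A = c(1, 0), B = c(1, 0))
  g1 <- protein_graph(data.frame(from = "A", to = "B"), features = feats)
  expect_equal(interaction_operator(g1, "A", "B"), proj, tolerance = 1e-12)

  feats2 <- rbind(A = c(1, 0), B = c(-1, 0)) # cosine -1 -> s = 0
  g2 <- protein_graph(data.frame(from = "A", to = "B"), features = feats2)
  expect_equal(max(Mod(interaction_operator(g2, "A", "B"))), 0)

  feats3 <- rbind(A = c(1, 0), B = c(0, 1)) # orthogonal -> s = 1/2
  g3 <- protein_graph(data.frame(from = "A", to = "B"), features = feats3)
  expect_equal(interaction_operator(g3, "A", "B"), proj / 2, tolerance = 1e-12)
})

test_that("constant integrand makes the normalized memory operator exact and lambda-free", {
  sp <- qubit_space(2)
  rho <- pure_density(plus_state(sp))
  g <- featureless_pair_graph()
  o_int <- interaction_operator(g, "q1", "q2", sp)
  for (lam in c(0.3, 1, 7)) {
    spec <- measurement_spec(lambda_decay = lam, horizon = 2, grid_step = 0.05)
    m <- measurement_operator(spec, const_trajectory(rho, spec), o_int)
    expect_equal(m, o_int, tolerance = 1e-9)
  }
  # zero interaction operator gives the zero measurement
  spec <- measurement_spec(horizon = 1, grid_step = 0.1)
  m0 <- measurement_operator(spec, const_trajectory(rho, spec), o_int * 0)
  expect_equal(max(Mod(m0)), 0)
})

test_that("large lambda concentrates the kernel at the endpoint", {
  sp <- composite_space("A")
  rho <- pure_density(plus_state(sp))
  # integrand diag(t, 1 - t): endpoint value diag(1, 0) at t = 1
  o_fun <- function(t, rho_m) diag(c(t, 1 - t)) + 0i
  spec <- measurement_spec(lambda_decay = 200, horizon = 1, grid_step = 0.002)
  m <- measurement_operator(spec, const_trajectory(rho, spec), o_fun)
  expect_equal(Re(diag(m)), c(1, 0), tolerance = 2 / 200)
  # small lambda approaches the plain time average diag(1/2, 1/2)
  spec2 <- measurement_spec(lambda_decay = 1e-3, horizon = 1, grid_step = 0.002)
  m2 <- measurement_operator(spec2, const_trajectory(rho, spec2), o_fun)
  expect_equal(Re(diag(m2)), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("trapezoid integration matches a 100x finer reference within 1e-6", {
  sp <- composite_space("A")
  rho <- pure_density(plus_state(sp))
  o_fun <- function(t, rho_m) diag(c(sin(t)^2, cos(t)^2)) + 0i
  coarse <- measurement_spec(lambda_decay = 1.3, horizon = 2, grid_step = 0.002)
  fine <- measurement_spec(lambda_decay = 1.3, horizon = 2, grid_step = 0.00002)
  m_c <- measurement_operator(coarse, const_trajectory(rho, coarse), o_fun)
  m_f <- measurement_operator(fine, const_trajectory(rho, fine), o_fun)
  expect_lt(max(Mod(m_c - m_f)), 1e-6)
})

test_that("interaction probabilities follow projector expectations", {
  sp <- qubit_space(2)
  g <- featureless_pair_graph()
  m <- interaction_operator(g, "q1", "q2", sp)
  rho11 <- pure_density(basis_state(c(1, 1), sp))
  expect_equal(interaction_probability(rho11, m), 1)
  rho00 <- pure_density(basis_state(c(0, 0), sp))
  expect_equal(interaction_probability(rho00, m), 0)
  mixed <- density_matrix(diag(4) / 4 + 0i, sp)
  expect_equal(interaction_probability(mixed, m), 0.25)
  expect_error(
    interaction_probability(pure_density(plus_state(composite_space("A"))), m),
    "dimension"
  )
})

test_that("probabilities stay in [0, 1] and increase with similarity", {
  set.seed(50)
  sp <- qubit_space(2)
  g <- featureless_pair_graph()
  proj <- interaction_operator(g, "q1", "q2", sp)
  spec <- measurement_spec(horizon = 1, grid_step = 0.05)
  for (rep in 1:20) {
    rho <- random_density(sp)
    m <- measurement_operator(spec, const_trajectory(rho, spec), proj)
    p <- interaction_probability(rho, m)
    expect_gte(p, 0)
    expect_lte(p, 1)
    # scaling similarity up scales the score up
    s_vals <- c(0.2, 0.5, 1)
    ps <- vapply(s_vals, function(s) interaction_probability(rho, s * m), numeric(1))
    expect_true(all(diff(ps) >= -1e-12))
  }
})

test_that("pair scoring is symmetric, threshold-aware and strategy-correct", {
  net <- generate_synthetic_network(
    synthetic_spec(n_vertices = 12, n_modules = 3, seed = 8)
  )
  cfg <- scoring_config(horizon = 1, grid_step = 0.1)
  pr <- net$positives[1, ]
  fwd <- score_all_pairs(net$graph, pr, cfg)
  rev <- score_all_pairs(net$graph, pr[, c("b", "a")], cfg)
  expect_identical(fwd$p_interaction, rev$p_interaction)

  # modules of 4 fit the default cap -> module-level strategy for positives
  expect_identical(fwd$strategy, "module")
  neg <- score_all_pairs(net$graph, net$negatives[1, ], cfg)
  expect_identical(neg$strategy, "pair")

  all_cand <- rbind(net$positives, net$negatives)
  hi <- score_all_pairs(net$graph, all_cand, scoring_config(
    horizon = 1,
    grid_step = 0.1, threshold = 1.0
  ))
  expect_true(all(hi$predicted == 0L))
  expect_error(
    score_all_pairs(net$graph, data.frame(a = "nope", b = "P001"), cfg),
    "not in graph"
  )
})

test_that("planted positives outrank inter-module negatives end to end", {
  net <- generate_synthetic_network(
    synthetic_spec(n_vertices = 24, n_modules = 3, seed = 101)
  )
  cfg <- scoring_config()
  scores <- score_all_pairs(net$graph, rbind(net$positives, net$negatives), cfg)
  labels <- c(rep(1, nrow(net$positives)), rep(0, nrow(net$negatives)))
  expect_gt(
    mean(scores$p_interaction[labels == 1]),
    mean(scores$p_interaction[labels == 0])
  )
})
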