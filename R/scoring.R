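#' Measurement specification for interaction scoring
#'
#' Parameters of the time-integrated measurement operator: exponential
#' binding-memory kernel `exp(-lambda (t - t'))` over the horizon `[0, t]`,
#' integrated by the trapezoid rule on a grid of step `dt`. With
#' `normalize = TRUE` the kernel mass `N = (1 - exp(-lambda t)) / lambda`
#' divides the integral, making the score a proper probability; the raw
#' (unnormalized) integral as defined can exceed 1 and is available with
#' `normalize = FALSE`.
#'
#' @param lambda_decay positive binding memory decay rate (1/time).
#' @param horizon positive measurement time `t`.
#' @param grid_step trapezoid grid step `dt <= horizon`.
#' @param normalize divide by the kernel mass (default `TRUE`).
#' @return Object of class `measurement_spec`.
#' @export
measurement_spec <- function(lambda_decay = 1, horizon = 2, grid_step = 0.05,
                             normalize = TRUE) {
  stopifnot(lambda_decay > 0, horizon > 0, grid_step > 0, grid_step <= horizon)
  structure(
    list(
      lambda_decay = lambda_decay, horizon = horizon,
      grid_step = grid_step, normalize = normalize
    ),
    class = "measurement_spec"
  )
}

#' @noRd
measurement_times <- function(spec) {
  n <- round(spec$horizon / spec$grid_step)
  if (abs(n * spec$grid_step - spec$horizon) > 1e-9) {
    stop("grid_step must divide horizon", call. = FALSE)
  }
  seq(0, spec$horizon, length.out = n + 1)
}

#' Feature similarity between two proteins
#'
#' Cosine similarity of the feature vectors mapped to `[0, 1]` via
#' `(1 + cos) / 2`; defaults to 1 for all pairs when the graph carries no
#' features (the quantum machinery then runs on topology alone).
#'
#' @param g a [protein_graph()].
#' @param i,j vertex identifiers.
#' @return Similarity in `[0, 1]`.
#' @export
feature_similarity <- function(g, i, j) {
  if (is.null(g$features)) {
    return(1)
  }
  xi <- g$features[i, ]
  xj <- g$features[j, ]
  ni <- sqrt(sum(xi^2))
  nj <- sqrt(sum(xj^2))
  if (ni == 0 || nj == 0) {
    return(0.5)
  } # undefined direction: maximally uninformative
  (1 + sum(xi * xj) / (ni * nj)) / 2
}

#' Pairwise interaction operator
#'
#' The instantaneous interaction observable for a protein pair: the joint
#' binding-competent projector `|11><11|` on the two-level pair, scaled by
#' the feature similarity `s_ij in [0, 1]`. Identical features give the bare
#' projector; anti-aligned features give the zero operator; absent features
#' give similarity 1. The spectrum lies in `[0, 1]`. This construction makes
#' the conformational-population-weighted score emerge exactly for product
#' states; alternative rules can be supplied to [measurement_operator()]
#' directly.
#'
#' @param g a [protein_graph()] (source of the features).
#' @param i,j vertex identifiers (two-level sites).
#' @param space the pair [composite_space()]; defaults to qubits on `(i, j)`.
#' @return Hermitian complex matrix on the pair space.
#' @export
interaction_operator <- function(g, i, j, space = NULL) {
  if (is.null(space)) space <- composite_space(c(i, j))
  pos <- site_positions(space, c(i, j))
  if (any(space$local_dims[pos] != 2)) {
    stop("interaction operator requires two-level sites", call. = FALSE)
  }
  s_ij <- feature_similarity(g, i, j)
  p1 <- matrix(c(0, 0, 0, 1), 2, 2) + 0i # |1><1|
  s_ij * embed_local(kronecker(p1, p1), c(i, j), space)
}

#' Memory-kernel measurement operator
#'
#' Builds
#' `M_ij(t) = N^(-1) * integral_0^t exp(-lambda (t - t')) Pi(t') O_int Pi(t') dt'`
#' on the trajectory's space by the trapezoid rule, where `Pi(t')` projects
#' onto the conformational basis -- realized as retention of the diagonal
#' part in the fixed computational basis -- and `N` is the kernel mass
#' `(1 - exp(-lambda t)) / lambda`, evaluated under the same quadrature rule
#' as the numerator when `spec$normalize` is set. For an integrand constant
#' in time the normalized operator equals that integrand exactly,
#' independent of `lambda`.
#'
#' @param spec a [measurement_spec()].
#' @param trajectory a [evolve()] result whose `times` equal the grid
#'   `seq(0, horizon, by = grid_step)` of `spec`.
#' @param o_int either a Hermitian matrix on the trajectory's space (the
#'   instantaneous interaction observable) or a function
#'   `function(t, rho_matrix)` returning one, evaluated along the
#'   trajectory.
#' @return Hermitian complex matrix; spectrum within `[0, 1]` under
#'   normalization whenever the integrand's is.
#' @export
measurement_operator <- function(spec, trajectory, o_int) {
  stopifnot(inherits(spec, "measurement_spec"), inherits(trajectory, "qpin_evolution"))
  grid <- measurement_times(spec)
  if (length(grid) != length(trajectory$times) ||
    max(abs(grid - trajectory$times)) > 1e-9) {
    stop("trajectory times do not match the measurement grid", call. = FALSE)
  }
  d <- trajectory$space$total_dim
  conf_project <- function(m) {
    out <- matrix(0 + 0i, d, d)
    diag(out) <- diag(m)
    out
  }
  t_end <- spec$horizon
  lam <- spec$lambda_decay
  w <- trapezoid_weights(grid)
  acc <- matrix(0 + 0i, d, d)
  for (k in seq_along(grid)) {
    ok <- if (is.function(o_int)) {
      as_complex_matrix(o_int(grid[k], trajectory$states[[k]]$matrix))
    } else {
      as_complex_matrix(o_int)
    }
    acc <- acc + w[k] * exp(-lam * (t_end - grid[k])) * conf_project(ok)
  }
  if (spec$normalize) {
    # kernel mass under the same quadrature rule, so a constant integrand
    # reproduces itself exactly; equals (1 - exp(-lam t)) / lam up to O(dt^2)
    acc <- acc / sum(w * exp(-lam * (t_end - grid)))
  }
  acc
}

#' Interaction probability from a measurement operator
#'
#' `P_ij(t) = Tr(M_ij(t) rho(t))`: real for Hermitian inputs (the residual
#' imaginary part must be below `1e-10`) and within `[0, 1]` whenever `M` is
#' normalized with spectrum in `[0, 1]`.
#'
#' @param rho_t [density_matrix()] (or matrix) at the measurement time.
#' @param m Hermitian measurement operator of matching dimension.
#' @return Real scalar.
#' @export
interaction_probability <- function(rho_t, m) {
  r <- rho_matrix(rho_t)
  m <- as_complex_matrix(m)
  if (!all(dim(r) == dim(m))) {
    stop("state and measurement operator dimensions differ", call. = FALSE)
  }
  val <- sum(diag(m %*% r))
  if (abs(Im(val)) > 1e-10) {
    stop(sprintf("interaction probability has imaginary part %.3g", Im(val)),
      call. = FALSE
    )
  }
  Re(val)
}

#' Dynamics configuration for pair scoring
#'
#' Physical parameters of the scoring simulations. Rates are in units of
#' the Hamiltonian coupling; the defaults (dephasing 0.1, binding 0.05,
#' thermal 0.01) are documented model choices, not empirically fitted
#' values. Candidate pairs whose shared module has at most `sim_sites_cap`
#' sites are scored from a module-level simulation (reduced to the pair by
#' partial trace); all other pairs use an isolated two-site simulation with
#' the pair's edge weight as coupling.
#'
#' @param coupling Hamiltonian coupling multiplying the graph Laplacian.
#' @param hbar Planck convention (default 1).
#' @param omegas per-vertex on-site frequencies (default 0).
#' @param rates named vector with entries `dephasing`, `binding`, `thermal`.
#' @param lambda_decay,horizon,grid_step,normalize see [measurement_spec()].
#' @param threshold classification threshold on the probability; ties are
#'   labeled 1.
#' @param sim_sites_cap largest module simulated at module level.
#' @param alpha cooperativity strength applied when `cooperativity = TRUE`
#'   (scores are multiplied by `1 + alpha * S(i:j)` of the reduced pair
#'   state and capped at 1).
#' @param cooperativity apply the entanglement-based enhancement factor.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(coupling = 1, hbar = 1, omegas = 0,
                           rates = c(dephasing = 0.1, binding = 0.05, thermal = 0.01),
                           lambda_decay = 1, horizon = 2, grid_step = 0.05,
                           normalize = TRUE, threshold = 0.5,
                           sim_sites_cap = 4, alpha = 0,
                           cooperativity = FALSE) {
  need <- c("dephasing", "binding", "thermal")
  if (!all(need %in% names(rates))) {
    stop("rates must name dephasing, binding and thermal", call. = FALSE)
  }
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  stopifnot(
    threshold >= 0, threshold <= 1, sim_sites_cap >= 2, sim_sites_cap <= 12,
    alpha >= 0
  )
  structure(
    list(
      coupling = coupling, hbar = hbar, omegas = omegas,
      rates = rates[need], lambda_decay = lambda_decay, horizon = horizon,
      grid_step = grid_step, normalize = normalize, threshold = threshold,
      sim_sites_cap = sim_sites_cap, alpha = alpha,
      cooperativity = cooperativity
    ),
    class = "scoring_config"
  )
}

#' @noRd
site_channels <- function(sites, rates) {
  out <- list()
  for (v in sites) {
    for (kind in names(rates)) {
      if (rates[[kind]] > 0) {
        out[[length(out) + 1]] <- lindblad_channel(kind, v, rates[[kind]])
      }
    }
  }
  out
}

# Simulate the induced subgraph on `sites`, all sites initialized in the
# uniform conformational superposition, and return the evolution on the
# measurement grid.
#' @noRd
simulate_subgraph <- function(g, sites, config) {
  sub_edges <- dplyr::filter(g$edges, .data$from %in% sites & .data$to %in% sites)
  sub <- protein_graph(sub_edges, vertices = sites)
  space <- composite_space(sites)
  omg <- resolve_omegas(g$vertices, config$omegas)[sites]
  spec <- extended_laplacian_spec(sub, omegas = omg, hbar = config$hbar)
  h <- hamiltonian_spec(spec, coupling = config$coupling)
  rho0 <- pure_density(plus_state(space))
  times <- measurement_times(measurement_spec(
    config$lambda_decay, config$horizon, config$grid_step, config$normalize
  ))
  evolve(rho0, h, site_channels(sites, config$rates), times)
}

#' Score candidate protein pairs for interaction
#'
#' The full scoring pipeline: for every candidate pair, simulate the
#' relevant open-system dynamics (module-level with pairwise reduction when
#' both proteins share a module of at most `sim_sites_cap` sites, isolated
#' two-site otherwise), build the memory-kernel measurement operator from
#' the similarity-weighted binding projector, and evaluate
#' `P_ij = Tr(M_ij rho_pair(horizon))`. Deterministic given graph and
#' configuration; symmetric in the pair order.
#'
#' @param g a [protein_graph()] (features and modules used when present).
#' @param pairs data frame with columns `a`, `b` (vertex ids), or a
#'   2-column matrix.
#' @param config a [scoring_config()].
#' @return Tibble with columns `protein_a`, `protein_b`, `p_interaction`,
#'   `predicted` (1 when `p >= threshold`), `similarity`, `strategy`.
#' @examples
#' net <- generate_synthetic_network(synthetic_spec(n_vertices = 12, seed = 7))
#' head(score_all_pairs(
#'   net$graph, net$positives[1:2, ],
#'   scoring_config(horizon = 1, grid_step = 0.1)
#' ))
#' @export
score_all_pairs <- function(g, pairs, config = scoring_config()) {
  stopifnot(inherits(g, "protein_graph"), inherits(config, "scoring_config"))
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop("pairs must have two columns", call. = FALSE)
  names(pairs)[1:2] <- c("a", "b")
  unknown <- setdiff(unique(c(pairs$a, pairs$b)), g$vertices)
  if (length(unknown) > 0) {
    stop(sprintf("pair vertices not in graph: %s", toString(unknown)), call. = FALSE)
  }

  mspec <- measurement_spec(
    config$lambda_decay, config$horizon,
    config$grid_step, config$normalize
  )
  idx <- stats::setNames(seq_along(g$vertices), g$vertices)
  module_cache <- list()

  module_sites <- function(m) g$vertices[g$modules == m]

  score_one <- function(a, b) {
    # canonical orientation: results are exactly symmetric in (a, b)
    if (idx[a] > idx[b]) {
      tmp <- a
      a <- b
      b <- tmp
    }
    same_module <- !is.null(g$modules) && g$modules[[a]] == g$modules[[b]]
    use_module <- same_module &&
      length(module_sites(g$modules[[a]])) <= config$sim_sites_cap

    if (use_module) {
      key <- as.character(g$modules[[a]])
      if (is.null(module_cache[[key]])) {
        sites <- module_sites(g$modules[[a]])
        module_cache[[key]] <<- list(
          sites = sites,
          ev = simulate_subgraph(g, sites, config)
        )
      }
      mc <- module_cache[[key]]
      pair_states <- lapply(mc$ev$states, function(s) partial_trace(s, c(a, b)))
      traj <- structure(
        list(
          times = mc$ev$times, states = pair_states,
          trace_drift = mc$ev$trace_drift,
          min_eigenvalue = mc$ev$min_eigenvalue,
          method = mc$ev$method, space = pair_states[[1]]$space
        ),
        class = "qpin_evolution"
      )
      strategy <- "module"
    } else {
      traj <- simulate_subgraph(g, c(a, b), config)
      strategy <- "pair"
    }
    o_int <- interaction_operator(g, a, b, traj$space)
    m_op <- measurement_operator(mspec, traj, o_int)
    rho_t <- traj$states[[length(traj$states)]]
    p <- interaction_probability(rho_t, m_op)
    if (config$cooperativity && config$alpha > 0) {
      s_ab <- entanglement_entropy(rho_t, list(a, b))
      p <- min(1, p * cooperativity_factor(s_ab, config$alpha))
    }
    p <- min(1, max(0, p))
    tibble::tibble(
      protein_a = a, protein_b = b, p_interaction = p,
      predicted = as.integer(p >= config$threshold),
      similarity = feature_similarity(g, a, b),
      strategy = strategy
    )
  }

  purrr::pmap_dfr(list(pairs$a, pairs$b), function(a, b) score_one(a, b))
}
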