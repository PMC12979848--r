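#' Pauli terms of a parameterized network Hamiltonian
#'
#' `H(theta) = sum_i c_i P_i` with each `P_i` a tensor product of Pauli
#' matrices on named sites (identity elsewhere). A term's coefficient is
#' either a fixed number or an entry of the shared parameter vector
#' (`index`). An empty `factors` map gives a constant (identity) offset.
#'
#' @param factors named character vector mapping site ids to `"X"`, `"Y"`
#'   or `"Z"`.
#' @param coefficient fixed coefficient (ignored when `index` is set).
#' @param index optional 1-based position in the parameter vector supplying
#'   the coefficient.
#' @return Object of class `pauli_term`.
#' @export
pauli_term <- function(factors, coefficient = 1, index = NA_integer_) {
  factors <- toupper(factors)
  if (length(factors) > 0) {
    if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
      stop("factors must be named by site id", call. = FALSE)
    }
    if (!all(factors %in% c("X", "Y", "Z"))) {
      stop("factors must be X, Y or Z", call. = FALSE)
    }
  }
  structure(
    list(
      factors = factors, coefficient = coefficient,
      index = as.integer(index)
    ),
    class = "pauli_term"
  )
}

#' @noRd
term_coefficient <- function(term, theta) {
  if (!is.na(term$index)) {
    if (term$index < 1 || term$index > length(theta)) {
      stop(sprintf("coefficient index %d out of range", term$index), call. = FALSE)
    }
    theta[term$index]
  } else {
    term$coefficient
  }
}

#' @noRd
term_matrix <- function(term, space) {
  if (length(term$factors) == 0) {
    return(complex_identity(space$total_dim))
  }
  op <- Reduce(kronecker, lapply(unname(term$factors), function(p) {
    pauli(tolower(p))
  }))
  embed_local(op, names(term$factors), space)
}

#' Assemble the dense Hamiltonian of a Pauli-term list
#' @param terms list of [pauli_term()]s.
#' @param space a [composite_space()] of qubit sites.
#' @param theta parameter vector for indexed coefficients.
#' @return Complex Hermitian matrix.
#' @export
assemble_hamiltonian <- function(terms, space, theta = numeric(0)) {
  acc <- matrix(0 + 0i, space$total_dim, space$total_dim)
  for (term in terms) {
    acc <- acc + term_coefficient(term, theta) * term_matrix(term, space)
  }
  acc
}

#' Hardware-efficient graph-aware ansatz
#'
#' The parameterized circuit preparing `|psi(theta)>` from `|0...0>`:
#' `layers` repetitions of per-site `Ry(theta) Rz(theta)` rotations followed
#' by fixed square-root-of-swap entangling gates along the listed graph
#' edges (a plain swap only permutes product states; its square root
#' genuinely entangles). All rotation generators have `±1/2` spectra, so the
#' exact parameter-shift rule applies to every circuit parameter. Parameter
#' indices are dense `1..n_params`.
#'
#' @param sites character vector of qubit site ids.
#' @param edges optional data frame with columns `from`, `to` (e.g. a
#'   [protein_graph()]'s edge table) fixing the entangler placement.
#' @param layers number of rotation+entangler layers (default 2).
#' @param param_offset first parameter index minus one, letting circuit
#'   parameters share one vector with Hamiltonian coefficients.
#' @return Object of class `qpin_ansatz` with fields `space`, `gates`,
#'   `n_params`, `param_indices`.
#' @export
build_ansatz <- function(sites, edges = NULL, layers = 2, param_offset = 0) {
  space <- composite_space(sites)
  gates <- list()
  np <- 0L
  for (l in seq_len(layers)) {
    for (v in sites) {
      for (axis in c("ry", "rz")) {
        np <- np + 1L
        gates[[length(gates) + 1]] <- list(
          type = axis, site = v,
          param = np + param_offset
        )
      }
    }
    if (!is.null(edges) && nrow(edges) > 0) {
      for (k in seq_len(nrow(edges))) {
        gates[[length(gates) + 1]] <- list(
          type = "sqrt_swap",
          sites = c(as.character(edges$from[k]), as.character(edges$to[k]))
        )
      }
    }
  }
  structure(
    list(
      space = space, gates = gates, n_params = np,
      param_indices = seq_len(np) + param_offset
    ),
    class = "qpin_ansatz"
  )
}

#' @export
print.qpin_ansatz <- function(x, ...) {
  cat(sprintf(
    "<qpin_ansatz: %d sites, %d gates, %d parameters>\n",
    length(x$space$site_order), length(x$gates), x$n_params
  ))
  invisible(x)
}

#' @noRd
sqrt_swap_gate <- function() {
  matrix(
    c(
      1, 0, 0, 0,
      0, (1 + 1i) / 2, (1 - 1i) / 2, 0,
      0, (1 - 1i) / 2, (1 + 1i) / 2, 0,
      0, 0, 0, 1
    ),
    4, 4,
    byrow = TRUE
  )
}

#' Run the ansatz circuit
#' @param ansatz a [build_ansatz()] circuit.
#' @param theta full parameter vector (circuit parameters read at the
#'   ansatz's `param_indices`).
#' @return A [pure_state()] on the ansatz space.
#' @export
run_ansatz <- function(ansatz, theta) {
  space <- ansatz$space
  psi <- rep(0 + 0i, space$total_dim)
  psi[1] <- 1
  for (gate in ansatz$gates) {
    if (!is.null(gate$param) && gate$param > length(theta)) {
      stop(sprintf("parameter index %d out of range", gate$param), call. = FALSE)
    }
    gm <- switch(gate$type,
      ry = {
        th <- theta[gate$param]
        matrix(
          c(
            cos(th / 2), sin(th / 2),
            -sin(th / 2), cos(th / 2)
          ),
          2, 2
        ) + 0i
      },
      rz = {
        th <- theta[gate$param]
        diag(c(exp(-1i * th / 2), exp(1i * th / 2)))
      },
      sqrt_swap = sqrt_swap_gate(),
      stop(sprintf("unknown gate type '%s'", gate$type), call. = FALSE)
    )
    target <- if (gate$type == "sqrt_swap") gate$sites else gate$site
    psi <- embed_local(gm, target, space) %*% psi
  }
  pure_state(as.vector(psi), space)
}

#' Variational energy of the parameterized Hamiltonian
#'
#' `E(theta) = <psi(theta)| H(theta) |psi(theta)>` by exact statevector
#' simulation (no sampling noise). Setting `shots` samples each Pauli term
#' from its `±1` outcome distribution instead, emulating a finite
#' measurement budget; this is a labeled stochastic option, not the
#' default.
#'
#' @param theta real parameter vector covering circuit parameters and any
#'   indexed Hamiltonian coefficients.
#' @param terms list of [pauli_term()]s.
#' @param ansatz a [build_ansatz()] circuit.
#' @param shots optional positive integer measurement count per term.
#' @return Real scalar energy.
#' @export
energy <- function(theta, terms, ansatz, shots = NULL) {
  psi <- run_ansatz(ansatz, theta)$amplitudes
  space <- ansatz$space
  if (is.null(shots)) {
    h <- assemble_hamiltonian(terms, space, theta)
    return(Re(Conj(psi) %*% h %*% psi)[1])
  }
  total <- 0
  for (term in terms) {
    coef <- term_coefficient(term, theta)
    if (length(term$factors) == 0) {
      total <- total + coef
      next
    }
    ev <- Re(Conj(psi) %*% term_matrix(term, space) %*% psi)[1]
    p_plus <- min(1, max(0, (1 + ev) / 2))
    total <- total + coef * (2 * stats::rbinom(1, shots, p_plus) / shots - 1)
  }
  total
}

#' Gradient of the variational energy
#'
#' Parameter-shift mode uses the exact rule
#' `g_k = (E(theta + pi/2 e_k) - E(theta - pi/2 e_k)) / 2` for circuit
#' parameters (all rotation generators have `±1/2` spectra) and the exact
#' linear derivative `<psi| P_k |psi>` for Hamiltonian-coefficient
#' parameters. A parameter referenced by both the circuit and a coefficient
#' breaks the shift rule and raises an error suggesting finite differences.
#' Finite-difference mode uses central differences with step `1e-6` on the
#' full energy.
#'
#' @inheritParams energy
#' @param mode `"parameter_shift"` or `"finite_difference"`.
#' @return Real vector of length `length(theta)`.
#' @export
gradient <- function(theta, terms, ansatz,
                     mode = c("parameter_shift", "finite_difference")) {
  mode <- match.arg(mode)
  n <- length(theta)
  g <- numeric(n)
  if (mode == "finite_difference") {
    hstep <- 1e-6
    for (k in seq_len(n)) {
      ep <- em <- theta
      ep[k] <- ep[k] + hstep
      em[k] <- em[k] - hstep
      g[k] <- (energy(ep, terms, ansatz) - energy(em, terms, ansatz)) / (2 * hstep)
    }
    return(g)
  }
  gate_idx <- ansatz$param_indices
  ham_idx <- unlist(lapply(terms, function(t) if (is.na(t$index)) NULL else t$index))
  shared <- intersect(gate_idx, ham_idx)
  if (length(shared) > 0) {
    stop(
      sprintf(
        "parameter(s) %s drive both a gate and a Hamiltonian coefficient; the shift rule does not apply -- use mode = 'finite_difference'",
        toString(shared)
      ),
      call. = FALSE
    )
  }
  for (k in intersect(seq_len(n), gate_idx)) {
    ep <- em <- theta
    ep[k] <- ep[k] + pi / 2
    em[k] <- em[k] - pi / 2
    g[k] <- (energy(ep, terms, ansatz) - energy(em, terms, ansatz)) / 2
  }
  if (length(ham_idx) > 0) {
    psi <- run_ansatz(ansatz, theta)$amplitudes
    for (term in terms) {
      if (is.na(term$index)) next
      ev <- if (length(term$factors) == 0) {
        1
      } else {
        Re(Conj(psi) %*% term_matrix(term, ansatz$space) %*% psi)[1]
      }
      g[term$index] <- g[term$index] + ev
    }
  }
  g
}

#' Training configuration
#'
#' @param lambda1 coherence regularization weight (penalizes the l1
#'   coherence of the prepared state).
#' @param lambda2 sparsity regularization weight (penalizes `sum |theta|`).
#' @param adam list with `step`, `beta1`, `beta2`, `eps`.
#' @param max_iters Adam iterations.
#' @param gradient_mode `"parameter_shift"` or `"finite_difference"`.
#' @param seed RNG seed for the uniform `(-pi, pi)` initialization.
#' @return Object of class `training_config`.
#' @export
training_config <- function(lambda1 = 0, lambda2 = 0,
                            adam = list(step = 0.1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
                            max_iters = 500,
                            gradient_mode = c("parameter_shift", "finite_difference"),
                            seed = 1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, max_iters >= 1)
  structure(
    list(
      lambda1 = lambda1, lambda2 = lambda2, adam = adam,
      max_iters = as.integer(max_iters),
      gradient_mode = match.arg(gradient_mode), seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Regularized total loss
#'
#' `L_total = L_quantum + lambda1 * L_coherence + lambda2 * L_sparsity`,
#' with `L_quantum` the supplied energy, `L_coherence` the l1 coherence of
#' the prepared state's density matrix and `L_sparsity = sum |theta|`.
#'
#' @param e_quantum the energy term.
#' @param state a [pure_state()] or [density_matrix()] (the ansatz state).
#' @param theta parameter vector.
#' @param cfg a [training_config()].
#' @return List with `total`, `quantum`, `coherence`, `sparsity`.
#' @export
total_loss <- function(e_quantum, state, theta, cfg) {
  stopifnot(inherits(cfg, "training_config"))
  rho <- if (inherits(state, "pure_state")) pure_density(state) else state
  coh <- l1_coherence(rho)
  sp <- sum(abs(theta))
  list(
    total = e_quantum + cfg$lambda1 * coh + cfg$lambda2 * sp,
    quantum = e_quantum, coherence = coh, sparsity = sp
  )
}

#' Adam optimizer
#'
#' Standard Adam recursion with bias-corrected first and second moments.
#' Exposed so arbitrary objectives (e.g. a cross-entropy over pair
#' predictions) can reuse the optimizer outside the VQE path.
#'
#' @param par initial parameter vector.
#' @param fn objective function `fn(par) -> scalar`.
#' @param gr gradient function `gr(par) -> vector`.
#' @param step,beta1,beta2,eps Adam hyperparameters.
#' @param max_iters iteration count.
#' @param trace_fn optional `function(iter, par, value)` called per
#'   iteration.
#' @return List with `par`, `value`, `trace` (numeric vector of objective
#'   values).
#' @export
adam_optimize <- function(par, fn, gr, step = 0.1, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8, max_iters = 500,
                          trace_fn = NULL) {
  m <- v <- numeric(length(par))
  values <- numeric(max_iters)
  for (it in seq_len(max_iters)) {
    g <- gr(par)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^it)
    vhat <- v / (1 - beta2^it)
    par <- par - step * mhat / (sqrt(vhat) + eps)
    values[it] <- fn(par)
    if (!is.finite(values[it])) {
      stop(
        sprintf("optimization diverged at iteration %d (loss %g)", it, values[it]),
        call. = FALSE
      )
    }
    if (!is.null(trace_fn)) trace_fn(it, par, values[it])
  }
  list(par = par, value = values[max_iters], trace = values)
}

#' Train the variational eigensolver
#'
#' Minimizes the regularized loss over the ansatz (and any indexed
#' Hamiltonian coefficients) with Adam. The energy gradient uses the
#' configured mode; the coherence term is differentiated by central finite
#' differences and the sparsity term by its subgradient `sign(theta)`.
#' Deterministic and bit-reproducible given `cfg$seed`.
#'
#' @param terms list of [pauli_term()]s.
#' @param ansatz a [build_ansatz()] circuit.
#' @param cfg a [training_config()].
#' @param n_params total parameter count (default: enough for the ansatz
#'   and every indexed coefficient).
#' @return Object of class `vqe_fit`: `theta`, `energy`, `loss` (final
#'   components), `trace` (tibble with per-iteration components),
#'   `terms`, `ansatz`, `config`.
#' @examples
#' fit <- train_vqe(
#'   list(pauli_term(c(A = "Z"))),
#'   build_ansatz("A", layers = 1),
#'   training_config(max_iters = 100)
#' )
#' glance(fit)
#' @export
train_vqe <- function(terms, ansatz, cfg = training_config(), n_params = NULL) {
  stopifnot(inherits(cfg, "training_config"))
  ham_idx <- unlist(lapply(terms, function(t) if (is.na(t$index)) NULL else t$index))
  if (is.null(n_params)) {
    n_params <- max(c(ansatz$param_indices, ham_idx, 0L))
  }
  theta0 <- with_seed(cfg$seed, stats::runif(n_params, -pi, pi))

  rows <- vector("list", cfg$max_iters)
  objective <- function(th) {
    e <- energy(th, terms, ansatz)
    total_loss(e, run_ansatz(ansatz, th), th, cfg)$total
  }
  grad_total <- function(th) {
    g <- gradient(th, terms, ansatz, mode = cfg$gradient_mode)
    if (cfg$lambda1 > 0) {
      hstep <- 1e-6
      for (k in seq_along(th)) {
        ep <- em <- th
        ep[k] <- ep[k] + hstep
        em[k] <- em[k] - hstep
        cp <- l1_coherence(pure_density(run_ansatz(ansatz, ep)))
        cm <- l1_coherence(pure_density(run_ansatz(ansatz, em)))
        g[k] <- g[k] + cfg$lambda1 * (cp - cm) / (2 * hstep)
      }
    }
    if (cfg$lambda2 > 0) g <- g + cfg$lambda2 * sign(th)
    g
  }
  tracer <- function(it, th, val) {
    e <- energy(th, terms, ansatz)
    comp <- total_loss(e, run_ansatz(ansatz, th), th, cfg)
    rows[[it]] <<- tibble::tibble(
      iter = it, total = comp$total, quantum = comp$quantum,
      coherence = comp$coherence, sparsity = comp$sparsity
    )
  }
  opt <- adam_optimize(theta0, objective, grad_total,
    step = cfg$adam$step, beta1 = cfg$adam$beta1, beta2 = cfg$adam$beta2,
    eps = cfg$adam$eps, max_iters = cfg$max_iters, trace_fn = tracer
  )
  theta <- opt$par
  e_final <- energy(theta, terms, ansatz)
  structure(
    list(
      theta = theta, energy = e_final,
      loss = total_loss(e_final, run_ansatz(ansatz, theta), theta, cfg),
      trace = dplyr::bind_rows(rows), terms = terms, ansatz = ansatz,
      config = cfg
    ),
    class = "vqe_fit"
  )
}

#' @export
print.vqe_fit <- function(x, ...) {
  cat(sprintf(
    "<vqe_fit: %d parameters, final energy %.6f, total loss %.6f after %d iterations>\n",
    length(x$theta), x$energy, x$loss$total, nrow(x$trace)
  ))
  invisible(x)
}
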