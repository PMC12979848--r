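#' Decoherence channels on protein sites
#'
#' The three environmental processes acting on individual proteins, each a
#' Lindblad jump operator with rate `gamma` (units 1/time):
#' * `dephasing` -- conformational dephasing, `sqrt(gamma) sigma_z`
#'   (destroys conformational coherence, keeps populations);
#' * `binding` -- binding/unbinding events, `sqrt(gamma) sigma_-`
#'   (relaxes the binding-competent state `|1>` to `|0>`);
#' * `thermal` -- thermal fluctuations, `sqrt(gamma) (a + a^dagger)`
#'   (truncates to `sigma_x` on two-level sites, the truncated harmonic
#'   ladder otherwise).
#'
#' @param kind one of `"dephasing"`, `"binding"`, `"thermal"`.
#' @param site vertex identifier the channel acts on.
#' @param rate nonnegative rate `gamma`.
#' @return Object of class `lindblad_channel`.
#' @export
lindblad_channel <- function(kind = c("dephasing", "binding", "thermal"),
                             site, rate) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0) {
    stop("rate must be a single nonnegative number", call. = FALSE)
  }
  structure(list(kind = kind, site = as.character(site), rate = rate),
    class = "lindblad_channel"
  )
}

# Local (unscaled) jump operator of a channel for local dimension d.
#' @noRd
channel_local_op <- function(kind, d) {
  if (d == 2) {
    return(switch(kind,
      dephasing = pauli("z"),
      binding = pauli("sm"),
      thermal = pauli("x")
    ))
  }
  if (kind == "thermal") {
    a <- matrix(0 + 0i, d, d)
    for (n in seq_len(d - 1)) a[n, n + 1] <- sqrt(n)
    return(a + dagger(a))
  }
  stop(
    sprintf("%s channel requires a two-level site (local dim is %d)", kind, d),
    call. = FALSE
  )
}

#' Dense jump operator of a channel on the full space
#' @param channel a [lindblad_channel()].
#' @param space a [composite_space()].
#' @return Complex matrix `sqrt(rate) * L` embedded on the full space.
#' @export
channel_operator <- function(channel, space) {
  pos <- site_positions(space, channel$site)
  op <- channel_local_op(channel$kind, space$local_dims[pos])
  sqrt(channel$rate) * embed_local(op, channel$site, space)
}

#' System Hamiltonian specification
#'
#' The network Hamiltonian is `H = coupling * L_Q + V`, with `L_Q` the
#' extended quantum graph Laplacian and `V` an optional Hermitian potential
#' on the composite space.
#'
#' @param laplacian an [extended_laplacian_spec()] (or [protein_graph()],
#'   promoted with default frequencies).
#' @param coupling real scalar multiplying the Laplacian.
#' @param potential optional Hermitian complex matrix on the composite
#'   space (checked to `1e-10`).
#' @return Object of class `hamiltonian_spec`.
#' @export
hamiltonian_spec <- function(laplacian, coupling = 1, potential = NULL) {
  if (inherits(laplacian, "protein_graph")) {
    laplacian <- extended_laplacian_spec(laplacian)
  }
  stopifnot(inherits(laplacian, "extended_laplacian_spec"))
  if (!is.null(potential)) {
    potential <- as_complex_matrix(potential)
    if (!is_hermitian(potential, 1e-10)) {
      stop("potential must be Hermitian within 1e-10", call. = FALSE)
    }
  }
  structure(
    list(laplacian = laplacian, coupling = coupling, potential = potential),
    class = "hamiltonian_spec"
  )
}

#' @rdname hamiltonian_spec
#' @param h a `hamiltonian_spec`.
#' @param space a [composite_space()].
#' @return `build_hamiltonian()`: the dense Hermitian matrix
#'   `coupling * L_Q + V`.
#' @export
build_hamiltonian <- function(h, space) {
  stopifnot(inherits(h, "hamiltonian_spec"))
  m <- h$coupling * extended_quantum_laplacian(h$laplacian, space)
  if (!is.null(h$potential)) {
    if (nrow(h$potential) != space$total_dim) {
      stop("potential dimension must match the composite space", call. = FALSE)
    }
    m <- m + h$potential
  }
  m
}

#' Vectorized Liouvillian of the master equation
#'
#' Builds the generator of
#' `drho/dt = -(i/hbar) [H, rho] + sum_k (L_k rho L_k^+ - (1/2) {L_k^+ L_k, rho})`
#' as a `D^2 x D^2` complex matrix acting on column-stacked (vec) density
#' matrices. The generator of this completely positive trace-preserving
#' semigroup always has `vec(I)` as a left null vector (trace preservation).
#'
#' @param h a [hamiltonian_spec()].
#' @param channels list of [lindblad_channel()]s.
#' @param space a [composite_space()].
#' @return Complex `D^2 x D^2` matrix.
#' @export
build_liouvillian <- function(h, channels, space) {
  d <- space$total_dim
  hm <- build_hamiltonian(h, space)
  hbar <- h$laplacian$hbar
  if (hbar <= 0) stop("hbar must be positive for dynamics", call. = FALSE)
  id <- complex_identity(d)
  lv <- (-1i / hbar) * (kronecker(id, hm) - kronecker(t(hm), id))
  for (ch in channels) {
    lk <- channel_operator(ch, space)
    ak <- dagger(lk) %*% lk
    lv <- lv + kronecker(Conj(lk), lk) -
      0.5 * (kronecker(id, ak) + kronecker(t(ak), id))
  }
  lv
}

# --- structured right-hand side (no D^2 x D^2 matrices) ------------------

# Closure computing drho/dt via permutations and elementwise masks; dense
# matrix products only for the optional potential and non-qubit thermal
# channels. Used by the RK4 integrator.
#' @noRd
make_lindblad_rhs <- function(h, channels, space) {
  d <- space$total_dim
  g <- h$laplacian$graph
  hbar <- h$laplacian$hbar
  coupling <- h$coupling
  digits <- basis_digits(space)
  dims <- space$local_dims
  strides <- rev(cumprod(rev(c(dims[-1], 1))))

  edge_perms <- list()
  edge_w <- numeric(0)
  if (nrow(g$edges) > 0) {
    for (k in seq_len(nrow(g$edges))) {
      pos <- site_positions(space, c(g$edges$from[k], g$edges$to[k]))
      sw <- digits
      sw[, pos[1]] <- digits[, pos[2]]
      sw[, pos[2]] <- digits[, pos[1]]
      edge_perms[[k]] <- as.vector(sw %*% strides) + 1
      edge_w[k] <- g$edges$weight[k]
    }
  }

  # on-site sigma_z energies as a diagonal vector
  omg <- h$laplacian$omegas
  dvec <- rep(0, d)
  for (v in names(omg)[omg != 0]) {
    pos <- site_positions(space, v)
    if (dims[pos] != 2) {
      stop(sprintf("on-site frequency on '%s' requires a two-level site", v),
        call. = FALSE
      )
    }
    dvec <- dvec + hbar * omg[[v]] * (1 - 2 * digits[, pos])
  }
  has_diag <- any(dvec != 0)
  dcol <- if (has_diag) matrix(dvec, d, d, byrow = TRUE) else NULL
  pot <- h$potential

  h_left <- function(rho) {
    acc <- if (has_diag) dvec * rho else matrix(0 + 0i, d, d)
    for (k in seq_along(edge_perms)) {
      acc <- acc + edge_w[k] * (rho - rho[edge_perms[[k]], , drop = FALSE])
    }
    acc <- coupling * acc
    if (!is.null(pot)) acc <- acc + pot %*% rho
    acc
  }
  h_right <- function(rho) {
    acc <- if (has_diag) rho * dcol else matrix(0 + 0i, d, d)
    for (k in seq_along(edge_perms)) {
      acc <- acc + edge_w[k] * (rho - rho[, edge_perms[[k]], drop = FALSE])
    }
    acc <- coupling * acc
    if (!is.null(pot)) acc <- acc + rho %*% pot
    acc
  }

  diss <- list()
  for (ch in channels) {
    if (ch$rate == 0) next
    pos <- site_positions(space, ch$site)
    gam <- ch$rate
    if (dims[pos] == 2) {
      dig <- digits[, pos]
      if (ch$kind == "dephasing") {
        z <- 1 - 2 * dig
        zmask <- outer(z, z)
        diss[[length(diss) + 1]] <- local({
          gam <- gam
          zmask <- zmask
          function(rho) gam * (rho * zmask - rho)
        })
      } else if (ch$kind == "binding") {
        flip <- seq_len(d) + (1 - 2 * dig) * strides[pos]
        idx0 <- which(dig == 0)
        nmask <- (outer(dig, dig, `+`)) / 2
        diss[[length(diss) + 1]] <- local({
          gam <- gam
          flip <- flip
          idx0 <- idx0
          nmask <- nmask
          function(rho) {
            out <- -gam * nmask * rho
            out[idx0, idx0] <- out[idx0, idx0] + gam * rho[flip[idx0], flip[idx0]]
            out
          }
        })
      } else { # thermal, qubit: sigma_x
        flip <- seq_len(d) + (1 - 2 * dig) * strides[pos]
        diss[[length(diss) + 1]] <- local({
          gam <- gam
          flip <- flip
          function(rho) gam * (rho[flip, flip] - rho)
        })
      }
    } else {
      lk <- channel_operator(ch, space)
      ak <- dagger(lk) %*% lk
      lkd <- dagger(lk)
      diss[[length(diss) + 1]] <- local({
        lk <- lk
        ak <- ak
        lkd <- lkd
        function(rho) lk %*% rho %*% lkd - 0.5 * (ak %*% rho + rho %*% ak)
      })
    }
  }

  rhs <- function(rho) {
    out <- (-1i / hbar) * (h_left(rho) - h_right(rho))
    for (f in diss) out <- out + f(rho)
    out
  }

  # crude upper bound on the generator norm, for step-size control
  wsum <- sum(edge_w)
  hnorm <- abs(coupling) * (2 * wsum + max(abs(dvec), 0)) +
    if (!is.null(pot)) max(rowSums(Mod(pot))) else 0
  rate_norm <- 0
  for (ch in channels) {
    pos <- site_positions(space, ch$site)
    opn <- if (dims[pos] == 2) 1 else 2 * sqrt(dims[pos] - 1)
    rate_norm <- rate_norm + 2 * ch$rate * opn^2
  }
  attr(rhs, "gen_norm") <- 2 * hnorm / hbar + rate_norm
  rhs
}

#' Evolve a network density matrix under the master equation
#'
#' Propagates `rho0` through the Lindblad dynamics defined by `h` and
#' `channels`, reporting the state at exactly the requested output times
#' (dense output by propagator multiplication, never interpolation).
#'
#' Method `"exact"` (automatic for `total_dim^2 <= 4096`) exponentiates the
#' vectorized Liouvillian; `"rk4"` integrates the master equation with a
#' classical fixed-step Runge-Kutta scheme, internal step
#' `min(0.005, 0.05 / ||generator||)`, subdividing each output interval
#' evenly. Every output state is checked: trace within `1e-8` of one and
#' smallest eigenvalue `>= -1e-9`; a breach raises an error carrying the
#' diagnostics -- states are never clipped silently.
#'
#' @param rho0 initial [density_matrix()].
#' @param h a [hamiltonian_spec()].
#' @param channels list of [lindblad_channel()]s (may be empty).
#' @param times increasing numeric vector of output times, starting at or
#'   after 0 (propagation always starts at 0).
#' @param method `"auto"`, `"exact"` or `"rk4"`.
#' @param validate check trace/positivity of every output state.
#' @return Object of class `qpin_evolution`: fields `times`, `states` (list
#'   of [density_matrix()]), `trace_drift`, `min_eigenvalue`, `method`.
#' @examples
#' sp <- composite_space("A")
#' g1 <- protein_graph(data.frame(from = character(), to = character()),
#'   vertices = "A"
#' )
#' h <- hamiltonian_spec(g1)
#' rho0 <- pure_density(pure_state(c(1, 1) / sqrt(2), sp))
#' ev <- evolve(rho0, h, list(lindblad_channel("dephasing", "A", 0.5)),
#'   times = c(0, 1, 2)
#' )
#' tidy(ev)
#' @export
evolve <- function(rho0, h, channels = list(), times,
                   method = c("auto", "exact", "rk4"), validate = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(rho0, "density_matrix"), inherits(h, "hamiltonian_spec"))
  space <- rho0$space
  times <- as.numeric(times)
  if (length(times) < 1 || any(diff(times) <= 0) || times[1] < 0) {
    stop("`times` must be increasing and start at or after 0", call. = FALSE)
  }
  d <- space$total_dim
  if (method == "auto") method <- if (d^2 <= 4096) "exact" else "rk4"

  states <- vector("list", length(times))
  if (method == "exact") {
    lv <- build_liouvillian(h, channels, space)
    gaps <- diff(c(0, times))
    props <- list()
    v <- as.vector(rho0$matrix)
    for (k in seq_along(times)) {
      gp <- gaps[k]
      if (gp > 0) {
        key <- sprintf("%.17g", gp)
        if (is.null(props[[key]])) props[[key]] <- expm_c(lv * gp)
        v <- props[[key]] %*% v
      }
      states[[k]] <- density_matrix(matrix(v, d, d), space, validate = FALSE)
    }
  } else {
    rhs <- make_lindblad_rhs(h, channels, space)
    dt_max <- min(0.005, 0.05 / max(attr(rhs, "gen_norm"), 1e-12))
    rho <- rho0$matrix
    t_prev <- 0
    for (k in seq_along(times)) {
      gap <- times[k] - t_prev
      if (gap > 0) {
        nstep <- max(1L, ceiling(gap / dt_max))
        hstep <- gap / nstep
        for (s in seq_len(nstep)) {
          k1 <- rhs(rho)
          k2 <- rhs(rho + hstep / 2 * k1)
          k3 <- rhs(rho + hstep / 2 * k2)
          k4 <- rhs(rho + hstep * k3)
          rho <- rho + hstep / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }
      states[[k]] <- density_matrix(rho, space, validate = FALSE)
      t_prev <- times[k]
    }
  }

  traces <- vapply(states, function(s) abs(Re(sum(diag(s$matrix))) - 1), numeric(1))
  drift <- max(traces)
  mineig <- min(vapply(
    states,
    function(s) min(herm_eigenvalues(s$matrix)), numeric(1)
  ))
  if (validate && (drift > 1e-8 || mineig < -1e-9)) {
    stop(
      sprintf(
        "evolution left the physical state space: max trace drift %.3g, min eigenvalue %.3g (method %s)",
        drift, mineig, method
      ),
      call. = FALSE
    )
  }
  structure(
    list(
      times = times, states = states, trace_drift = drift,
      min_eigenvalue = mineig, method = method, space = space
    ),
    class = "qpin_evolution"
  )
}

#' @export
print.qpin_evolution <- function(x, ...) {
  cat(sprintf(
    "<qpin_evolution: %d times in [%g, %g], dim %d, method %s, trace drift %.2g, min eig %.2g>\n",
    length(x$times), min(x$times), max(x$times), x$space$total_dim,
    x$method, x$trace_drift, x$min_eigenvalue
  ))
  invisible(x)
}

#' Stationary state of the Lindblad generator
#'
#' Solves for the density matrix in the kernel of the vectorized
#' Liouvillian. The generator must have a one-dimensional kernel (checked
#' via singular values); a degenerate steady manifold -- e.g. pure
#' dephasing, whose fixed points are all diagonal states -- is an error
#' naming the kernel dimension.
#'
#' @inheritParams build_liouvillian
#' @param tol singular values below `tol * max(sv)` count as zero.
#' @return A [density_matrix()] with residual `||L(rho)|| <= 1e-9`.
#' @export
steady_state <- function(h, channels, space, tol = 1e-9) {
  lv <- build_liouvillian(h, channels, space)
  sv <- svd(lv)
  thresh <- tol * max(sv$d[1], 1)
  kdim <- sum(sv$d < thresh)
  if (kdim != 1L) {
    stop(
      sprintf("steady state not unique: Liouvillian kernel dimension is %d", kdim),
      call. = FALSE
    )
  }
  d <- space$total_dim
  rho <- hermitize(matrix(sv$v[, ncol(sv$v)], d, d))
  tr <- Re(sum(diag(rho)))
  if (abs(tr) < 1e-10) stop("kernel vector has vanishing trace", call. = FALSE)
  rho <- rho / tr
  resid <- sqrt(sum(Mod(lv %*% as.vector(rho))^2))
  if (resid > 1e-9) {
    stop(sprintf("steady-state residual %.3g exceeds 1e-9", resid), call. = FALSE)
  }
  density_matrix(rho, space)
}
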