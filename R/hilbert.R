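#' Composite Hilbert spaces over graph vertices
#'
#' Each protein (site) carries a finite local space of conformational basis
#' states; the network state lives on the tensor product over selected sites.
#' The first site in `sites` is the leftmost (most significant) Kronecker
#' factor -- one fixed convention shared by every operator and oracle in the
#' package. Total dimension is capped at 4096 (12 qubits): exact
#' density-matrix simulation beyond that is not attempted, use pair or module
#' subspaces instead (see [score_all_pairs()]).
#'
#' @param sites character vector of site (vertex) identifiers, no duplicates.
#' @param dims integer local dimensions (each >= 2), recycled to
#'   `length(sites)`. Default 2: basis `c0` = ground/closed conformation,
#'   `c1` = binding-competent conformation.
#' @param spin if `TRUE`, each local dimension is doubled to carry a spin-1/2
#'   factor; no package operator couples to it, it only enlarges the space.
#' @return An object of class `composite_space` with fields `site_order`,
#'   `local_dims`, `total_dim`.
#' @examples
#' composite_space(c("A", "B"))
#' @export
composite_space <- function(sites, dims = 2, spin = FALSE) {
  sites <- as.character(sites)
  if (length(sites) == 0) stop("need at least one site", call. = FALSE)
  if (anyDuplicated(sites)) stop("duplicate sites in site_order", call. = FALSE)
  dims <- as.integer(rep_len(dims, length(sites)))
  if (any(dims < 2)) stop("local dimensions must be >= 2", call. = FALSE)
  if (spin) dims <- dims * 2L
  total <- prod(dims)
  if (total > 4096) {
    stop(
      sprintf(
        "total dimension %d exceeds the 4096 cap for exact simulation; use pair or module subspaces",
        total
      ),
      call. = FALSE
    )
  }
  structure(
    list(site_order = sites, local_dims = dims, total_dim = as.integer(total)),
    class = "composite_space"
  )
}

#' @export
print.composite_space <- function(x, ...) {
  cat(sprintf(
    "<composite_space: %d sites (%s), dims %s, total %d>\n",
    length(x$site_order), toString(x$site_order),
    toString(x$local_dims), x$total_dim
  ))
  invisible(x)
}

# Mixed-radix digits of every basis index: total_dim x n_sites matrix,
# digits in 0..(d_k - 1), site 1 most significant.
#' @noRd
basis_digits <- function(space) {
  n <- length(space$site_order)
  d <- space$local_dims
  strides <- rev(cumprod(rev(c(d[-1], 1))))
  idx <- 0:(space$total_dim - 1)
  vapply(seq_len(n), function(k) (idx %/% strides[k]) %% d[k], numeric(space$total_dim))
}

#' @noRd
site_positions <- function(space, sites) {
  pos <- match(sites, space$site_order)
  if (anyNA(pos)) {
    stop(
      sprintf("unknown site(s): %s", toString(sites[is.na(pos)])),
      call. = FALSE
    )
  }
  pos
}

# 0-based position of each basis state in the reordered (sub, rest) basis,
# where `sub` runs over the listed positions in their given order.
#' @noRd
reorder_index <- function(space, positions) {
  digits <- basis_digits(space)
  d <- space$local_dims
  rest_pos <- setdiff(seq_along(d), positions)
  radix_index <- function(pos) {
    if (length(pos) == 0) {
      return(rep(0, space$total_dim))
    }
    out <- rep(0, space$total_dim)
    for (k in pos) out <- out * d[k] + digits[, k]
    out
  }
  sub <- radix_index(positions)
  rest <- radix_index(rest_pos)
  rest_dim <- prod(d[rest_pos])
  list(q = sub * rest_dim + rest, rest_dim = rest_dim, sub_dim = prod(d[positions]))
}

#' Embed a local operator into the full composite space
#'
#' Places `op` (given on one or more sites, Kronecker-ordered as listed in
#' `sites`) into the full space, acting as the identity on every other
#' tensor factor.
#'
#' @param op complex matrix on the named sites (dimension must equal the
#'   product of their local dimensions).
#' @param sites character vector of site ids the operator acts on.
#' @param space a [composite_space()].
#' @return Complex `total_dim x total_dim` matrix.
#' @examples
#' sp <- composite_space(c("A", "B"))
#' embed_local(matrix(c(0, 1, 1, 0), 2, 2), "A", sp) # sigma_x on A
#' @export
embed_local <- function(op, sites, space) {
  op <- as_complex_matrix(op)
  pos <- site_positions(space, sites)
  sub_dim <- prod(space$local_dims[pos])
  if (nrow(op) != sub_dim || ncol(op) != sub_dim) {
    stop(
      sprintf(
        "operator dimension %dx%d does not match sites (%s) with product dimension %d",
        nrow(op), ncol(op), toString(sites), sub_dim
      ),
      call. = FALSE
    )
  }
  ri <- reorder_index(space, pos)
  k <- kronecker(op, complex_identity(ri$rest_dim))
  k[ri$q + 1, ri$q + 1]
}

#' Partial trace over a subset of sites
#'
#' Traces out every site not listed in `keep`, returning the reduced density
#' matrix on the kept sites (in their original `site_order` order). Trace and
#' Hermiticity are preserved exactly.
#'
#' @param rho a [density_matrix()] (or plain complex matrix on `space`).
#' @param keep nonempty character vector of site ids to retain.
#' @param space the [composite_space()] of `rho`; taken from `rho` when it is
#'   a `density_matrix`.
#' @return A [density_matrix()] on the kept sites.
#' @export
partial_trace <- function(rho, keep, space = NULL) {
  if (inherits(rho, "density_matrix")) {
    space <- rho$space
    m <- rho$matrix
  } else {
    if (is.null(space)) stop("`space` required for a bare matrix", call. = FALSE)
    m <- as_complex_matrix(rho)
  }
  if (length(keep) == 0) stop("`keep` must be nonempty", call. = FALSE)
  pos <- sort(site_positions(space, keep))
  kept_sites <- space$site_order[pos]
  sub_space <- composite_space(kept_sites, space$local_dims[pos])
  if (length(pos) == length(space$site_order)) {
    return(density_matrix(m, sub_space, validate = FALSE))
  }
  ri <- reorder_index(space, pos)
  s <- order(ri$q) # s[m] = original index of m-th reordered basis state
  m2 <- m[s, s]
  kdim <- ri$sub_dim
  rdim <- ri$rest_dim
  dim(m2) <- c(rdim, kdim, rdim, kdim)
  out <- matrix(0 + 0i, kdim, kdim)
  for (r in seq_len(rdim)) out <- out + m2[r, , r, ]
  density_matrix(out, sub_space, validate = FALSE)
}

#' Pure quantum network states
#'
#' A normalized complex amplitude vector over the composite basis.
#'
#' @param amplitudes complex vector of length `total_dim`; must be normalized
#'   to 1 within `1e-10`.
#' @param space a [composite_space()].
#' @return Object of class `pure_state`.
#' @export
pure_state <- function(amplitudes, space) {
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != space$total_dim) {
    stop("amplitude vector length must equal total_dim", call. = FALSE)
  }
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-10) {
    stop(sprintf("state not normalized: sum |amp|^2 = %.12g", nrm), call. = FALSE)
  }
  structure(list(amplitudes = amplitudes, space = space), class = "pure_state")
}

#' @export
print.pure_state <- function(x, ...) {
  cat(sprintf(
    "<pure_state on %d sites, dim %d>\n",
    length(x$space$site_order), x$space$total_dim
  ))
  invisible(x)
}

#' Basis product states and uniform-superposition states
#'
#' `basis_state()` builds `|digits>`; `plus_state()` builds the uniform
#' superposition of all local basis states on every site (for qubits,
#' `|+>^(x) n`).
#'
#' @param digits integer vector of local basis indices (0-based), one per site.
#' @param space a [composite_space()].
#' @return A [pure_state()].
#' @export
basis_state <- function(digits, space) {
  d <- space$local_dims
  stopifnot(length(digits) == length(d), all(digits >= 0), all(digits < d))
  strides <- rev(cumprod(rev(c(d[-1], 1))))
  idx <- sum(digits * strides) + 1
  amp <- rep(0 + 0i, space$total_dim)
  amp[idx] <- 1
  pure_state(amp, space)
}

#' @rdname basis_state
#' @export
plus_state <- function(space) {
  amp <- rep(1 / sqrt(space$total_dim) + 0i, space$total_dim)
  pure_state(amp, space)
}

#' Density matrices on a composite space
#'
#' Hermitian, trace-one, positive semidefinite complex matrices. Validation
#' tolerances: Hermiticity and trace within `1e-10`, eigenvalues `>= -1e-9`.
#' Invalid matrices are rejected with the worst violation named; see
#' [validate_density()] for a non-throwing report.
#'
#' @param matrix complex square matrix of dimension `total_dim`.
#' @param space a [composite_space()].
#' @param validate check the invariants (default `TRUE`). Internal code paths
#'   that preserve validity by construction may skip it.
#' @return Object of class `density_matrix` with fields `matrix`, `space`.
#' @export
density_matrix <- function(matrix, space, validate = TRUE) {
  m <- as_complex_matrix(matrix)
  if (nrow(m) != space$total_dim || ncol(m) != space$total_dim) {
    stop("matrix dimension must equal total_dim", call. = FALSE)
  }
  if (validate) {
    rep <- validate_density(m)
    if (!rep$valid) {
      stop(sprintf("invalid density matrix: %s", rep$message), call. = FALSE)
    }
  }
  structure(list(matrix = m, space = space), class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf(
    "<density_matrix on %d sites (%s), dim %d, purity %.4f>\n",
    length(x$space$site_order), toString(x$space$site_order),
    x$space$total_dim, purity(x)
  ))
  invisible(x)
}

#' Validate a candidate density matrix
#'
#' Checks Hermiticity (within `1e-10`), unit trace (within `1e-10`) and
#' positive semidefiniteness (eigenvalues `>= -1e-9`). Never throws: returns
#' a report naming the worst violation, so integrators can surface their own
#' diagnostics instead of clipping.
#'
#' @param m complex square matrix.
#' @param tol_herm,tol_trace,tol_psd violation tolerances.
#' @return List with `valid` (logical), `herm_violation`, `trace_violation`,
#'   `min_eigenvalue`, `message`.
#' @export
validate_density <- function(m, tol_herm = 1e-10, tol_trace = 1e-10,
                             tol_psd = 1e-9) {
  m <- as_complex_matrix(m)
  if (nrow(m) != ncol(m)) stop("expected a square matrix", call. = FALSE)
  herm <- max(Mod(m - dagger(m)))
  tr <- abs(sum(diag(m)) - 1)
  mineig <- min(herm_eigenvalues(m))
  problems <- character()
  if (herm > tol_herm) problems <- c(problems, sprintf("Hermiticity violation %.3g", herm))
  if (tr > tol_trace) problems <- c(problems, sprintf("trace violation %.3g", tr))
  if (mineig < -tol_psd) problems <- c(problems, sprintf("positivity violation: min eigenvalue %.3g", mineig))
  list(
    valid = length(problems) == 0,
    herm_violation = herm, trace_violation = tr, min_eigenvalue = mineig,
    message = if (length(problems)) paste(problems, collapse = "; ") else "ok"
  )
}

#' Density matrix of a pure state; purity of a density matrix
#'
#' @param psi a [pure_state()].
#' @return `pure_density()`: the rank-one [density_matrix()]
#'   `|psi><psi|`; `purity()`: the real scalar `Tr(rho^2)` (1 iff pure).
#' @export
pure_density <- function(psi) {
  stopifnot(inherits(psi, "pure_state"))
  density_matrix(outer(psi$amplitudes, Conj(psi$amplitudes)), psi$space,
    validate = FALSE
  )
}

#' @rdname pure_density
#' @param rho a [density_matrix()].
#' @export
purity <- function(rho) {
  m <- if (inherits(rho, "density_matrix")) rho$matrix else as_complex_matrix(rho)
  Re(sum(m * Conj(m)))
}

#' Random states for property testing
#'
#' `random_density()` draws from the Ginibre ensemble (`G G^dagger`
#' normalized to unit trace, full rank almost surely); `random_pure()` draws
#' a Haar-distributed pure state. Both use the current R RNG stream.
#'
#' @param space a [composite_space()].
#' @param rank optional rank of the Ginibre factor (default full).
#' @return A [density_matrix()] / [pure_state()].
#' @export
random_density <- function(space, rank = NULL) {
  d <- space$total_dim
  k <- if (is.null(rank)) d else as.integer(rank)
  g <- matrix(
    complex(
      real = stats::rnorm(d * k),
      imaginary = stats::rnorm(d * k)
    ),
    d, k
  )
  m <- g %*% dagger(g)
  density_matrix(m / Re(sum(diag(m))), space, validate = FALSE)
}

#' @rdname random_density
#' @export
random_pure <- function(space) {
  d <- space$total_dim
  a <- complex(real = stats::rnorm(d), imaginary = stats::rnorm(d))
  pure_state(a / sqrt(sum(Mod(a)^2)), space)
}

#' Serialize states and operators to a plain-JSON container
#'
#' The container holds `site_order`, `local_dims` and the flattened real and
#' imaginary parts (column-major); no binary format is involved.
#'
#' @param x a [density_matrix()], or a complex matrix plus `space`.
#' @param path file path to write / read.
#' @param space a [composite_space()] when `x` is a bare matrix.
#' @return `state_to_json()` returns `path` invisibly; `state_from_json()`
#'   returns a [density_matrix()].
#' @export
state_to_json <- function(x, path, space = NULL) {
  if (inherits(x, "density_matrix")) {
    space <- x$space
    m <- x$matrix
  } else {
    if (is.null(space)) stop("`space` required for a bare matrix", call. = FALSE)
    m <- as_complex_matrix(x)
  }
  obj <- list(
    site_order = space$site_order,
    local_dims = space$local_dims,
    dim = nrow(m),
    re = as.numeric(Re(m)),
    im = as.numeric(Im(m))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname state_to_json
#' @export
state_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- composite_space(obj$site_order, obj$local_dims)
  m <- matrix(complex(real = obj$re, imaginary = obj$im), obj$dim, obj$dim)
  density_matrix(m, sp)
}
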