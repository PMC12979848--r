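#' Pauli matrices
#'
#' @param which one of `"x"`, `"y"`, `"z"`, `"i"` (identity), `"sm"`
#'   (lowering operator `|0><1|`), `"sp"` (raising `|1><0|`).
#' @return A 2x2 complex matrix. Sign convention: `sigma_z |0> = +|0>`,
#'   `sigma_z |1> = -|1>`, with `|0>` the ground/closed and `|1>` the
#'   binding-competent conformation.
#' @export
pauli <- function(which = c("x", "y", "z", "i", "sm", "sp")) {
  which <- match.arg(which)
  switch(which,
    x = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    y = matrix(c(0, 1i, -1i, 0), 2, 2),
    z = diag(c(1, -1)) + 0i,
    i = complex_identity(2),
    sm = matrix(c(0, 0, 1, 0), 2, 2) + 0i, # |0><1| (column-major)
    sp = matrix(c(0, 1, 0, 0), 2, 2) + 0i # |1><0|
  )
}

#' Quantum-enhanced graph Laplacian on the vertex space
#'
#' The classical Laplacian `L = D - A` plus an on-site quantum correction
#' `hbar * diag(omega)`: a real symmetric `n x n` matrix on the
#' n-dimensional vertex space. With all `omega` equal the spectrum is that
#' of `L` shifted by `hbar * omega`; with `hbar = 0` it reduces to the
#' classical Laplacian.
#'
#' @param g a [protein_graph()].
#' @param omegas per-vertex frequencies: a single number, or a (possibly
#'   partially) named numeric vector; unnamed vertices default to 0.
#' @param hbar Planck constant convention (default 1, natural units; only
#'   the products `hbar * omega` matter).
#' @return Real symmetric `n x n` matrix.
#' @export
quantum_enhanced_laplacian <- function(g, omegas = 0, hbar = 1) {
  classical_laplacian(g) + hbar * diag(resolve_omegas(g$vertices, omegas),
    nrow = length(g$vertices)
  )
}

#' @noRd
resolve_omegas <- function(vertices, omegas) {
  out <- stats::setNames(rep(0, length(vertices)), vertices)
  if (is.null(omegas)) {
    return(out)
  }
  if (is.null(names(omegas))) {
    out[] <- rep_len(as.numeric(omegas), length(vertices))
  } else {
    unknown <- setdiff(names(omegas), vertices)
    if (length(unknown) > 0) {
      stop(sprintf("omegas name unknown vertices: %s", toString(unknown)), call. = FALSE)
    }
    out[names(omegas)] <- as.numeric(omegas)
  }
  out
}

#' Quantum swap operator between two sites
#'
#' The unitary permuting the tensor factors of sites `i` and `j`:
#' `P |...a...b...> = |...b...a...>` on the computational basis. `P` is
#' Hermitian, unitary and involutive (`P^2 = I`); product states of the form
#' `|psi> (x) |psi>` on the two sites are fixed points.
#'
#' @param space a [composite_space()].
#' @param i,j distinct site identifiers with equal local dimensions.
#' @return Complex `total_dim x total_dim` permutation matrix.
#' @export
swap_operator <- function(space, i, j) {
  pos <- site_positions(space, c(i, j))
  if (pos[1] == pos[2]) stop("swap sites must be distinct", call. = FALSE)
  d <- space$local_dims
  if (d[pos[1]] != d[pos[2]]) {
    stop("swap requires equal local dimensions on both sites", call. = FALSE)
  }
  digits <- basis_digits(space)
  swapped <- digits
  swapped[, pos[1]] <- digits[, pos[2]]
  swapped[, pos[2]] <- digits[, pos[1]]
  strides <- rev(cumprod(rev(c(d[-1], 1))))
  target <- as.vector(swapped %*% strides) + 1
  p <- matrix(0 + 0i, space$total_dim, space$total_dim)
  p[cbind(target, seq_len(space$total_dim))] <- 1
  p
}

#' Specification of the extended quantum graph Laplacian
#'
#' Bundles the ingredients of the many-body graph Laplacian: edge weights
#' `W_ij`, on-site frequencies `omega_i` and the `hbar` convention.
#'
#' @inheritParams quantum_enhanced_laplacian
#' @return Object of class `extended_laplacian_spec`.
#' @export
extended_laplacian_spec <- function(g, omegas = 0, hbar = 1) {
  stopifnot(inherits(g, "protein_graph"), hbar >= 0)
  structure(
    list(graph = g, omegas = resolve_omegas(g$vertices, omegas), hbar = hbar),
    class = "extended_laplacian_spec"
  )
}

#' Extended quantum graph Laplacian (many-body)
#'
#' Builds the operator
#' `sum_{(i,j) in E} W_ij (I - P_ij)  +  sum_i hbar omega_i sigma_z^(i)`
#' on the composite space: the topological term measures quantum distance
#' between adjacent proteins through swap operators (it annihilates states
#' with `|psi_i> = |psi_j>` across every edge, in particular all symmetric
#' product states when `omega = 0`), and the on-site term encodes
#' conformational energy differences. The topological part is positive
#' semidefinite; the whole operator is Hermitian.
#'
#' The `sigma_z` term presumes two-level sites: a nonzero `omega_i` on a
#' site with local dimension other than 2 is an error.
#'
#' @param spec an [extended_laplacian_spec()] (or a [protein_graph()], which
#'   is promoted with default frequencies).
#' @param space a [composite_space()] covering all graph vertices. Defaults
#'   to qubits over the graph's vertices.
#' @return Complex Hermitian `total_dim x total_dim` matrix.
#' @export
extended_quantum_laplacian <- function(spec, space = NULL) {
  if (inherits(spec, "protein_graph")) spec <- extended_laplacian_spec(spec)
  stopifnot(inherits(spec, "extended_laplacian_spec"))
  g <- spec$graph
  if (is.null(space)) space <- composite_space(g$vertices)
  site_positions(space, g$vertices) # all vertices must be present
  d <- space$total_dim
  h <- matrix(0 + 0i, d, d)
  id <- complex_identity(d)
  for (k in seq_len(nrow(g$edges))) {
    h <- h + g$edges$weight[k] *
      (id - swap_operator(space, g$edges$from[k], g$edges$to[k]))
  }
  nz <- names(spec$omegas)[spec$omegas != 0]
  for (v in nz) {
    pos <- site_positions(space, v)
    if (space$local_dims[pos] != 2) {
      stop(
        sprintf(
          "on-site frequency on '%s' requires a two-level site (local dim is %d)",
          v, space$local_dims[pos]
        ),
        call. = FALSE
      )
    }
    h <- h + spec$hbar * spec$omegas[[v]] * embed_local(pauli("z"), v, space)
  }
  h
}

#' @noRd
edge_key <- function(i, j) paste(i, j, sep = " -> ")

#' Quantum graph gradient of a vertex operator field
#'
#' For a field `f` assigning an operator on one shared space to every
#' vertex, the gradient at directed edge `(i, j)` is
#' `sqrt(W_ij) * (f(j) %*% f(i) - f(i) %*% f(j))` -- the commutator
#' `[f(j), f(i)]` scaled by the square-rooted edge weight. It is
#' antisymmetric under orientation reversal and vanishes when the two
#' operators commute.
#'
#' @param f named list mapping every vertex of `g` to a complex matrix, all
#'   of one shared dimension. Site-local operators can be lifted to the
#'   shared space with [embed_local()] first.
#' @param g a [protein_graph()].
#' @return Named list of matrices keyed `"i -> j"`, both orientations of
#'   every edge.
#' @export
quantum_gradient <- function(f, g) {
  missing <- setdiff(g$vertices, names(f))
  if (length(missing) > 0) {
    stop(sprintf("vertex operators missing for: %s", toString(missing)), call. = FALSE)
  }
  out <- list()
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$from[k]
    j <- g$edges$to[k]
    sw <- sqrt(g$edges$weight[k])
    fi <- as_complex_matrix(f[[i]])
    fj <- as_complex_matrix(f[[j]])
    grad <- sw * (fj %*% fi - fi %*% fj)
    out[[edge_key(i, j)]] <- grad
    out[[edge_key(j, i)]] <- -grad
  }
  out
}

#' Quantum graph divergence of an edge operator field
#'
#' For a field `F` on directed edges, the divergence at vertex `i` is
#' `sum_{j ~ i} sqrt(W_ij) * (F(i,j) %*% rho_i + rho_i %*% F(i,j))` -- the
#' anticommutator of each incident edge operator (center vertex first) with
#' the local density operator, weight-scaled. Hermitian edge operators give
#' Hermitian divergences. Isolated vertices get the zero matrix.
#'
#' @param F named list of matrices keyed `"i -> j"` (as produced by
#'   [quantum_gradient()]); the orientation with `i` the center vertex is
#'   used.
#' @param g a [protein_graph()].
#' @param rho_local named list mapping each vertex to its local density
#'   operator on the shared space ([density_matrix()] or plain matrix).
#' @return Named list mapping each vertex to a complex matrix.
#' @export
quantum_divergence <- function(F, g, rho_local) {
  get_rho <- function(v) {
    r <- rho_local[[v]]
    if (is.null(r)) stop(sprintf("no local density for vertex '%s'", v), call. = FALSE)
    if (inherits(r, "density_matrix")) r$matrix else as_complex_matrix(r)
  }
  out <- list()
  for (v in g$vertices) {
    inc <- which(g$edges$from == v | g$edges$to == v)
    rho <- get_rho(v)
    acc <- matrix(0 + 0i, nrow(rho), ncol(rho))
    for (k in inc) {
      j <- if (g$edges$from[k] == v) g$edges$to[k] else g$edges$from[k]
      fk <- F[[edge_key(v, j)]]
      if (is.null(fk)) {
        stop(sprintf("edge operator missing for %s", edge_key(v, j)), call. = FALSE)
      }
      fk <- as_complex_matrix(fk)
      acc <- acc + sqrt(g$edges$weight[k]) * (fk %*% rho + rho %*% fk)
    }
    out[[v]] <- acc
  }
  out
}
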