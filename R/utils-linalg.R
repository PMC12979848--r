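# Dense complex linear algebra helpers shared across the package.
# Everything here works on plain base-R complex matrices.

#' Conjugate transpose
#' @param m complex matrix.
#' @return The Hermitian adjoint of `m`.
#' @keywords internal
#' @noRd
dagger <- function(m) Conj(t(m))

#' @noRd
frobenius_norm <- function(m) sqrt(sum(Mod(m)^2))

#' @noRd
is_hermitian <- function(m, tol = 1e-10) {
  max(Mod(m - dagger(m))) <= tol
}

#' @noRd
hermitize <- function(m) (m + dagger(m)) / 2

# Eigenvalues of a (numerically) Hermitian matrix, descending, real.
#' @noRd
herm_eigenvalues <- function(m) {
  eigen(hermitize(m), symmetric = TRUE, only.values = TRUE)$values
}

#' @noRd
as_complex_matrix <- function(m) {
  if (!is.matrix(m)) stop("expected a matrix", call. = FALSE)
  if (!is.complex(m)) {
    storage.mode(m) <- "double"
    m <- m + 0i
  }
  m
}

#' @noRd
complex_identity <- function(n) diag(n) + 0i

#' Matrix exponential of a complex square matrix
#'
#' Scaling-and-squaring with a degree-13 Pade approximant. Base R and the
#' recommended packages only exponentiate real matrices; Liouvillians are
#' complex and non-Hermitian, so this is implemented here.
#'
#' @param m complex (or real) square matrix.
#' @return `exp(m)` as a complex matrix.
#' @examples
#' expm_c(matrix(c(0, 1i, 1i, 0), 2, 2))
#' @export
expm_c <- function(m) {
  m <- as_complex_matrix(m)
  n <- nrow(m)
  if (n != ncol(m)) stop("expm_c() requires a square matrix", call. = FALSE)
  if (n == 1L) return(matrix(exp(m[1, 1]), 1, 1))
  # Pade-13 coefficients (Higham 2005)
  b <- c(
    64764752532480000, 32382376266240000, 7771770303897600,
    1187353796428800, 129060195264000, 10559470521600, 670442572800,
    33522128640, 1323241920, 40840800, 960960, 16380, 182, 1
  )
  theta13 <- 5.371920351148152
  nrm <- max(colSums(Mod(m)))  # 1-norm
  s <- 0L
  if (nrm > theta13) {
    s <- ceiling(log2(nrm / theta13))
    m <- m / 2^s
  }
  id <- complex_identity(n)
  m2 <- m %*% m
  m4 <- m2 %*% m2
  m6 <- m4 %*% m2
  u <- m %*% (m6 %*% (b[14] * m6 + b[12] * m4 + b[10] * m2) +
    b[8] * m6 + b[6] * m4 + b[4] * m2 + b[2] * id)
  v <- m6 %*% (b[13] * m6 + b[11] * m4 + b[9] * m2) +
    b[7] * m6 + b[5] * m4 + b[3] * m2 + b[1] * id
  f <- solve(v - u, v + u)
  if (s > 0) for (k in seq_len(s)) f <- f %*% f
  f
}

# Trapezoid-rule weights for a (possibly non-uniform) increasing grid.
#' @noRd
trapezoid_weights <- function(times) {
  n <- length(times)
  if (n < 2L) stop("trapezoid rule needs at least two grid points", call. = FALSE)
  d <- diff(times)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

# Run code with a temporarily-seeded RNG, restoring global state after.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
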