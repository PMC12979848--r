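# Independent brute-force oracles, deliberately written with naive index
# loops so they share no code path with the package implementations.

# partial trace by explicit double-index summation
pt_oracle <- function(m, space, keep_pos) {
  dims <- space$local_dims
  n <- length(dims)
  digits_of <- function(idx0) {
    out <- integer(n)
    for (k in n:1) {
      out[k] <- idx0 %% dims[k]
      idx0 <- idx0 %/% dims[k]
    }
    out
  }
  index_of <- function(dg) {
    idx <- 0
    for (k in seq_len(n)) idx <- idx * dims[k] + dg[k]
    idx
  }
  rest_pos <- setdiff(seq_len(n), keep_pos)
  kdim <- prod(dims[keep_pos])
  out <- matrix(0 + 0i, kdim, kdim)
  all_digits <- lapply(0:(prod(dims) - 1), digits_of)
  sub_index <- function(dg, pos) {
    idx <- 0
    for (k in pos) idx <- idx * dims[k] + dg[k]
    idx
  }
  for (a in seq_along(all_digits)) {
    for (b in seq_along(all_digits)) {
      da <- all_digits[[a]]
      db <- all_digits[[b]]
      if (!identical(da[rest_pos], db[rest_pos])) next
      out[sub_index(da, keep_pos) + 1, sub_index(db, keep_pos) + 1] <-
        out[sub_index(da, keep_pos) + 1, sub_index(db, keep_pos) + 1] + m[a, b]
    }
  }
  out
}

# operator embedding by explicit basis-pair loop
embed_oracle <- function(op, space, op_pos) {
  dims <- space$local_dims
  n <- length(dims)
  d <- prod(dims)
  digits_of <- function(idx0) {
    out <- integer(n)
    for (k in n:1) {
      out[k] <- idx0 %% dims[k]
      idx0 <- idx0 %/% dims[k]
    }
    out
  }
  sub_index <- function(dg, pos) {
    idx <- 0
    for (k in pos) idx <- idx * dims[k] + dg[k]
    idx
  }
  rest_pos <- setdiff(seq_len(n), op_pos)
  out <- matrix(0 + 0i, d, d)
  for (a in 1:d) {
    for (b in 1:d) {
      da <- digits_of(a - 1)
      db <- digits_of(b - 1)
      if (!identical(da[rest_pos], db[rest_pos])) next
      out[a, b] <- op[sub_index(da, op_pos) + 1, sub_index(db, op_pos) + 1]
    }
  }
  out
}

# extended quantum graph Laplacian by direct basis construction
ext_laplacian_oracle <- function(g, space, omegas = NULL, hbar = 1) {
  dims <- space$local_dims
  n <- length(dims)
  d <- prod(dims)
  digits_of <- function(idx0) {
    out <- integer(n)
    for (k in n:1) {
      out[k] <- idx0 %% dims[k]
      idx0 <- idx0 %/% dims[k]
    }
    out
  }
  index_of <- function(dg) {
    idx <- 0
    for (k in seq_len(n)) idx <- idx * dims[k] + dg[k]
    idx + 1
  }
  h <- matrix(0 + 0i, d, d)
  for (e in seq_len(nrow(g$edges))) {
    pi_ <- match(g$edges$from[e], space$site_order)
    pj <- match(g$edges$to[e], space$site_order)
    w <- g$edges$weight[e]
    for (col in 1:d) {
      dg <- digits_of(col - 1)
      sw <- dg
      sw[c(pi_, pj)] <- dg[c(pj, pi_)]
      h[col, col] <- h[col, col] + w
      h[index_of(sw), col] <- h[index_of(sw), col] - w
    }
  }
  if (!is.null(omegas)) {
    for (v in names(omegas)) {
      pv <- match(v, space$site_order)
      for (col in 1:d) {
        dg <- digits_of(col - 1)
        z <- if (dg[pv] == 0) 1 else -1
        h[col, col] <- h[col, col] + hbar * omegas[[v]] * z
      }
    }
  }
  h
}

# AUC as the fraction of positive/negative pairs ranked correctly
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# shannon entropy of a probability vector
shannon_oracle <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p) / log(base))
}

random_graph <- function(n, p = 0.4, weighted = TRUE) {
  v <- paste0("v", seq_len(n))
  cmb <- utils::combn(n, 2)
  keep <- stats::runif(ncol(cmb)) < p
  if (!any(keep)) keep[1] <- TRUE
  protein_graph(
    data.frame(
      from = v[cmb[1, keep]], to = v[cmb[2, keep]],
      weight = if (weighted) stats::runif(sum(keep), 0.2, 2) else 1
    ),
    vertices = v
  )
}

qubit_space <- function(n) composite_space(paste0("q", seq_len(n)))

frob <- function(a, b) sqrt(sum(Mod(a - b)^2))
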