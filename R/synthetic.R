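#' Synthetic modular networks with planted interactions
#'
#' Generates a planted-partition (stochastic block model) protein graph: `n`
#' vertices split as evenly as possible into modules, each unordered pair
#' connected independently with probability `p_intra` (same module) or
#' `p_inter` (different modules), unit edge weights. Every vertex receives a
#' feature vector equal to its module centroid (standard-normal entries) plus
#' isotropic Gaussian noise of scale `feature_noise`, so intra-module pairs
#' are feature-similar and inter-module pairs are not -- emulating the
#' assortative structure and correlated evidence found in curated interaction
#' databases, at desk scale.
#'
#' Candidate pairs for link-prediction evaluation are planted among the
#' *non*-edges: positives are sampled intra-module non-edges (structurally
#' plausible missing interactions), negatives are sampled inter-module
#' non-edges.
#'
#' @param n_vertices number of proteins.
#' @param n_modules number of modules; must not exceed `n_vertices`.
#' @param p_intra,p_inter edge probabilities, `p_intra >= p_inter`.
#' @param feature_dim length of the per-vertex feature vectors.
#' @param feature_noise standard deviation of the feature noise around the
#'   module centroid.
#' @param n_pairs number of positive and of negative candidate pairs to
#'   sample (each capped by availability).
#' @param seed integer seed; the same spec is bitwise-reproducible.
#' @return A `synthetic_spec` (for `synthetic_spec()`), or for
#'   [generate_synthetic_network()] a list of class `synthetic_network` with
#'   elements `graph` (a [protein_graph()] carrying features and modules),
#'   `positives` and `negatives` (tibbles with columns `a`, `b`).
#' @examples
#' net <- generate_synthetic_network(synthetic_spec(n_vertices = 20, seed = 1))
#' net$graph
#' @export
synthetic_spec <- function(n_vertices = 24, n_modules = 3, p_intra = 0.5,
                           p_inter = 0.05, feature_dim = 8,
                           feature_noise = 0.5, n_pairs = 20, seed = 1) {
  stopifnot(
    n_vertices >= 2, n_modules >= 1, n_modules <= n_vertices,
    p_intra >= 0, p_intra <= 1, p_inter >= 0, p_inter <= 1,
    feature_dim >= 1, feature_noise >= 0, n_pairs >= 1
  )
  if (p_intra < p_inter) {
    stop("planted structure must be assortative: p_intra >= p_inter", call. = FALSE)
  }
  structure(
    list(
      n_vertices = as.integer(n_vertices), n_modules = as.integer(n_modules),
      p_intra = p_intra, p_inter = p_inter,
      feature_dim = as.integer(feature_dim), feature_noise = feature_noise,
      n_pairs = as.integer(n_pairs), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @param spec a [synthetic_spec()].
#' @export
generate_synthetic_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_vertices
    vertices <- sprintf("P%03d", seq_len(n))
    modules <- stats::setNames(sort(rep_len(seq_len(spec$n_modules), n)), vertices)

    pairs <- utils::combn(n, 2)
    same <- modules[pairs[1, ]] == modules[pairs[2, ]]
    p <- ifelse(same, spec$p_intra, spec$p_inter)
    drawn <- stats::runif(ncol(pairs)) < p

    edges <- tibble::tibble(
      from = vertices[pairs[1, drawn]],
      to = vertices[pairs[2, drawn]],
      weight = 1
    )

    centroids <- matrix(stats::rnorm(spec$n_modules * spec$feature_dim),
      nrow = spec$n_modules
    )
    features <- centroids[modules, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$feature_dim, sd = spec$feature_noise), nrow = n)
    rownames(features) <- vertices

    g <- protein_graph(edges,
      vertices = vertices, features = features,
      modules = modules
    )

    non <- !drawn
    pos_pool <- which(non & same)
    neg_pool <- which(non & !same)
    if (length(pos_pool) == 0 || length(neg_pool) == 0) {
      stop(
        "spec yields an empty positive or negative candidate set; ",
        "adjust sizes or edge probabilities",
        call. = FALSE
      )
    }
    take <- function(pool) {
      k <- min(spec$n_pairs, length(pool))
      sel <- if (length(pool) == 1L) pool else sample(pool, k)
      tibble::tibble(a = vertices[pairs[1, sel]], b = vertices[pairs[2, sel]])
    }
    structure(
      list(graph = g, positives = take(pos_pool), negatives = take(neg_pool)),
      class = "synthetic_network"
    )
  })
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf(
    "<synthetic_network: %d vertices, %d edges, %d planted positives, %d negatives>\n",
    length(x$graph$vertices), nrow(x$graph$edges),
    nrow(x$positives), nrow(x$negatives)
  ))
  invisible(x)
}
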