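#' Weighted protein interaction graphs
#'
#' A `protein_graph` is the classical substrate of the package: an undirected
#' weighted graph over named proteins, optionally carrying per-protein feature
#' vectors and module (community) labels. Vertex order is canonical --
#' first-appearance order from the input -- and every matrix built from the
#' graph (adjacency, Laplacians, many-body operators) indexes by this order.
#'
#' @param edges a data frame with columns `from`, `to` and optionally
#'   `weight` (positive interaction strength, default 1). Self-loops are
#'   rejected; duplicate edges with conflicting weights are an error, because
#'   conflicting interaction evidence should be resolved explicitly upstream.
#' @param vertices optional character vector fixing the vertex set and order;
#'   defaults to first-appearance order in `edges`. May include isolated
#'   vertices absent from `edges`.
#' @param features optional numeric matrix of per-protein feature vectors,
#'   one row per vertex (rownames = vertex ids), all rows the same length.
#' @param modules optional named integer vector of module labels, names =
#'   vertex ids.
#' @return An object of class `protein_graph` with fields `vertices`,
#'   `edges` (a tibble `from`, `to`, `weight`), `features`, `modules`.
#' @examples
#' g <- protein_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' classical_laplacian(g)
#' @export
protein_graph <- function(edges, vertices = NULL, features = NULL,
                          modules = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)

  if (any(edges$from == edges$to)) {
    bad <- which(edges$from == edges$to)[1]
    stop(sprintf("self-loop on vertex '%s' is not allowed", edges$from[bad]),
      call. = FALSE
    )
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop("all edge weights must be finite and > 0", call. = FALSE)
  }

  seen <- unique(c(rbind(edges$from, edges$to)))
  if (is.null(vertices)) {
    vertices <- seen
  } else {
    vertices <- as.character(vertices)
    if (anyDuplicated(vertices)) stop("vertex identifiers must be unique", call. = FALSE)
    missing <- setdiff(seen, vertices)
    if (length(missing) > 0) {
      stop(
        sprintf("edge endpoints not in vertex set: %s", toString(missing)),
        call. = FALSE
      )
    }
  }

  # canonical unordered representation: endpoint with smaller canonical index first
  idx <- stats::setNames(seq_along(vertices), vertices)
  a <- ifelse(idx[edges$from] <= idx[edges$to], edges$from, edges$to)
  b <- ifelse(idx[edges$from] <= idx[edges$to], edges$to, edges$from)
  edges <- tibble::tibble(from = a, to = b, weight = edges$weight)
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(edges$weight, key, function(w) length(unique(w)))
    if (any(agg > 1)) {
      bad <- sub("\r", " -- ", names(agg)[agg > 1][1])
      stop(
        sprintf("duplicate edge '%s' with conflicting weights", bad),
        call. = FALSE
      )
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- dplyr::arrange(edges, idx[.data$from], idx[.data$to])

  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (is.null(rownames(features))) {
      if (nrow(features) != length(vertices)) {
        stop("`features` must have one row per vertex", call. = FALSE)
      }
      rownames(features) <- vertices
    }
    missing <- setdiff(vertices, rownames(features))
    if (length(missing) > 0) {
      stop(sprintf("features missing for: %s", toString(missing)), call. = FALSE)
    }
    features <- features[vertices, , drop = FALSE]
  }
  if (!is.null(modules)) {
    modules <- stats::setNames(as.integer(modules), names(modules))
    missing <- setdiff(vertices, names(modules))
    if (length(missing) > 0) {
      stop(sprintf("module labels missing for: %s", toString(missing)), call. = FALSE)
    }
    modules <- modules[vertices]
  }

  structure(
    list(
      vertices = vertices, edges = edges,
      features = features, modules = modules
    ),
    class = "protein_graph"
  )
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf(
    "<protein_graph: %d vertices, %d edges%s%s>\n",
    length(x$vertices), nrow(x$edges),
    if (!is.null(x$features)) sprintf(", %d features/vertex", ncol(x$features)) else "",
    if (!is.null(x$modules)) sprintf(", %d modules", length(unique(x$modules))) else ""
  ))
  print(x$edges, n = 6)
  invisible(x)
}

#' @export
as_tibble.protein_graph <- function(x, ...) x$edges

#' Number of vertices / vertex identifiers
#' @param g a [protein_graph()].
#' @return `graph_vertices()` the character vector of vertex ids in canonical
#'   order; `n_vertices()` its length.
#' @export
graph_vertices <- function(g) g$vertices

#' @rdname graph_vertices
#' @export
n_vertices <- function(g) length(g$vertices)

#' Weighted adjacency, degree and Laplacian matrices
#'
#' `classical_laplacian()` returns `L = D - A` with `A` the weighted adjacency
#' matrix and `D` the diagonal matrix of weighted degrees. `L` is symmetric
#' positive semidefinite with zero row sums; the multiplicity of its zero
#' eigenvalue equals the number of connected components.
#'
#' @param g a [protein_graph()].
#' @return A real symmetric `n x n` matrix indexed by canonical vertex order.
#' @export
adjacency_matrix <- function(g) {
  n <- length(g$vertices)
  a <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  if (nrow(g$edges) > 0) {
    i <- match(g$edges$from, g$vertices)
    j <- match(g$edges$to, g$vertices)
    a[cbind(i, j)] <- g$edges$weight
    a[cbind(j, i)] <- g$edges$weight
  }
  a
}

#' @rdname adjacency_matrix
#' @export
classical_laplacian <- function(g) {
  a <- adjacency_matrix(g)
  diag(rowSums(a)) - a
}

#' Read a weighted edge list from a plain-text file
#'
#' One edge per line: `node_a node_b [weight]`, whitespace separated; lines
#' starting with `#` and blank lines are ignored. A missing third field
#' defaults to weight 1. Vertex order is first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param directed if `TRUE`, the two orientations of a pair are merged after
#'   checking that their weights agree; storage is always undirected.
#' @return A [protein_graph()].
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("edge list contains no edges", call. = FALSE)
  rows <- lapply(keep, function(ln) {
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (!length(parts) %in% c(2L, 3L)) {
      stop(sprintf("line %d: expected 2 or 3 fields, got %d", ln, length(parts)),
        call. = FALSE
      )
    }
    w <- if (length(parts) == 3L) suppressWarnings(as.numeric(parts[3])) else 1
    if (is.na(w)) {
      stop(sprintf("line %d: weight '%s' is not numeric", ln, parts[3]), call. = FALSE)
    }
    if (w <= 0) {
      stop(sprintf("line %d: weight must be > 0, got %g", ln, w), call. = FALSE)
    }
    tibble::tibble(from = parts[1], to = parts[2], weight = w)
  })
  edges <- dplyr::bind_rows(rows)
  vertices <- unique(c(rbind(edges$from, edges$to)))
  protein_graph(edges, vertices = vertices)
}

#' Read per-protein feature vectors from a TSV file
#'
#' First column: vertex id; remaining columns: numeric features. A header row
#' is expected.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix with vertex ids as rownames.
#' @export
read_node_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a module-assignment table (vertex, module) from a TSV file
#' @param path path to the TSV file (no header required; two columns).
#' @return Named integer vector of module labels.
#' @export
read_module_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (is.character(df[[1]]) && df[[1]][1] %in% c("vertex", "node", "protein")) {
    df <- df[-1, , drop = FALSE]
  }
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Write ranked interaction predictions to TSV
#'
#' Output columns are `protein_a`, `protein_b`, `p_interaction`, `predicted`,
#' sorted by descending probability with ties broken lexicographically by
#' `(protein_a, protein_b)`.
#'
#' @param predictions a data frame with columns `protein_a`, `protein_b`,
#'   `p_interaction` (in `[0, 1]`) and `predicted` (0/1).
#' @param path output file path.
#' @return The sorted tibble, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("protein_a", "protein_b", "p_interaction", "predicted")
  if (!all(need %in% names(predictions))) {
    stop(sprintf("predictions must have columns: %s", toString(need)), call. = FALSE)
  }
  p <- predictions$p_interaction
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p_interaction values must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(predictions[, need]) |>
    dplyr::arrange(
      dplyr::desc(.data$p_interaction), .data$protein_a, .data$protein_b
    )
  ok <- tryCatch(
    {
      utils::write.table(out, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
      )
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)), call. = FALSE)
  invisible(out)
}

#' Multilayer protein networks
#'
#' A thin container for several interaction layers (physical, genetic,
#' functional, ...) over one shared vertex set. Layers are full
#' [protein_graph()] objects; no cross-layer fusion is performed.
#'
#' @param layers list of [protein_graph()] objects with identical vertex lists.
#' @param layer_names optional character vector of layer names.
#' @return An object of class `multilayer_network`.
#' @export
multilayer_network <- function(layers, layer_names = NULL) {
  if (length(layers) < 1) stop("need at least one layer", call. = FALSE)
  v0 <- layers[[1]]$vertices
  same <- vapply(layers, function(l) identical(l$vertices, v0), logical(1))
  if (!all(same)) stop("all layers must share one vertex list", call. = FALSE)
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_along(layers))
  if (length(layer_names) != length(layers)) {
    stop("layer_names must match layers in length", call. = FALSE)
  }
  structure(list(layers = layers, layer_names = layer_names),
    class = "multilayer_network"
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf(
    "<multilayer_network: %d layers (%s), %d vertices>\n",
    length(x$layers), toString(x$layer_names), length(x$layers[[1]]$vertices)
  ))
  invisible(x)
}
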