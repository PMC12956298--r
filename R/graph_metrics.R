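#' Onnela weighted clustering coefficient
#'
#' Per-node triangle intensity for a weighted undirected graph. Weights are
#' normalized by the matrix-wide maximum, and each triangle contributes the
#' geometric mean of its three normalized weights:
#' \deqn{C_i = \frac{\sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}}{k_i (k_i - 1)}}
#' where \eqn{k_i} counts the strictly positive edges at node i and the sum
#' runs over ordered neighbour pairs. Nodes with fewer than two neighbours
#' get C = 0. Structurally missing pairs carry weight 0 and therefore act
#' as absent edges.
#'
#' @param matrix a filtered nonnegative [connectivity_matrix()], or a plain
#'   symmetric nonnegative matrix.
#' @return named numeric vector of per-node clustering values in \[0, 1\].
#' @export
weighted_clustering <- function(matrix) {
  w <- if (inherits(matrix, "connectivity_matrix")) matrix$weights else as.matrix(matrix)
  if (any(w < 0)) stop("weights must be nonnegative; filter the matrix first")
  n <- nrow(w)
  k <- rowSums(w > 0)
  mx <- max(w)
  cl <- rep(0, n)
  if (mx > 0) {
    wh <- (w / mx)^(1 / 3)
    num <- diag(wh %*% wh %*% wh)     # 2 x sum over unordered triangles at i
    denom <- k * (k - 1)
    ok <- denom > 0
    cl[ok] <- num[ok] / denom[ok]
  }
  names(cl) <- rownames(w)
  cl
}

#' Weighted shortest-path distances
#'
#' Maps each positive weight to a connection length 1/w and runs Dijkstra's
#' algorithm over all node pairs. Absent (zero-weight or structurally
#' missing) edges have no direct length; unreachable pairs get `Inf`.
#'
#' @param matrix a filtered nonnegative [connectivity_matrix()] or plain
#'   symmetric nonnegative matrix.
#' @return symmetric matrix of shortest-path lengths, zero diagonal.
#' @export
weighted_shortest_paths <- function(matrix) {
  w <- if (inherits(matrix, "connectivity_matrix")) matrix$weights else as.matrix(matrix)
  if (any(w < 0)) stop("weights must be nonnegative; filter the matrix first")
  if (is.null(rownames(w)))
    rownames(w) <- colnames(w) <- sprintf("n%03d", seq_len(nrow(w)))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
    diag(d) <- 0
    return(d)
  }
  ## vertex order equals matrix order, so the result inherits the node order
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Nodal global efficiency
#'
#' \deqn{E_i = \frac{1}{n-1} \sum_{j \ne i} 1/d_{ij}} with \eqn{1/\infty = 0},
#' where d is the weighted shortest-path matrix. Quantifies how efficiently
#' node i exchanges information with the rest of the network.
#'
#' @param d distance matrix from [weighted_shortest_paths()].
#' @return named numeric vector of per-node efficiencies.
#' @export
nodal_global_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes for efficiency")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  names(eff) <- rownames(d)
  eff
}

#' Nodal metrics bundle
#'
#' Computes the two small-world metrics used as model covariates —
#' clustering (segregation) and nodal global efficiency (integration) —
#' plus the positive-edge degree, for one subject's filtered connectome.
#'
#' @param matrix a filtered nonnegative [connectivity_matrix()].
#' @return data.frame (node_id, clustering, efficiency, degree).
#' @export
compute_nodal_metrics <- function(matrix) {
  cl <- weighted_clustering(matrix)
  eff <- nodal_global_efficiency(weighted_shortest_paths(matrix))
  deg <- rowSums(matrix$weights > 0)
  data.frame(node_id = matrix$nodes, clustering = as.numeric(cl),
             efficiency = as.numeric(eff), degree = as.integer(deg),
             stringsAsFactors = FALSE)
}

#' Write per-subject nodal metrics as TSV
#' @param metrics data.frame from [compute_nodal_metrics()].
#' @param path file path.
#' @export
write_nodal_metrics <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
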