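#' Construct a connectivity matrix
#'
#' A per-subject weighted functional connectome: a symmetric zero-diagonal
#' weight matrix plus a symmetric logical mask marking structurally missing
#' pairs (region pairs excluded from network construction, e.g. centroids
#' closer than the distance threshold). Structurally missing pairs always
#' carry weight 0 and are distinct from observed zero weights.
#'
#' @param weights symmetric numeric matrix, zero diagonal, dimnames = node
#'   ids.
#' @param structural_missing symmetric logical matrix, same shape; default
#'   all FALSE.
#' @return object of class `connectivity_matrix` (list: weights,
#'   structural_missing, nodes).
#' @export
connectivity_matrix <- function(weights, structural_missing = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-10) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(structural_missing))
    structural_missing <- matrix(FALSE, n, n)
  structural_missing <- structural_missing | t(structural_missing)
  diag(structural_missing) <- FALSE
  if (any(weights[structural_missing] != 0))
    stop("structurally missing pairs must have weight 0")
  if (is.null(rownames(weights)))
    rownames(weights) <- colnames(weights) <- sprintf("n%03d", seq_len(n))
  dimnames(structural_missing) <- dimnames(weights)
  structure(list(weights = weights,
                 structural_missing = structural_missing,
                 nodes = rownames(weights)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- length(x$nodes)
  up <- upper.tri(x$weights)
  cat(sprintf("connectivity_matrix: %d nodes, %d/%d pairs structurally missing, %d positive edges\n",
              n, sum(x$structural_missing[up]), sum(up),
              sum(x$weights[up] > 0)))
  invisible(x)
}

#' Correlation network from region time series
#'
#' Column-standardizes each run (mean 0, SD 1 per node), concatenates the
#' runs in time, and computes the Pearson correlation between all node
#' pairs. The diagonal is set to zero. The result is signed and
#' unfiltered; apply [apply_edge_filters()] before computing metrics.
#'
#' @param runs a single time-by-node matrix/data.frame or a list of them;
#'   all runs must share node columns and have >= 3 time points.
#' @param fisher_z if TRUE, return Fisher z-transformed correlations
#'   (default FALSE: plain Pearson).
#' @return a signed [connectivity_matrix()] (no pairs missing).
#' @export
correlation_network <- function(runs, fisher_z = FALSE) {
  if (!is.list(runs) || is.data.frame(runs)) runs <- list(runs)
  if (length(runs) < 1) stop("need at least one run")
  runs <- lapply(runs, as.matrix)
  cols <- colnames(runs[[1]])
  if (is.null(cols)) {
    cols <- sprintf("n%03d", seq_len(ncol(runs[[1]])))
    runs <- lapply(runs, function(r) { colnames(r) <- cols; r })
  }
  std <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (!identical(colnames(r), cols)) stop("runs must share node columns")
    if (nrow(r) < 3) stop("each run needs >= 3 time points")
    s <- apply(r, 2, sd)
    if (any(s == 0))
      stop("zero-variance node in run ", i, ": ",
           paste(cols[s == 0], collapse = ", "))
    scale(r)
  })
  ts <- do.call(rbind, std)
  r <- cor(ts)
  if (fisher_z) r <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  diag(r) <- 0
  connectivity_matrix(r)
}

#' Apply the standard edge filters
#'
#' Sets negative weights to zero (observed zeros) and structurally excludes
#' any pair of nodes whose centroids lie strictly less than `min_dist_mm`
#' apart (short-distance connectivity is motion-inflated). Idempotent.
#'
#' @param matrix a [connectivity_matrix()] (may be signed).
#' @param nodes a [node_table()] matching the matrix node order.
#' @param min_dist_mm distance-exclusion threshold in mm (strict `<`).
#' @return a filtered nonnegative [connectivity_matrix()].
#' @export
apply_edge_filters <- function(matrix, nodes, min_dist_mm = 20) {
  w <- matrix$weights
  if (nrow(w) != nrow(nodes))
    stop("matrix dimension does not match node table")
  w[w < 0] <- 0
  d <- node_distances(nodes)
  miss <- matrix$structural_missing | (d < min_dist_mm)
  diag(miss) <- FALSE
  w[miss] <- 0
  connectivity_matrix(w, miss)
}

#' Network density
#'
#' Fraction of eligible node pairs carrying a strictly positive weight;
#' eligible pairs are all unordered pairs minus the structurally missing
#' ones.
#'
#' @param matrix a filtered [connectivity_matrix()].
#' @return density in \[0, 1\].
#' @export
network_density <- function(matrix) {
  up <- upper.tri(matrix$weights)
  eligible <- up & !matrix$structural_missing
  if (sum(eligible) == 0) stop("no eligible pairs: density undefined")
  sum(matrix$weights[eligible] > 0) / sum(eligible)
}

#' Read / write a connectivity matrix as TSV
#'
#' The weight matrix is written as a square TSV with a node_id header row
#' and column; the structural-missing mask goes to a companion file
#' (`<path>.missing.tsv` by default) as 0/1.
#'
#' @param matrix a [connectivity_matrix()].
#' @param path weight file path.
#' @param missing_path mask file path.
#' @export
write_connectivity_matrix <- function(matrix, path,
                                      missing_path = paste0(path, ".missing.tsv")) {
  write.table(matrix$weights, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  write.table(matrix$structural_missing * 1L, missing_path, sep = "\t",
              quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @export
read_connectivity_matrix <- function(path,
                                     missing_path = paste0(path, ".missing.tsv")) {
  w <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  miss <- NULL
  if (file.exists(missing_path))
    miss <- as.matrix(read.delim(missing_path, row.names = 1,
                                 check.names = FALSE)) > 0
  connectivity_matrix(w, miss)
}
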