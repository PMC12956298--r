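#' Construct a node table
#'
#' A node table defines the vertex set of a connectome: one row per brain
#' region with a unique label, a 3D centroid in millimetres, and a logical
#' flag marking membership in the default mode network (DMN).
#'
#' @param node_id character vector of unique region labels.
#' @param x,y,z numeric centroid coordinates (mm).
#' @param dmn logical DMN membership flag.
#' @return A `data.frame` of class `node_table`.
#' @export
node_table <- function(node_id, x, y, z, dmn) {
  node_id <- as.character(node_id)
  if (anyDuplicated(node_id)) stop("node_id values must be unique")
  if (!all(is.finite(c(x, y, z)))) stop("node coordinates must be finite")
  dmn <- as.logical(dmn)
  if (anyNA(dmn)) stop("dmn flag must be TRUE/FALSE")
  if (sum(dmn) < 3L || sum(!dmn) < 3L)
    stop("need at least 3 DMN and 3 non-DMN nodes")
  out <- data.frame(node_id = node_id, x = as.numeric(x), y = as.numeric(y),
                    z = as.numeric(z), dmn = dmn, stringsAsFactors = FALSE)
  class(out) <- c("node_table", "data.frame")
  out
}

#' Pairwise Euclidean centroid distances
#'
#' @param nodes a [node_table()].
#' @return symmetric matrix of distances in mm, dimnames = node ids.
#' @export
node_distances <- function(nodes) {
  d <- as.matrix(stats::dist(as.matrix(nodes[, c("x", "y", "z")])))
  dimnames(d) <- list(nodes$node_id, nodes$node_id)
  d
}

#' Generate a synthetic node layout
#'
#' Places `n_nodes` region centroids in a cubic volume of side `box_mm`.
#' Non-DMN nodes are uniform over the box; the `n_dmn` DMN nodes are drawn
#' around a single randomly placed centroid so the DMN forms a spatially
#' coherent block, as a cortical subnetwork does. Deterministic given
#' `seed`.
#'
#' @param n_nodes total number of nodes.
#' @param n_dmn number of nodes flagged as DMN (`0 < n_dmn < n_nodes`).
#' @param box_mm side of the bounding cube in mm.
#' @param seed integer seed.
#' @param dmn_spread_mm SD of the isotropic Gaussian spread of DMN nodes
#'   around their centroid.
#' @return a [node_table()] with exactly `n_dmn` rows flagged `dmn = TRUE`.
#' @export
generate_node_layout <- function(n_nodes, n_dmn, box_mm = 160, seed = 1L,
                                 dmn_spread_mm = box_mm / 5) {
  if (n_dmn >= n_nodes || n_dmn <= 0)
    stop("invalid argument: need 0 < n_dmn < n_nodes")
  set.seed(seed)
  n_out <- n_nodes - n_dmn
  xyz_out <- matrix(runif(3 * n_out, 0, box_mm), ncol = 3)
  centre <- runif(3, 0.3 * box_mm, 0.7 * box_mm)
  xyz_dmn <- matrix(rnorm(3 * n_dmn, mean = rep(centre, each = n_dmn),
                          sd = dmn_spread_mm), ncol = 3)
  xyz_dmn <- pmin(pmax(xyz_dmn, 0), box_mm)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  node_table(ids,
             x = c(xyz_dmn[, 1], xyz_out[, 1]),
             y = c(xyz_dmn[, 2], xyz_out[, 2]),
             z = c(xyz_dmn[, 3], xyz_out[, 3]),
             dmn = c(rep(TRUE, n_dmn), rep(FALSE, n_out)))
}

#' Read / write a node table as TSV
#'
#' Columns: node_id, x, y, z, dmn.
#' @param nodes a [node_table()].
#' @param path file path.
#' @return `read_node_table` returns a [node_table()].
#' @export
write_node_table <- function(nodes, path) {
  write.table(as.data.frame(nodes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  node_table(df$node_id, df$x, df$y, df$z, df$dmn)
}
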