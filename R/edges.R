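#' Canonical edge index for an undirected graph
#'
#' Enumerates the upper-triangular node pairs (i < j) of an `n_nodes` graph in
#' row-major order: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This is the
#' fixed edge ordering used everywhere in the package, so that per-subject
#' edge vectors, saliences and bootstrap ratios can be mapped back onto the
#' node-by-node matrix without ambiguity.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param node_ids Optional character vector of node identifiers; defaults to
#'   `"n001"`-style labels.
#' @return A data frame with columns `i`, `j` (integer node positions,
#'   `i < j`), `node_i`, `node_j` (ids); `n_nodes*(n_nodes-1)/2` rows.
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(n_nodes, node_ids = NULL) {
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 2)
    stop("n_nodes must be a single integer >= 2")
  n_nodes <- as.integer(n_nodes)
  if (is.null(node_ids)) node_ids <- default_node_ids(n_nodes)
  if (length(node_ids) != n_nodes) stop("node_ids length must equal n_nodes")
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  data.frame(i = i, j = j,
             node_i = node_ids[i], node_j = node_ids[j],
             stringsAsFactors = FALSE)
}

default_node_ids <- function(n) sprintf("n%03d", seq_len(n))

#' Vectorize a connectivity matrix into the canonical edge order
#'
#' Extracts the strict upper triangle of a symmetric node-by-node matrix in
#' the row-major (i < j) order of [edge_index()].
#'
#' @param m Symmetric numeric matrix with zero diagonal (a `connectivity_matrix`
#'   or plain matrix).
#' @param tol Symmetry tolerance (maximum absolute `m - t(m)` allowed).
#' @return Numeric vector of length `n*(n-1)/2`.
#' @seealso [unvectorize_edges()] for the inverse.
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  m <- as_conn_values(m)
  if (max(abs(m - t(m))) > tol) stop("matrix is not symmetric within tolerance ", tol)
  # row-major upper triangle == column-major lower triangle of the transpose
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_edges()]: places the edge vector into both triangles
#' of an `n_nodes` square matrix with a zero diagonal.
#'
#' @param edges Numeric vector of length `n_nodes*(n_nodes-1)/2`.
#' @param n_nodes Number of nodes; inferred from `length(edges)` if omitted.
#' @param node_ids Optional dimnames.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
unvectorize_edges <- function(edges, n_nodes = NULL, node_ids = NULL) {
  ne <- length(edges)
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * ne)) / 2
    if (abs(n_nodes - round(n_nodes)) > 1e-9)
      stop("edge vector length ", ne, " is not n*(n-1)/2 for integer n")
    n_nodes <- as.integer(round(n_nodes))
  }
  if (ne != n_nodes * (n_nodes - 1L) / 2L)
    stop("edge vector length does not match n_nodes")
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- edges      # fills t(upper) in row-major upper order
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (!is.null(node_ids)) dimnames(m) <- list(node_ids, node_ids)
  m
}

as_conn_values <- function(m) {
  if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
}
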