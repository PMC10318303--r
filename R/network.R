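# System segregation and the node-label permutation test on thresholded
# bootstrap-ratio matrices.

edge_within_mask <- function(partition, n_nodes = length(partition$node_ids)) {
  ei <- edge_index(n_nodes)
  partition$network[ei$i] == partition$network[ei$j]
}

#' System segregation of a connectome
#'
#' `S = (W - B) / W`, where `W` is the mean connectivity over within-network
#' edges and `B` the mean over between-network edges. Negative edges are, by
#' default, set to zero before averaging (the convention of the standard
#' segregation metric); they can instead be kept as-is or replaced by their
#' absolute value.
#'
#' @param x A `connectivity_matrix`, a symmetric matrix, or a canonical edge
#'   vector.
#' @param partition A `network_partition` (>= 2 networks) matching `x`.
#' @param negative_policy `"zero"` (default), `"keep"`, or `"absolute"`.
#' @return Segregation score (scalar). 1 when between-network connectivity
#'   averages zero; 0 when within and between averages are equal.
#' @export
system_segregation <- function(x, partition,
                               negative_policy = c("zero", "keep", "absolute")) {
  negative_policy <- match.arg(negative_policy)
  stopifnot(inherits(partition, "network_partition"))
  n_nodes <- length(partition$node_ids)
  if (length(partition$networks) < 2) stop("partition must have >= 2 networks")
  edges <- if (is.matrix(x) || inherits(x, "connectivity_matrix"))
    vectorize_edges(x) else as.numeric(x)
  if (length(edges) != n_nodes * (n_nodes - 1) / 2)
    stop("edge count does not match partition node count")
  edges <- switch(negative_policy,
                  zero = pmax(edges, 0),
                  keep = edges,
                  absolute = abs(edges))
  within <- edge_within_mask(partition, n_nodes)
  w <- mean(edges[within])
  b <- mean(edges[!within])
  if (w == 0) stop("mean within-network connectivity is zero; segregation undefined")
  (w - b) / w
}

#' Per-subject segregation scores for an edge-data matrix
#'
#' @param edges An `edge_matrix`.
#' @param partition Matching `network_partition`.
#' @param negative_policy Passed to [system_segregation()].
#' @return Named numeric vector, one score per subject.
#' @export
segregation_scores <- function(edges, partition,
                               negative_policy = c("zero", "keep", "absolute")) {
  negative_policy <- match.arg(negative_policy)
  out <- apply(edges$values, 1, system_segregation, partition = partition,
               negative_policy = negative_policy)
  names(out) <- edges$subject_ids
  out
}

#' Threshold a bootstrap-ratio matrix into signed binary matrices
#'
#' Edges with `bsr >= tau` become 1 in the positive matrix; edges with
#' `bsr <= -tau` become -1 in the negative matrix; all non-significant
#' entries (`|bsr| < tau`) are zero in both.
#'
#' @param bsr Symmetric node x node BSR matrix (finite entries).
#' @param tau Threshold (default 2.8, two-tailed normal p of about 0.005).
#' @return List with `positive` (0/1) and `negative` (0/-1) matrices.
#' @export
threshold_bsr <- function(bsr, tau = 2.8) {
  bsr <- as_conn_values(bsr)
  if (any(!is.finite(bsr))) stop("non-finite BSR entries")
  list(positive = (bsr >= tau) * 1, negative = (bsr <= -tau) * -1)
}

#' Network-block means of a node-by-node matrix
#'
#' Block (A, B) is the mean over all node pairs i in A, j in B, excluding the
#' diagonal; diagonal blocks average their within-network node pairs (upper
#' triangle only). Networks of size 1 have no within-network pairs and their
#' diagonal block is reported as `NA`.
#'
#' @param m Symmetric node x node matrix.
#' @param partition Matching `network_partition`.
#' @return Symmetric networks x networks matrix of block means.
#' @export
network_block_means <- function(m, partition) {
  m <- as_conn_values(m)
  labs <- partition$networks
  f <- factor(partition$network, levels = labs)
  if (length(f) != nrow(m)) stop("partition does not match node count")
  ind <- stats::model.matrix(~ f - 1)              # nodes x networks indicator
  sums <- crossprod(ind, m %*% ind)                # block pair sums (both triangles)
  sz <- as.numeric(table(f))
  cnt <- outer(sz, sz)
  diag(cnt) <- sz * (sz - 1)                       # diagonal excluded
  out <- sums / cnt                                # symmetric double-count cancels
  out[cnt == 0] <- NA_real_
  dimnames(out) <- list(labs, labs)
  out
}

#' Node-label permutation test of network-block effects
#'
#' Thresholds the BSR matrix into positive and negative signed-binary
#' matrices, computes network-block means, and builds a null distribution by
#' shuffling the node-to-network labels (preserving network sizes) and
#' recomputing the block means `n_perm` times. Positive blocks are tested
#' one-sided against null means that are greater than or equal to the
#' observed mean; negative blocks against null means that are less than or
#' equal (more negative is more extreme). P-values use the add-one
#' estimator.
#'
#' @param bsr Symmetric node x node BSR matrix.
#' @param partition Matching `network_partition`.
#' @param tau BSR threshold (default 2.8).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return A `signed_block_result`: list with `positive_means`,
#'   `negative_means`, `positive_p`, `negative_p`, `n_perm`, `tau`.
#' @export
network_permutation_test <- function(bsr, partition, tau = 2.8,
                                     n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  thr <- threshold_bsr(bsr, tau)
  obs_pos <- network_block_means(thr$positive, partition)
  obs_neg <- network_block_means(thr$negative, partition)
  k <- length(partition$networks)
  cnt_pos <- matrix(0L, k, k)
  cnt_neg <- matrix(0L, k, k)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- partition
      perm$network <- sample(partition$network)
      null_pos <- network_block_means(thr$positive, perm)
      null_neg <- network_block_means(thr$negative, perm)
      cnt_pos <- cnt_pos + (null_pos >= obs_pos)
      cnt_neg <- cnt_neg + (null_neg <= obs_neg)
    }
  })
  structure(list(positive_means = obs_pos, negative_means = obs_neg,
                 positive_p = (1 + cnt_pos) / (n_perm + 1),
                 negative_p = (1 + cnt_neg) / (n_perm + 1),
                 n_perm = n_perm, tau = tau),
            class = "signed_block_result")
}

#' @export
print.signed_block_result <- function(x, ...) {
  cat("network-block permutation test (tau =", x$tau, ",", x$n_perm,
      "permutations)\n")
  cat("positive block means, range:",
      paste(round(range(x$positive_means, na.rm = TRUE), 3), collapse = " .. "),
      "\nnegative block means, range:",
      paste(round(range(x$negative_means, na.rm = TRUE), 3), collapse = " .. "),
      "\n")
  invisible(x)
}
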