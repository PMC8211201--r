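# Global network measures on weighted association matrices.
#
# Density and clustering follow the edge-counting definitions of the
# standard graph-library functions and are therefore computed on the
# binarized graph (edge iff index > 0); modularity and community
# detection use the weights.

check_assoc <- function(m, min_n = 2L) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || !is.numeric(m)) {
    stop("association matrix must be a square numeric matrix", call. = FALSE)
  }
  if (nrow(m) < min_n) {
    stop("association matrix must have at least ", min_n, " individuals",
         call. = FALSE)
  }
  if (any(m < 0)) stop("association indices must be non-negative", call. = FALSE)
  invisible(m)
}

assoc_graph <- function(m) {
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Graph density of an association network
#'
#' The number of dyads with a positive association index divided by the
#' number of possible dyads `n(n-1)/2`.
#'
#' @param m Symmetric association matrix (zero diagonal).
#' @return Density in `[0, 1]`.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- m[1, 3] <- m[3, 1] <- 0.5
#' m[2, 3] <- m[3, 2] <- 0.2
#' graph_density(m)  # 3 of 6 possible edges
#' @export
graph_density <- function(m) {
  check_assoc(m, min_n = 2L)
  n <- nrow(m)
  sum(m[upper.tri(m)] > 0) / (n * (n - 1) / 2)
}

#' Global clustering coefficient (transitivity)
#'
#' The proportion of connected triples that close into triangles,
#' `3 * triangles / connected triples`, on the binarized graph.
#' Networks with no connected triples return 0.
#'
#' @param m Symmetric association matrix with at least 3 individuals.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
global_clustering <- function(m) {
  check_assoc(m, min_n = 3L)
  tr <- igraph::transitivity(assoc_graph(m), type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Weighted Newman modularity of a partition
#'
#' `Q = (1 / 2W) * sum_ij (w_ij - s_i s_j / 2W) * delta(c_i, c_j)`,
#' where `s_i` is node strength and `W` the total edge weight: the
#' excess of within-community edge weight over the strength-preserving
#' random expectation.
#'
#' @param m Symmetric weighted association matrix (zero diagonal).
#' @param membership Community labels, one per individual, in matrix
#'   order (a named vector is matched against the matrix dimnames when
#'   both are available).
#' @return Modularity value; 0 (with attribute `degenerate = TRUE`) for
#'   an edgeless matrix.
#' @examples
#' m <- matrix(0, 4, 4)
#' m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 1
#' network_modularity(m, c(1, 1, 2, 2))  # two disconnected cliques: 0.5
#' @export
network_modularity <- function(m, membership) {
  check_assoc(m, min_n = 2L)
  if (inherits(membership, "netss_partition")) membership <- membership$membership
  if (length(membership) != nrow(m)) {
    stop("membership must cover every individual in the matrix", call. = FALSE)
  }
  if (!is.null(names(membership)) && !is.null(rownames(m))) {
    if (!setequal(names(membership), rownames(m))) {
      stop("membership names do not match matrix dimnames", call. = FALSE)
    }
    membership <- membership[rownames(m)]
  }
  if (anyNA(membership)) stop("membership contains missing labels", call. = FALSE)
  w2 <- sum(m)  # = 2W for a symmetric matrix with zero diagonal
  if (w2 == 0) {
    return(structure(0, degenerate = TRUE))
  }
  s <- rowSums(m)
  q <- 0
  for (k in unique(membership)) {
    idx <- which(membership == k)
    q <- q + sum(m[idx, idx]) / w2 - (sum(s[idx]) / w2)^2
  }
  q
}

new_partition <- function(membership, q = NA_real_, degenerate = FALSE) {
  structure(list(membership = membership,
                 q = as.numeric(q),
                 n_communities = length(unique(membership)),
                 degenerate = isTRUE(degenerate)),
            class = "netss_partition")
}

#' @export
print.netss_partition <- function(x, ...) {
  cat(sprintf("Partition of %d individuals into %d communities (Q = %.4f%s)\n",
              length(x$membership), x$n_communities, x$q,
              if (x$degenerate) ", degenerate" else ""))
  print(table(community = x$membership))
  invisible(x)
}

#' Greedy agglomerative community detection
#'
#' Modularity-maximizing agglomerative merging on the weighted network
#' (igraph's fast-greedy algorithm): starting from singletons,
#' repeatedly merge the community pair with the largest modularity gain
#' and return the partition at the modularity peak of the merge path.
#' Deterministic for a given matrix.
#'
#' An edgeless matrix is a defined degenerate case: every individual is
#' its own community and `q = 0`, which downstream coding rules treat
#' as "no community structure detectable".
#'
#' @param m Symmetric weighted association matrix.
#' @return A partition object (class `netss_partition`) with fields
#'   `membership` (named vector), `q` (its weighted modularity),
#'   `n_communities` and `degenerate`.
#' @export
fast_greedy_communities <- function(m) {
  check_assoc(m, min_n = 2L)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (!any(m > 0)) {
    return(new_partition(stats::setNames(seq_len(nrow(m)), ids),
                         q = 0, degenerate = TRUE))
  }
  fg <- igraph::cluster_fast_greedy(assoc_graph(m))
  memb <- stats::setNames(as.integer(igraph::membership(fg)), ids)
  new_partition(memb, q = as.numeric(network_modularity(m, memb)))
}

#' All global metrics of an association network
#'
#' @param m Symmetric weighted association matrix.
#' @param partition Optional precomputed [fast_greedy_communities()]
#'   result.
#' @return List with `q`, `n_communities`, `density`, `clustering`
#'   (`NA` for networks of fewer than 3 individuals, where no triple
#'   exists) and the `partition`.
#' @export
global_metrics <- function(m, partition = NULL) {
  check_assoc(m, min_n = 2L)
  p <- partition %||% fast_greedy_communities(m)
  list(q = p$q,
       n_communities = p$n_communities,
       density = graph_density(m),
       clustering = if (nrow(m) >= 3) global_clustering(m) else NA_real_,
       partition = p)
}
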