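#' k-shell (k-core) decomposition
#'
#' Standard k-core peeling: for k = 1, 2, ... iteratively remove all nodes of
#' degree at most k; a node's shell index is the largest k at which it
#' survives. Computed via [igraph::coreness()].
#'
#' @param net an undirected simple igraph graph.
#' @return named integer vector of shell indices.
#' @export
k_shell <- function(net) {
  check_simple(net)
  ks <- igraph::coreness(net, mode = "all")
  setNames(as.integer(ks), node_ids(net))
}

# Shifted power iteration on A + I (the shift removes the sign ambiguity of
# bipartite spectra; eigenvectors are unchanged and eigenvalues shift by 1).
# Deterministic uniform start vector, so no RNG is consumed.
power_iterate <- function(net, tol = 1e-10, max_iter = 100000L) {
  n <- igraph::vcount(net)
  if (n == 0) stop("network is empty")
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- (A + Matrix::Diagonal(n))
  v <- rep(1 / sqrt(n), n)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    u <- as.numeric(A %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) stop("power iteration degenerated to the zero vector")
    u <- u / nu
    if (sqrt(sum((u - v)^2)) < tol) {
      v <- u
      lam <- nu
      break
    }
    v <- u
    lam <- nu
    if (it == max_iter) stop("power iteration failed to converge in ",
                             max_iter, " iterations")
  }
  list(vector = v, value = lam - 1)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the (unweighted) adjacency matrix, computed by
#' shifted power iteration from a deterministic uniform start vector and
#' normalized to unit Euclidean length. On a connected undirected graph all
#' entries are positive (Perron-Frobenius).
#'
#' @param net a connected undirected igraph graph.
#' @param tol convergence tolerance on the iterate difference.
#' @return named numeric vector with unit sum of squares.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10) {
  setNames(power_iterate(net, tol = tol)$vector, node_ids(net))
}

#' Largest adjacency eigenvalue
#'
#' Spectral radius of the adjacency matrix, whose inverse approximates the
#' epidemic threshold of SIS-type processes on the network.
#'
#' @inheritParams eigenvector_centrality
#' @return a positive scalar.
#' @export
largest_eigenvalue <- function(net, tol = 1e-10) {
  power_iterate(net, tol = tol)$value
}

#' Node score table: ExF, ExF^M, k-shell and eigenvector centrality
#'
#' Convenience wrapper assembling the full per-node metric table used by the
#' benchmarking harness. On weighted graphs both the weighted and unweighted
#' expected force are reported.
#'
#' @inheritParams expected_force_all
#' @param tol tolerance for the eigenvector computation.
#' @return a data frame with columns `node`, `degree`, `exf` (unweighted
#'   ExF), `exf_weighted` (present only for weighted graphs), `exfm`,
#'   `kshell`, `eigencent`, `excluded_as_hub`.
#' @export
node_score_table <- function(net, x = 2, alpha = 2, exclude_hubs = TRUE,
                             hub_fraction = 0.6, tol = 1e-10) {
  tab <- expected_force_all(net, x = x, alpha = alpha, modified = TRUE,
                            weighted = FALSE, exclude_hubs = exclude_hubs,
                            hub_fraction = hub_fraction)
  if (is_weighted_graph(net)) {
    keep <- which(!tab$excluded_as_hub)
    tab$exf_weighted <- NA_real_
    tab$exf_weighted[keep] <- unname(expected_force(net, keep, x = x,
                                                    weighted = TRUE))
  }
  tab$kshell <- unname(k_shell(net))
  tab$eigencent <- unname(eigenvector_centrality(net, tol = tol))
  tab[c("node", "degree", "exf",
        if (is_weighted_graph(net)) "exf_weighted",
        "exfm", "kshell", "eigencent", "excluded_as_hub")]
}
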