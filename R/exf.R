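#' Enumerate transmission clusters around a seed node
#'
#' Enumerates every ordered sequence of `x` transmission events starting from
#' `seed` in an otherwise fully susceptible network, assuming no recovery.
#' Each event infects a node that is susceptible and adjacent (via an edge
#' oriented infected-to-susceptible in directed graphs) to an already
#' infected node; distinct orderings of the same infected set are distinct
#' clusters, so two connected neighbours of the seed yield four clusters.
#' Each cluster carries its cluster degree `d` (the number, or total weight,
#' of edges from the infected set to susceptible nodes) and a formation
#' weight `p` (product over events of edge weight divided by the total
#' eligible infected-to-susceptible weight at that step; identically 1 on
#' unweighted graphs). Branches that exhaust their component before `x`
#' events are kept at their maximal achievable length.
#'
#' @param net an igraph graph (optionally weighted and/or directed).
#' @param seed a node identifier (vertex name) or index.
#' @param x number of transmission events (at least 1); `x = 2` is the
#'   standard choice.
#' @param weighted logical; default uses edge weights when present.
#' @return an object of class `cluster_ensemble`: a list with elements
#'   `seed`, `x`, `J` (number of clusters), `d`, `p`, `dbar` (normalized
#'   `p*d`), and `infected` (list of infected node-id vectors, seed first).
#' @examples
#' tri <- igraph::graph_from_literal(i - a, i - b, a - b)
#' enumerate_clusters(tri, "i")$J  # 4
#' @export
enumerate_clusters <- function(net, seed, x = 2, weighted = NULL) {
  stopifnot(x >= 1)
  if (is.null(weighted)) weighted <- is_weighted_graph(net)
  csr <- graph_csr(net, weighted = weighted)
  s0 <- resolve_nodes(net, seed)
  if (length(s0) != 1) stop("exactly one seed node required")
  nbrs <- function(v) {
    if (csr$ptr[v + 1L] == csr$ptr[v]) return(NULL)
    k <- (csr$ptr[v] + 1L):csr$ptr[v + 1L]
    cbind(to = csr$nbr[k] + 1L, w = csr$wt[k])
  }
  d_out <- numeric(0); p_out <- numeric(0); sets <- list()
  recurse <- function(infected, p_acc, depth) {
    # eligible infected -> susceptible edges
    src <- integer(0); tgt <- integer(0); ew <- numeric(0)
    for (v in infected) {
      nb <- nbrs(v)
      if (is.null(nb)) next
      sus <- !(nb[, 1] %in% infected)
      src <- c(src, rep(v, sum(sus)))
      tgt <- c(tgt, nb[sus, 1]); ew <- c(ew, nb[sus, 2])
    }
    if (depth == x || length(tgt) == 0) {
      d_out[[length(d_out) + 1L]] <<- sum(ew)
      p_out[[length(p_out) + 1L]] <<- p_acc
      sets[[length(sets) + 1L]] <<- csr$names[infected]
      return(invisible())
    }
    W <- sum(ew)
    for (k in seq_along(tgt)) {
      pk <- if (weighted) p_acc * ew[k] / W else p_acc
      recurse(c(infected, tgt[k]), pk, depth + 1L)
    }
  }
  recurse(s0, 1, 0L)
  pd <- p_out * d_out
  tot <- sum(pd)
  structure(list(seed = csr$names[s0], x = x, J = length(d_out),
                 d = d_out, p = p_out,
                 dbar = if (tot > 0) pd / tot else rep(0, length(d_out)),
                 infected = sets, weighted = weighted),
            class = "cluster_ensemble")
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  cat("Transmission cluster ensemble: seed", x$seed, "| x =", x$x,
      "| J =", x$J, "clusters\n")
  cat("cluster degrees d:", paste(signif(x$d, 4), collapse = " "), "\n")
  if (x$weighted)
    cat("formation weights p:", paste(signif(x$p, 4), collapse = " "), "\n")
  invisible(x)
}

#' Expected force of a seed node
#'
#' The expected force (ExF) summarizes the distribution of the force of
#' infection a node generates: enumerate all transmission clusters after `x`
#' transmission events ([enumerate_clusters()]), normalize the cluster
#' degrees to `q_k = d_k / sum(d_j)`, and return the entropy
#' `-sum(q_k log q_k)` (natural logarithm). On weighted graphs the cluster
#' degrees are edge-weight sums, so the definition carries over unchanged;
#' setting `formation_weights = TRUE` additionally folds each cluster's
#' formation probability `p_k` into the normalization
#' (`q_k = p_k d_k / sum(p_j d_j)`), an alternative combination that down-
#' weights clusters reached through low-weight edges. A node whose
#' neighbourhood admits at most one cluster, or only clusters with zero
#' onward connectivity, has expected force 0.
#'
#' @param net an igraph graph.
#' @param v node identifiers (vertex names) or indices; default all nodes.
#' @param x number of transmission events.
#' @param weighted logical; default uses edge weights when present. Set
#'   `FALSE` to compute the unweighted ExF of a weighted graph.
#' @param formation_weights logical; fold cluster formation probabilities
#'   into the entropy weights (weighted graphs only, see Details).
#' @return named numeric vector of expected-force values.
#' @examples
#' star <- igraph::make_star(4, mode = "undirected")
#' igraph::V(star)$name <- c("hub", "a", "b", "c")
#' expected_force(star, "hub")  # log(6)
#' @export
expected_force <- function(net, v = NULL, x = 2, weighted = NULL,
                           formation_weights = FALSE) {
  if (is.null(weighted)) weighted <- is_weighted_graph(net)
  idx <- resolve_nodes(net, v)
  if (x == 2) {
    csr <- graph_csr(net, weighted = weighted)
    val <- .exf_x2_cpp(csr$ptr, csr$nbr, csr$wt, csr$strength,
                       as.integer(idx - 1L), weighted,
                       isTRUE(formation_weights),
                       igraph::is_directed(net))
  } else {
    val <- vapply(idx, function(i) {
      ce <- enumerate_clusters(net, i, x = x, weighted = weighted)
      q <- if (formation_weights) ce$p * ce$d else ce$d
      q <- q[q > 0]
      if (length(q) == 0 || sum(q) == 0) return(0)
      q <- q / sum(q)
      -sum(q * log(q))
    }, 0)
  }
  setNames(val, node_ids(net)[idx])
}

#' Degree-corrected expected force (ExF^M)
#'
#' Multiplies the expected force by the log of the seed's degree after
#' rescaling the degree by `alpha > 1`:
#' `ExF^M = ExF * log(alpha * deg)`. The rescaling keeps the multiplier
#' strictly positive for degree-one nodes (log of one is zero), which matter
#' in networks where many low-degree nodes hang off hubs. The multiplier is
#' exposed through `rescale` for sensitivity analyses.
#'
#' @inheritParams expected_force
#' @param alpha degree rescaling factor, strictly greater than 1.
#' @param rescale function of `(alpha, degree)` returning the multiplier;
#'   defaults to `log(alpha * degree)`.
#' @return named numeric vector of ExF^M values.
#' @export
expected_force_modified <- function(net, v = NULL, alpha = 2, x = 2,
                                    weighted = NULL,
                                    rescale = function(alpha, degree)
                                      log(alpha * degree)) {
  if (!is.numeric(alpha) || alpha <= 1)
    stop("alpha must be greater than 1")
  idx <- resolve_nodes(net, v)
  e <- expected_force(net, idx, x = x, weighted = weighted)
  deg <- igraph::degree(net, v = idx,
                        mode = if (igraph::is_directed(net)) "out" else "all")
  e * rescale(alpha, pmax(deg, 1))
}

#' Expected force of every node, with optional hub exclusion
#'
#' Computes per-node ExF (and ExF^M) for a whole network. Hubs, defined as
#' nodes whose degree strictly exceeds `hub_fraction` times the maximum
#' degree, can be flagged and left unscored, matching the seed-selection
#' protocol of the validation experiments.
#'
#' @inheritParams expected_force_modified
#' @param modified logical; also compute ExF^M.
#' @param exclude_hubs logical; flag hubs and skip scoring them.
#' @param hub_fraction hub threshold as a fraction of the maximum degree.
#' @return a data frame with columns `node`, `degree`, `exf`, optionally
#'   `exfm`, and `excluded_as_hub`.
#' @export
expected_force_all <- function(net, x = 2, alpha = 2, modified = TRUE,
                               weighted = NULL, exclude_hubs = FALSE,
                               hub_fraction = 0.6) {
  if (igraph::vcount(net) == 0) stop("network is empty")
  if (modified && (!is.numeric(alpha) || alpha <= 1))
    stop("alpha must be greater than 1")
  ids <- node_ids(net)
  deg <- igraph::degree(net,
                        mode = if (igraph::is_directed(net)) "out" else "all")
  excl <- if (exclude_hubs) deg > hub_fraction * max(deg) else rep(FALSE, length(deg))
  out <- data.frame(node = ids, degree = as.integer(deg),
                    exf = NA_real_, stringsAsFactors = FALSE)
  keep <- which(!excl)
  out$exf[keep] <- unname(expected_force(net, keep, x = x, weighted = weighted))
  if (modified) {
    out$exfm <- NA_real_
    out$exfm[keep] <- out$exf[keep] * log(alpha * pmax(deg[keep], 1))
  }
  out$excluded_as_hub <- excl
  out
}
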