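# Internal helpers shared across modules.

# Compressed sparse row (out-)adjacency of an igraph graph, 0-based, for the
# compiled kernels. `weighted = FALSE` forces unit weights regardless of any
# weight attribute.
graph_csr <- function(net, weighted = NULL) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  if (is.null(weighted)) weighted <- is_weighted_graph(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(net)) {
    as.numeric(igraph::E(net)$weight)
  } else rep(1, nrow(el))
  if (igraph::is_directed(net)) {
    from <- el[, 1]; to <- el[, 2]; ww <- w
  } else {
    from <- c(el[, 1], el[, 2]); to <- c(el[, 2], el[, 1]); ww <- c(w, w)
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; ww <- ww[ord]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), nbr = as.integer(to - 1L), wt = ww,
       strength = tapply_sum(from, ww, n),
       n = n, names = node_ids(net), weighted = weighted)
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

node_ids <- function(net) {
  nm <- igraph::vertex_attr(net, "name")
  if (is.null(nm)) as.character(seq_len(igraph::vcount(net))) else as.character(nm)
}

is_weighted_graph <- function(net) {
  "weight" %in% igraph::edge_attr_names(net)
}

# Resolve user-supplied node ids (names or indices) to 1-based indices.
resolve_nodes <- function(net, v) {
  ids <- node_ids(net)
  if (is.null(v)) return(seq_along(ids))
  if (is.numeric(v)) {
    idx <- as.integer(v)
    if (any(idx < 1 | idx > length(ids))) stop("node index out of range")
    return(idx)
  }
  idx <- match(as.character(v), ids)
  if (anyNA(idx)) stop("unknown node id(s): ",
                       paste(as.character(v)[is.na(idx)], collapse = ", "))
  idx
}

check_simple <- function(net) {
  if (!igraph::is_simple(net))
    stop("network must be simple (no self-loops or multi-edges); see read_edge_list()")
  invisible(net)
}

check_weights_positive <- function(net) {
  if (is_weighted_graph(net) && any(igraph::E(net)$weight <= 0))
    stop("all edge weights must be positive")
  invisible(net)
}
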