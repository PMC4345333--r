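library(igraph)

# Brute-force enumeration of ordered transmission clusters, written against
# the dense adjacency matrix. Deliberately independent of the package's
# CSR-based implementation: used as the oracle for J and the expected force.
oracle_clusters <- function(g, seed, x = 2, weighted = FALSE) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (weighted) "weight" else NULL, sparse = TRUE))
  n <- nrow(A)
  out <- list()
  visit <- function(set, p) {
    sus <- setdiff(seq_len(n), set)
    sub <- A[set, sus, drop = FALSE]
    d <- sum(sub)
    elig <- which(sub > 0, arr.ind = TRUE)
    if (length(set) == x + 1 || nrow(elig) == 0) {
      out[[length(out) + 1L]] <<- list(d = d, p = p, set = set)
      return(invisible())
    }
    for (k in seq_len(nrow(elig))) {
      w <- sub[elig[k, 1], elig[k, 2]]
      visit(c(set, sus[elig[k, 2]]), p * w / d)
    }
  }
  visit(seed, 1)
  out
}

oracle_exf <- function(g, seed, x = 2, weighted = FALSE,
                       formation_weights = FALSE) {
  cl <- oracle_clusters(g, seed, x = x, weighted = weighted)
  d <- vapply(cl, `[[`, 0, "d")
  p <- vapply(cl, `[[`, 0, "p")
  q <- if (formation_weights) p * d else d
  q <- q[q > 0]
  if (length(q) == 0 || sum(q) == 0) return(0)
  q <- q / sum(q)
  -sum(q * log(q))
}

# Closed-form cluster count for undirected unweighted graphs at x = 2,
# valid when the seed's component has at least 3 nodes.
oracle_J_closed <- function(g, seed) {
  nb <- as.integer(neighbors(g, seed))
  p1 <- length(nb)
  p1 * (p1 - 1) + sum(degree(g)[nb] - 1)
}

# k-core by literal iterative peeling.
oracle_kshell <- function(g) {
  shell <- setNames(rep(0L, vcount(g)), V(g)$name)
  h <- g
  k <- 0L
  while (vcount(h) > 0) {
    repeat {
      drop <- V(h)[degree(h) <= k]
      if (length(drop) == 0) break
      shell[drop$name] <- k
      h <- delete_vertices(h, drop)
      if (vcount(h) == 0) break
    }
    k <- k + 1L
  }
  shell
}

# Random small test graph with character names; may be disconnected.
rand_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.15, 0.6)
  g <- sample_gnp(n, p)
  V(g)$name <- as.character(seq_len(n))
  g
}

# Recompute the infected-susceptible edge weight from a status vector.
write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
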