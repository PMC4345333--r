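test_that("cluster enumeration counts ordered event sequences", {
  tri <- igraph::graph_from_literal(i - a, i - b, a - b)
  expect_equal(enumerate_clusters(tri, "i")$J, 4)

  path2 <- igraph::graph_from_literal(i - a, i - b)
  expect_equal(enumerate_clusters(path2, "i")$J, 2)

  # chain i-a-b-c: only one ordered sequence of two events from i
  p4 <- igraph::graph_from_literal(i - a, a - b, b - c)
  ce <- enumerate_clusters(p4, "i")
  expect_equal(ce$J, 1)
  expect_equal(ce$d, 1)  # one edge (b-c) leaves {i,a,b}
  expect_setequal(ce$infected[[1]], c("i", "a", "b"))

  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("h", "a", "b", "c")
  ce <- enumerate_clusters(star, "h")
  expect_equal(ce$J, 6)
  expect_equal(ce$d, rep(1, 6))

  expect_error(enumerate_clusters(tri, "nope"), "unknown node")
})

test_that("expected force matches hand-derived values", {
  p4 <- igraph::graph_from_literal(i - a, a - b, b - c)
  expect_identical(unname(expected_force(p4, "i")), 0)

  star <- igraph::make_star(4, mode = "undirected")
  expect_equal(unname(expected_force(star, 1)), log(6), tolerance = 1e-12)

  ring <- igraph::make_ring(5)
  expect_equal(unname(expected_force(ring)), rep(log(4), 5), tolerance = 1e-12)

  dyad <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_identical(unname(expected_force(dyad, 1)), 0)
})

test_that("enumeration and ExF agree with the brute-force oracle and closed form", {
  set.seed(2024)
  checked <- 0
  while (checked < 200) {
    g <- rand_graph(sample(4:12, 1))
    seed <- sample(igraph::vcount(g), 1)
    comp <- igraph::components(g)
    comp_size <- comp$csize[comp$membership[seed]]
    ce <- enumerate_clusters(g, seed)
    if (comp_size >= 3) {
      expect_equal(ce$J, oracle_J_closed(g, seed))
    }
    expect_equal(unname(expected_force(g, seed)), oracle_exf(g, seed),
                 tolerance = 1e-12)
    # the enumerator's cluster-degree entropy agrees with the fast path
    q <- ce$d[ce$d > 0]
    ent <- if (length(q) && sum(q) > 0) {
      q <- q / sum(q); -sum(q * log(q))
    } else 0
    expect_equal(ent, unname(expected_force(g, seed)), tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("weighted and directed ExF agree with the oracle", {
  set.seed(77)
  for (rep in 1:40) {
    g <- assign_weights(rand_graph(sample(5:10, 1)), "uniform3")
    seed <- sample(igraph::vcount(g), 1)
    expect_equal(unname(expected_force(g, seed, weighted = TRUE)),
                 oracle_exf(g, seed, weighted = TRUE), tolerance = 1e-12)
    expect_equal(unname(expected_force(g, seed, weighted = TRUE,
                                       formation_weights = TRUE)),
                 oracle_exf(g, seed, weighted = TRUE,
                            formation_weights = TRUE), tolerance = 1e-12)
  }
  for (rep in 1:40) {
    g <- igraph::sample_gnp(sample(5:10, 1), 0.4, directed = TRUE)
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    seed <- sample(igraph::vcount(g), 1)
    expect_equal(unname(expected_force(g, seed)), oracle_exf(g, seed),
                 tolerance = 1e-12)
  }
})

test_that("formation weights of complete branches sum to one", {
  set.seed(31)
  for (rep in 1:25) {
    g <- assign_weights(rand_graph(8, 0.5), "uniform10")
    seed <- sample(8, 1)
    ce <- enumerate_clusters(g, seed, weighted = TRUE)
    if (igraph::degree(g, seed) > 0)
      expect_equal(sum(ce$p), 1, tolerance = 1e-12)
  }
})

test_that("ExF is invariant under node relabeling", {
  set.seed(99)
  g <- chung_lu_pareto(150)
  perm <- sample(igraph::vcount(g))
  h <- igraph::permute(g, perm)
  e_g <- expected_force(g)
  e_h <- expected_force(h)
  expect_equal(e_h[names(e_g)], e_g, tolerance = 1e-12)
})

test_that("entropy bounds hold: 0 <= ExF <= log(J)", {
  set.seed(17)
  for (rep in 1:60) {
    g <- rand_graph(sample(4:12, 1))
    seed <- sample(igraph::vcount(g), 1)
    ce <- enumerate_clusters(g, seed)
    e <- unname(expected_force(g, seed))
    expect_gte(e, 0)
    if (ce$J >= 1) expect_lte(e, log(max(ce$J, 1)) + 1e-12)
    # equality iff all positive-degree clusters have equal degree
    if (ce$J > 1 && length(unique(ce$d)) == 1 && ce$d[1] > 0)
      expect_equal(e, log(ce$J), tolerance = 1e-12)
  }
})

test_that("weighted ExF with constant weights equals unweighted ExF", {
  set.seed(5)
  g <- chung_lu_pareto(200)
  igraph::E(g)$weight <- rep(3, igraph::ecount(g))
  expect_equal(expected_force(g, weighted = TRUE),
               expected_force(g, weighted = FALSE), tolerance = 1e-12)
  # the probability-weighted combination is close but not identical
  ewp <- expected_force(g, weighted = TRUE, formation_weights = TRUE)
  expect_gt(cor(ewp, expected_force(g, weighted = FALSE)), 0.99)
})

test_that("ExF^M validates alpha and scales monotonically with degree", {
  star <- igraph::make_star(5, mode = "undirected")
  expect_error(expected_force_modified(star, alpha = 1), "alpha")
  expect_error(expected_force_modified(star, alpha = 0.5), "alpha")

  # degree-1 node: multiplier is log(2)
  p4 <- igraph::graph_from_literal(a - b, b - c, c - d)
  e <- expected_force(p4, "b")
  expect_equal(unname(expected_force_modified(p4, "b", alpha = 2)),
               unname(e) * log(2 * 2), tolerance = 1e-12)

  # zero ExF stays zero for any alpha
  expect_identical(unname(expected_force_modified(p4, "a", alpha = 8)), 0)

  # strictly increasing in degree at fixed ExF
  set.seed(3)
  g <- chung_lu_pareto(150)
  e <- expected_force(g)
  d <- igraph::degree(g)
  m <- expected_force_modified(g)
  i <- which(e > 0)[1]
  mult <- m[i] / e[i]
  expect_equal(unname(mult), unname(log(2 * d[i])), tolerance = 1e-12)
})

test_that("expected_force_all flags hubs without scoring them", {
  star10 <- igraph::make_star(11, mode = "undirected")
  igraph::V(star10)$name <- c("hub", paste0("l", 1:10))
  tab <- expected_force_all(star10, exclude_hubs = TRUE, hub_fraction = 0.6)
  expect_true(tab$excluded_as_hub[tab$node == "hub"])
  expect_true(is.na(tab$exf[tab$node == "hub"]))
  expect_false(any(tab$excluded_as_hub[tab$node != "hub"]))
  expect_false(anyNA(tab$exf[tab$node != "hub"]))

  tab2 <- expected_force_all(star10, exclude_hubs = FALSE)
  expect_false(anyNA(tab2$exf))
  expect_equal(nrow(tab2), 11)
})
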