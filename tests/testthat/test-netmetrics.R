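test_that("star, cycle and path centralities match hand enumeration", {
  star <- pairwise_network(paste0("N", 1:5),
                           data.frame(from = "N1", to = paste0("N", 2:5),
                                      weight = 1))
  ct <- compute_centralities(star)
  expect_equal(ct$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(ct$betweenness[1], 6)
  expect_equal(ct$closeness[1], 1)
  expect_equal(ct$closeness[2], 4 / 7)

  cycle <- pairwise_network(paste0("N", 1:4),
                            data.frame(from = c("N1", "N2", "N3", "N1"),
                                       to = c("N2", "N3", "N4", "N4"),
                                       weight = 1))
  ctc <- compute_centralities(cycle)
  expect_equal(ctc$pagerank, rep(0.25, 4), tolerance = 1e-9)

  path3 <- pairwise_network(c("a", "b", "c"),
                            data.frame(from = c("a", "b"), to = c("b", "c"),
                                       weight = 1))
  ctp <- compute_centralities(path3)
  expect_equal(ctp$eigenvector, c(0.7071, 1, 0.7071), tolerance = 1e-4)
  # pagerank sums to 1, eigenvector/hub max-normalized
  expect_equal(sum(ctp$pagerank), 1, tolerance = 1e-10)
  expect_equal(max(ctp$hub_score), 1)
})

test_that("centralities match brute-force path enumeration on small graphs", {
  set.seed(101)
  for (r in 1:25) {
    n <- sample(4:7, 1)
    weighted <- r %% 2 == 0
    net <- random_network(n, p_edge = 0.55, weighted = weighted)
    if (nrow(net$edges) == 0) next
    ct <- compute_centralities(net, weighted = TRUE)
    oracle <- centrality_oracle(adjacency_lengths(net, weighted = TRUE))
    expect_equal(ct$closeness, oracle$closeness, tolerance = 1e-9)
    expect_equal(ct$betweenness, oracle$betweenness, tolerance = 1e-9)
    deg <- vapply(net$nodes, function(v)
      sum(net$edges$from == v | net$edges$to == v), numeric(1))
    expect_equal(ct$degree, as.integer(deg), ignore_attr = TRUE)
  }
})

test_that("pagerank satisfies its defining linear system", {
  set.seed(102)
  for (r in 1:10) {
    net <- random_network(6, p_edge = 0.6, weighted = TRUE, connected = TRUE)
    ct <- compute_centralities(net)
    A <- matrix(0, 6, 6)
    for (k in seq_len(nrow(net$edges))) {
      i <- match(net$edges$from[k], net$nodes)
      j <- match(net$edges$to[k], net$nodes)
      A[i, j] <- A[j, i] <- abs(net$edges$weight[k])
    }
    s <- rowSums(A)
    pr <- ct$pagerank
    rhs <- (1 - 0.85) / 6 + 0.85 * as.numeric(t(A / s) %*% pr)
    expect_equal(pr, rhs, tolerance = 1e-8)
    expect_equal(sum(pr), 1, tolerance = 1e-10)
  }
})

test_that("hub score equals authority and eigenvector centrality when undirected", {
  # holds exactly on connected non-bipartite graphs (simple principal
  # eigenvalue); bipartite graphs have a degenerate HITS eigenspace
  set.seed(103)
  for (r in 1:10) {
    net <- random_network(6, p_edge = 0.6, weighted = TRUE, connected = TRUE)
    g <- as_igraph(net)
    if (is_bipartite_net(net)) next
    ct <- compute_centralities(net)
    hs <- igraph::hits_scores(g, weights = igraph::E(g)$absweight,
                              scale = TRUE)
    expect_equal(ct$hub_score, as.numeric(hs$hub), tolerance = 1e-6)
    expect_equal(as.numeric(hs$hub), as.numeric(hs$authority),
                 tolerance = 1e-6)
    expect_equal(ct$hub_score, ct$eigenvector, tolerance = 1e-6)
  }
})

test_that("modularity evaluates the weighted formula exactly", {
  net <- two_triangles()
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  # two 3-cliques + bridge, unit weights: Q = 2 (3/7 - (7/14)^2) = 5/14
  expect_equal(modularity_q(net, memb), 5 / 14, tolerance = 1e-12)
  # one community -> 0; weight scaling leaves Q unchanged
  expect_equal(modularity_q(net, stats::setNames(rep(1, 6), letters[1:6])), 0)
  net2 <- net
  net2$edges$weight <- net$edges$weight * 7.3
  expect_equal(modularity_q(net2, memb), 5 / 14, tolerance = 1e-12)
  # agrees with igraph on a random weighted graph
  set.seed(104)
  rnet <- random_network(7, 0.5, weighted = TRUE)
  if (nrow(rnet$edges) > 0) {
    g <- as_igraph(rnet)
    memb_r <- stats::setNames(sample(1:3, 7, replace = TRUE), rnet$nodes)
    expect_equal(modularity_q(rnet, memb_r),
                 igraph::modularity(g, memb_r[rnet$nodes],
                                    weights = igraph::E(g)$absweight),
                 tolerance = 1e-12)
  }
})

test_that("fast-greedy recovers the exhaustively optimal two-clique split", {
  net <- two_triangles()
  part <- detect_communities(net)
  groups <- split(part$membership$disease, part$membership$community)
  expect_equal(length(groups), 2)
  expect_true(setequal(groups[[1]], c("a", "b", "c")) ||
                setequal(groups[[1]], c("d", "e", "f")))
  expect_equal(part$Q, 5 / 14, tolerance = 1e-12)

  # exhaustive search over all 203 partitions of 6 nodes confirms optimality
  best <- -Inf
  for (assign in all_partitions(6)) {
    q <- modularity_q(net, stats::setNames(assign, letters[1:6]))
    best <- max(best, q)
  }
  expect_equal(part$Q, best, tolerance = 1e-12)
})

test_that("degenerate community inputs behave as declared", {
  edgeless <- pairwise_network(paste0("N", 1:5))
  expect_warning(part <- detect_communities(edgeless), "no edges")
  expect_equal(part$Q, 0)
  expect_equal(sort(part$membership$community), 1:5)

  # a clique's modularity optimum is Q = 0, attained by several partitions
  # (including the single community); the returned partition must attain it
  clique <- pairwise_network(c("a", "b", "c"),
                             data.frame(from = c("a", "a", "b"),
                                        to = c("b", "c", "c"), weight = 1))
  pc <- detect_communities(clique)
  expect_equal(pc$Q, 0, tolerance = 1e-12)
  best <- max(vapply(all_partitions(3), function(a)
    modularity_q(clique, stats::setNames(a, c("a", "b", "c"))), numeric(1)))
  expect_equal(pc$Q, best, tolerance = 1e-12)

  # a partition can never be worse than all-singletons
  set.seed(105)
  for (r in 1:5) {
    net <- random_network(6, 0.4, weighted = TRUE)
    if (nrow(net$edges) == 0) next
    part <- detect_communities(net)
    singletons <- stats::setNames(seq_along(net$nodes), net$nodes)
    expect_gte(part$Q, modularity_q(net, singletons) - 1e-12)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(106)
  net <- random_network(6, 0.5, weighted = TRUE, connected = TRUE)
  ct <- compute_centralities(net)
  perm <- sample(6)
  nodes2 <- net$nodes[perm]
  net2 <- pairwise_network(nodes2, net$edges)
  ct2 <- compute_centralities(net2)
  m <- match(net$nodes, ct2$disease)
  expect_equal(ct2$betweenness[m], ct$betweenness, tolerance = 1e-9)
  expect_equal(ct2$pagerank[m], ct$pagerank, tolerance = 1e-9)
  expect_equal(ct2$closeness[m], ct$closeness, tolerance = 1e-9)
})

test_that("bridge ranking orders by metric with degree and catalog tie-breaks", {
  star <- pairwise_network(paste0("N", 1:5),
                           data.frame(from = "N1", to = paste0("N", 2:5),
                                      weight = 1))
  rb <- rank_bridges(compute_centralities(star), top_k = 1)
  expect_equal(rb$disease, "N1")

  # clique: all betweenness zero -> catalog order decides, deterministically
  clique <- pairwise_network(c("x", "y", "z"),
                             data.frame(from = c("x", "x", "y"),
                                        to = c("y", "z", "z"), weight = 1))
  rc <- rank_bridges(compute_centralities(clique))
  expect_equal(rc$disease, c("x", "y", "z"))
  expect_error(rank_bridges(compute_centralities(clique), metric = "nope"),
               "metric")
})

test_that("isolated nodes score zero closeness and keep the network total", {
  net <- pairwise_network(c("a", "b", "c", "iso"),
                          data.frame(from = c("a", "b"), to = c("b", "c"),
                                     weight = c(2, 0.5)))
  ct <- compute_centralities(net)
  expect_equal(ct$closeness[ct$disease == "iso"], 0)
  expect_equal(ct$degree[ct$disease == "iso"], 0L)
  expect_equal(sum(ct$pagerank), 1, tolerance = 1e-9)
  # weighted distances: d(a,b) = 1/2, d(b,c) = 2
  expect_equal(ct$closeness[ct$disease == "b"], 2 / (0.5 + 2))
})
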