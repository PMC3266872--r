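test_that("out_degree counts distinct outgoing edges", {
  toy <- build_toy_network()
  od <- out_degree(toy)
  expect_equal(od[5], 8L)
  expect_equal(od[7:14], rep(0L, 8))
  expect_equal(sum(od), edge_count(toy))
  expect_equal(mean(out_degree(generate_er_network(100, 990, seed = 1))), 9.9)
})

test_that("k_shell_out matches hand-pruned small cases", {
  # complete digraph on 4 nodes: everyone survives k = 3
  cd <- directed_network(4, cbind(rep(1:4, each = 3),
                                  unlist(lapply(1:4, function(i) setdiff(1:4, i)))),
                         rep("E", 4))
  expect_equal(k_shell_out(cd), rep(3L, 4))
  # directed chain: removing the sink cascades, all shells 0
  ch <- directed_network(3, rbind(c(1, 2), c(2, 3)), rep("E", 3))
  expect_equal(k_shell_out(ch), rep(0L, 3))
})

test_that("k_shell_out equals literal brute-force pruning on random digraphs", {
  for (i in 1:60) {
    n <- sample(5:40, 1)
    net <- rand_digraph(n, stats::runif(1, 0.05, 0.5), seed = 5000 + i)
    expect_identical(k_shell_out(net), brute_k_shell_out(n, net$edges))
  }
})

test_that("k_shell_out never exceeds out-degree and igraph coreness agrees", {
  net <- rand_digraph(200, 0.05, seed = 17)
  ks <- k_shell_out(net)
  expect_true(all(ks <= out_degree(net)))
  expect_equal(ks, as.integer(igraph::coreness(as_igraph(net), mode = "out")))
})

test_that("deleting an edge never increases any k-shell-out index", {
  for (i in 1:20) {
    net <- rand_digraph(25, 0.2, seed = 900 + i)
    ks <- k_shell_out(net)
    drop <- sample(nrow(net$edges), 1)
    sub <- directed_network(net$n_nodes, net$edges[-drop, , drop = FALSE],
                            net$node_kind)
    expect_true(all(k_shell_out(sub) <= ks))
  }
})

test_that("clustering coefficient matches closed forms", {
  # undirected-projected complete graph -> 1
  cd <- directed_network(5, cbind(rep(1:5, each = 4),
                                  unlist(lapply(1:5, function(i) setdiff(1:5, i)))),
                         rep("E", 5))
  expect_equal(clustering_coefficient(cd), 1)
  # tree -> 0
  tr <- directed_network(7, cbind(rep(1:3, each = 2), 2:7), rep("E", 7))
  expect_equal(clustering_coefficient(tr), 0)
  # ring lattice, 4 nearest neighbours -> 3(k-2)/(4(k-1)) = 0.5
  n <- 20
  e <- do.call(rbind, lapply(1:n, function(i) cbind(i, ((i + c(1, 2) - 1) %% n) + 1)))
  ring <- directed_network(n, rbind(e, e[, 2:1]), rep("E", n))
  expect_equal(clustering_coefficient(ring), 0.5)
  expect_warning(clustering_coefficient(
    directed_network(4, rbind(c(1, 2)), rep("E", 4))), "degenerate")
})

test_that("average shortest path matches enumeration and the ER asymptotic", {
  cd <- directed_network(4, cbind(rep(1:4, each = 3),
                                  unlist(lapply(1:4, function(i) setdiff(1:4, i)))),
                         rep("E", 4))
  expect_equal(as.numeric(average_shortest_path(cd)), 1)
  p3 <- directed_network(3, rbind(c(1, 2), c(2, 3)), rep("E", 3))
  expect_equal(as.numeric(average_shortest_path(p3)), 4 / 3)
  expect_error(average_shortest_path(
    directed_network(3, matrix(integer(0), ncol = 2), rep("E", 3))), "edgeless")
  # ER with projected mean degree 10: L near ln(n)/ln(k)
  er <- generate_er_network(500, 2500, seed = 2)
  expect_lt(abs(as.numeric(average_shortest_path(er)) /
                  (log(500) / log(10)) - 1), 0.1)
})

test_that("small-world index self-normalizes on ER input and is label-invariant", {
  er <- generate_er_network(500, 5000, seed = 11)
  res <- small_world_index(er, n_references = 10, seed = 21)
  expect_lt(abs(res$swi - 1), 0.15)
  expect_equal(res$swi, (res$clustering / res$clustering_rand) /
                 (res$path_length / res$path_length_rand))
  # relabeling the nodes leaves the SWI unchanged
  set.seed(42)
  perm <- sample(er$n_nodes)
  relab <- directed_network(er$n_nodes,
                            cbind(perm[er$edges[, 1]], perm[er$edges[, 2]]),
                            er$node_kind[order(perm)])
  res2 <- small_world_index(relab, n_references = 10, seed = 21)
  expect_equal(res2$swi, res$swi, tolerance = 1e-12)
})

test_that("Watts-Strogatz input yields a super-unity small-world index", {
  set.seed(31)
  g <- igraph::sample_smallworld(1, 500, 5, 0.05)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- rbind(el, el[, 2:1])
  el <- el[!duplicated(paste(el[, 1], el[, 2])), ]
  ws <- directed_network(500, el, rep("E", 500))
  expect_gt(small_world_index(ws, n_references = 10, seed = 3)$swi, 1)
})

test_that("betweenness matches brute-force shortest-path enumeration", {
  # star via reciprocal edges: the centre dominates
  star <- directed_network(6, rbind(cbind(1, 2:6), cbind(2:6, 1)), rep("E", 6))
  b <- betweenness_centrality(star)
  expect_true(all(b[1] > b[2:6]))
  # complete digraph: no intermediate vertices
  cd <- directed_network(4, cbind(rep(1:4, each = 3),
                                  unlist(lapply(1:4, function(i) setdiff(1:4, i)))),
                         rep("E", 4))
  expect_equal(betweenness_centrality(cd), rep(0, 4))
  for (i in 1:8) {
    net <- rand_digraph(12, 0.2, seed = 700 + i)
    expect_equal(betweenness_centrality(net),
                 brute_betweenness(net$n_nodes, net$edges), tolerance = 1e-9)
  }
})

test_that("embeddedness metrics scale to large sparse networks", {
  net <- generate_er_network(10000, 1000000, seed = 4)
  elapsed <- system.time({
    prof <- embeddedness_profile(net)
  })[["elapsed"]]
  expect_lt(elapsed, 30)
  expect_equal(nrow(prof), 10000L)
  expect_false(anyNA(prof))
})
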