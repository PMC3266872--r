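test_that("generating_measure validates its fields", {
  expect_error(generating_measure(matrix(0.5, 2, 2), c(0.5, 0.6), 2), "sum to 1")
  expect_error(generating_measure(matrix(1.5, 2, 2), c(0.5, 0.5), 2), "\\[0, 1\\]")
  expect_error(generating_measure(matrix(0.5, 2, 2), c(0.5, 0.5), 0), ">= 1")
  expect_error(generating_measure(matrix(0.5, 2, 2), c(0.5, 0.5), 13), "exceeds limit")
  expect_error(generating_measure(rbind(c(0.9, 0.1), c(0.2, 0.9)), c(0.5, 0.5), 2),
               "symmetric")
})

test_that("multifractal generator is deterministic and density-calibrated", {
  m <- generating_measure(rbind(c(0.9, 0.1), c(0.1, 0.9)), c(0.25, 0.75), 3)
  a <- generate_multifractal_network(m, 500, 12, seed = 7)
  b <- generate_multifractal_network(m, 500, 12, seed = 7)
  expect_identical(a$edges, b$edges)
  # expected-density calibration over 20 draws: within 5% of n * mean degree
  ec <- vapply(1:20, function(i) {
    edge_count(generate_multifractal_network(m, 800, 15, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(ec) / (800 * 15) - 1), 0.05)
})

test_that("uniform generating measure degenerates to Erdos-Renyi statistics", {
  um <- generating_measure(matrix(0.5, 2, 2), c(0.5, 0.5), 2)
  ps <- vapply(1:20, function(i) {
    a <- generate_multifractal_network(um, 400, 8, seed = i)
    b <- generate_er_network(400, edge_count(a), seed = 100 + i)
    suppressWarnings(stats::ks.test(out_degree(a), out_degree(b))$p.value)
  }, numeric(1))
  # pooled: the two out-degree samples are indistinguishable
  expect_gt(stats::pchisq(-2 * sum(log(ps)), df = 40, lower.tail = FALSE), 0.01)
  expect_gt(min(ps), 0.01)
})

test_that("an assortative measure with unequal lengths inflates out-degree variance", {
  # equal interval lengths make every category's expected degree identical
  # (row sums of the iterated measure factorize), so heterogeneity requires
  # unequal lengths
  hm <- generating_measure(rbind(c(0.9, 0.1), c(0.1, 0.9)), c(0.25, 0.75), 3)
  vm <- stats::var(out_degree(generate_multifractal_network(hm, 1000, 20, seed = 1)))
  ve <- mean(vapply(1:20, function(i) {
    stats::var(out_degree(generate_er_network(1000, 20000, seed = i)))
  }, numeric(1)))
  expect_gt(vm / ve, 2)
})

test_that("a too-concentrated measure errors with the offending scale factor", {
  m <- generating_measure(rbind(c(1, 0.001), c(0.001, 1)), c(0.5, 0.5), 3)
  expect_error(generate_multifractal_network(m, 200, 60, seed = 1),
               "too concentrated")
})

test_that("node kinds follow the configured inhibitory fraction", {
  m <- generating_measure(matrix(0.5, 2, 2), c(0.5, 0.5), 2)
  net <- generate_multifractal_network(m, 10000, 20, inh_fraction = 0.2, seed = 1)
  expect_equal(sum(net$node_kind == "E"), 8000L)
  expect_equal(sum(net$node_kind == "I"), 2000L)
})

test_that("ER generator produces exact uniform edge sets", {
  expect_equal(edge_count(generate_er_network(50, 0, seed = 1)), 0L)
  er <- generate_er_network(100, 990, seed = 3)
  expect_equal(edge_count(er), 990L)
  expect_equal(mean(out_degree(er)), 9.9)
  expect_error(generate_er_network(10, 91, seed = 1), "n_edges")
  # matched control preserves node and edge counts
  m <- generating_measure(rbind(c(0.8, 0.2), c(0.2, 0.8)), c(0.4, 0.6), 2)
  mf <- generate_multifractal_network(m, 300, 10, seed = 5)
  ctrl <- generate_er_network(mf$n_nodes, edge_count(mf), seed = 6)
  expect_equal(ctrl$n_nodes, mf$n_nodes)
  expect_equal(edge_count(ctrl), edge_count(mf))
})

test_that("modular-hub network matches the Gedankenexperiment layout", {
  net <- build_modular_hub_network(seed = 1)
  expect_equal(net$n_nodes, 900L)
  expect_equal(which(net$node_kind == "E"), 1:700)
  expect_equal(which(net$node_kind == "I"), 701:900)
  small <- net$gen_meta$params$small
  large <- net$gen_meta$params$large
  hubs <- net$gen_meta$params$hubs
  expect_length(small, 150L)
  # strictly one-way: no edge from the small subnetwork into the large one
  from_small <- net$edges[net$edges[, 1] %in% small, 2]
  expect_length(intersect(from_small, c(large, hubs)), 0L)
  # every small node reachable from some hub; nothing in the large subnetwork
  # reachable from the small one
  g <- as_igraph(net)
  d_hub_small <- igraph::distances(g, v = hubs, to = small, mode = "out")
  expect_true(all(apply(d_hub_small, 2, function(x) any(is.finite(x)))))
  d_small_large <- igraph::distances(g, v = small, to = large, mode = "out")
  expect_true(all(!is.finite(d_small_large)))
  expect_error(build_modular_hub_network(n_total = 800), "inconsistent")
})

test_that("toy network pins the published wiring", {
  toy <- build_toy_network()
  expect_equal(toy$n_nodes, 14L)
  tg <- function(v) sort(toy$edges[toy$edges[, 1] == v, 2])
  expect_equal(tg(5), 7:14)
  expect_equal(tg(1), c(2L, 3L, 4L, 6L))
  expect_equal(out_degree(toy)[7:14], rep(0L, 8))
  ks <- k_shell_out(toy)
  expect_gt(ks[1], ks[5])
  expect_identical(build_toy_network()$edges, toy$edges)
})

test_that("default ensemble spans sub- and super-unity small-world indices", {
  meas <- ensemble_measures(10, seed = 0)
  swi <- vapply(seq_along(meas), function(i) {
    net <- generate_multifractal_network(meas[[i]], 500, 10, seed = i - 1)
    small_world_index(net, n_references = 5, seed = 50 + i)$swi
  }, numeric(1))
  expect_lt(min(swi), 1)
  expect_gt(max(swi), 1)
})
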