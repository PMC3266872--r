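test_that("subpopulation selection stratifies excitatory nodes disjointly", {
  # 10 nodes, metric = node id, 2 groups of 5
  prof <- data.frame(node = 1:10, out_degree = 1:10, k_shell_out = 0L)
  plan <- select_subpopulations(prof, rep("E", 10), "out_degree",
                                n_groups = 2, group_size = 5)
  expect_equal(sort(plan$groups[[1]]), 1:5)
  expect_equal(sort(plan$groups[[2]]), 6:10)
  expect_true(all(diff(plan$group_means) > 0))
  # constant metric cannot stratify
  prof$out_degree <- 5L
  expect_error(select_subpopulations(prof, rep("E", 10), "out_degree", 2, 5),
               "cannot stratify")
  # too few excitatory nodes
  expect_error(select_subpopulations(data.frame(node = 1:10, out_degree = 1:10),
                                     rep("E", 10), "out_degree", 3, 5),
               "too few")
})

test_that("the full-scale plan covers 7500 distinct excitatory nodes", {
  set.seed(2)
  prof <- data.frame(node = 1:10000, out_degree = stats::rpois(10000, 50))
  kinds <- c(rep("E", 8000), rep("I", 2000))
  plan <- select_subpopulations(prof, kinds, "out_degree",
                                n_groups = 30, group_size = 250)
  all_nodes <- unlist(plan$groups)
  expect_length(all_nodes, 7500L)
  expect_equal(anyDuplicated(all_nodes), 0L)
  expect_true(all(kinds[all_nodes] == "E"))
  expect_true(all(diff(plan$group_means) > 0))
})

test_that("PSTH bins are left-closed right-open and population-summed", {
  sp <- spike_data(c(1, 2, 3), c(1L, 2L, 1L), t_stop = 5, n_nodes = 3L)
  h <- compute_psth(sp, bin_width = 1, window = c(0, 4))
  expect_equal(h$counts, c(0L, 1L, 1L, 1L))
  expect_equal(sum(h$counts), 3L)
  # boundary spike falls in the right-hand bin
  sp2 <- spike_data(2, 1L, t_stop = 5, n_nodes = 1L)
  h2 <- compute_psth(sp2, bin_width = 2, window = c(0, 6))
  expect_equal(h2$counts, c(0L, 1L, 0L))
  expect_error(compute_psth(sp, 1, c(3, 3)), "empty")
  # no spikes -> all-zero counts
  sp0 <- spike_data(numeric(0), integer(0), t_stop = 5, n_nodes = 2L)
  expect_equal(compute_psth(sp0, 1, c(0, 4))$counts, rep(0L, 4))
})

test_that("response peak reads the PSTH maximum, optionally baseline-corrected", {
  sp <- spike_data(c(0.5, 1.5, 2.5, 3.1, 3.2, 3.3), rep(1L, 6),
                   t_stop = 5, n_nodes = 1L)
  h <- compute_psth(sp, bin_width = 1, window = c(0, 5))
  expect_equal(response_peak(h), 3)
  expect_equal(response_peak(h, baseline_window = c(0, 3)), 3 - 1)
  flat <- compute_psth(spike_data(c(0.5, 1.5), c(1L, 1L), 5, 1L), 1, c(0, 2))
  expect_equal(response_peak(flat), 1)
})

test_that("the experiment grid is keyed, complete and deterministic", {
  m <- ensemble_measures(1, seed = 0, include_disassortative = FALSE)[[1]]
  net <- generate_multifractal_network(m, 400, 12, seed = 3)
  p <- lif_params(j_exc = 1)
  rec <- run_experiment_grid(list(net), n_groups = 2, group_size = 40,
                             params = p, background_rates = 10000,
                             stim_rate = 2000, n_trials = 1, seed = 6)
  expect_equal(nrow(rec), 2L)
  expect_true(all(c("network", "group", "trial", "mean_out_degree",
                    "mean_k_shell_out", "psth_peak", "total_spikes",
                    "baseline_spikes", "control_spikes", "failed") %in% names(rec)))
  expect_true(all(rec$psth_peak <= rec$total_spikes))
  expect_false(any(rec$failed))
  rec2 <- run_experiment_grid(list(net), n_groups = 2, group_size = 40,
                              params = p, background_rates = 10000,
                              stim_rate = 2000, n_trials = 1, seed = 6)
  expect_identical(rec, rec2)
})

test_that("only the stimulated targets differ between group protocols", {
  a <- make_stimulus(1:10, onset = 200, duration = 30, rate = 4000, weight = 1)
  b <- make_stimulus(11:20, onset = 200, duration = 30, rate = 4000, weight = 1)
  fields <- setdiff(names(a), "targets")
  expect_equal(unclass(a)[fields], unclass(b)[fields])
  expect_false(any(a$targets %in% b$targets))
})

test_that("stimulating the higher-out-degree group usually evokes the larger peak", {
  m <- ensemble_measures(2, seed = 0, include_disassortative = FALSE)[[2]]
  net <- generate_multifractal_network(m, 800, 30, seed = 4)
  p <- lif_params(j_exc = 1)
  bg <- calibrate_background(net, p, seed = 2)
  prof <- embeddedness_profile(net)
  plan <- select_subpopulations(prof, net$node_kind, "out_degree",
                                n_groups = 2, group_size = 80)
  peaks <- function(gr, sd) {
    st <- make_stimulus(gr, 200, 30, 4000, p$j_exc)
    sp <- simulate_lif(net, p, background_rate = bg, stimuli = st,
                       t_stop = 300, seed = sd)
    response_peak(compute_psth(sp, 5, c(200, 300)))
  }
  wins <- vapply(1:10, function(sd) {
    peaks(plan$groups[[2]], sd) >= peaks(plan$groups[[1]], sd)
  }, logical(1))
  expect_gte(sum(wins), 8L)
})
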