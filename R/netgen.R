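#' Generating measure for the multifractal network generator
#'
#' A multifractal generating measure is a k x k symmetric matrix of link
#' probabilities together with k interval lengths summing to one. Iterating the
#' measure m times refines the unit interval into k^m sub-intervals; the link
#' probability between two sub-intervals is the product of the m matrix entries
#' indexed by the two category sequences. Networks drawn from such a measure
#' range from Erdos-Renyi-like (uniform matrix) to strongly heterogeneous,
#' clustered topologies (diagonal-dominant matrix).
#'
#' @param link_probs k x k symmetric numeric matrix with entries in \[0, 1\].
#' @param lengths k positive interval lengths summing to 1 (within 1e-12).
#' @param iterations number of refinement iterations m >= 1.
#' @param max_intervals upper bound on k^m, guarding against blow-up.
#'
#' @return An object of class `generating_measure`.
#' @export
generating_measure <- function(link_probs, lengths, iterations,
                               max_intervals = 4096L) {
  link_probs <- as.matrix(link_probs)
  k <- nrow(link_probs)
  if (k < 2L || ncol(link_probs) != k) {
    stop("link_probs must be a square matrix with k >= 2")
  }
  if (any(link_probs < 0) || any(link_probs > 1)) {
    stop("all link_probs entries must lie in [0, 1]")
  }
  if (!isTRUE(all.equal(link_probs, t(link_probs), tolerance = 1e-12))) {
    stop("link_probs must be symmetric (the pair probability is unordered)")
  }
  if (length(lengths) != k || any(lengths <= 0)) {
    stop("lengths must be k positive reals")
  }
  if (abs(sum(lengths) - 1) > 1e-12) stop("lengths must sum to 1 (within 1e-12)")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (k^iterations > max_intervals) {
    stop(sprintf("k^m = %d refined intervals exceeds limit %d",
                 k^iterations, max_intervals))
  }
  structure(
    list(n_categories = k, link_probs = link_probs,
         lengths = as.numeric(lengths), iterations = iterations),
    class = "generating_measure"
  )
}

#' @export
print.generating_measure <- function(x, ...) {
  cat(sprintf("<generating_measure> k=%d, m=%d, lengths=(%s)\n",
              x$n_categories, x$iterations,
              paste(signif(x$lengths, 3), collapse = ", ")))
  print(signif(x$link_probs, 3))
  invisible(x)
}

# Block-level view of the iterated measure: category sequences of length m
# collapse node coordinates into k^m blocks, so the generator is a stochastic
# block model whose block probabilities are m-fold entry products.
iterated_blocks <- function(measure) {
  k <- measure$n_categories
  m <- measure$iterations
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  nb <- nrow(seqs)
  pb <- matrix(1, nb, nb)
  for (t in seq_len(m)) {
    pb <- pb * measure$link_probs[seqs[, t], seqs[, t], drop = FALSE]
  }
  list(pb = pb, seqs = seqs, nb = nb)
}

#' Draw a directed network from a multifractal generating measure
#'
#' Each node receives an independent category sequence (equivalently a uniform
#' coordinate on \[0, 1) read through the iterated interval division); every
#' ordered pair (i, j), i != j, receives an edge with probability proportional
#' to the iterated measure value at the two coordinates, globally rescaled so
#' that the expected edge count equals `n_nodes * target_mean_degree`.
#' Probabilities are clipped to \[0, 1\] after rescaling; if the clipped mass
#' affects more than `max_clip_fraction` of ordered pairs the measure is too
#' concentrated for the requested density and an error is raised. The forward
#' and backward edge of a pair are sampled independently with the same
#' probability.
#'
#' @param measure a [generating_measure()].
#' @param n_nodes number of nodes (>= 2).
#' @param target_mean_degree desired mean out-degree (< n_nodes - 1).
#' @param inh_fraction fraction of inhibitory nodes; default 0.2 gives the
#'   conventional 4:1 excitatory:inhibitory split.
#' @param seed integer RNG seed; the draw is deterministic given the seed.
#' @param max_clip_fraction largest tolerated fraction of ordered pairs whose
#'   rescaled probability exceeds 1.
#'
#' @return A [directed_network()].
#' @export
generate_multifractal_network <- function(measure, n_nodes, target_mean_degree,
                                          inh_fraction = 0.2, seed = 1L,
                                          max_clip_fraction = 0.05) {
  stopifnot(inherits(measure, "generating_measure"))
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("n_nodes must be >= 2")
  if (target_mean_degree >= n_nodes - 1) {
    stop("target_mean_degree must be < n_nodes - 1")
  }
  set.seed(seed)
  k <- measure$n_categories
  m <- measure$iterations
  blocks <- iterated_blocks(measure)

  cats <- matrix(
    sample.int(k, n_nodes * m, replace = TRUE, prob = measure$lengths),
    nrow = n_nodes, ncol = m
  )
  # block index via base-k encoding matching expand.grid order (first column
  # varies fastest)
  block <- as.integer(1 + (cats - 1L) %*% k^(seq_len(m) - 1L))
  n_per <- tabulate(block, nbins = blocks$nb)

  # ordered candidate-pair counts per block pair
  npairs <- outer(n_per, n_per)
  diag(npairs) <- diag(npairs) - n_per
  e_expected <- sum(blocks$pb * npairs)
  if (e_expected <= 0) stop("measure assigns zero probability everywhere")
  scale <- n_nodes * target_mean_degree / e_expected
  p <- scale * blocks$pb
  clipped <- sum(npairs[p > 1]) / sum(npairs)
  if (clipped > max_clip_fraction) {
    stop(sprintf(paste0(
      "rescaling factor %.3g pushes %.1f%% of pair probabilities above 1 ",
      "(limit %.1f%%): measure too concentrated for the requested density"),
      scale, 100 * clipped, 100 * max_clip_fraction))
  }
  p <- pmin(p, 1)

  members <- split(seq_len(n_nodes), factor(block, levels = seq_len(blocks$nb)))
  pre <- integer(0); post <- integer(0)
  for (a in seq_len(blocks$nb)) {
    na <- n_per[a]
    if (na == 0L) next
    for (b in seq_len(blocks$nb)) {
      nb_ <- n_per[b]
      np <- npairs[a, b]
      if (np == 0L || p[a, b] == 0) next
      ne <- stats::rbinom(1L, np, p[a, b])
      if (ne == 0L) next
      idx <- sample.int(np, ne)
      if (a == b) {
        r <- (idx - 1L) %/% (na - 1L) + 1L
        c0 <- (idx - 1L) %% (na - 1L) + 1L
        j <- c0 + (c0 >= r)
        pre <- c(pre, members[[a]][r]); post <- c(post, members[[a]][j])
      } else {
        r <- (idx - 1L) %/% nb_ + 1L
        c0 <- (idx - 1L) %% nb_ + 1L
        pre <- c(pre, members[[a]][r]); post <- c(post, members[[b]][c0])
      }
    }
  }
  directed_network(
    n_nodes, cbind(pre, post), prefix_kinds(n_nodes, inh_fraction),
    gen_meta = list(
      generator = "multifractal", seed = seed,
      params = list(k = k, iterations = m,
                    link_probs = measure$link_probs,
                    lengths = measure$lengths,
                    target_mean_degree = target_mean_degree,
                    inh_fraction = inh_fraction))
  )
}

#' Draw an Erdos-Renyi directed control network
#'
#' Samples exactly `n_edges` distinct directed non-self edges uniformly at
#' random: the randomization model that preserves node and edge counts (hence
#' average connectivity) of a network it is matched to, but none of its
#' specific topology.
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of directed edges, 0 <= n_edges <= n_nodes*(n_nodes-1).
#' @param inh_fraction fraction of inhibitory nodes.
#' @param seed integer RNG seed.
#' @return A [directed_network()].
#' @export
generate_er_network <- function(n_nodes, n_edges, inh_fraction = 0.2, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  n_edges <- as.integer(n_edges)
  max_edges <- as.numeric(n_nodes) * (n_nodes - 1)
  if (n_edges < 0L || n_edges > max_edges) {
    stop(sprintf("n_edges must lie in [0, %d]", max_edges))
  }
  set.seed(seed)
  idx <- sample.int(max_edges, n_edges)
  pre <- (idx - 1L) %/% (n_nodes - 1L) + 1L
  r <- (idx - 1L) %% (n_nodes - 1L) + 1L
  post <- r + (r >= pre)
  directed_network(
    n_nodes, cbind(pre, post), prefix_kinds(n_nodes, inh_fraction),
    gen_meta = list(generator = "er", seed = seed,
                    params = list(n_edges = n_edges, inh_fraction = inh_fraction))
  )
}

#' Build the modular-hub network
#'
#' Two random subnetworks — a large one and a small one — each wired internally
#' as a directed Bernoulli graph with probability `p_within`, plus `n_hubs`
#' excitatory nodes of the large subnetwork that additionally send one-way
#' projections onto the small subnetwork (`hub_fan_out` random targets each).
#' There are no edges from the small subnetwork back to the large one or to the
#' hubs, so activity in the small subnetwork cannot influence the large one:
#' correlated events observed there are, by construction, an epiphenomenon of
#' hub activation.
#'
#' Node layout (1-based): excitatory nodes first (large then small), then
#' inhibitory nodes (large then small). With the defaults this yields ids 1-700
#' excitatory and 701-900 inhibitory, a small subnetwork of 150 nodes
#' (ids 581-700 and 871-900), and 900 nodes in total.
#'
#' @param n_large_exc,n_large_inh excitatory / inhibitory sizes of the large
#'   subnetwork.
#' @param n_small size of the small subnetwork (an `small_inh_fraction` of it
#'   inhibitory).
#' @param n_hubs number of hub nodes, drawn from the large excitatory nodes.
#' @param p_within internal connection probability of both subnetworks.
#' @param hub_fan_out number of small-subnetwork targets per hub.
#' @param small_inh_fraction inhibitory fraction inside the small subnetwork.
#' @param n_total expected total size; an inconsistent partition errors.
#' @param seed integer RNG seed.
#'
#' @return A [directed_network()]; `gen_meta$params` records the hub ids and
#'   the small-subnetwork member ids.
#' @export
build_modular_hub_network <- function(n_large_exc = 580L, n_large_inh = 170L,
                                      n_small = 150L, n_hubs = 50L,
                                      p_within = 0.1, hub_fan_out = 100L,
                                      small_inh_fraction = 0.2,
                                      n_total = n_large_exc + n_large_inh + n_small,
                                      seed = 1L) {
  if (n_large_exc + n_large_inh + n_small != n_total) {
    stop("subnetwork sizes are inconsistent with the requested total")
  }
  n_small_inh <- round(small_inh_fraction * n_small)
  n_small_exc <- n_small - n_small_inh
  n_exc <- n_large_exc + n_small_exc
  n <- n_total
  # layout: [large exc][small exc][large inh][small inh]
  large <- c(seq_len(n_large_exc), n_exc + seq_len(n_large_inh))
  small <- c(n_large_exc + seq_len(n_small_exc), n_exc + n_large_inh + seq_len(n_small_inh))
  kinds <- c(rep("E", n_exc), rep("I", n - n_exc))

  set.seed(seed)
  bernoulli_block <- function(ids, p) {
    nn <- length(ids)
    np <- as.numeric(nn) * (nn - 1)
    hit <- which(stats::runif(np) < p)
    pre <- (hit - 1L) %/% (nn - 1L) + 1L
    r <- (hit - 1L) %% (nn - 1L) + 1L
    post <- r + (r >= pre)
    cbind(ids[pre], ids[post])
  }
  e_large <- bernoulli_block(large, p_within)
  e_small <- bernoulli_block(small, p_within)
  hubs <- sort(sample(seq_len(n_large_exc), n_hubs))
  if (hub_fan_out > n_small) stop("hub_fan_out exceeds the small subnetwork size")
  e_hub <- do.call(rbind, lapply(hubs, function(h) {
    cbind(h, sample(small, hub_fan_out))
  }))
  edges <- rbind(e_large, e_small, e_hub)
  edges <- edges[!duplicated((as.numeric(edges[, 1]) - 1) * n + edges[, 2]), , drop = FALSE]
  directed_network(
    n, edges, kinds,
    gen_meta = list(generator = "modular_hub", seed = seed,
                    params = list(n_large_exc = n_large_exc,
                                  n_large_inh = n_large_inh,
                                  n_small = n_small, n_hubs = n_hubs,
                                  p_within = p_within, hub_fan_out = hub_fan_out,
                                  hubs = hubs, small = sort(small),
                                  large = sort(large)))
  )
}

#' Build the 14-node toy network
#'
#' A fixed deterministic network contrasting two candidate influencers: node 5
#' fans out to the eight leaf nodes 7-14 (high out-degree, but its targets are
#' sinks), while node 1 sits inside a recurrent core {1, 2, 3, 4, 6} of lower
#' out-degree but higher k-shell-out index; the core reaches node 5 through the
#' bridge 6 -> 5. Under regular firing node 5 activates more nodes than node 1,
#' but under bursting node 1's activation sweeps the whole network while node
#' 5's still dies in the leaves — the interaction the cascade model quantifies.
#'
#' @return A [directed_network()] with 14 excitatory nodes.
#' @export
build_toy_network <- function() {
  edges <- rbind(
    cbind(1L, c(2L, 3L, 4L, 6L)),
    cbind(2L, c(3L, 4L)),
    cbind(3L, c(4L, 6L)),
    cbind(4L, c(6L, 1L)),
    cbind(6L, c(1L, 2L, 5L)),
    cbind(5L, 7:14)
  )
  directed_network(14L, edges, rep("E", 14L),
                   gen_meta = list(generator = "toy", seed = NA,
                                   params = list()))
}

#' Default heterogeneous ensemble of generating measures
#'
#' Draws an ensemble of 2-category generating measures spanning a wide range
#' of topologies: iterations m in {2, 3}, diagonal entries in \[0.3, 0.95\],
#' off-diagonal in \[0.02, 0.4\], first interval length in \[0.2, 0.8\] —
#' assortative (clustered) topologies of varying heterogeneity. When
#' `include_disassortative` is set (the default), every 5th draw is instead
#' mapped into a disassortative regime (diagonal \[0.05, 0.3\], off-diagonal
#' \[0.45, 0.8\]) whose bipartite-like structure has *sub-random* clustering,
#' so the realized small-world index of the ensemble spans values below and
#' above 1. The underlying random draws are identical for both settings, so
#' the assortative draws agree entry-for-entry between them.
#'
#' @param n_measures number of measures to draw.
#' @param seed integer RNG seed for the parameter draws.
#' @param include_disassortative map every 5th draw into the disassortative
#'   regime; disable to obtain a purely assortative (heterogeneous-out-degree)
#'   ensemble.
#' @return list of [generating_measure()] objects.
#' @export
ensemble_measures <- function(n_measures = 100L, seed = 0L,
                              include_disassortative = TRUE) {
  set.seed(seed)
  lapply(seq_len(n_measures), function(i) {
    m <- sample(2:3, 1L)
    d <- stats::runif(2L, 0.3, 0.95)
    o <- stats::runif(1L, 0.02, 0.4)
    l1 <- stats::runif(1L, 0.2, 0.8)
    if (include_disassortative && i %% 5L == 0L) {
      d <- 0.05 + (d - 0.3) / 0.65 * 0.25
      o <- 0.45 + (o - 0.02) / 0.38 * 0.35
    }
    generating_measure(matrix(c(d[1], o, o, d[2]), 2L, 2L),
                       lengths = c(l1, 1 - l1), iterations = m)
  })
}
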