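# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately literal restatements of the definitions, sharing no
# code with the package internals.

# k-shell-out by literal repeated pruning: for k = 1, 2, ... delete every node
# whose out-degree within the surviving subgraph is < k, until stable.
brute_k_shell_out <- function(n, edges) {
  shell <- integer(n)
  alive <- rep(TRUE, n)
  k <- 1L
  while (any(alive)) {
    repeat {
      if (nrow(edges) > 0L) {
        keep <- alive[edges[, 1L]] & alive[edges[, 2L]]
        od <- tabulate(edges[keep, 1L], nbins = n)
      } else {
        od <- integer(n)
      }
      rem <- which(alive & od < k)
      if (length(rem) == 0L) break
      shell[rem] <- k - 1L
      alive[rem] <- FALSE
    }
    k <- k + 1L
  }
  shell
}

# Betweenness by explicit enumeration of every shortest path (exponential;
# keep n small). BFS distances, then recursive backtracking over predecessors.
brute_betweenness <- function(n, edges) {
  out_adj <- lapply(seq_len(n), function(v) edges[edges[, 1L] == v, 2L])
  in_adj <- lapply(seq_len(n), function(v) edges[edges[, 2L] == v, 1L])
  btw <- numeric(n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(out_adj[frontier])), which(is.finite(d)))
      d[nxt] <- d[frontier[1L]] + 1
      frontier <- nxt
    }
    enum_paths <- function(u) {
      if (u == s) return(list(s))
      preds <- in_adj[[u]][d[in_adj[[u]]] == d[u] - 1]
      unlist(lapply(preds, function(w) {
        lapply(enum_paths(w), function(pp) c(pp, u))
      }), recursive = FALSE)
    }
    for (t in seq_len(n)) {
      if (t == s || !is.finite(d[t])) next
      paths <- enum_paths(t)
      interior <- unlist(lapply(paths, function(pp) pp[-c(1L, length(pp))]))
      if (length(interior) > 0L) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        btw[idx] <- btw[idx] + as.numeric(tab) / length(paths)
      }
    }
  }
  btw
}

# Threshold cascade by fixed-point recomputation: given a tier assignment,
# recompute every node's tier from scratch as 1 + the first tier at which its
# cumulative input reaches theta; iterate to the fixed point.
brute_cascade_tiers <- function(net, seed_node, params) {
  n <- net$n_nodes
  A <- matrix(0, n, n)
  A[net$edges] <- 1
  u_emit <- rep(if (params$mode == "bursting") params$spikes_burst else 1, n)
  u_emit[seed_node] <- params$spikes_stimulus
  tier <- rep(NA_integer_, n); tier[seed_node] <- 0L
  repeat {
    newtier <- rep(NA_integer_, n); newtier[seed_node] <- 0L
    for (v in setdiff(seq_len(n), seed_node)) {
      for (t in 0:n) {
        emitters <- which(!is.na(tier) & tier <= t)
        if (length(emitters) == 0L) next
        if (sum(u_emit[emitters] * A[emitters, v]) >= params$theta) {
          newtier[v] <- t + 1L
          break
        }
      }
    }
    if (identical(newtier, tier)) break
    tier <- newtier
  }
  tier
}

# textbook two-pass Pearson correlation
two_pass_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random simple digraph as a directed_network
rand_digraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(matrix(stats::runif(n * n), n, n) < p & !diag(n), arr.ind = TRUE)
  directed_network(n, pairs, rep("E", n))
}
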