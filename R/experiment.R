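#' Select embeddedness-stratified subpopulations
#'
#' Sorts the excitatory nodes by a per-node metric (ties broken by node id)
#' and takes `n_groups` disjoint contiguous blocks of `group_size` nodes
#' spanning the sorted range (block starts equally spaced when there are more
#' excitatory nodes than `n_groups * group_size`), so every group has a
#' different — strictly increasing — average degree of embeddedness.
#'
#' @param profile an [embeddedness_profile()] (or data.frame with columns
#'   `node` and the metric).
#' @param node_kinds per-node `"E"`/`"I"` labels.
#' @param metric column name to stratify by (`"out_degree"`, `"k_shell_out"`,
#'   ...).
#' @param n_groups number of groups; default 30.
#' @param group_size nodes per group; default 250.
#' @return object of class `subpopulation_plan`: list with `groups` (list of
#'   node-id vectors, low to high metric), `metric`, `group_means`.
#' @export
select_subpopulations <- function(profile, node_kinds, metric = "out_degree",
                                  n_groups = 30L, group_size = 250L) {
  stopifnot(metric %in% names(profile))
  exc <- profile$node[node_kinds[profile$node] == "E"]
  n_exc <- length(exc)
  if (n_groups * group_size > n_exc) {
    stop(sprintf("too few excitatory nodes (%d) for %d groups of %d",
                 n_exc, n_groups, group_size))
  }
  vals <- profile[[metric]][match(exc, profile$node)]
  ord <- exc[order(vals, exc)]
  # equally spaced disjoint block starts across the sorted range
  starts <- round(seq(1, n_exc - group_size + 1, length.out = n_groups))
  for (i in seq_len(n_groups)[-1]) {
    starts[i] <- max(starts[i], starts[i - 1] + group_size)
  }
  groups <- lapply(starts, function(s) ord[s:(s + group_size - 1L)])
  means <- vapply(groups, function(gr) mean(profile[[metric]][match(gr, profile$node)]),
                  numeric(1))
  if (any(diff(means) <= 0)) {
    stop("cannot stratify: group mean ", metric, " values are not strictly increasing")
  }
  structure(list(groups = groups, metric = metric, group_means = means),
            class = "subpopulation_plan")
}

#' @export
print.subpopulation_plan <- function(x, ...) {
  cat(sprintf("<subpopulation_plan> %d groups of %d nodes by %s; group means %.3g .. %.3g\n",
              length(x$groups), length(x$groups[[1]]), x$metric,
              min(x$group_means), max(x$group_means)))
  invisible(x)
}

#' Peri-stimulus time histogram
#'
#' Population-summed spike counts in left-closed right-open time bins over a
#' window.
#'
#' @param spikes a [spike_data()].
#' @param bin_width bin width (ms) > 0.
#' @param window `c(t0, t1)` ms, t1 > t0.
#' @return object of class `psth`: `counts`, `breaks`, `bin_width`, `window`.
#' @export
compute_psth <- function(spikes, bin_width = 5, window) {
  stopifnot(bin_width > 0)
  if (window[2] <= window[1]) stop("empty PSTH window")
  breaks <- seq(window[1], window[2], by = bin_width)
  if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, window[2])
  t <- spikes$times[spikes$times >= window[1] & spikes$times < window[2]]
  counts <- if (length(t) > 0L) {
    tabulate(findInterval(t, breaks, left.open = FALSE), nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  structure(list(counts = counts, breaks = breaks, bin_width = bin_width,
                 window = window),
            class = "psth")
}

#' Peak of a PSTH
#'
#' The maximum bin count of the histogram, optionally after subtracting a
#' baseline estimated as the mean bin count over `baseline_window` (off by
#' default: the raw peak is the response measure).
#'
#' @param psth a [compute_psth()] result.
#' @param baseline_window optional `c(t0, t1)` ms used to estimate and
#'   subtract a baseline level per bin.
#' @return numeric peak (spikes per bin).
#' @export
response_peak <- function(psth, baseline_window = NULL) {
  peak <- max(psth$counts)
  if (!is.null(baseline_window)) {
    lo <- psth$breaks[-length(psth$breaks)]
    base <- mean(psth$counts[lo >= baseline_window[1] & lo < baseline_window[2]])
    peak <- peak - base
  }
  peak
}

#' Run the stimulation-grid experiment
#'
#' For each network: stratify excitatory nodes into embeddedness groups,
#' calibrate (or accept) a background rate, and run one simulation per
#' (group, trial) in which only the stimulated `targets` differ between
#' groups — stimulus onset, duration, rate and weight are identical. Each
#' record carries the group's mean out-degree and mean k-shell-out index, the
#' PSTH peak and the network-wide total spike count in the response window.
#'
#' @param networks list of [directed_network()] objects (names become network
#'   ids; unnamed lists are numbered).
#' @param metric stratification metric, `"out_degree"` or `"k_shell_out"`.
#' @param n_groups,group_size subpopulation plan (see
#'   [select_subpopulations()]).
#' @param params a [lif_params()].
#' @param background_rates per-network background rate (events/s); a single
#'   value is recycled; `NULL` calibrates per network with
#'   [calibrate_background()].
#' @param stim_onset,stim_duration,stim_rate,stim_weight stimulus parameters
#'   shared by every group (see [make_stimulus()]); the default weight is the
#'   excitatory synaptic jump `params$j_exc`, i.e. stimulus events are
#'   ordinary excitatory synaptic events, and the default rate of 1000
#'   events/s puts the mean stimulus drive (`rate * weight * tau_m`) at the
#'   threshold distance, supra-noise but non-saturating.
#' @param response_window length of the response window (ms) starting at
#'   stimulus onset.
#' @param psth_bin PSTH bin width (ms).
#' @param n_trials trials per group (seeded independently).
#' @param seed master seed; records are keyed by (network, group, trial) and a
#'   rerun with the same seed reproduces them exactly.
#' @return data.frame with one row per (network, group, trial):
#'   `network`, `group`, `trial`, `mean_out_degree`, `mean_k_shell_out`,
#'   `psth_peak`, `total_spikes`, `baseline_spikes` (count in an equally long
#'   pre-onset window), `control_spikes` (count in the response window of a
#'   twin run with identical seed and no stimulus, so `total_spikes -
#'   control_spikes` is the causally evoked response), `failed`.
#' @export
run_experiment_grid <- function(networks, metric = "out_degree",
                                n_groups = 30L, group_size = 250L,
                                params = lif_params(),
                                background_rates = NULL,
                                stim_onset = 200, stim_duration = 30,
                                stim_rate = 4000, stim_weight = NULL,
                                response_window = 100, psth_bin = 5,
                                n_trials = 1L, seed = 1L) {
  stim_weight <- stim_weight %||% params$j_exc
  if (inherits(networks, "directed_network")) networks <- list(networks)
  ids <- names(networks) %||% NULL
  if (is.null(ids)) ids <- as.character(seq_along(networks))
  t_stop <- stim_onset + response_window
  rows <- list()
  for (ni in seq_along(networks)) {
    net <- networks[[ni]]
    prof <- embeddedness_profile(net)
    plan <- select_subpopulations(prof, net$node_kind, metric,
                                  n_groups = n_groups, group_size = group_size)
    bg <- if (is.null(background_rates)) {
      as.numeric(calibrate_background(net, params, seed = seed + 1000L * ni))
    } else if (length(background_rates) == 1L) {
      background_rates
    } else {
      background_rates[ni]
    }
    # one no-stimulus twin run per trial: identical seed, hence identical
    # background streams -- its response-window count is the causal control
    ctrl <- vapply(seq_len(n_trials), function(tr) {
      run_seed <- seed + 100000L * ni + 100L * tr
      sp <- simulate_lif(net, params, background_rate = bg, t_stop = t_stop,
                         seed = run_seed)
      sum(sp$times >= stim_onset & sp$times < stim_onset + response_window)
    }, numeric(1))
    for (gi in seq_along(plan$groups)) {
      gr <- plan$groups[[gi]]
      for (tr in seq_len(n_trials)) {
        run_seed <- seed + 100000L * ni + 100L * tr
        stim <- make_stimulus(gr, onset = stim_onset, duration = stim_duration,
                              rate = stim_rate, weight = stim_weight)
        rec <- tryCatch({
          sp <- simulate_lif(net, params, background_rate = bg, stimuli = stim,
                             t_stop = t_stop, seed = run_seed)
          win <- c(stim_onset, stim_onset + response_window)
          psth <- compute_psth(sp, bin_width = psth_bin, window = win)
          base_win <- c(stim_onset - response_window, stim_onset)
          list(psth_peak = response_peak(psth),
               total_spikes = sum(sp$times >= win[1] & sp$times < win[2]),
               baseline_spikes = sum(sp$times >= base_win[1] & sp$times < base_win[2]),
               failed = FALSE)
        }, error = function(e) {
          warning(sprintf("simulation failed (network %s, group %d, trial %d): %s",
                          ids[ni], gi, tr, conditionMessage(e)))
          list(psth_peak = NA_real_, total_spikes = NA_integer_,
               baseline_spikes = NA_integer_, failed = TRUE)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          network = ids[ni], group = gi, trial = tr,
          mean_out_degree = mean(prof$out_degree[match(gr, prof$node)]),
          mean_k_shell_out = mean(prof$k_shell_out[match(gr, prof$node)]),
          psth_peak = rec$psth_peak, total_spikes = rec$total_spikes,
          baseline_spikes = rec$baseline_spikes,
          control_spikes = ctrl[tr], failed = rec$failed
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  n_failed <- sum(out$failed)
  if (n_failed > 0L) {
    message(sprintf("%d of %d grid simulations failed", n_failed, nrow(out)))
  }
  out
}
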