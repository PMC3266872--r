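#' Leaky integrate-and-fire parameters
#'
#' Current-based (delta-synapse) LIF neuron constants. The defaults are the
#' canonical sparse balanced-network regime: membrane time constant 20 ms,
#' resting and reset potential 0 mV, threshold 20 mV, absolute refractory
#' period 2 ms, synaptic delay 1.5 ms, excitatory post-synaptic jump 0.1 mV,
#' relative inhibitory strength g = 5 (inhibitory jump = -g * j_exc) and
#' integration step 0.1 ms — a configuration producing asynchronous-irregular
#' baseline activity once the background rate is calibrated (see
#' [calibrate_background()]).
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest,v_reset,v_th resting, reset and threshold potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param delay synaptic transmission delay (ms); must be >= dt.
#' @param j_exc excitatory post-synaptic potential jump (mV).
#' @param g dimensionless inhibition/excitation strength ratio (>= 0).
#' @param dt integration step (ms).
#' @return object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 20, v_rest = 0, v_reset = 0, v_th = 20,
                       t_ref = 2, delay = 1.5, j_exc = 0.1, g = 5, dt = 0.1) {
  stopifnot(tau_m > 0, dt > 0, delay > 0, t_ref > 0, v_th > v_reset, g >= 0,
            delay >= dt)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset, v_th = v_th,
                 t_ref = t_ref, delay = delay, j_exc = j_exc, g = g, dt = dt),
            class = "lif_params")
}

#' Timed Poisson stimulus protocol
#'
#' An extra independent Poisson event stream delivered to every target neuron
#' during `[onset, onset + duration)`. Construction only validates; a protocol
#' whose window lies beyond the end of a simulation simply has no effect.
#'
#' @param targets nonempty vector of 1-based target node ids.
#' @param onset stimulus onset (ms).
#' @param duration stimulus duration (ms); default 30.
#' @param rate event rate per target (events/s).
#' @param weight voltage jump per event (mV).
#' @return object of class `stimulus_protocol`.
#' @export
make_stimulus <- function(targets, onset, duration = 30, rate, weight) {
  targets <- as.integer(targets)
  if (length(targets) == 0L) stop("stimulus must target at least one neuron")
  if (duration <= 0) stop("stimulus duration must be > 0")
  stopifnot(onset >= 0, rate >= 0)
  structure(list(targets = targets, onset = onset, duration = duration,
                 rate = rate, weight = weight),
            class = "stimulus_protocol")
}

#' Spike data container
#'
#' Time-sorted spike events from one simulation run.
#'
#' @param times spike times (ms).
#' @param nodes 1-based ids of the spiking neurons.
#' @param t_stop end of the simulated interval (ms).
#' @param n_nodes number of neurons in the simulated network.
#' @return object of class `spike_data` with fields `times`, `nodes`,
#'   `t_stop`, `n_nodes`.
#' @export
spike_data <- function(times, nodes, t_stop, n_nodes) {
  stopifnot(length(times) == length(nodes))
  if (length(times) > 0L) {
    stopifnot(all(times >= 0), all(times <= t_stop), !is.unsorted(times))
  }
  structure(list(times = as.numeric(times), nodes = as.integer(nodes),
                 t_stop = as.numeric(t_stop), n_nodes = as.integer(n_nodes)),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  rate <- if (x$t_stop > 0 && x$n_nodes > 0) {
    length(x$times) / x$n_nodes / (x$t_stop / 1000)
  } else NA_real_
  cat(sprintf("<spike_data> %d spikes, %d neurons, %.0f ms (mean rate %.2f /s)\n",
              length(x$times), x$n_nodes, x$t_stop, rate))
  invisible(x)
}

#' Simulate a leaky integrate-and-fire network
#'
#' Current-based LIF dynamics with exact exponential membrane decay per time
#' step: presynaptic spikes arrive as instantaneous voltage jumps (`+j_exc`
#' from excitatory, `-g * j_exc` from inhibitory neurons) after the synaptic
#' delay; crossing threshold emits a spike, resets the membrane and clamps it
#' for the refractory period (inputs arriving during refractoriness are
#' discarded). Every neuron receives an independent Poisson background stream
#' of rate `background_rate` (jump `j_exc`), and optionally extra stimulus
#' streams (see [make_stimulus()]). Each neuron draws its background and
#' stimulus events from its own RNG substream derived from `seed`, so results
#' are deterministic and the background input is unchanged when a stimulus is
#' added or removed.
#'
#' @param net a [directed_network()].
#' @param params a [lif_params()].
#' @param background_rate Poisson background rate per neuron (events/s).
#' @param stimuli a [make_stimulus()] protocol, a list of them, or `NULL`.
#' @param drive constant suprathreshold drive expressed as the steady-state
#'   membrane offset I*R it would produce (mV); 0 for none.
#' @param t_stop simulated duration (ms).
#' @param seed integer master seed.
#' @return a [spike_data()] object containing every spike.
#' @export
simulate_lif <- function(net, params = lif_params(), background_rate = 0,
                         stimuli = NULL, drive = 0, t_stop, seed = 1L) {
  validate_network(net)
  stopifnot(inherits(params, "lif_params"), t_stop > 0, net$n_nodes >= 1L)
  if (inherits(stimuli, "stimulus_protocol")) stimuli <- list(stimuli)
  if (is.null(stimuli)) stimuli <- list()
  for (s in stimuli) stopifnot(inherits(s, "stimulus_protocol"))
  res <- lif_simulate_cpp(
    net$n_nodes, net$edges[, 1L], net$edges[, 2L], net$node_kind == "I",
    params$tau_m, params$v_rest, params$v_reset, params$v_th,
    params$t_ref, params$delay, params$j_exc, params$g, params$dt,
    background_rate, params$j_exc, drive,
    lapply(stimuli, unclass), t_stop, as.integer(seed)
  )
  spike_data(res$times, res$nodes, t_stop = t_stop, n_nodes = net$n_nodes)
}

#' Population firing rate of a spike train
#'
#' @param spikes a [spike_data()].
#' @param window `c(t0, t1)` ms; default the whole run.
#' @param nodes restrict to these node ids; default all.
#' @return mean rate in spikes/s per neuron.
#' @export
population_rate <- function(spikes, window = c(0, spikes$t_stop),
                            nodes = seq_len(spikes$n_nodes)) {
  sel <- spikes$times >= window[1] & spikes$times < window[2] &
    spikes$nodes %in% nodes
  sum(sel) / length(nodes) / ((window[2] - window[1]) / 1000)
}

#' Calibrate the Poisson background rate
#'
#' Bisection on the per-neuron background rate so that the baseline population
#' rate (measured over the second half of a `t_sim` ms run, discarding the
#' onset transient) falls inside `rate_band`. The search brackets the
#' threshold rate `v_th / (j_exc * tau_m)` — the external rate at which the
#' mean drive alone reaches threshold.
#'
#' @param net a [directed_network()].
#' @param params a [lif_params()].
#' @param rate_band acceptable baseline band in spikes/s; default 2-10.
#' @param t_sim calibration run length (ms).
#' @param seed integer seed for the calibration runs.
#' @param max_iter bisection iterations.
#' @return the calibrated background rate (events/s), with attribute
#'   `achieved_rate` (spikes/s).
#' @export
calibrate_background <- function(net, params = lif_params(),
                                 rate_band = c(2, 10), t_sim = 500,
                                 seed = 1L, max_iter = 14L) {
  nu_thr <- params$v_th / (params$j_exc * params$tau_m) * 1000  # events/s
  target <- sqrt(prod(rate_band))
  measure <- function(bg) {
    sp <- simulate_lif(net, params, background_rate = bg, t_stop = t_sim,
                       seed = seed)
    population_rate(sp, window = c(t_sim / 2, t_sim))
  }
  lo <- 0.6 * nu_thr; hi <- 2.5 * nu_thr
  r_lo <- measure(lo)
  while (r_lo > rate_band[2] && lo > 0.1 * nu_thr) {
    hi <- lo; lo <- lo * 0.7; r_lo <- measure(lo)
  }
  best <- NULL; best_rate <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- measure(mid)
    if (r_mid >= rate_band[1] && r_mid <= rate_band[2] &&
        (is.null(best) || abs(log(r_mid / target)) < abs(log(best_rate / target)))) {
      best <- mid; best_rate <- r_mid
    }
    # stop once the achieved rate is close to the band centre
    if (!is.null(best) && abs(log(best_rate / target)) < log(1.1)) break
    if (r_mid < target) lo <- mid else hi <- mid
  }
  if (is.null(best)) {
    stop(sprintf("background calibration failed: no rate found inside band [%g, %g]",
                 rate_band[1], rate_band[2]))
  }
  structure(best, achieved_rate = best_rate)
}
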