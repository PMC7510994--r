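#' Background stimulus model
#'
#' Each neuron receives independent Poisson-timed current events (rate
#' `rate_hz`) whose amplitudes are `amplitude_gain` times a Gamma(`k`,
#' `theta`) draw (mean k * theta = 1 before the gain). By default the event
#' is injected into the neuron's decaying excitatory drive accumulator
#' (`mode = "decay"`), which makes a mean-amplitude event strong enough to
#' fire a resting regular-spiking neuron within a few milliseconds;
#' `mode = "impulse"` instead applies the current for exactly one timestep.
#'
#' @param rate_hz Per-neuron event rate in Hz (default 1).
#' @param k,theta Gamma shape and scale (defaults 2 and 0.5).
#' @param amplitude_gain Current multiplier (default 15).
#' @param mode `"decay"` or `"impulse"`.
#' @return A list of class `stimulus_model`.
#' @export
stimulus_model <- function(rate_hz = 1, k = 2, theta = 0.5,
                           amplitude_gain = 15,
                           mode = c("decay", "impulse")) {
  stopifnot(rate_hz >= 0, k > 0, theta > 0)
  structure(list(rate_hz = rate_hz, k = k, theta = theta,
                 amplitude_gain = amplitude_gain,
                 mode = match.arg(mode)), class = "stimulus_model")
}

#' Single forward-Euler step of the Izhikevich model
#'
#' v' = v + dt (0.04 v^2 + 5 v + 140 - u + I), u' = u + dt a (b v - u), both
#' right-hand sides evaluated at the old state; if v' crosses 30 mV the
#' neuron spikes and is reset within the step (v' := c, u' := u' + d).
#' Vectorized over neurons.
#'
#' @param v,u Membrane potential (mV) and recovery variable.
#' @param I Total input current.
#' @param a,b,c,d Izhikevich parameters.
#' @param dt Timestep in ms (default 0.2).
#' @return A list with `v`, `u` and logical `spiked`.
#' @export
izhikevich_step <- function(v, u, I, a, b, c, d, dt = 0.2) {
  if (!all(is.finite(v), is.finite(u), is.finite(I))) {
    stop("non-finite membrane state")
  }
  vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  un <- u + dt * a * (b * v - u)
  sp <- vn >= 30
  vn[sp] <- c[sp]
  un[sp] <- un[sp] + d[sp]
  list(v = vn, u = un, spiked = sp)
}

#' Exponential decay of synaptic drive accumulators
#'
#' Both accumulators decay as AMPA / GABA_A currents with time constant
#' `tau` (default 5 ms): each is multiplied by exp(-dt / tau).
#'
#' @param g_exc,g_inh Accumulators (g_exc >= 0, g_inh <= 0).
#' @param dt Elapsed time in ms.
#' @param tau Decay time constant in ms (default 5).
#' @return A list with decayed `g_exc`, `g_inh`.
#' @export
decay_synapses <- function(g_exc, g_inh, dt, tau = 5) {
  stopifnot(tau > 0)
  f <- exp(-dt / tau)
  list(g_exc = g_exc * f, g_inh = g_inh * f)
}

#' Deliver a spike to a postsynaptic neuron
#'
#' Adds `s_post * weight` to the target's excitatory (weight > 0) or
#' inhibitory (weight <= 0) accumulator; `s_post` is the target's
#' desensitization factor, which attenuates inputs to a recently spiked
#' neuron.
#'
#' @param g_exc,g_inh Accumulator vectors.
#' @param post Target neuron index.
#' @param weight Signed synaptic weight.
#' @param s_post Desensitization factor in (0, 1].
#' @return A list with updated `g_exc`, `g_inh`.
#' @export
deliver_spike <- function(g_exc, g_inh, post, weight, s_post) {
  if (post < 1 || post > length(g_exc)) stop("unknown post id")
  if (weight > 0) g_exc[post] <- g_exc[post] + s_post * weight
  else g_inh[post] <- g_inh[post] + s_post * weight
  list(g_exc = g_exc, g_inh = g_inh)
}

#' Update the input-desensitization factor
#'
#' A neuron that has just spiked has its incoming stimuli attenuated by 40%
#' (factor reset to `floor` = 0.6); otherwise the factor relaxes toward 1
#' with time constant `tau_d`: s' = 1 - (1 - s) exp(-dt / tau_d).
#'
#' @param s Current factor(s) in (0, 1].
#' @param spiked Logical: did the neuron spike this step?
#' @param dt Timestep in ms.
#' @param tau_d Recovery time constant in ms (default 150).
#' @param floor Post-spike attenuation floor (default 0.6).
#' @return Updated factor(s).
#' @export
update_desensitization <- function(s, spiked, dt, tau_d = 150, floor = 0.6) {
  out <- 1 - (1 - s) * exp(-dt / tau_d)
  out[spiked] <- floor
  out
}

#' Generate background stimulation events
#'
#' Per-neuron homogeneous Poisson event times with gamma-distributed
#' amplitudes, as used for background drive during simulation. This is the
#' event-level view of the stimulus (the simulator draws the same law
#' internally, clock by clock).
#'
#' @param n_neurons Number of neurons.
#' @param duration_ms Duration in ms (> 0).
#' @param stim A [stimulus_model()].
#' @param seed Optional seed.
#' @return A data frame with columns `neuron`, `time_ms`, `amplitude`
#'   (gain applied), ordered by time.
#' @export
background_events <- function(n_neurons, duration_ms, stim = stimulus_model(),
                              seed = NULL) {
  stopifnot(duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  if (stim$rate_hz == 0) {
    return(data.frame(neuron = integer(), time_ms = numeric(),
                      amplitude = numeric()))
  }
  mean_int <- 1000 / stim$rate_hz
  res <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    t <- cumsum(stats::rexp(ceiling(2 * duration_ms / mean_int) + 10,
                            1 / mean_int))
    while (t[length(t)] < duration_ms) {
      t <- c(t, t[length(t)] +
               cumsum(stats::rexp(10, 1 / mean_int)))
    }
    t <- t[t < duration_ms]
    res[[i]] <- data.frame(neuron = rep.int(i, length(t)), time_ms = t)
  }
  out <- do.call(rbind, res)
  out$amplitude <- stim$amplitude_gain *
    stats::rgamma(nrow(out), stim$k, scale = stim$theta)
  out[order(out$time_ms), , drop = FALSE]
}

#' Initial simulation state for a network
#'
#' Membrane potentials start at -65 mV with u = b v (near rest), accumulators
#' empty, desensitization fully recovered, plasticity traces zero, and no
#' spikes in flight.
#'
#' @param net An `izhi_network`.
#' @return A list of class `izhi_state`.
#' @export
initial_state <- function(net) {
  n <- nrow(net$neurons)
  structure(list(
    v = rep(-65, n),
    u = net$neurons$b * -65,
    g_exc = rep(0, n), g_inh = rep(0, n),
    s = rep(1, n), x_trace = rep(0, n), y_trace = rep(0, n),
    queue = matrix(numeric(), 0, 3,
                   dimnames = list(NULL, c("steps_left", "id", "weight"))),
    ids = net$neurons$id
  ), class = "izhi_state")
}

#' Run a network simulation
#'
#' Advances the network for `duration_ms` in fixed steps of
#' `net$config$dt_ms`, with decaying delayed synaptic currents, input
#' desensitization, stochastic background drive, and (optionally) additive
#' STDP at excitatory-excitatory synapses. Spikes crossing a block boundary
#' are carried in the returned state and delivered when the simulation is
#' continued from it.
#'
#' @param net An `izhi_network`.
#' @param duration_ms Simulated duration in ms (>= 0).
#' @param stim A [stimulus_model()] (default: 1 Hz gamma events).
#' @param stdp An [stdp_config()] to enable plasticity, or `NULL` for frozen
#'   weights.
#' @param state An `izhi_state` to continue from (default: fresh
#'   [initial_state()]).
#' @param record Record the spike raster (default `TRUE`).
#' @param seed Optional seed for the background drive.
#' @param ext_events Optional data frame of deterministic one-step current
#'   injections with columns `neuron` (original id), `time_ms`, `amplitude`;
#'   mainly for controlled experiments and tests.
#' @param tau_syn_ms,desens_floor,desens_tau_ms Synaptic decay constant and
#'   desensitization parameters (defaults 5, 0.6, 150).
#' @return A list of class `izhi_sim` with elements `raster`
#'   (a `spike_raster` data frame: `neuron`, `time_ms`), `state`
#'   (continuation state), and `network` (with post-plasticity weights).
#' @examples
#' net <- build_network(n = 50, mean_degree = 10, seed = 1)
#' sim <- simulate_network(net, 1000, seed = 2)
#' head(sim$raster)
#' @export
simulate_network <- function(net, duration_ms, stim = stimulus_model(),
                             stdp = NULL, state = NULL, record = TRUE,
                             seed = NULL, ext_events = NULL,
                             tau_syn_ms = 5, desens_floor = 0.6,
                             desens_tau_ms = 150) {
  stopifnot(inherits(net, "izhi_network"), duration_ms >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- initial_state(net)
  n <- nrow(net$neurons)
  if (length(state$v) != n || !identical(state$ids, net$neurons$id)) {
    stop("state does not match network (size or neuron ids differ)")
  }
  dt <- net$config$dt_ms
  idx <- seq_len(n)                        # compact indices
  names(idx) <- as.character(net$neurons$id)
  e <- net$edges
  pre_c <- idx[as.character(e$pre)]
  post_c <- idx[as.character(e$post)]
  delay_steps <- as.integer(round(e$delay_ms / dt))
  delay_steps[delay_steps < 1L] <- 1L
  is_exc <- net$neurons$kind == "excitatory"

  queue <- state$queue
  if (nrow(queue) > 0) {                   # map carried ids; drop dead targets
    keep <- as.character(queue[, 2]) %in% names(idx) & queue[, 1] >= 0
    queue <- queue[keep, , drop = FALSE]
    queue[, 2] <- idx[as.character(queue[, 2])]
  }

  if (is.null(ext_events) || nrow(ext_events) == 0) {
    ext_step <- integer(); ext_neuron <- integer(); ext_amp <- numeric()
  } else {
    ord <- order(ext_events$time_ms)
    ext_events <- ext_events[ord, , drop = FALSE]
    ext_step <- as.integer(floor(ext_events$time_ms / dt + 1e-9))
    ext_neuron <- as.integer(idx[as.character(ext_events$neuron)])
    ext_amp <- as.numeric(ext_events$amplitude)
  }

  stdp_on <- !is.null(stdp)
  if (stdp_on) stopifnot(inherits(stdp, "stdp_config"))

  res <- sim_core(pre_c, post_c, e$weight, delay_steps, is_exc,
                  net$neurons$a, net$neurons$b, net$neurons$c, net$neurons$d,
                  state$v, state$u, state$g_exc, state$g_inh, state$s,
                  state$x_trace, state$y_trace, queue,
                  duration_ms, dt, tau_syn_ms, desens_floor, desens_tau_ms,
                  stim$rate_hz, stim$k, stim$theta, stim$amplitude_gain,
                  stim$mode == "impulse",
                  ext_step, ext_neuron, ext_amp,
                  stdp_on,
                  if (stdp_on) stdp$tau_ms else 20,
                  if (stdp_on) stdp$a_plus else 0,
                  if (stdp_on) stdp$a_minus else 0,
                  if (stdp_on) stdp$w_min else 0,
                  if (stdp_on) stdp$w_max else 4,
                  record)

  net$edges$weight <- res$weights
  qout <- res$queue
  if (nrow(qout) > 0) qout[, 2] <- net$neurons$id[qout[, 2]]
  colnames(qout) <- c("steps_left", "id", "weight")
  new_state <- structure(list(
    v = res$v, u = res$u, g_exc = res$g_exc, g_inh = res$g_inh, s = res$s,
    x_trace = res$x_trace, y_trace = res$y_trace,
    queue = qout, ids = net$neurons$id
  ), class = "izhi_state")

  raster <- spike_raster(net$neurons$id[res$spike_neuron], res$spike_time,
                         duration_ms, n)
  structure(list(raster = raster, state = new_state, network = net),
            class = "izhi_sim")
}

#' Construct a spike raster
#'
#' @param neuron Neuron ids.
#' @param time_ms Spike times in ms (in \[0, duration)).
#' @param duration_ms Raster duration.
#' @param n_neurons Number of (surviving) neurons.
#' @return A data frame of class `spike_raster` with attributes
#'   `duration_ms` and `n_neurons`.
#' @export
spike_raster <- function(neuron, time_ms, duration_ms, n_neurons) {
  structure(data.frame(neuron = as.integer(neuron), time_ms = time_ms),
            duration_ms = duration_ms, n_neurons = n_neurons,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.izhi_sim <- function(x, ...) {
  r <- x$raster
  cat(sprintf("simulation: %.1f s, %d neurons, %d spikes (%.2f Hz mean)\n",
              attr(r, "duration_ms") / 1000, attr(r, "n_neurons"), nrow(r),
              nrow(r) / attr(r, "n_neurons") /
                (attr(r, "duration_ms") / 1000)))
  invisible(x)
}

#' Raster plot of a simulation
#'
#' @param x A `spike_raster`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spike_raster <- function(x, ...) {
  graphics::plot(x$time_ms / 1000, x$neuron, pch = ".", cex = 0.8,
                 xlab = "time (s)", ylab = "neuron", ...)
  invisible(x)
}
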