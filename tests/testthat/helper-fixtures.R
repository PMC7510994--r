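# Small networks and hand-built fixtures shared across test files.

tiny_net <- function(n = 60, mean_degree = 12, seed = 42, ...) {
  build_network(n = n, mean_degree = mean_degree, seed = seed, ...)
}

# A two-neuron chain (pre -> post) with an arbitrary weight/delay, built by
# hand so simulations can probe event ordering precisely.
chain_net <- function(weight = 30, delay_ms = 2, kind = c("excitatory",
                                                          "excitatory"),
                      jitter = 0) {
  pars <- rbind(sample_neuron_params(kind[1], jitter),
                sample_neuron_params(kind[2], jitter))
  neurons <- data.frame(id = 1:2, kind = kind, pars,
                        x = c(0, 1), y = c(0, 0), z = c(1, 0))
  edges <- data.frame(pre = 1L, post = 2L, weight = weight,
                      delay_ms = delay_ms)
  structure(list(neurons = neurons, edges = edges,
                 config = list(n = 2, frac_exc = mean(kind == "excitatory"),
                               mean_degree = 1, degree_cv = 0,
                               exc_scale = c(0, 4), inh_scale = c(-14, 0),
                               max_delay_ms = 8, dt_ms = 0.2,
                               param_jitter = jitter, seed = NULL)),
            class = "izhi_network")
}

# Raster of perfectly synchronized volleys: `per_volley` neurons spiking
# together every `period_ms`.
volley_raster <- function(n_volleys = 10, period_ms = 100, per_volley = 100,
                          duration_ms = 1000) {
  t <- rep(seq(50, by = period_ms, length.out = n_volleys),
           each = per_volley)
  spike_raster(rep(seq_len(per_volley), n_volleys), t, duration_ms,
               per_volley)
}

# One-step current injections strong enough to force a spike at an exact
# step, for controlled spike-timing experiments.
forced_spikes <- function(neuron, time_ms, amplitude = 1e4) {
  data.frame(neuron = neuron, time_ms = time_ms, amplitude = amplitude)
}
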