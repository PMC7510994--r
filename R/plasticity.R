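#' STDP configuration (additive Song rule)
#'
#' Pre-before-post spike pairs potentiate by `a_plus` exp(-dt/tau), post- (or
#' same-step) pairs depress by `a_minus` exp(-|dt|/tau). Updates are additive
#' (weight-independent) with hard clipping to \[`w_min`, `w_max`\], the
#' formulation whose fixed-point weight distribution is bimodal. Applied at
#' excitatory-excitatory synapses only. By default `a_plus` = 0.005 w_max
#' and `a_minus` = 1.05 a_plus (slight depression dominance).
#'
#' @param tau_ms Plasticity time constant in ms (default 20).
#' @param w_max,w_min Weight bounds (defaults 4 and 0).
#' @param a_plus Potentiation increment (default `0.005 * w_max`).
#' @param a_minus_ratio Ratio a_minus / a_plus (default 1.05).
#' @param timing `"emission"` (spike pairing at soma emission times, the
#'   default) or `"arrival"`; the implementation pairs emission times.
#' @return A list of class `stdp_config`.
#' @export
stdp_config <- function(tau_ms = 20, w_max = 4, w_min = 0,
                        a_plus = 0.005 * w_max, a_minus_ratio = 1.05,
                        timing = c("emission", "arrival")) {
  stopifnot(tau_ms > 0, a_plus > 0, a_minus_ratio > 0, w_min < w_max)
  timing <- match.arg(timing)
  if (timing == "arrival") {
    stop("arrival-time pairing is not implemented; use timing = 'emission'")
  }
  structure(list(tau_ms = tau_ms, a_plus = a_plus,
                 a_minus = a_minus_ratio * a_plus,
                 w_max = w_max, w_min = w_min, timing = timing),
            class = "stdp_config")
}

#' Pairwise STDP weight change
#'
#' Weight change for a single pre/post spike pair with timing difference
#' `dt_ms` = t_post - t_pre: positive differences potentiate,
#' nonpositive differences (including exactly coincident spikes) depress.
#'
#' @param dt_ms t_post - t_pre in ms (vectorized).
#' @param cfg An [stdp_config()].
#' @return Signed weight change(s).
#' @export
stdp_delta <- function(dt_ms, cfg = stdp_config()) {
  if (!all(is.finite(dt_ms))) stop("'dt_ms' must be finite")
  ifelse(dt_ms > 0,
         cfg$a_plus * exp(-dt_ms / cfg$tau_ms),
         -cfg$a_minus * exp(-abs(dt_ms) / cfg$tau_ms))
}

#' Total STDP weight change for one synapse from spike trains
#'
#' Computes the accumulated (unclipped) weight change of a single
#' excitatory-excitatory synapse given its pre- and postsynaptic emission
#' times, either by the online eligibility-trace scheme the simulator uses
#' (`method = "traces"`) or by brute-force all-pairs summation of
#' [stdp_delta()] (`method = "pairs"`). The two are mathematically
#' equivalent; the all-pairs form serves as the independent oracle for the
#' trace form. Spike times are assumed aligned to the step grid; spikes of
#' the two trains falling in the same step pair on the depression branch.
#'
#' @param pre_times,post_times Spike time vectors in ms.
#' @param cfg An [stdp_config()].
#' @param method `"traces"` or `"pairs"`.
#' @param dt_ms Step grid for the trace scheme (default 0.2).
#' @return Total signed weight change (no clipping).
#' @export
stdp_pair_change <- function(pre_times, post_times, cfg = stdp_config(),
                             method = c("traces", "pairs"), dt_ms = 0.2) {
  method <- match.arg(method)
  if (method == "pairs") {
    if (length(pre_times) == 0 || length(post_times) == 0) return(0)
    d <- outer(post_times, pre_times, "-")
    return(sum(stdp_delta(as.vector(d), cfg)))
  }
  # online trace scheme, replaying the simulator's per-step ordering
  steps <- sort(unique(c(round(pre_times / dt_ms), round(post_times / dt_ms))))
  pre_s <- round(pre_times / dt_ms)
  post_s <- round(post_times / dt_ms)
  x <- 0; y <- 0; last <- NA; dw <- 0
  for (st in steps) {
    if (!is.na(last)) {
      f <- exp(-(st - last) * dt_ms / cfg$tau_ms)
      x <- x * f; y <- y * f
    }
    pre_now <- any(pre_s == st)
    post_now <- any(post_s == st)
    if (post_now) dw <- dw + cfg$a_plus * x      # pre trace excludes same-step
    if (post_now) y <- y + 1
    if (pre_now) dw <- dw - cfg$a_minus * y      # post trace includes same-step
    if (pre_now) x <- x + 1
    last <- st
  }
  dw
}

#' Excitatory-excitatory synapse selector
#'
#' Indices of the edges subject to plasticity (both endpoints excitatory).
#' Inhibitory synapses are never registered for STDP.
#'
#' @param net An `izhi_network`.
#' @return Integer vector of row indices into `net$edges`.
#' @export
stdp_edges <- function(net) {
  kind <- net$neurons$kind
  names(kind) <- as.character(net$neurons$id)
  which(kind[as.character(net$edges$pre)] == "excitatory" &
        kind[as.character(net$edges$post)] == "excitatory")
}
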