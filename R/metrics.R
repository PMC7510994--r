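#' Per-neuron and population firing rates
#'
#' Spikes in the window divided by window length, per surviving neuron;
#' silent neurons count as 0 Hz and enter the population mean.
#'
#' @param raster A `spike_raster`.
#' @param window Length-2 window \[t0, t1) in ms (default: whole raster).
#' @param ids Surviving neuron ids (default: all neurons the raster knows
#'   about via `attr(raster, "ids")`, else the ids present plus
#'   `attr(raster, "n_neurons")` silent unnamed ones are not invented --
#'   pass `ids` explicitly for injured networks).
#' @return A list with `per_neuron` (named Hz vector over `ids`) and
#'   `mean` (population mean Hz).
#' @export
firing_rate <- function(raster, window = NULL, ids = NULL) {
  if (is.null(window)) window <- c(0, attr(raster, "duration_ms"))
  if (diff(window) <= 0) stop("empty or invalid window")
  if (is.null(ids)) ids <- sort(unique(raster$neuron))
  sel <- raster$time_ms >= window[1] & raster$time_ms < window[2]
  cnt <- table(factor(raster$neuron[sel], levels = ids))
  hz <- as.numeric(cnt) / (diff(window) / 1000)
  names(hz) <- as.character(ids)
  list(per_neuron = hz, mean = mean(hz))
}

#' Coefficient of variation of inter-spike intervals
#'
#' Per neuron with at least two spikes in the window: SD of the ISIs over
#' their mean. The population value is the mean over qualifying neurons.
#' CoV ISI is 0 for perfectly periodic firing and about 1 for Poisson
#' firing.
#'
#' @inheritParams firing_rate
#' @return A list with `per_neuron` (named vector, qualifying neurons only)
#'   and `mean`.
#' @export
cov_isi <- function(raster, window = NULL) {
  if (is.null(window)) window <- c(0, attr(raster, "duration_ms"))
  if (diff(window) <= 0) stop("empty or invalid window")
  sel <- raster$time_ms >= window[1] & raster$time_ms < window[2]
  r <- raster[sel, , drop = FALSE]
  r <- r[order(r$neuron, r$time_ms), , drop = FALSE]
  by_n <- split(r$time_ms, r$neuron)
  by_n <- by_n[vapply(by_n, length, 1L) >= 2]
  cv <- vapply(by_n, function(t) {
    isi <- diff(t)
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  list(per_neuron = cv, mean = if (length(cv)) mean(cv) else NA_real_)
}

#' Sliding-window population spike counts
#'
#' Number of spikes in a `window_ms` window slid in steps of `stride_ms`
#' across the raster: element i covers \[ (i-1) stride, (i-1) stride +
#' window ). Length = floor((duration - window) / stride) + 1.
#'
#' @param raster A `spike_raster`.
#' @param window_ms Window length in ms (default 10).
#' @param stride_ms Stride in ms (default 0.2, the integration timestep).
#' @return Numeric count trace with attributes `stride_ms`, `window_ms`,
#'   `duration_ms`.
#' @export
windowed_counts <- function(raster, window_ms = 10, stride_ms = 0.2) {
  stopifnot(window_ms >= stride_ms)
  dur <- attr(raster, "duration_ms")
  nbin <- as.integer(round(dur / stride_ms))
  w <- as.integer(round(window_ms / stride_ms))
  if (nbin < w) stop("raster shorter than one window")
  bin <- floor(raster$time_ms / stride_ms + 1e-9) + 1
  counts <- tabulate(bin, nbins = nbin)
  cs <- c(0, cumsum(counts))
  out <- cs[(w + 1):(nbin + 1)] - cs[1:(nbin - w + 1)]
  structure(as.numeric(out), stride_ms = stride_ms, window_ms = window_ms,
            duration_ms = dur)
}

#' Detect population oscillations in a count trace
#'
#' Local maxima of the sliding-window spike-count trace with topographic
#' prominence >= `prominence_min` (in spikes per window) are accepted as
#' oscillation events; peaks closer than `min_sep_ms` are merged into the
#' higher one. For each event the full width at half maximum is measured at
#' half the prominence-referenced height (peak minus local baseline) by
#' linear interpolation of the flank crossings, and the phase interval is
#' `t_peak` +/- 0.7 FWHM (1.4 FWHM total). Peak times refer to the center
#' of the counting window.
#'
#' @param counts A trace from [windowed_counts()].
#' @param prominence_min Prominence threshold in spikes (default 1).
#' @param min_sep_ms Minimum peak separation in ms (default 10, one window).
#' @param n_surviving Optional network size for the magnitude fraction.
#' @param half `"prominence"` (default) or `"absolute"` reference for the
#'   half-height level.
#' @return A list with `events` (data frame: `t_peak`, `magnitude`,
#'   `fraction`, `fwhm_ms`, `t_lo`, `t_hi`) and `osc_freq_hz` (events per
#'   second of trace duration). A flat trace yields zero events.
#' @export
detect_oscillations <- function(counts, prominence_min = 1, min_sep_ms = 10,
                                n_surviving = NULL,
                                half = c("prominence", "absolute")) {
  half <- match.arg(half)
  stride <- attr(counts, "stride_ms")
  window <- attr(counts, "window_ms")
  dur <- attr(counts, "duration_ms")
  if (length(counts) == 0) stop("empty count trace")
  pk <- find_peaks_cpp(as.numeric(counts), prominence_min,
                       as.integer(round(min_sep_ms / stride)),
                       half == "absolute")
  t_peak <- (as.numeric(pk$idx) - 1) * stride + window / 2
  height <- as.numeric(pk$height)
  fwhm <- as.numeric(pk$width_steps) * stride
  ev <- data.frame(
    t_peak = t_peak,
    magnitude = height,
    fraction = if (is.null(n_surviving)) rep(NA_real_, length(height))
               else height / n_surviving,
    fwhm_ms = fwhm,
    t_lo = t_peak - 0.7 * fwhm,
    t_hi = t_peak + 0.7 * fwhm
  )
  list(events = ev, osc_freq_hz = nrow(ev) / (dur / 1000))
}

#' Firing likelihood across oscillation phase bins
#'
#' For every oscillation event, spikes inside the phase interval
#' \[`t_lo`, `t_hi`\] (1.4 FWHM centered on the peak) are assigned to
#' `n_bins` equal sub-intervals; counts are aggregated per neuron group and
#' normalized within group to per-bin firing likelihoods. Methods sections
#' of this analysis use deciles; the figure-level summaries use quintiles.
#'
#' @param raster A `spike_raster`.
#' @param events Event data frame from [detect_oscillations()].
#' @param n_bins Number of phase bins (5 or 10; default 10).
#' @param groups Named character/factor vector mapping neuron id to group
#'   (e.g. excitatory/inhibitory, index strata).
#' @return A list with `counts` (group x bin matrix), `likelihood`
#'   (row-normalized), `n_events`, and `n_spikes_binned`.
#' @export
phase_occupancy <- function(raster, events, n_bins = 10, groups) {
  if (nrow(events) == 0) stop("no oscillation events supplied")
  stopifnot(n_bins %in% c(5, 10))
  glev <- sort(unique(as.character(groups)))
  cnt <- matrix(0, length(glev), n_bins, dimnames = list(glev, NULL))
  n_binned <- 0
  for (k in seq_len(nrow(events))) {
    lo <- events$t_lo[k]; hi <- events$t_hi[k]
    if (hi <= lo) { warning("zero-width event skipped"); next }
    sel <- raster$time_ms >= lo & raster$time_ms <= hi
    if (!any(sel)) next
    b <- pmin(n_bins, floor((raster$time_ms[sel] - lo) / (hi - lo) *
                              n_bins) + 1)
    g <- as.character(groups[as.character(raster$neuron[sel])])
    keep <- !is.na(g)
    tb <- table(factor(g[keep], levels = glev), factor(b[keep],
                                                       levels = 1:n_bins))
    cnt <- cnt + unclass(tb)
    n_binned <- n_binned + sum(keep)
  }
  rs <- rowSums(cnt)
  lik <- sweep(cnt, 1, ifelse(rs > 0, rs, 1), "/")
  list(counts = cnt, likelihood = lik, n_events = nrow(events),
       n_spikes_binned = n_binned)
}

#' Neuron-connectivity index
#'
#' Per neuron: (total input strength - total output strength) / total
#' strength, with strengths summed as absolute synaptic weights; ranges over
#' \[-1, 1\] (+1 = inputs only, -1 = outputs only). Isolated neurons are
#' reported as `NA`. After settling, the index correlates strongly with the
#' neuron's firing rate.
#'
#' @param net An `izhi_network`.
#' @return Named numeric vector over neuron ids.
#' @export
connectivity_index <- function(net) {
  ids <- net$neurons$id
  e <- net$edges
  instr <- tapply(abs(e$weight), factor(e$post, levels = ids), sum,
                  default = 0)
  outstr <- tapply(abs(e$weight), factor(e$pre, levels = ids), sum,
                   default = 0)
  tot <- as.numeric(instr) + as.numeric(outstr)
  idx <- ifelse(tot > 0, (as.numeric(instr) - as.numeric(outstr)) / tot,
                NA_real_)
  names(idx) <- as.character(ids)
  idx
}

#' Five-metric activity summary of a measurement window
#'
#' The population firing rate, mean CoV ISI, oscillation frequency, mean
#' oscillation peak magnitude (as a fraction of surviving network size) and
#' mean oscillation FWHM for one raster. When no oscillation is detected the
#' oscillation metrics are reported as missing (`NA`), not zero.
#'
#' @param raster A `spike_raster`.
#' @param ids Surviving neuron ids.
#' @param window_ms Sliding-window length for oscillation counting
#'   (default 10).
#' @param stride_ms Sliding-window stride (default 0.2).
#' @param prominence_min Peak prominence threshold (default 1).
#' @return One-row data frame: `firing_rate_hz`, `cov_isi`, `osc_freq_hz`,
#'   `osc_magnitude` (fraction), `osc_fwhm_ms`, `n_surviving`,
#'   `duration_s`.
#' @export
summarize_metrics <- function(raster, ids, window_ms = 10, stride_ms = 0.2,
                              prominence_min = 1) {
  fr <- firing_rate(raster, ids = ids)
  cv <- cov_isi(raster)
  ct <- windowed_counts(raster, window_ms, stride_ms)
  osc <- detect_oscillations(ct, prominence_min, n_surviving = length(ids))
  has_osc <- nrow(osc$events) > 0
  data.frame(
    firing_rate_hz = fr$mean,
    cov_isi = cv$mean,
    osc_freq_hz = if (has_osc) osc$osc_freq_hz else NA_real_,
    osc_magnitude = if (has_osc) mean(osc$events$fraction) else NA_real_,
    osc_fwhm_ms = if (has_osc) mean(osc$events$fwhm_ms) else NA_real_,
    n_surviving = length(ids),
    duration_s = attr(raster, "duration_ms") / 1000
  )
}
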