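test_that("firing rates count spikes per second, including silent neurons", {
  r <- spike_raster(rep(1L, 300), seq(0, 299999, length.out = 300),
                    300000, 2)
  fr <- firing_rate(r, ids = c(1, 2))
  expect_equal(unname(fr$per_neuron["1"]), 1)
  expect_equal(unname(fr$per_neuron["2"]), 0)
  expect_equal(fr$mean, 0.5)
  expect_error(firing_rate(r, window = c(5, 5)), "window")
})

test_that("CoV ISI is 0 for periodic, ~1 for Poisson, and scale-invariant", {
  per <- spike_raster(rep(1L, 100), seq(10, 1000, by = 10), 1100, 1)
  expect_equal(cov_isi(per)$mean, 0)

  set.seed(50)
  t <- cumsum(rexp(5000, 1 / 10))
  poi <- spike_raster(rep(1L, length(t)), t, max(t) + 1, 1)
  expect_equal(cov_isi(poi)$mean, 1, tolerance = 0.05)

  # multiplying all spike times by a constant leaves CoV unchanged
  sc <- spike_raster(rep(1L, length(t)), 3 * t, 3 * (max(t) + 1), 1)
  expect_equal(cov_isi(sc)$mean, cov_isi(poi)$mean, tolerance = 1e-12)

  # neurons with < 2 spikes are skipped
  one <- spike_raster(c(1L, 2L, 2L), c(5, 1, 2), 10, 2)
  expect_false("1" %in% names(cov_isi(one)$per_neuron))
})

test_that("sliding-window counts partition spikes and catch coincidences", {
  empty <- spike_raster(integer(), numeric(), 100, 5)
  expect_true(all(windowed_counts(empty) == 0))

  co <- spike_raster(1:7, rep(50, 7), 100, 7)
  ct <- windowed_counts(co)
  expect_equal(max(ct), 7)

  # disjoint windows (stride = window) partition the raster
  set.seed(51)
  r <- spike_raster(sample(1:10, 500, TRUE), runif(500, 0, 1000), 1000, 10)
  ct10 <- windowed_counts(r, window_ms = 10, stride_ms = 10)
  expect_equal(sum(ct10), 500)
})

test_that("oscillation detection recovers constructed volleys and flat traces", {
  # constant trace: no local maxima, hence no events
  oscf <- detect_oscillations(structure(rep(5, 2000), stride_ms = 0.5,
                                        window_ms = 10, duration_ms = 1000))
  expect_equal(nrow(oscf$events), 0)
  expect_equal(oscf$osc_freq_hz, 0)

  v <- volley_raster(n_volleys = 10, period_ms = 100, per_volley = 100,
                     duration_ms = 1000)
  osc <- detect_oscillations(windowed_counts(v), n_surviving = 100)
  expect_equal(nrow(osc$events), 10)
  expect_equal(osc$osc_freq_hz, 10)
  expect_equal(osc$events$magnitude, rep(100, 10))
  expect_equal(osc$events$fraction, rep(1, 10))
  # volleys sit at 50, 150, ... and peak times refer to window centers
  expect_equal(osc$events$t_peak, seq(50, 950, by = 100), tolerance = 1)
})

test_that("the detector localizes Gaussian bumps to one stride and 10% FWHM", {
  stride <- 0.5
  t <- seq(0, 2000, by = stride)
  mu <- c(300, 800, 1500)
  sigma <- c(10, 25, 40)
  amp <- c(60, 40, 80)
  x <- rowSums(mapply(function(m, s, a) a * exp(-(t - m)^2 / (2 * s^2)),
                      mu, sigma, amp))
  trace <- structure(x, stride_ms = stride, window_ms = 10,
                     duration_ms = max(t))
  osc <- detect_oscillations(trace, prominence_min = 5, min_sep_ms = 100)
  expect_equal(nrow(osc$events), 3)
  # t_peak carries the window-center offset; remove it for the comparison
  est_idx_time <- osc$events$t_peak - attr(trace, "window_ms") / 2
  expect_equal(est_idx_time, mu, tolerance = stride)
  expect_equal(osc$events$fwhm_ms, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.10 * 2 * sqrt(2 * log(2)) * min(sigma))
})

test_that("phase occupancy bins spikes within the 1.4-FWHM interval", {
  ev <- data.frame(t_peak = 100, magnitude = 10, fraction = NA,
                   fwhm_ms = 10, t_lo = 93, t_hi = 107)
  groups <- stats::setNames(rep("exc", 50), as.character(1:50))

  central <- spike_raster(1:50, rep(100, 50), 200, 50)
  po <- phase_occupancy(central, ev, n_bins = 10, groups)
  expect_equal(unname(po$likelihood["exc", 6]), 1)  # t = 100 -> bin 6 of 10

  set.seed(52)
  unif <- spike_raster(sample(1:50, 5000, TRUE), runif(5000, 93, 107),
                       200, 50)
  po2 <- phase_occupancy(unif, ev, n_bins = 10, groups)
  expect_equal(max(abs(po2$likelihood["exc", ] - 0.1)), 0, tolerance = 0.03)
  expect_equal(sum(po2$likelihood["exc", ]), 1)

  outside <- spike_raster(1:10, rep(150, 10), 200, 10)
  po3 <- phase_occupancy(outside, ev, n_bins = 5,
                         stats::setNames(rep("exc", 10),
                                         as.character(1:10)))
  expect_equal(sum(po3$counts), 0)
  expect_lte(po2$n_spikes_binned, nrow(unif))
})

test_that("the connectivity index reflects input/output strength balance", {
  net <- chain_net(weight = 2)
  idx <- connectivity_index(net)
  expect_equal(unname(idx["1"]), -1)   # outputs only
  expect_equal(unname(idx["2"]), 1)    # inputs only

  # balanced in/out strength -> 0; inhibitory weights count in absolute value
  net3 <- chain_net(weight = 2)
  net3$neurons <- rbind(net3$neurons, net3$neurons[1, ])
  net3$neurons$id <- 1:3
  net3$neurons$kind[3] <- "inhibitory"
  net3$edges <- data.frame(pre = c(1L, 2L, 3L), post = c(2L, 3L, 1L),
                           weight = c(2, 2, -2), delay_ms = 1)
  idx3 <- connectivity_index(net3)
  expect_equal(unname(idx3), c(0, 0, 0))

  iso <- chain_net(weight = 2)
  iso$edges <- iso$edges[0, ]
  expect_true(all(is.na(connectivity_index(iso))))
})

test_that("metric summaries report missing oscillation metrics when silent", {
  qr <- spike_raster(rep(1:5, 2), seq(100, 1000, by = 100), 2000, 5)
  ms <- summarize_metrics(qr, ids = 1:5)
  expect_true(is.na(ms$osc_freq_hz) || ms$osc_freq_hz >= 0)
  expect_equal(ms$n_surviving, 5)

  v <- volley_raster()
  msv <- summarize_metrics(v, ids = 1:100)
  expect_equal(msv$osc_freq_hz, 10)
  expect_equal(msv$osc_magnitude, 1)
  expect_true(msv$osc_magnitude >= 0 && msv$osc_magnitude <= 1)
})
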