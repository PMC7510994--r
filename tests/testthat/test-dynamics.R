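test_that("the Euler step matches hand-evaluated updates and the reset rule", {
  # hand evaluation: 0.04*65^2 = 169; RHS = 169 - 325 + 140 + 13 + 10 = 7
  st <- izhikevich_step(v = -65, u = -13, I = 10, a = 0.02, b = 0.2,
                        c = -65, d = 8)
  expect_equal(st$v, -63.6)
  expect_equal(st$u, -13)
  expect_false(st$spiked)

  # threshold crossing resets within the step
  st <- izhikevich_step(v = 30, u = 0, I = 0, a = 0.02, b = 0.2,
                        c = -65, d = 8)
  expect_true(st$spiked)
  expect_equal(st$v, -65)
  expect_equal(st$u, 0 + 0.2 * 0.02 * (0.2 * 30 - 0) + 8)

  # resting fixed point of the quadratic nullcline with u = b v:
  # 0.04 v^2 + 4.8 v + 140 = 0 -> v = -70 (stable)
  st <- izhikevich_step(v = -70, u = -14, I = 0, a = 0.02, b = 0.2,
                        c = -65, d = 8)
  expect_lt(abs(st$v - -70), 1e-9)

  expect_error(izhikevich_step(v = NaN, u = 0, I = 0, a = 0.02, b = 0.2,
                               c = -65, d = 8), "non-finite")
})

test_that("synaptic decay follows the closed form and composes over steps", {
  d <- decay_synapses(g_exc = 1, g_inh = 0, dt = 5, tau = 5)
  expect_equal(d$g_exc, exp(-1))
  expect_equal(d$g_inh, 0)

  g <- 1
  for (i in 1:25) g <- decay_synapses(g, 0, dt = 0.2, tau = 5)$g_exc
  expect_equal(g, exp(-1), tolerance = 1e-12)
})

test_that("spike delivery scales with the target's desensitization factor", {
  d <- deliver_spike(numeric(3), numeric(3), post = 2, weight = 4, s_post = 1)
  expect_equal(d$g_exc[2], 4)
  d <- deliver_spike(numeric(3), numeric(3), post = 1, weight = -14,
                     s_post = 1)
  expect_equal(d$g_inh[1], -14)
  d <- deliver_spike(numeric(3), numeric(3), post = 3, weight = 4,
                     s_post = 0.6)
  expect_equal(d$g_exc[3], 2.4)
  expect_error(deliver_spike(numeric(3), numeric(3), post = 9, weight = 1,
                             s_post = 1), "post")
})

test_that("desensitization resets to the floor on a spike and relaxes to 1", {
  expect_equal(update_desensitization(1, spiked = TRUE, dt = 0.2), 0.6)
  expect_equal(update_desensitization(1, spiked = FALSE, dt = 0.2), 1)
  # closed form: 150 ms after a spike, s = 1 - 0.4 e^{-1}
  expect_equal(update_desensitization(0.6, spiked = FALSE, dt = 150),
               1 - 0.4 * exp(-1))
})

test_that("background events follow the Poisson/gamma stimulus law", {
  ev0 <- background_events(10, 1000, stimulus_model(rate_hz = 0))
  expect_equal(nrow(ev0), 0)

  ev <- background_events(1000, 60000, stimulus_model(), seed = 4)
  expect_lt(abs(nrow(ev) - 60000), 3 * sqrt(60000))
  # amplitudes: gain x Gamma(2, 1/2), so mean gain x 1
  expect_equal(mean(ev$amplitude) / 15, 1, tolerance = 0.02)
  expect_true(all(ev$time_ms >= 0 & ev$time_ms < 60000))
})

test_that("simulation contracts: empty duration, silence without drive, firing with it", {
  net <- tiny_net(n = 20, mean_degree = 4, seed = 2)
  s0 <- initial_state(net)
  sim <- simulate_network(net, 0, seed = 1)
  expect_equal(nrow(sim$raster), 0)
  expect_equal(sim$state$v, s0$v)

  quiet <- simulate_network(net, 500, stim = stimulus_model(rate_hz = 0),
                            seed = 1)
  expect_equal(nrow(quiet$raster), 0)

  # a single mean-amplitude background event fires a resting RS neuron
  # within 20 ms
  one <- chain_net(weight = 0)
  ev <- data.frame(neuron = 1, time_ms = 1, amplitude = 15)
  # decay-mode injection: emulate by adding to the accumulator via a short
  # burst is not needed -- route through stim machinery instead
  sim1 <- simulate_network(one, 20, stim = stimulus_model(rate_hz = 0),
                           state = {
                             st <- initial_state(one)
                             st$g_exc[1] <- 15
                             st
                           }, seed = 1)
  expect_gte(sum(sim1$raster$neuron == 1), 1)
  expect_lt(min(sim1$raster$time_ms[sim1$raster$neuron == 1]), 20)
})

test_that("a two-neuron chain delivers drive exactly one delay after the pre spike", {
  for (delay in c(2, 4.8)) {
    net <- chain_net(weight = 30, delay_ms = delay)
    sim <- simulate_network(net, 50, stim = stimulus_model(rate_hz = 0),
                            ext_events = forced_spikes(1, 10), seed = 1)
    t_pre <- sim$raster$time_ms[sim$raster$neuron == 1][1]
    expect_equal(t_pre, 10)
    t_post <- sim$raster$time_ms[sim$raster$neuron == 2][1]
    # drive arrives exactly `delay` later; integration to threshold takes a
    # few further steps, identical across delays
    expect_gte(t_post, t_pre + delay)
  }
  # shifting the delay shifts the post spike by exactly the difference
  t_post <- vapply(c(2, 4), function(delay) {
    net <- chain_net(weight = 30, delay_ms = delay)
    sim <- simulate_network(net, 50, stim = stimulus_model(rate_hz = 0),
                            ext_events = forced_spikes(1, 10), seed = 1)
    sim$raster$time_ms[sim$raster$neuron == 2][1]
  }, numeric(1))
  expect_equal(diff(t_post), 2)
})

test_that("identical network, seed and config reproduce the raster exactly", {
  net <- tiny_net(n = 80, mean_degree = 16, seed = 5)
  a <- simulate_network(net, 2000, seed = 31)
  b <- simulate_network(net, 2000, seed = 31)
  expect_identical(a$raster, b$raster)
  expect_identical(a$network$edges$weight, b$network$edges$weight)
  c <- simulate_network(net, 2000, seed = 32)
  expect_false(identical(a$raster, c$raster))
})

test_that("block-wise simulation carries in-flight spikes across boundaries", {
  net <- chain_net(weight = 30, delay_ms = 6)
  # pre spike at 9.8 ms, block ends at 10 ms: arrival is in the next block
  s1 <- simulate_network(net, 10, stim = stimulus_model(rate_hz = 0),
                         ext_events = forced_spikes(1, 9.8), seed = 1)
  expect_gt(nrow(s1$state$queue), 0)
  s2 <- simulate_network(net, 40, stim = stimulus_model(rate_hz = 0),
                         state = s1$state, seed = 1)
  expect_true(any(s2$raster$neuron == 2))
})

test_that("a short default simulation stays in a plausible activity band", {
  net <- tiny_net(n = 200, mean_degree = 20, seed = 8)
  sim <- simulate_network(net, 20000, stdp = stdp_config(), seed = 9)
  fr <- firing_rate(sim$raster, ids = net$neurons$id)$mean
  expect_gt(fr, 0.1)
  expect_lt(fr, 50)
  # the invariant v < 30 holds at exit
  expect_true(all(sim$state$v < 30))
  expect_true(all(sim$state$g_exc >= 0))
  expect_true(all(sim$state$g_inh <= 0))
  expect_true(all(sim$state$s > 0 & sim$state$s <= 1))
})

test_that("non-finite membrane state aborts with neuron context", {
  net <- tiny_net(n = 10, mean_degree = 2, seed = 1)
  st <- initial_state(net)
  st$v[3] <- Inf
  expect_error(simulate_network(net, 10, state = st, seed = 1),
               "neuron 3")
})
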