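test_that("one-way ANOVA with Tukey-Kramer matches first principles", {
  # identical groups: no effect
  g <- rep(c("a", "b", "c"), each = 4)
  v <- rep(c(1, 2, 3, 4), 3)
  res <- anova_tukey(v, g)
  expect_lt(res$F, 1e-10)
  expect_true(all(res$pairs$p_adj > 0.99))

  # two groups: F equals the square of the pooled t statistic
  set.seed(60)
  x <- rnorm(8); y <- rnorm(10, 1)
  res2 <- anova_tukey(c(x, y), rep(c("x", "y"), c(8, 10)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-9)

  # three-group fixture against hand-computed sums of squares
  vals <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 8, 7, 13, 9, 11, 8, 12, 13)
  grp <- rep(c("g1", "g2", "g3"), each = 6)
  gm <- tapply(vals, grp, mean)
  ss_b <- sum(6 * (gm - mean(vals))^2)
  ss_w <- sum((vals - gm[grp])^2)
  f_hand <- (ss_b / 2) / (ss_w / 15)
  res3 <- anova_tukey(vals, grp)
  expect_equal(res3$F, f_hand, tolerance = 1e-12)
  expect_equal(nrow(res3$pairs), 3)

  expect_error(anova_tukey(1:4, rep("a", 4)), "two groups")
  expect_error(anova_tukey(rep(1, 6), rep(c("a", "b"), 3)), "degenerate")
})

test_that("Bonferroni-corrected Welch t-tests behave as advertised", {
  set.seed(61)
  x <- rnorm(10); y <- rnorm(10, 3)
  single <- ttest_bonferroni(list(list(x, y)))
  expect_equal(single$p, single$p_adj)
  expect_equal(single$t, unname(t.test(x, y)$statistic))

  same <- ttest_bonferroni(list(list(1:5, 1:5 + 0.001)))
  expect_false(same$significant)

  # closed-form Welch statistic for known means/SDs
  a <- c(10, 12, 14, 16, 18); b <- c(11, 11, 13, 13, 12)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  multi <- ttest_bonferroni(list(list(a, b), list(x, y), list(a, a)))
  expect_equal(multi$t[1], t_hand, tolerance = 1e-12)
  expect_equal(multi$p_adj, pmin(multi$p * 3, 1))
})

test_that("settling stops by the vacuous criterion after two blocks", {
  cfg <- desk_config(n = 60, mean_degree = 8, settle_block_s = 2,
                     settle_max_s = 60, settle_tol = Inf)
  net <- tiny_net(n = 60, mean_degree = 8, seed = 70)
  st <- settle(net, cfg, seed = 71)
  expect_true(st$converged)
  expect_equal(st$elapsed_s, 4)
  expect_equal(nrow(st$trace), 2)
})

test_that("a stationary frozen-weight network passes the convergence rule", {
  cfg <- desk_config(n = 80, mean_degree = 10, settle_block_s = 10,
                     settle_max_s = 120, settle_tol = 0.25)
  cfg$stdp <- NULL   # frozen weights: statistics are stationary
  net <- tiny_net(n = 80, mean_degree = 10, seed = 72)
  st <- suppressWarnings(settle(net, cfg, seed = 73))
  expect_true(st$converged)
  expect_identical(st$network$edges$weight, net$edges$weight)
})

test_that("the protocol produces the full grid of measured phases", {
  cfg <- desk_config(n = 80, mean_degree = 10, n_replicates = 2,
                     settle_block_s = 2, settle_max_s = 4, settle_tol = Inf,
                     measure_s = 2, recovery_max_s = 4,
                     injury_fractions = 0.2)
  res <- suppressWarnings(run_protocol(cfg, seed = 74))
  expect_s3_class(res, "izhi_results")
  # rows = replicates x (baseline + |grid| x 2 phases)
  expect_equal(nrow(res), 2 * (1 + 1 * 2))
  expect_setequal(unique(res$phase), c("baseline", "injured", "recovered"))
  expect_true(all(res$n_surviving[res$phase == "baseline"] == 80))
  expect_true(all(res$n_surviving[res$phase != "baseline"] == 64))

  # empty grid: baseline-only table
  cfg0 <- cfg; cfg0$injury_fractions <- numeric()
  res0 <- suppressWarnings(run_protocol(cfg0, seed = 74))
  expect_equal(nrow(res0), 2)
  expect_true(all(res0$phase == "baseline"))

  agg <- aggregate_results(res, "firing_rate_hz")
  expect_equal(sum(agg$n), nrow(res))

  # fixed master seed: bit-reproducible end to end
  res2 <- suppressWarnings(run_protocol(cfg, seed = 74))
  expect_identical(res$firing_rate_hz, res2$firing_rate_hz)
})

test_that("the E/I sweep self-normalizes at the reference composition", {
  cfg <- desk_config(n = 80, mean_degree = 10, n_replicates = 2,
                     settle_block_s = 2, settle_max_s = 4, settle_tol = Inf,
                     measure_s = 2)
  sw <- suppressWarnings(ei_sweep(cfg, frac_exc_grid = 0.8, seed = 75))
  norm <- sw$normalized
  vals <- unlist(norm[abs(norm$frac_exc - 0.8) < 1e-9,
                      c("firing_rate_hz", "cov_isi", "osc_freq_hz",
                        "osc_magnitude", "osc_fwhm_ms")])
  # every metric defined at this scale self-normalizes to exactly 1
  expect_true(all(is.na(vals) | abs(vals - 1) < 1e-12))
  expect_equal(unname(vals["firing_rate_hz"]), 1, tolerance = 1e-12)
  expect_error(ei_sweep(cfg, frac_exc_grid = c(0.65, 0.95)), "0.8")
})
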