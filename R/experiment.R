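#' Protocol configuration
#'
#' Bundles the knobs of the settle -> measure -> injure -> measure ->
#' recover -> measure protocol. The full-scale defaults are the study
#' conditions: 1000 neurons, 80/20 E/I, settling with STDP in 5-minute
#' blocks until firing rate and oscillation frequency both change by less
#' than 1% between consecutive blocks (cap 4 simulated hours), 5-minute
#' measurement windows, ten replicates, injury grid 5%-95% in 5% steps.
#' [desk_config()] provides a documented reduced profile for fast runs.
#'
#' @param n,frac_exc,mean_degree,degree_cv Network construction parameters.
#' @param n_replicates Independent replicate networks per condition
#'   (default 10).
#' @param settle_block_s Settling/convergence comparison block in seconds
#'   (default 300).
#' @param settle_max_s Settling cap in seconds (default 14400 = 4 h).
#' @param settle_tol Relative-change convergence threshold (default 0.01).
#' @param measure_s Measurement window in seconds (default 300).
#' @param recovery_max_s Post-injury recovery cap in seconds (default
#'   14400).
#' @param injury_modes,injury_fractions Injury grid (defaults: random mode,
#'   fractions 0.05-0.95 by 0.05).
#' @param stim A [stimulus_model()].
#' @param stdp An [stdp_config()].
#' @param param_jitter Izhikevich parameter jitter.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(n = 1000, frac_exc = 0.8, mean_degree = 100,
                            degree_cv = 0.1, n_replicates = 10,
                            settle_block_s = 300, settle_max_s = 14400,
                            settle_tol = 0.01, measure_s = 300,
                            recovery_max_s = 14400,
                            injury_modes = "random",
                            injury_fractions = seq(0.05, 0.95, by = 0.05),
                            stim = stimulus_model(),
                            stdp = stdp_config(),
                            param_jitter = 0.05) {
  stopifnot(measure_s <= settle_max_s, all(injury_fractions > 0),
            all(injury_fractions < 1))
  structure(as.list(environment()), class = "protocol_config")
}

#' Reduced desk-scale protocol profile
#'
#' A smaller, faster instance of the same protocol used for development and
#' property checks: 300 neurons that keep the full-scale per-neuron
#' connection count (mean total degree 100, i.e. higher density), 60-second
#' settling blocks with a 20-minute cap, 60-second measurement windows and
#' 5 replicates. Preserving the input count per neuron keeps the reduced
#' network in the recurrence-dominated regime of the full-scale model;
#' scaling the degree down with n would leave each neuron driven mostly by
#' the background stimulus and change the dynamics qualitatively.
#' Directional findings (injury lowers activity, plasticity recovers it) are
#' assessed at this scale; absolute metric levels belong to the full-scale
#' configuration.
#'
#' @param ... Overrides passed to [protocol_config()].
#' @export
desk_config <- function(...) {
  defaults <- list(n = 300, mean_degree = 100, n_replicates = 5,
                   settle_block_s = 60, settle_max_s = 1200,
                   measure_s = 60, recovery_max_s = 600,
                   injury_fractions = c(0.1, 0.4))
  args <- utils::modifyList(defaults, list(...))
  do.call(protocol_config, args)
}

#' Settle a network with STDP
#'
#' Simulates in blocks of `cfg$settle_block_s` with plasticity on, stopping
#' when the population firing rate and the oscillation frequency both change
#' by less than `cfg$settle_tol` (relative) between consecutive blocks, or
#' at the `max_s` cap (a warning is recorded in the result, and the run
#' proceeds). Returns the reweighted network, the last block's raster and
#' the continuation state.
#'
#' @param net An `izhi_network`.
#' @param cfg A [protocol_config()].
#' @param seed Optional seed.
#' @param state Optional continuation state.
#' @param max_s Settling cap (default `cfg$settle_max_s`).
#' @return A list of class `izhi_settle`: `network`, `raster`, `state`,
#'   `elapsed_s`, `converged`, `trace` (per-block metrics).
#' @export
settle <- function(net, cfg = protocol_config(), seed = NULL, state = NULL,
                   max_s = cfg$settle_max_s) {
  if (!is.null(seed)) set.seed(seed)
  block_ms <- cfg$settle_block_s * 1000
  elapsed <- 0
  prev <- NULL
  converged <- FALSE
  trace <- list()
  sim <- NULL
  while (elapsed < max_s) {
    sim <- simulate_network(net, block_ms, stim = cfg$stim, stdp = cfg$stdp,
                            state = state)
    state <- sim$state
    net <- sim$network
    elapsed <- elapsed + cfg$settle_block_s
    fr <- firing_rate(sim$raster, ids = net$neurons$id)$mean
    ct <- windowed_counts(sim$raster, stride_ms = net$config$dt_ms)
    of <- detect_oscillations(ct)$osc_freq_hz
    trace[[length(trace) + 1]] <- data.frame(elapsed_s = elapsed,
                                             firing_rate_hz = fr,
                                             osc_freq_hz = of)
    if (!is.null(prev)) {
      rel <- function(cur, old) {
        if (old == 0) ifelse(cur == 0, 0, Inf) else abs(cur - old) / old
      }
      if (is.infinite(cfg$settle_tol) ||
          (rel(fr, prev$fr) < cfg$settle_tol &&
           rel(of, prev$of) < cfg$settle_tol)) {
        converged <- TRUE
        break
      }
    }
    prev <- list(fr = fr, of = of)
  }
  if (!converged) {
    warning(sprintf("settling did not converge within %d s (proceeding)",
                    as.integer(max_s)))
  }
  structure(list(network = net, raster = sim$raster, state = state,
                 elapsed_s = elapsed, converged = converged,
                 trace = do.call(rbind, trace)),
            class = "izhi_settle")
}

# Deterministic child seeds: one root seed spawns per-replicate, per-stage
# streams so that all conditions within a replicate share one settled
# network.
.child_seeds <- function(seed, n_replicates, n_streams = 8) {
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1, n_replicates * n_streams),
         nrow = n_replicates)
}

#' Run the full injury/recovery protocol
#'
#' Per replicate: build a network, settle it with STDP, measure the baseline
#' window, then for every (mode, fraction) in the injury grid: copy the
#' settled network, injure it, measure for `cfg$measure_s` with frozen
#' weights, let it recover with STDP under the settling convergence rule
#' (cap `cfg$recovery_max_s`), and measure again. LFR/HFR deletions rank
#' neurons by their baseline-window firing rates.
#'
#' @param cfg A [protocol_config()].
#' @param seed Master seed.
#' @param progress Emit per-stage messages (default `FALSE`).
#' @return A data frame of class `izhi_results`: one row per (replicate,
#'   condition, phase) with the five activity metrics. Phases are
#'   `baseline`, `injured` (frozen weights), `recovered` (post-STDP).
#' @export
run_protocol <- function(cfg = protocol_config(), seed = 1,
                         progress = FALSE) {
  seeds <- .child_seeds(seed, cfg$n_replicates)
  grid <- expand.grid(mode = cfg$injury_modes,
                      fraction = cfg$injury_fractions,
                      stringsAsFactors = FALSE)
  rows <- list()
  note <- function(...) if (progress) message(sprintf(...))
  for (r in seq_len(cfg$n_replicates)) {
    note("replicate %d/%d: build + settle", r, cfg$n_replicates)
    net <- build_network(n = cfg$n, frac_exc = cfg$frac_exc,
                         mean_degree = cfg$mean_degree,
                         degree_cv = cfg$degree_cv,
                         param_jitter = cfg$param_jitter,
                         seed = seeds[r, 1])
    st <- settle(net, cfg, seed = seeds[r, 2])
    base_sim <- simulate_network(st$network, cfg$measure_s * 1000,
                                 stim = cfg$stim, stdp = cfg$stdp,
                                 state = st$state, seed = seeds[r, 3])
    base_net <- base_sim$network
    base_state <- base_sim$state
    base_rates <- firing_rate(base_sim$raster,
                              ids = base_net$neurons$id)$per_neuron
    rows[[length(rows) + 1]] <- cbind(
      data.frame(replicate = r, condition = "baseline", mode = "none",
                 fraction = 0, phase = "baseline"),
      summarize_metrics(base_sim$raster, base_net$neurons$id))
    for (g in seq_len(nrow(grid))) {
      mode <- grid$mode[g]; frac <- grid$fraction[g]
      cond <- sprintf("%s:%.2f", mode, frac)
      note("replicate %d: %s", r, cond)
      inj <- injure(base_net, frac, mode, rates = base_rates,
                    seed = seeds[r, 4] + g)
      inj_sim <- simulate_network(inj$network, cfg$measure_s * 1000,
                                  stim = cfg$stim, stdp = NULL,
                                  seed = seeds[r, 5] + g)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(replicate = r, condition = cond, mode = mode,
                   fraction = frac, phase = "injured"),
        summarize_metrics(inj_sim$raster, inj$network$neurons$id))
      set.seed(seeds[r, 6] + g)
      rec <- settle(inj$network, cfg, state = inj_sim$state,
                    max_s = cfg$recovery_max_s)
      rec_sim <- simulate_network(rec$network, cfg$measure_s * 1000,
                                  stim = cfg$stim, stdp = cfg$stdp,
                                  state = rec$state, seed = seeds[r, 7] + g)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(replicate = r, condition = cond, mode = mode,
                   fraction = frac, phase = "recovered"),
        summarize_metrics(rec_sim$raster, rec$network$neurons$id))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("izhi_results", "data.frame")
  out
}

#' Group means and standard errors of a result table
#'
#' @param results An `izhi_results` table from [run_protocol()].
#' @param metric Metric column name (default `"firing_rate_hz"`).
#' @return A data frame with one row per (condition, phase): `mean`, `se`,
#'   `n` (missing values dropped).
#' @export
aggregate_results <- function(results, metric = "firing_rate_hz") {
  key <- interaction(results$condition, results$phase, drop = TRUE,
                     sep = "\x1f")
  agg <- lapply(split(results[[metric]], key), function(x) {
    x <- x[!is.na(x)]
    data.frame(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
               n = length(x))
  })
  info <- do.call(rbind, strsplit(names(agg), "\x1f", fixed = TRUE))
  out <- cbind(data.frame(condition = info[, 1], phase = info[, 2]),
               do.call(rbind, agg))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' @param values Numeric response vector.
#' @param group Grouping vector (>= 2 groups, each >= 2 samples).
#' @param conf_level Confidence level for the Tukey intervals (default
#'   0.95).
#' @return A list with `F`, `p`, `df`, and `pairs` (a data frame of pairwise
#'   differences with Tukey-Kramer adjusted p-values, unequal n supported).
#' @export
anova_tukey <- function(values, group, conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("each group needs at least two samples")
  wvar <- tapply(values, group, stats::var)
  if (all(wvar == 0)) stop("degenerate input: zero variance in all groups")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]), pairs = pairs)
}

#' Welch t-tests with Bonferroni correction
#'
#' @param pairs A list of length-2 lists/structures, each holding the two
#'   sample vectors to compare.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data frame with `t`, `df`, `p`, `p_adj` (Bonferroni over the
#'   number of pairs) and `significant` at `alpha`.
#' @export
ttest_bonferroni <- function(pairs, alpha = 0.05) {
  m <- length(pairs)
  res <- lapply(pairs, function(pr) {
    stopifnot(length(pr[[1]]) >= 2, length(pr[[2]]) >= 2)
    tt <- stats::t.test(pr[[1]], pr[[2]])
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(out$p * m, 1)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Sweep the excitatory/inhibitory composition
#'
#' Baseline-only protocol (build -> settle -> measure) per excitatory
#' fraction in `frac_exc_grid`, with group-mean metrics normalized to the
#' 80% excitatory network. Also reports per-composition oscillation phase
#' occupancy (quintiles, excitatory vs inhibitory) to track how spike timing
#' within oscillations shifts with E/I balance.
#'
#' @param cfg A [protocol_config()] (its `frac_exc` is overridden by the
#'   grid).
#' @param frac_exc_grid Excitatory fractions to test (must include 0.8; the
#'   study range is 0.65-0.95).
#' @param seed Master seed.
#' @return A list with `table` (per replicate x composition metrics),
#'   `normalized` (grid x metric group means divided by the 0.8 row), and
#'   `phase` (named list of quintile likelihood matrices).
#' @export
ei_sweep <- function(cfg = protocol_config(), frac_exc_grid = c(0.65, 0.8,
                                                                0.95),
                     seed = 1) {
  if (!any(abs(frac_exc_grid - 0.8) < 1e-9)) {
    stop("'frac_exc_grid' must include the 0.8 reference composition")
  }
  rows <- list()
  phase <- list()
  for (fe in frac_exc_grid) {
    seeds <- .child_seeds(seed + round(1000 * fe), cfg$n_replicates)
    occ_sum <- NULL
    for (r in seq_len(cfg$n_replicates)) {
      net <- build_network(n = cfg$n, frac_exc = fe,
                           mean_degree = cfg$mean_degree,
                           degree_cv = cfg$degree_cv,
                           param_jitter = cfg$param_jitter,
                           seed = seeds[r, 1])
      st <- settle(net, cfg, seed = seeds[r, 2])
      sim <- simulate_network(st$network, cfg$measure_s * 1000,
                              stim = cfg$stim, stdp = cfg$stdp,
                              state = st$state, seed = seeds[r, 3])
      ms <- summarize_metrics(sim$raster, st$network$neurons$id)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(frac_exc = fe, replicate = r), ms)
      ct <- windowed_counts(sim$raster, stride_ms = net$config$dt_ms)
      osc <- detect_oscillations(ct, n_surviving = nrow(st$network$neurons))
      if (nrow(osc$events) > 0) {
        grp <- st$network$neurons$kind
        names(grp) <- as.character(st$network$neurons$id)
        po <- phase_occupancy(sim$raster, osc$events, n_bins = 5, grp)
        occ_sum <- if (is.null(occ_sum)) po$counts else occ_sum + po$counts
      }
    }
    if (!is.null(occ_sum)) {
      rs <- rowSums(occ_sum)
      phase[[sprintf("%.2f", fe)]] <- sweep(occ_sum, 1,
                                            ifelse(rs > 0, rs, 1), "/")
    }
  }
  tab <- do.call(rbind, rows)
  metrics <- c("firing_rate_hz", "cov_isi", "osc_freq_hz", "osc_magnitude",
               "osc_fwhm_ms")
  gm <- stats::aggregate(tab[metrics], list(frac_exc = tab$frac_exc), mean,
                         na.rm = TRUE)
  ref <- gm[abs(gm$frac_exc - 0.8) < 1e-9, metrics]
  norm <- gm
  norm[metrics] <- sweep(as.matrix(gm[metrics]), 2, as.numeric(ref), "/")
  list(table = tab, group_means = gm, normalized = norm, phase = phase)
}
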