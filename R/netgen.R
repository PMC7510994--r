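#' Sample uniform positions on the unit sphere
#'
#' Draws `n` points uniformly (isotropically) on the surface of the unit
#' sphere by normalizing standard Gaussian triples. Neurons are placed this
#' way to avoid edge effects in a bounded domain; distances between neurons
#' (great-circle arclength) set synaptic transmission delays.
#'
#' @param n Number of points (>= 1).
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return An `n x 3` numeric matrix with unit-norm rows.
#' @export
sample_positions <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a single integer >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(p^2))
  while (any(nrm < 1e-12)) {           # astronomically rare, but keep exact
    bad <- nrm < 1e-12
    p[bad, ] <- matrix(stats::rnorm(3 * sum(bad)), ncol = 3)
    nrm <- sqrt(rowSums(p^2))
  }
  p / nrm
}

# Canonical Izhikevich parameter sets: regular-spiking (excitatory phenotype)
# and fast-spiking (inhibitory phenotype).
.izhi_canonical <- list(
  excitatory = c(a = 0.02, b = 0.2, c = -65, d = 8),
  inhibitory = c(a = 0.1,  b = 0.2, c = -65, d = 2)
)

#' Sample per-neuron Izhikevich parameters
#'
#' Returns parameters (a, b, c, d) centered on the canonical regular-spiking
#' (excitatory) or fast-spiking (inhibitory) values, with independent uniform
#' multiplicative jitter of +/- `jitter` about each canonical value so that
#' the population is heterogeneous rather than a clone army.
#'
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param jitter Nonnegative jitter fraction (default 0.05, i.e. +/-5%).
#' @param n Number of neurons to draw.
#' @param seed Optional seed.
#' @return A data frame with columns `a`, `b`, `c`, `d` (`n` rows).
#' @export
sample_neuron_params <- function(kind = c("excitatory", "inhibitory"),
                                 jitter = 0.05, n = 1, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(jitter) || length(jitter) != 1L || jitter < 0) {
    stop("'jitter' must be a single nonnegative number")
  }
  if (!is.null(seed)) set.seed(seed)
  base <- .izhi_canonical[[kind]]
  out <- vapply(base, function(p) p * (1 + stats::runif(n, -jitter, jitter)),
                numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, names(base)))
  as.data.frame(out)
}

#' Build random directed connectivity
#'
#' Draws a target out-degree per neuron from
#' Normal(`mean_degree`/2, (`degree_cv` x `mean_degree`/2)^2), rounds, clips
#' to \[1, n-1\], and connects each neuron to that many distinct uniformly
#' chosen targets (no self-edges). In-degree then arises from random
#' targeting, so the total (in + out) degree averages `mean_degree` -- the
#' Erdos-Renyi-like substrate of the model.
#'
#' @param n Number of neurons.
#' @param mean_degree Target mean total (in + out) degree (default 100).
#' @param degree_cv Coefficient of variation of the out-degree draw
#'   (default 0.1).
#' @param seed Optional seed.
#' @return A data frame with integer columns `pre`, `post` (1-based ids).
#' @export
build_connectivity <- function(n, mean_degree = 100, degree_cv = 0.1,
                               seed = NULL) {
  if (mean_degree >= n) stop("'mean_degree' must be < n")
  if (!is.null(seed)) set.seed(seed)
  mu <- mean_degree / 2
  k <- round(stats::rnorm(n, mu, degree_cv * mu))
  k <- pmin(pmax(k, 1L), n - 1L)
  pre <- rep.int(seq_len(n), k)
  post <- integer(length(pre))
  pos <- 1L
  for (i in seq_len(n)) {
    tgt <- sample.int(n - 1L, k[i])           # uniform w/o replacement
    tgt <- tgt + (tgt >= i)                   # skip self
    post[pos:(pos + k[i] - 1L)] <- tgt
    pos <- pos + k[i]
  }
  data.frame(pre = pre, post = post)
}

#' Seed synaptic weights
#'
#' Excitatory weights are drawn from a symmetric bimodal mixture on \[0, 1\]
#' (two Beta(2, 8)-shaped lobes, one reflected about 0.5, equal mass) and
#' scaled to `exc_scale`; the bimodal seeding anticipates the fixed-point
#' distribution of additive STDP, under which weights migrate to the bounds.
#' Inhibitory weights are drawn from Normal(0.5, 0.05) on \[0, 1\], clipped,
#' and mapped linearly onto `inh_scale`.
#'
#' @param edges Data frame with columns `pre`, `post`.
#' @param kind Character vector of neuron kinds indexed by id
#'   (`"excitatory"` / `"inhibitory"`).
#' @param exc_scale,inh_scale Length-2 ordered ranges (defaults `c(0, 4)`
#'   and `c(-14, 0)`).
#' @param bimodal_shape Beta shape parameters of one lobe (default `c(2, 8)`).
#' @param seed Optional seed.
#' @return `edges` with a numeric `weight` column appended.
#' @export
seed_weights <- function(edges, kind, exc_scale = c(0, 4),
                         inh_scale = c(-14, 0), bimodal_shape = c(2, 8),
                         seed = NULL) {
  if (exc_scale[1] > exc_scale[2] || inh_scale[1] > inh_scale[2]) {
    stop("weight scales must be ordered (lo <= hi)")
  }
  if (!is.null(seed)) set.seed(seed)
  is_e <- kind[edges$pre] == "excitatory"
  w <- numeric(nrow(edges))
  m_e <- sum(is_e)
  if (m_e > 0) {
    lobe <- stats::rbeta(m_e, bimodal_shape[1], bimodal_shape[2])
    hi <- stats::runif(m_e) < 0.5
    u <- ifelse(hi, 1 - lobe, lobe)
    w[is_e] <- exc_scale[1] + u * diff(exc_scale)
  }
  m_i <- sum(!is_e)
  if (m_i > 0) {
    u <- pmin(pmax(stats::rnorm(m_i, 0.5, 0.05), 0), 1)
    w[!is_e] <- inh_scale[1] + u * diff(inh_scale)
  }
  edges$weight <- w
  edges
}

#' Arclength-proportional synaptic delays
#'
#' Delay = `max_delay` x (great-circle arclength / pi), rounded up to the
#' next positive multiple of the timestep so that no delay is zero (a zero
#' delay would break event ordering). Coincident positions get the minimum
#' one-step delay.
#'
#' @param positions Matrix of unit 3-vectors (rows indexed by neuron id).
#' @param pre,post Integer id vectors defining the edges.
#' @param max_delay Maximum delay in ms (default 8).
#' @param dt Timestep in ms (default 0.2).
#' @return Numeric vector of delays in ms, all in (0, `max_delay`\].
#' @export
compute_delays <- function(positions, pre, post, max_delay = 8, dt = 0.2) {
  dotp <- rowSums(positions[pre, , drop = FALSE] *
                  positions[post, , drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, dotp)))
  delay <- max_delay * ang / pi
  steps <- ceiling(delay / dt - 1e-9)
  steps[steps < 1] <- 1
  steps * dt
}

#' Build a spiking cortical network
#'
#' Constructs the full synthetic substrate: `n` neurons (fraction `frac_exc`
#' regular-spiking excitatory, remainder fast-spiking inhibitory, parameters
#' jittered per neuron), placed uniformly on the unit sphere, randomly
#' connected with ~`mean_degree` total connections per neuron, weights seeded
#' bimodally (excitatory, scaled to `exc_scale`) or normally (inhibitory,
#' scaled to `inh_scale`), and arclength-proportional delays capped at
#' `max_delay_ms`.
#'
#' @param n Number of neurons (default 1000).
#' @param frac_exc Excitatory fraction (default 0.8; the E/I sweep uses
#'   0.65-0.95).
#' @param mean_degree Mean total degree (default 100).
#' @param degree_cv Out-degree coefficient of variation (default 0.1).
#' @param exc_scale,inh_scale Weight ranges (defaults `c(0, 4)`, `c(-14, 0)`).
#' @param max_delay_ms Delay cap in ms (default 8).
#' @param dt_ms Timestep in ms (default 0.2).
#' @param param_jitter Izhikevich parameter jitter fraction (default 0.05).
#' @param seed Optional integer seed; the whole construction is reproducible
#'   given the seed.
#' @return An object of class `izhi_network`: a list with data frames
#'   `neurons` (`id`, `kind`, `a`-`d`, `x`, `y`, `z`) and `edges`
#'   (`pre`, `post`, `weight`, `delay_ms`), plus the construction `config`.
#' @examples
#' net <- build_network(n = 100, mean_degree = 10, seed = 1)
#' net
#' @export
build_network <- function(n = 1000, frac_exc = 0.8, mean_degree = 100,
                          degree_cv = 0.1, exc_scale = c(0, 4),
                          inh_scale = c(-14, 0), max_delay_ms = 8,
                          dt_ms = 0.2, param_jitter = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_exc <- round(n * frac_exc)
  kind <- rep(c("excitatory", "inhibitory"), c(n_exc, n - n_exc))
  pars <- rbind(sample_neuron_params("excitatory", param_jitter, n_exc),
                sample_neuron_params("inhibitory", param_jitter, n - n_exc))
  pos <- sample_positions(n)
  edges <- build_connectivity(n, mean_degree, degree_cv)
  edges <- seed_weights(edges, kind, exc_scale, inh_scale)
  edges$delay_ms <- compute_delays(pos, edges$pre, edges$post,
                                   max_delay_ms, dt_ms)
  neurons <- data.frame(id = seq_len(n), kind = kind, pars,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3])
  structure(list(
    neurons = neurons,
    edges = edges,
    config = list(n = n, frac_exc = frac_exc, mean_degree = mean_degree,
                  degree_cv = degree_cv, exc_scale = exc_scale,
                  inh_scale = inh_scale, max_delay_ms = max_delay_ms,
                  dt_ms = dt_ms, param_jitter = param_jitter, seed = seed)
  ), class = "izhi_network")
}

#' @export
print.izhi_network <- function(x, ...) {
  n <- nrow(x$neurons)
  ne <- sum(x$neurons$kind == "excitatory")
  cat(sprintf("Izhikevich network: %d neurons (%d exc / %d inh), %d edges\n",
              n, ne, n - ne, nrow(x$edges)))
  cat(sprintf("  mean total degree %.1f, delays (%.1f, %.1f] ms, dt %.1f ms\n",
              2 * nrow(x$edges) / n, min(x$edges$delay_ms),
              max(x$edges$delay_ms), x$config$dt_ms))
  invisible(x)
}

#' @export
summary.izhi_network <- function(object, ...) {
  e <- object$edges
  kind <- object$neurons$kind
  exc_e <- kind[e$pre] == "excitatory"
  out <- list(
    n = nrow(object$neurons),
    n_exc = sum(kind == "excitatory"),
    n_edges = nrow(e),
    mean_total_degree = 2 * nrow(e) / nrow(object$neurons),
    exc_weight_range = range(e$weight[exc_e]),
    inh_weight_range = if (any(!exc_e)) range(e$weight[!exc_e]) else c(NA, NA),
    delay_range_ms = range(e$delay_ms)
  )
  class(out) <- "summary.izhi_network"
  out
}

#' @export
print.summary.izhi_network <- function(x, ...) {
  cat(sprintf("neurons: %d (%d excitatory)\nedges: %d (mean total degree %.2f)\n",
              x$n, x$n_exc, x$n_edges, x$mean_total_degree))
  cat(sprintf("excitatory weights in [%.3f, %.3f]; inhibitory in [%.3f, %.3f]\n",
              x$exc_weight_range[1], x$exc_weight_range[2],
              x$inh_weight_range[1], x$inh_weight_range[2]))
  cat(sprintf("delays in [%.1f, %.1f] ms\n", x$delay_range_ms[1],
              x$delay_range_ms[2]))
  invisible(x)
}
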