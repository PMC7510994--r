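#' Delete neurons from a network (neurodegeneration)
#'
#' Permanently removes `round(fraction * n)` neurons and every synapse
#' touching them, where `n` is the size of the network being injured.
#' Three protocols are available:
#' \describe{
#'   \item{`random`}{E/I-ratio-preserving random deletion: 4 excitatory
#'     neurons removed for every 1 inhibitory (excitatory count =
#'     `round(0.8 * n_del)`), chosen uniformly within each kind.}
#'   \item{`focal`}{Spatially contiguous lesion: a random center is drawn on
#'     the sphere and the `n_del` neurons nearest to it (great-circle
#'     arclength, kind-agnostic) are removed.}
#'   \item{`lfr` / `hfr`}{Activity-targeted deletion of excitatory neurons
#'     only: excitatory neurons are ranked by their measured firing rate and
#'     the bottom (`lfr`) or top (`hfr`) `n_del` are removed; ties are broken
#'     by a seeded random shuffle. Inhibitory neurons are untouched.}
#' }
#'
#' @param net An `izhi_network`.
#' @param fraction Deleted fraction of the network in \[0, 1).
#' @param mode One of `"random"`, `"focal"`, `"lfr"`, `"hfr"`.
#' @param rates Named numeric vector of per-neuron firing rates (names =
#'   neuron ids) covering all excitatory neurons; required for
#'   `lfr` / `hfr`.
#' @param seed Optional seed.
#' @return A list with `network` (the injured `izhi_network`, original ids
#'   retained) and `deleted` (integer ids removed); focal injuries also
#'   report the lesion `center` (unit 3-vector).
#' @examples
#' net <- build_network(n = 100, mean_degree = 10, seed = 1)
#' inj <- injure(net, 0.1, "random", seed = 2)
#' length(inj$deleted)
#' @export
injure <- function(net, fraction, mode = c("random", "focal", "lfr", "hfr"),
                   rates = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "izhi_network"), fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  nr <- net$neurons
  n <- nrow(nr)
  n_del <- round(fraction * n)
  if (n_del == 0) return(list(network = net, deleted = integer()))
  center <- NULL

  if (mode == "random") {
    n_exc_del <- round(0.8 * n_del)
    n_inh_del <- n_del - n_exc_del
    exc_ids <- nr$id[nr$kind == "excitatory"]
    inh_ids <- nr$id[nr$kind == "inhibitory"]
    if (n_exc_del > length(exc_ids) || n_inh_del > length(inh_ids)) {
      stop("requested deletions exceed available neurons of a kind")
    }
    deleted <- c(sample(exc_ids, n_exc_del), sample(inh_ids, n_inh_del))
  } else if (mode == "focal") {
    if (n_del > n) stop("requested deletions exceed network size")
    center <- stats::rnorm(3)
    center <- center / sqrt(sum(center^2))
    arc <- acos(pmin(1, pmax(-1, as.matrix(nr[, c("x", "y", "z")]) %*% center)))
    deleted <- nr$id[order(arc)][seq_len(n_del)]
    center <- as.numeric(center)
  } else {
    exc_ids <- nr$id[nr$kind == "excitatory"]
    if (is.null(rates)) stop("'rates' is required for lfr/hfr deletion")
    if (!all(as.character(exc_ids) %in% names(rates))) {
      stop("'rates' must cover all excitatory neurons")
    }
    if (n_del > length(exc_ids)) {
      stop("requested deletions exceed the excitatory population")
    }
    r <- as.numeric(rates[as.character(exc_ids)])
    ord <- order(r, stats::runif(length(r)),
                 decreasing = (mode == "hfr"))
    deleted <- exc_ids[ord][seq_len(n_del)]
  }

  deleted <- sort(as.integer(deleted))
  net$neurons <- nr[!nr$id %in% deleted, , drop = FALSE]
  rownames(net$neurons) <- NULL
  keep_e <- !(net$edges$pre %in% deleted) & !(net$edges$post %in% deleted)
  net$edges <- net$edges[keep_e, , drop = FALSE]
  rownames(net$edges) <- NULL
  out <- list(network = net, deleted = deleted)
  if (!is.null(center)) out$center <- center
  out
}
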