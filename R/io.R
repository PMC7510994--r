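# Text serialization: a tab-separated edge list plus a companion neuron
# table, both with '#'-prefixed header lines carrying the construction
# config. Deterministic %.17g formatting makes identical topologies
# serialize byte-identically and round-trip exactly.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a network to tab-separated text files
#'
#' @param net An `izhi_network`.
#' @param edges_file Path for the edge list (`pre_id`, `post_id`, `weight`,
#'   `delay_ms`).
#' @param neurons_file Path for the neuron table (`id`, `kind`, `a`-`d`,
#'   `x`, `y`, `z`).
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, edges_file, neurons_file) {
  cfg <- net$config
  hdr <- sprintf("# %s",
                 paste(names(cfg),
                       vapply(cfg, function(v)
                         paste(format(v, digits = 17), collapse = ","),
                         character(1)),
                       sep = "=", collapse = " "))
  ec <- c(hdr, "# pre_id\tpost_id\tweight\tdelay_ms",
          sprintf("%d\t%d\t%s\t%s", net$edges$pre, net$edges$post,
                  .fmt_num(net$edges$weight), .fmt_num(net$edges$delay_ms)))
  writeLines(ec, edges_file)
  nn <- net$neurons
  nc <- c(hdr, "# id\tkind\ta\tb\tc\td\tx\ty\tz",
          sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s", nn$id, nn$kind,
                  .fmt_num(nn$a), .fmt_num(nn$b), .fmt_num(nn$c),
                  .fmt_num(nn$d), .fmt_num(nn$x), .fmt_num(nn$y),
                  .fmt_num(nn$z)))
  writeLines(nc, neurons_file)
  invisible(c(edges_file, neurons_file))
}

#' Read a network written by [write_network()]
#'
#' @param edges_file,neurons_file Paths written by [write_network()].
#' @return An `izhi_network` (its `config` carries the scalar keys that
#'   survive the text header).
#' @export
read_network <- function(edges_file, neurons_file) {
  e <- utils::read.table(edges_file, sep = "\t", comment.char = "#",
                         col.names = c("pre", "post", "weight", "delay_ms"))
  nn <- utils::read.table(neurons_file, sep = "\t", comment.char = "#",
                          col.names = c("id", "kind", "a", "b", "c", "d",
                                        "x", "y", "z"),
                          colClasses = c("integer", "character",
                                         rep("numeric", 7)))
  hdr <- sub("^# ", "", readLines(edges_file, n = 1))
  kv <- strsplit(strsplit(hdr, " ")[[1]], "=")
  cfg <- lapply(kv, function(p) {
    vals <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num))) vals else num
  })
  names(cfg) <- vapply(kv, `[`, character(1), 1)
  structure(list(neurons = nn, edges = e, config = cfg),
            class = "izhi_network")
}

#' Write a spike raster to tab-separated text
#'
#' One spike per row (`neuron_id`, `time_ms`), sorted by time, with a
#' '#'-prefixed header holding duration and network size.
#'
#' @param raster A `spike_raster`.
#' @param file Output path.
#' @export
write_raster <- function(raster, file) {
  ord <- order(raster$time_ms, raster$neuron)
  writeLines(c(sprintf("# duration_ms=%s n_neurons=%d",
                       .fmt_num(attr(raster, "duration_ms")),
                       attr(raster, "n_neurons")),
               "# neuron_id\ttime_ms",
               sprintf("%d\t%s", raster$neuron[ord],
                       .fmt_num(raster$time_ms[ord]))),
             file)
  invisible(file)
}

#' Read a spike raster written by [write_raster()]
#'
#' @param file Path written by [write_raster()].
#' @return A `spike_raster`.
#' @export
read_raster <- function(file) {
  hdr <- sub("^# ", "", readLines(file, n = 1))
  kv <- strsplit(strsplit(hdr, " ")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  d <- utils::read.table(file, sep = "\t", comment.char = "#",
                         col.names = c("neuron", "time_ms"))
  spike_raster(d$neuron, d$time_ms, as.numeric(vals[["duration_ms"]]),
               as.integer(as.numeric(vals[["n_neurons"]])))
}

#' Write a result table with a JSON-like run manifest header
#'
#' @param results An `izhi_results` table.
#' @param file Output TSV path.
#' @export
write_results <- function(results, file) {
  utils::write.table(results, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
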