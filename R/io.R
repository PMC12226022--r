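#' @name plastinet-io
#' @title Delimited-text readers and writers with JSON provenance
#'
#' @description
#' All artefacts are exchanged as plain text: networks as a whitespace
#' edge list (`pre post`) with a sidecar node table, synapse tables and
#' schedules as tab-separated tables, spike trains as two-column
#' `source_id time_ms` files, and plasticity traces as a wide table of
#' report times by synapse. Every writer emits a `<file>.json` sidecar
#' holding the seed/parameter provenance and package version. When the
#' `rhdf5` package is available, [write_trace_h5()] additionally stores a
#' trace as an HDF5 container with datasets `/report_times`, `/rho`,
#' `/U_SE`, `/g_AMPA`.
NULL

.write_provenance <- function(path, extra = list()) {
  prov <- c(list(package = "plastinet",
                 version = as.character(utils::packageVersion("plastinet"))),
            extra)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname plastinet-io
#' @param network a [gen_network()] object.
#' @param path output path stem; writers append suffixes.
#' @export
write_network <- function(network, path) {
  write.table(network$edges, paste0(path, "_edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(network$nodes, paste0(path, "_nodes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  .write_provenance(path, network$provenance)
  invisible(path)
}

#' @rdname plastinet-io
#' @export
read_network <- function(path) {
  nodes <- read.table(paste0(path, "_nodes.tsv"), header = TRUE)
  edges <- read.table(paste0(path, "_edges.tsv"), header = TRUE)
  if (any(edges$pre == edges$post)) stop("self-loops in edge list")
  if (!all(c(edges$pre, edges$post) %in% nodes$node_id))
    stop("edge endpoint not among declared nodes")
  if (anyDuplicated(edges)) stop("duplicate edges")
  structure(list(nodes = nodes, edges = edges, provenance = list()),
            class = "directed_network")
}

#' @rdname plastinet-io
#' @param syn_table a synapse table.
#' @export
write_synapse_table <- function(syn_table, path, extra = list()) {
  write.table(syn_table, paste0(path, ".tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  .write_provenance(path, extra)
  invisible(path)
}

#' @rdname plastinet-io
#' @export
read_synapse_table <- function(path) read.table(paste0(path, ".tsv"),
                                                header = TRUE)

#' @rdname plastinet-io
#' @param spikes named list of spike-time vectors, ms.
#' @export
write_spike_trains <- function(spikes, path, extra = list()) {
  df <- data.frame(source_id = rep(names(spikes), lengths(spikes)),
                   time_ms = unlist(spikes, use.names = FALSE))
  write.table(df, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  .write_provenance(path, extra)
  invisible(path)
}

#' @rdname plastinet-io
#' @export
read_spike_trains <- function(path) {
  df <- read.table(paste0(path, ".tsv"), header = TRUE,
                   colClasses = c("character", "numeric"))
  lapply(split(df$time_ms, df$source_id), .strictify)
}

#' @rdname plastinet-io
#' @param trace a `plasticity_trace` from [simulate_plasticity()].
#' @param extra extra provenance fields.
#' @export
write_trace <- function(trace, path, extra = list()) {
  for (what in c("rho", "U_SE", "g_AMPA")) {
    m <- trace[[what]]
    df <- data.frame(syn_id = trace$syn_id, m)
    names(df) <- c("syn_id", sprintf("t%g", trace$time_s))
    write.table(df, paste0(path, "_", what, ".tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  write.table(trace$final, paste0(path, "_final.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  .write_provenance(path, c(extra, list(report_times_s = trace$time_s)))
  invisible(path)
}

#' @rdname plastinet-io
#' @export
read_trace <- function(path) {
  rd <- function(what) {
    df <- read.table(paste0(path, "_", what, ".tsv"), header = TRUE,
                     check.names = FALSE)
    list(syn = df$syn_id, m = as.matrix(df[, -1, drop = FALSE]))
  }
  r <- rd("rho"); u <- rd("U_SE"); g <- rd("g_AMPA")
  structure(list(time_s = as.numeric(sub("^t", "", colnames(r$m))),
                 rho = unname(r$m), U_SE = unname(u$m), g_AMPA = unname(g$m),
                 syn_id = r$syn,
                 final = read.table(paste0(path, "_final.tsv"),
                                    header = TRUE)),
            class = "plasticity_trace")
}

#' @rdname plastinet-io
#' @export
write_trace_h5 <- function(trace, path, extra = list()) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 output")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(trace$time_s, path, "report_times")
  rhdf5::h5write(trace$rho, path, "rho")
  rhdf5::h5write(trace$U_SE, path, "U_SE")
  rhdf5::h5write(trace$g_AMPA, path, "g_AMPA")
  rhdf5::h5write(trace$syn_id, path, "syn_id")
  .write_provenance(path, extra)
  invisible(path)
}

#' @rdname plastinet-io
#' @export
read_trace_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 input")
  structure(list(time_s = as.numeric(rhdf5::h5read(path, "report_times")),
                 rho = rhdf5::h5read(path, "rho"),
                 U_SE = rhdf5::h5read(path, "U_SE"),
                 g_AMPA = rhdf5::h5read(path, "g_AMPA"),
                 syn_id = as.vector(rhdf5::h5read(path, "syn_id"))),
            class = "plasticity_trace")
}
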