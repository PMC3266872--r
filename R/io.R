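#' Read and write networks
#'
#' Two plain-text serializations are supported:
#' \describe{
#'   \item{`"tsv"`}{an edge list: a header line
#'     `# nodes=<n> inh_frac=<f> generator=<name> seed=<s>`, a second header
#'     line `# meta=<json>` carrying the full generator metadata, then one
#'     `pre<TAB>post` pair per line, 0-based. The TSV format assumes the
#'     prefix node layout (all excitatory ids before all inhibitory ids),
#'     which every generator in this package produces except custom kinds.}
#'   \item{`"graphml"`}{GraphML with node attribute `kind` in `{E, I}` and a
#'     graph attribute `meta` holding the generator metadata as JSON; carries
#'     arbitrary kind layouts.}
#' }
#' Writing then reading reproduces nodes, edges, kinds and generator metadata.
#'
#' @param net a [directed_network()].
#' @param path file path.
#' @param format `"tsv"` or `"graphml"`; default guessed from the extension.
#' @return `read_network` returns a [directed_network()]; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path, format = guess_format(path)) {
  validate_network(net)
  format <- match.arg(format, c("tsv", "graphml"))
  if (format == "tsv") {
    kinds <- net$node_kind
    inh_frac <- mean(kinds == "I")
    n_inh <- sum(kinds == "I")
    if (!identical(kinds, c(rep("E", net$n_nodes - n_inh), rep("I", n_inh)))) {
      stop("TSV edge lists require the prefix kind layout; use graphml instead")
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nodes=%d inh_frac=%s generator=%s seed=%s",
                       net$n_nodes, format(inh_frac, digits = 15),
                       net$gen_meta$generator %||% "manual",
                       format(net$gen_meta$seed %||% NA)), con)
    writeLines(paste0("# meta=", meta_to_json(net$gen_meta)), con)
    if (nrow(net$edges) > 0L) {
      writeLines(sprintf("%d\t%d", net$edges[, 1L] - 1L, net$edges[, 2L] - 1L), con)
    }
  } else {
    g <- as_igraph(net)
    g$meta <- meta_to_json(net$gen_meta)
    g$n_nodes <- net$n_nodes
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("tsv", "graphml"))
  if (format == "tsv") {
    lines <- readLines(path)
    if (length(lines) == 0L || !startsWith(lines[1L], "# nodes=")) {
      stop("line 1: missing '# nodes=' header")
    }
    hdr <- lines[1L]
    n <- as.integer(sub(".*nodes=(\\d+).*", "\\1", hdr))
    inh_frac <- as.numeric(sub(".*inh_frac=([0-9.eE+-]+).*", "\\1", hdr))
    meta <- list(generator = sub(".*generator=(\\S+).*", "\\1", hdr),
                 seed = sub(".*seed=(\\S+).*", "\\1", hdr))
    body_start <- 2L
    if (length(lines) >= 2L && startsWith(lines[2L], "# meta=")) {
      meta <- meta_from_json(sub("^# meta=", "", lines[2L]))
      body_start <- 3L
    }
    body <- lines[seq_along(lines) >= body_start]
    body <- body[nzchar(body)]
    if (length(body) > 0L) {
      parts <- strsplit(body, "\t", fixed = TRUE)
      bad <- which(lengths(parts) != 2L)
      if (length(bad) > 0L) {
        stop(sprintf("line %d: expected 'pre<TAB>post'", body_start - 1L + bad[1L]))
      }
      mat <- matrix(suppressWarnings(as.integer(unlist(parts))),
                    ncol = 2L, byrow = TRUE)
      if (anyNA(mat)) {
        bad <- which(is.na(mat[, 1L]) | is.na(mat[, 2L]))[1L]
        stop(sprintf("line %d: non-integer node id", body_start - 1L + bad))
      }
      edges <- mat + 1L
    } else {
      edges <- matrix(integer(0), ncol = 2L)
    }
    directed_network(n, edges, prefix_kinds(n, inh_frac), gen_meta = meta)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    n <- igraph::vcount(g)
    kinds <- igraph::V(g)$kind
    if (is.null(kinds)) stop("graphml file lacks the 'kind' node attribute")
    meta <- if (!is.null(g$meta)) meta_from_json(g$meta) else list(generator = "manual", seed = NA)
    edges <- igraph::as_edgelist(g, names = FALSE)
    directed_network(n, edges, kinds, gen_meta = meta)
  }
}

guess_format <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
}

meta_to_json <- function(meta) {
  as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"))
}

meta_from_json <- function(txt) {
  jsonlite::fromJSON(txt, simplifyMatrix = TRUE)
}

#' Read and write spike data
#'
#' The de facto spike-raster exchange format: two whitespace-separated columns
#' `time_ms neuron_id`, time-sorted, ids 1-based.
#'
#' @param spikes a [spike_data()] object.
#' @param path file path.
#' @param t_stop,n_nodes metadata needed to rebuild the object when reading
#'   (stored on a `#` header line when written by this package).
#' @return `read_spikes` returns a [spike_data()]; `write_spikes` returns
#'   `path` invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_stop=%s n_nodes=%d", format(spikes$t_stop), spikes$n_nodes), con)
  if (length(spikes$times) > 0L) {
    writeLines(sprintf("%.6f %d", spikes$times, spikes$nodes), con)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, t_stop = NULL, n_nodes = NULL) {
  lines <- readLines(path)
  if (length(lines) > 0L && startsWith(lines[1L], "#")) {
    t_stop <- t_stop %||% as.numeric(sub(".*t_stop=([0-9.eE+-]+).*", "\\1", lines[1L]))
    n_nodes <- n_nodes %||% as.integer(sub(".*n_nodes=(\\d+).*", "\\1", lines[1L]))
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L) {
    parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    times <- as.numeric(parts[, 1L]); nodes <- as.integer(parts[, 2L])
  } else {
    times <- numeric(0); nodes <- integer(0)
  }
  if (is.null(t_stop)) t_stop <- if (length(times)) max(times) else 0
  if (is.null(n_nodes)) n_nodes <- if (length(nodes)) max(nodes) else 0L
  spike_data(times, nodes, t_stop = t_stop, n_nodes = n_nodes)
}
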