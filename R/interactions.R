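#' Directed interaction set
#'
#' The shared container for directed networks: both the prior directed
#' protein-protein interaction (PPI) network and the constructed
#' condition-specific regulatory network are sets of ordered
#' (source, target) gene pairs. Self-loops are dropped (with a message
#' reporting the count) and duplicate edges collapsed; edges are stored
#' in a canonical sorted order so that downstream results are
#' deterministic regardless of input order.
#'
#' @param edges a two-column data.frame (or matrix) of character gene
#'   identifiers, columns `from` and `to`; or `NULL` for an empty set.
#' @param nodes optional character vector of additional isolated nodes to
#'   include beyond the endpoints of `edges`.
#'
#' @return an object of class `interaction_set` with elements
#'   `edges` (data.frame with columns `from`, `to`) and `nodes`
#'   (sorted character vector).
#' @export
interaction_set <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L)
      stop("edges must have two columns (from, to)")
    ed <- data.frame(from = as.character(edges[[1L]]),
                     to = as.character(edges[[2L]]),
                     stringsAsFactors = FALSE)
    if (anyNA(ed$from) || anyNA(ed$to) || any(!nzchar(ed$from)) ||
        any(!nzchar(ed$to)))
      stop("edge endpoints must be non-empty, non-missing identifiers")
    loops <- ed$from == ed$to
    if (any(loops)) {
      message("interaction_set: dropped ", sum(loops), " self-loop(s)")
      ed <- ed[!loops, , drop = FALSE]
    }
    ed <- unique(ed)
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    rownames(ed) <- NULL
  }
  all_nodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
  structure(list(edges = ed, nodes = all_nodes), class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set:", length(x$nodes), "nodes,",
      nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Number of edges / nodes of an interaction set
#' @param net an `interaction_set`
#' @return integer count
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

# internal: edge keys for fast membership tests
edge_keys <- function(edges) paste(edges$from, edges$to, sep = "\r")

#' Test membership of directed edges
#'
#' @param net an `interaction_set`
#' @param from,to character vectors (recycled) of source and target ids
#' @return logical vector
#' @export
has_edge <- function(net, from, to) {
  paste(from, to, sep = "\r") %in% edge_keys(net$edges)
}

#' Convert an interaction set to an igraph object
#'
#' Isolated nodes are preserved as vertices.
#'
#' @param net an `interaction_set`
#' @return a directed `igraph` graph
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Read a directed network from disk
#'
#' Supported formats: `edgelist` (TSV with a `source`/`target` header,
#' `#` comment lines ignored), `sif` (Cytoscape simple interaction format,
#' `source<TAB>relation<TAB>target`) and `graphml`. Self-loops are dropped
#' and duplicates collapsed on ingestion, as for [interaction_set()].
#'
#' @param path file to read
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`, or `"auto"`
#'   (guess from the file extension, default edgelist).
#' @return an `interaction_set`
#' @export
read_interactions <- function(path, format = c("auto", "edgelist", "sif",
                                               "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml",
                     "edgelist")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    return(interaction_set(data.frame(from = el[, 1], to = el[, 2],
                                      stringsAsFactors = FALSE),
                           nodes = igraph::V(g)$name))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(interaction_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (format == "sif") 3L else 2L
  # tolerate a header line on edge lists (extra columns beyond the first
  # two, e.g. correlation statistics, are ignored)
  if (format == "edgelist" && length(parts) > 0L &&
      tolower(parts[[1L]][1L]) %in% c("source", "from")) {
    parts <- parts[-1L]
    idx <- idx[-1L]
  }
  bad <- which(vapply(parts, length, integer(1)) < want)
  if (length(bad) > 0L)
    stop("malformed line ", idx[bad[1L]], " in ", path,
         ": expected at least ", want, " tab-separated fields")
  if (length(parts) == 0L) return(interaction_set())
  m <- t(vapply(parts, function(p) p[seq_len(want)], character(want)))
  interaction_set(data.frame(from = m[, 1L], to = m[, want],
                             stringsAsFactors = FALSE))
}

#' Write a directed network to disk
#'
#' @param net an `interaction_set`
#' @param path output file
#' @param format `"edgelist"` (TSV with `source`/`target` header),
#'   `"sif"` (relation type `regulates`) or `"graphml"`.
#' @return invisibly, `path`
#' @export
write_interactions <- function(net, path,
                               format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  body <- if (nrow(net$edges) == 0L) character() else switch(
    format,
    sif = paste(net$edges$from, "regulates", net$edges$to, sep = "\t"),
    edgelist = paste(net$edges$from, net$edges$to, sep = "\t"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    writeLines(body, path)
  } else {
    writeLines(c("source\ttarget", body), path)
  }
  invisible(path)
}
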