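#' Build a co-evolution network at a score cutoff
#'
#' An edge joins two positions when their correlated-mutation score is
#' defined and at least `cutoff` (inclusive). Nodes are the edge endpoints:
#' isolated positions are not part of the network, so the network size
#' counts co-evolving positions only. Connected components are ordered by
#' decreasing size, ties broken by smallest member position.
#'
#' @param mat a `cma_matrix`.
#' @param cutoff numeric score cutoff in \[0, 1\].
#' @return object of class `coevo_network`: list with `nodes` (sorted 3D
#'   numbers), `edges` (data frame `i`, `j`, `weight` with `i < j`),
#'   `components` (list of sorted integer vectors), `cutoff`, `method`.
#'   An empty network (no edge reaches the cutoff) is valid.
#' @export
build_network <- function(mat, cutoff) {
  stopifnot(inherits(mat, "cma_matrix"), cutoff >= 0, cutoff <= 1)
  idx <- which(upper.tri(mat$scores) & !is.na(mat$scores) &
                 mat$scores >= cutoff, arr.ind = TRUE)
  edges <- data.frame(i = mat$positions[idx[, 1L]],
                      j = mat$positions[idx[, 2L]],
                      weight = mat$scores[idx])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$i, edges$j)))
  comps <- list()
  if (length(nodes)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$i), to = as.character(edges$j)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes)))
    mem <- igraph::components(g)$membership
    comps <- split(as.integer(names(mem)), mem)
    comps <- lapply(comps, sort)
    ord <- order(-lengths(comps), vapply(comps, min, integer(1L)))
    comps <- unname(comps[ord])
  }
  structure(list(nodes = nodes, edges = edges, components = comps,
                 cutoff = cutoff, method = mat$method),
            class = "coevo_network")
}

#' @export
print.coevo_network <- function(x, ...) {
  cat(sprintf("Co-evolution network (%s, cutoff %.2f): %d positions, %d edges, %d components\n",
              x$method, x$cutoff, length(x$nodes), nrow(x$edges),
              length(x$components)))
  if (length(x$components))
    cat("  component sizes:", paste(lengths(x$components), collapse = ", "), "\n")
  invisible(x)
}

#' The main network (largest connected component)
#'
#' @param network a `coevo_network`.
#' @return sorted integer vector of the largest component's positions
#'   (ties: the component containing the lowest position), or `NULL` with a
#'   warning for an empty network.
#' @export
main_network <- function(network) {
  stopifnot(inherits(network, "coevo_network"))
  if (length(network$components) == 0L) {
    warning("empty network: no main network")
    return(NULL)
  }
  network$components[[1L]]
}

#' Hub of a network component
#'
#' The hub is the position of maximal degree (number of incident edges)
#' within a component; degree ties are broken by the lowest position
#' number.
#'
#' @param network a `coevo_network`.
#' @param component integer vector of positions (default: the main
#'   network).
#' @return integer position number of the hub.
#' @export
hub <- function(network, component = NULL) {
  stopifnot(inherits(network, "coevo_network"))
  if (is.null(component)) component <- main_network(network)
  if (is.null(component) || length(component) == 0L)
    cn_stop("cannot take the hub of an empty component", "input_error")
  e <- network$edges
  e <- e[e$i %in% component & e$j %in% component, , drop = FALSE]
  deg <- table(factor(c(e$i, e$j), levels = sort(component)))
  cand <- names(deg)[deg == max(deg)]
  as.integer(min(as.integer(cand)))
}

#' F-measure between two sets of network positions
#'
#' Precision is the fraction of `a` also in `b`, recall the fraction of `b`
#' also in `a`, and F their harmonic mean. Two empty sets are identical
#' (F = 1); exactly one empty set gives F = 0.
#'
#' @param a,b integer vectors of positions (or `coevo_network` objects,
#'   whose node sets are used).
#' @return object of class `network_comparison`: list with `precision`,
#'   `recall`, `f_measure`, `intersection`.
#' @export
f_measure <- function(a, b) {
  if (inherits(a, "coevo_network")) a <- a$nodes
  if (inherits(b, "coevo_network")) b <- b$nodes
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  ni <- length(intersect(a, b))
  if (length(a) == 0L && length(b) == 0L) {
    p <- r <- f <- 1
  } else if (length(a) == 0L || length(b) == 0L) {
    p <- r <- f <- 0
  } else {
    p <- ni / length(a)
    r <- ni / length(b)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  structure(list(precision = p, recall = r, f_measure = f,
                 intersection = ni),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("precision %.3f, recall %.3f, F-measure %.3f (|intersection| = %d)\n",
              x$precision, x$recall, x$f_measure, x$intersection))
  invisible(x)
}

#' Convert a network to an igraph graph
#'
#' @param network a `coevo_network`.
#' @return an `igraph` graph with vertex attribute `name` (position) and
#'   edge attribute `weight`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "coevo_network"))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(network$edges$i),
               to = as.character(network$edges$j),
               weight = network$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes)))
}

#' Export a network for graph viewers
#'
#' Writes either a cytoscape-style elements JSON document (node id,
#' degree, keyword flags; edge source/target/weight) or GraphML. An empty
#' network yields a valid empty document.
#'
#' @param network a `coevo_network`.
#' @param path output file path.
#' @param annotations optional `annotation_table` ([build_annotation_table()]);
#'   keywords annotated at a node are attached to it.
#' @param format `"json"` (cytoscape elements) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, annotations = NULL,
                         format = c("json", "graphml")) {
  stopifnot(inherits(network, "coevo_network"))
  format <- match.arg(format)
  kw <- function(p) {
    if (is.null(annotations)) return(character(0))
    sort(unique(annotations$keyword[annotations$d3_number == p]))
  }
  if (format == "json") {
    e <- network$edges
    deg <- table(factor(c(e$i, e$j), levels = network$nodes))
    nodes <- lapply(network$nodes, function(p) {
      list(data = list(id = as.character(p), degree = as.integer(deg[as.character(p)]),
                       keywords = as.list(kw(p))))
    })
    edges <- lapply(seq_len(nrow(e)), function(k) {
      list(data = list(source = as.character(e$i[k]),
                       target = as.character(e$j[k]),
                       weight = e$weight[k]))
    })
    doc <- list(elements = list(nodes = nodes, edges = edges),
                cutoff = network$cutoff, method = network$method)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    g <- as_igraph(network)
    if (!is.null(annotations) && length(network$nodes))
      g <- igraph::set_vertex_attr(
        g, "keywords",
        value = vapply(network$nodes,
                       function(p) paste(kw(p), collapse = ","),
                       character(1L)))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write a position/colour map for structure viewers
#'
#' One colour per connected component, as a plain TSV any structure viewer
#' can consume (columns `d3_number`, `component_index`, `hex_colour`).
#'
#' @param network a `coevo_network`.
#' @param path output path.
#' @return the data frame written, invisibly.
#' @export
write_colour_map <- function(network, path) {
  stopifnot(inherits(network, "coevo_network"))
  nc <- length(network$components)
  cols <- if (nc) hcl(h = seq(15, 375, length.out = nc + 1L)[seq_len(nc)],
                      c = 100, l = 65) else character(0)
  df <- do.call(rbind, lapply(seq_len(nc), function(k) {
    data.frame(d3_number = network$components[[k]], component_index = k,
               hex_colour = cols[k])
  }))
  if (is.null(df))
    df <- data.frame(d3_number = integer(0), component_index = integer(0),
                     hex_colour = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
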