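#' Write a network in Graph Modeling Language (GML)
#'
#' Nodes carry arbitrary scalar attributes; edges carry a numeric weight
#' (stored as attribute `mi` by default, matching the mutual-information
#' networks this package produces). The file re-parses to an identical
#' node/edge set via [read_gml()]. The GML `Creator` line is normalised so
#' that repeated runs produce byte-identical files.
#'
#' @param nodes Data frame with a `name` column plus optional scalar
#'   attribute columns.
#' @param edges Data frame with columns `from`, `to` (node names) and an
#'   optional numeric `weight` column.
#' @param path Output path.
#' @param weight_attr Name under which the edge weight is stored.
#' @return `path`, invisibly.
#' @export
write_gml <- function(nodes, edges, path, weight_attr = "mi") {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot("name" %in% names(nodes))
  if (anyDuplicated(nodes$name)) abort("Node names must be unique")
  if (nrow(edges)) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    unknown <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(unknown)) {
      abort(paste0("Edge endpoint(s) not among nodes: ",
                   paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  bare <- if (nrow(edges)) {
    as.data.frame(edges[, c("from", "to")])
  } else {
    data.frame(from = character(), to = character())
  }
  g <- igraph::graph_from_data_frame(bare, directed = FALSE, vertices = nodes)
  if ("weight" %in% names(edges) && nrow(edges)) {
    g <- igraph::set_edge_attr(g, weight_attr, value = edges$weight)
  }
  igraph::write_graph(g, path, format = "gml")
  # igraph stamps a timestamped Creator line; fix it for reproducibility
  lines <- readLines(path, warn = FALSE)
  lines[startsWith(lines, "Creator")] <- "Creator \"funcgsr\""
  writeLines(lines, path)
  invisible(path)
}

#' Read a GML network
#'
#' @param path Path to a GML file written by [write_gml()] (or any
#'   igraph-readable GML).
#' @return List with tibbles `nodes` (name + attributes) and `edges`
#'   (`from`, `to`, numeric attributes).
#' @export
read_gml <- function(path) {
  stopifnot(file.exists(path))
  g <- igraph::read_graph(path, format = "gml")
  nattr <- igraph::vertex_attr(g)
  nattr$id <- NULL
  nodes <- tibble::as_tibble(nattr)
  ends <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble::as_tibble(igraph::edge_attr(g))
  edges <- dplyr::bind_cols(
    tibble::tibble(from = as.character(ends[, 1]), to = as.character(ends[, 2])),
    edges
  )
  list(nodes = nodes, edges = edges)
}
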