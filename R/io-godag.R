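#' Construct a Gene Ontology DAG
#'
#' Holds `is_a` parent-child relations between ontology terms. Edges point
#' child -> parent. The graph must be acyclic and every edge endpoint must
#' be a known term.
#'
#' @param terms Data frame with columns `id` and `name` (one row per term).
#' @param edges Data frame with columns `child` and `parent` (term ids).
#' @return An object of class `go_dag`: list with tibbles `terms`, `edges`.
#' @export
go_dag <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "name") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id)) abort("Term ids must be unique")
  dangling <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(dangling)) {
    abort(paste0("Edge endpoint(s) not in term table: ",
                 paste(utils::head(dangling, 5), collapse = ", ")))
  }
  dag <- structure(list(terms = terms, edges = edges), class = "go_dag")
  g <- dag_graph(dag)
  if (nrow(edges) && !igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    abort(sprintf("Cycle detected involving edge %s -> %s", ends[1], ends[2]))
  }
  dag
}

# igraph view of the DAG, edges child -> parent; vertex names are term ids
# (the term's human-readable name rides along as `term_name`)
dag_graph <- function(dag) {
  vertices <- data.frame(id = dag$terms$id, term_name = dag$terms$name)
  igraph::graph_from_data_frame(
    as.data.frame(dag$edges[, c("child", "parent")]),
    directed = TRUE, vertices = vertices
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<GO DAG: %d terms, %d is_a edges>\n", nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Read a GO DAG from an OBO subset or an edge list
#'
#' Accepts either of two dialects: (1) OBO `[Term]` stanzas with `id:`,
#' `name:` and `is_a:` lines (other lines ignored; obsolete terms skipped),
#' or (2) a 2-column tab-separated child/parent edge list (with or without a
#' `child parent` header). The dialect is detected from the file content.
#' Only `is_a` relations are represented.
#'
#' @param path Path to the input file.
#' @return A [go_dag()].
#' @export
read_godag <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(trimws(lines), "[Term]"))) {
    read_godag_obo(lines)
  } else {
    read_godag_edges(lines)
  }
}

read_godag_obo <- function(lines) {
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  if (!length(starts)) abort("No [Term] stanzas found")
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0)
  children <- character(0); parents <- character(0)
  for (i in seq_along(starts)) {
    chunk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    if (any(grepl("^is_obsolete: *true", chunk))) next
    id <- sub("^id: *", "", grep("^id:", chunk, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", chunk, value = TRUE)[1])
    if (is.na(id)) abort(sprintf("[Term] stanza %d lacks an id", i))
    isa <- grep("^is_a:", chunk, value = TRUE)
    isa <- sub("^is_a: *", "", isa)
    isa <- trimws(sub("!.*$", "", isa))  # strip trailing "! name" comments
    ids <- c(ids, id); nms <- c(nms, if (is.na(nm)) id else nm)
    children <- c(children, rep(id, length(isa))); parents <- c(parents, isa)
  }
  # parents referenced but not declared as stanzas are dangling -> go_dag errors
  go_dag(tibble::tibble(id = ids, name = nms),
         tibble::tibble(child = children, parent = parents))
}

read_godag_edges <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad)) {
    abort(sprintf("Edge-list line %d does not have exactly 2 tab-separated fields", bad[1]))
  }
  child <- vapply(fields, `[[`, "", 1L)
  parent <- vapply(fields, `[[`, "", 2L)
  if (identical(tolower(c(child[1], parent[1])), c("child", "parent"))) {
    child <- child[-1]; parent <- parent[-1]
  }
  ids <- unique(c(child, parent))
  go_dag(tibble::tibble(id = ids, name = ids),
         tibble::tibble(child = child, parent = parent))
}

#' Write a GO DAG as a child/parent edge list
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_godag <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  readr::write_tsv(dag$edges[, c("child", "parent")], path, progress = FALSE)
  invisible(path)
}
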