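#' Summarise terms on the GO DAG by common ancestors
#'
#' Builds the ancestor closure of the input terms (the terms plus every
#' `is_a` ancestor), takes the connected components of the induced
#' subgraph as clusters — so offspring terms sharing ancestry fall
#' together — and labels each cluster by its minimal common ancestor(s):
#' the lowest node(s) of the closure that are ancestors-or-self of every
#' member term.
#'
#' @param terms Character vector of term ids to summarise (e.g. merged
#'   factor elements after id resolution). Ids absent from the DAG are
#'   reported and skipped.
#' @param dag A [go_dag()].
#' @return Tibble of class `go_cluster_summary` with one row per cluster:
#'   `cluster` (index), `ancestor_id`, `ancestor_name` (list-columns when
#'   several minimal common ancestors tie), `member_terms` (list-column of
#'   the input terms in the cluster), `n_members`.
#' @export
map_to_dag <- function(terms, dag) {
  stopifnot(inherits(dag, "go_dag"))
  terms <- unique(terms)
  if (!length(terms)) abort("Empty term list")
  unknown <- setdiff(terms, dag$terms$id)
  if (length(unknown)) {
    warn(paste0("Skipping term(s) absent from the DAG: ",
                paste(utils::head(unknown, 10), collapse = ", ")))
    terms <- setdiff(terms, unknown)
  }
  if (!length(terms)) abort("No input term resolves to the DAG")
  g <- dag_graph(dag)

  # ancestors-or-self of each input term (edges point child -> parent)
  anc <- lapply(terms, function(t) {
    names(igraph::subcomponent(g, t, mode = "out"))
  })
  closure <- unique(unlist(anc))
  sub <- igraph::induced_subgraph(g, closure)
  comp <- igraph::components(sub, mode = "weak")
  membership <- comp$membership[terms]

  name_of <- stats::setNames(dag$terms$name, dag$terms$id)
  out <- purrr::map_dfr(sort(unique(membership)), function(ci) {
    members <- terms[membership == ci]
    # common ancestors: closure nodes that are ancestor-or-self of every member
    common <- Reduce(intersect, anc[match(members, terms)])
    # minimal = lowest: drop any common ancestor that is a strict ancestor
    # of another common ancestor
    minimal <- common[vapply(common, function(a) {
      desc <- setdiff(names(igraph::subcomponent(g, a, mode = "in")), a)
      !any(common %in% desc)
    }, logical(1))]
    minimal <- sort(minimal)
    tibble::tibble(
      cluster = ci,
      ancestor_id = list(minimal),
      ancestor_name = list(unname(name_of[minimal])),
      member_terms = list(sort(members)),
      n_members = length(members)
    )
  })
  out$cluster <- seq_len(nrow(out))
  class(out) <- c("go_cluster_summary", class(out))
  out
}

#' Verify cluster members descend from their ancestors
#'
#' Checks, by DAG traversal, that every member of every cluster is the
#' labelled ancestor itself or one of its descendants.
#'
#' @param summary A [map_to_dag()] result.
#' @param dag The [go_dag()] it was computed on.
#' @return `TRUE` (invisibly) or an error naming the violation.
#' @export
check_cluster_summary <- function(summary, dag) {
  g <- dag_graph(dag)
  for (r in seq_len(nrow(summary))) {
    for (a in summary$ancestor_id[[r]]) {
      reach <- names(igraph::subcomponent(g, a, mode = "in"))  # descendants + self
      bad <- setdiff(summary$member_terms[[r]], reach)
      if (length(bad)) {
        abort(sprintf("Cluster %d: member(s) %s not descendants of ancestor %s",
                      r, paste(bad, collapse = ", "), a))
      }
    }
  }
  invisible(TRUE)
}
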