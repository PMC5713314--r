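#' k-nearest-neighbour mutual information (KSG estimator)
#'
#' First Kraskov-Stoegbauer-Grassberger estimator with max-norm
#' neighbourhoods, in nats, clipped below at zero. GSR vectors are
#' discrete-ish (pair-match fractions), so a deterministic seeded jitter of
#' magnitude `1e-10` breaks ties by default; with `jitter = FALSE`, tied
#' or constant inputs are an error (the estimator's neighbour counts
#' degenerate).
#'
#' @param x,y Numeric vectors of equal length `n >= 2k + 2`.
#' @param k Neighbour count (default 3, the estimator's canonical choice).
#' @param jitter Break ties with tiny seeded noise (default TRUE).
#' @param seed Seed for the jitter.
#' @return Estimated mutual information in nats (>= 0).
#' @export
knn_mutual_information <- function(x, y, k = 3L, jitter = TRUE, seed = 1L) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2L * k + 2L) abort("Need at least 2k + 2 observations")
  if (var(x) == 0 || var(y) == 0) abort("Constant input")
  if (!jitter && (anyDuplicated(x) || anyDuplicated(y))) {
    abort("Tied values degenerate the kNN estimator; enable `jitter`")
  }
  if (jitter) {
    set.seed(seed)
    x <- x + rnorm(length(x), 0, 1e-10)
    y <- y + rnorm(length(y), 0, 1e-10)
  }
  max(.ksg_mi_pair(as.numeric(x), as.numeric(y), as.integer(k)), 0)
}

# Pairwise KSG MI over the columns of X (samples x variables), with the
# same deterministic jitter contract as knn_mutual_information().
mi_matrix <- function(X, k = 3L, jitter = TRUE, seed = 1L) {
  X <- as.matrix(X)
  if (jitter) {
    set.seed(seed)
    X <- X + matrix(rnorm(length(X), 0, 1e-10), nrow(X), ncol(X))
  }
  M <- .ksg_mi_matrix(X, as.integer(k))
  dimnames(M) <- list(colnames(X), colnames(X))
  M
}

# Permutation-null MI floor: 95th percentile of MI between randomly chosen
# column pairs after permuting one column (destroying dependence).
mi_permutation_floor <- function(X, k = 3L, n_perm = 100L, prob = 0.95,
                                 seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  X <- X + matrix(rnorm(length(X), 0, 1e-10), nrow(X), ncol(X))
  null_mi <- vapply(seq_len(n_perm), function(b) {
    ij <- sample(ncol(X), 2L)
    max(.ksg_mi_pair(X[, ij[1]], sample(X[, ij[2]]), as.integer(k)), 0)
  }, numeric(1))
  quantile(null_mi, probs = prob, names = FALSE)
}

new_mi_network <- function(nodes, edges, dpi_tolerance, k_neighbors,
                           mi_floor = NA_real_) {
  structure(
    list(nodes = tibble::as_tibble(nodes), edges = tibble::as_tibble(edges),
         dpi_tolerance = dpi_tolerance, k_neighbors = k_neighbors,
         mi_floor = mi_floor),
    class = "mi_network"
  )
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("<MI network: %d nodes, %d edges (k = %s, DPI tolerance %.3g)>\n",
              nrow(x$nodes), nrow(x$edges),
              format(x$k_neighbors), x$dpi_tolerance))
  invisible(x)
}

#' @export
tidy.mi_network <- function(x, ...) x$edges

#' @export
glance.mi_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_deregulated = if ("deregulated" %in% names(x$nodes)) {
      sum(x$nodes$deregulated)
    } else NA_integer_,
    dpi_tolerance = x$dpi_tolerance, k_neighbors = x$k_neighbors,
    mi_floor = x$mi_floor
  )
}

#' ARACNE pruning of a mutual-information matrix
#'
#' Drops edges below `mi_floor`, then applies the data processing
#' inequality in its multiplicative form: within every triangle of
#' surviving edges, edge `(i, j)` is removed when
#' `mi(i, j) < min(mi(i, k), mi(j, k)) * (1 - dpi_tolerance)` — the
#' weakest edge of a triangle is presumed an indirect interaction. All
#' removals are decided against the original matrix and applied
#' simultaneously, so the result does not depend on edge order.
#'
#' @param mi_matrix Symmetric non-negative matrix of pairwise MI values
#'   (diagonal ignored), with variable names as dimnames.
#' @param dpi_tolerance Multiplicative DPI tolerance (default 0.05).
#' @param mi_floor Minimum MI for an edge to enter the network.
#' @return An `mi_network`: `nodes` (tibble with `name`), `edges` (tibble
#'   `from`, `to`, `mi`; one row per unordered pair, no self-edges).
#' @export
aracne_prune <- function(mi_matrix, dpi_tolerance = 0.05, mi_floor = 0) {
  M <- as.matrix(mi_matrix)
  if (nrow(M) != ncol(M) || !isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    abort("MI matrix must be symmetric")
  }
  if (any(M[upper.tri(M)] < 0)) abort("MI values must be non-negative")
  nm <- colnames(M) %||% paste0("V", seq_len(ncol(M)))
  dimnames(M) <- list(nm, nm)
  p <- ncol(M)
  present <- M >= mi_floor
  diag(present) <- FALSE

  keep_from <- character(0); keep_to <- character(0); keep_mi <- numeric(0)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (!present[i, j]) next
      ks <- which(present[i, ] & present[j, ])
      ks <- setdiff(ks, c(i, j))
      removed <- length(ks) > 0 &&
        any(M[i, j] < pmin(M[i, ks], M[j, ks]) * (1 - dpi_tolerance))
      if (!removed) {
        keep_from <- c(keep_from, nm[i]); keep_to <- c(keep_to, nm[j])
        keep_mi <- c(keep_mi, M[i, j])
      }
    }
  }
  new_mi_network(
    nodes = tibble::tibble(name = nm),
    edges = tibble::tibble(from = keep_from, to = keep_to, mi = keep_mi),
    dpi_tolerance = dpi_tolerance, k_neighbors = NA_integer_,
    mi_floor = mi_floor
  )
}

#' Function network of the merged carcinoma cohort
#'
#' Merges the named diseases' case and control datasets on their common
#' genes, re-learns rank templates from the pooled (tissue-shared)
#' controls, recomputes GSR indices, and reconstructs the function
#' interaction network: pairwise KSG mutual information between gene-set
#' GSR vectors across the merged case samples, an MI floor from a
#' permutation null (95th percentile over `n_perm` permuted pairs) unless
#' given, and ARACNE/DPI pruning. Nodes carry the deregulation flag
#' (BH-adjusted `q < alpha` on merged cases vs controls).
#'
#' @param cohorts Named list as returned by [gen_cohort()]: per disease, a
#'   list with `case` and `control` [expression_dataset()]s.
#' @param collection A [gene_set_collection()].
#' @param diseases Diseases to merge (default `c("CCC", "EC")`).
#' @param alpha Deregulation significance level on BH-adjusted values.
#' @param k KSG neighbour count.
#' @param dpi_tolerance Multiplicative DPI tolerance.
#' @param mi_floor Optional explicit MI floor (otherwise permutation null).
#' @param n_perm Permutations for the null floor.
#' @param min_common_genes Passed to [integrate_common_genes()].
#' @param cases_only Compute MI across merged case samples only (default),
#'   or across cases and controls.
#' @param seed Seed for jitter and the permutation null.
#' @return An `mi_network` whose nodes carry `deregulated` and `q`.
#' @export
merge_and_network <- function(cohorts, collection, diseases = c("CCC", "EC"),
                              alpha = 0.01, k = 3L, dpi_tolerance = 0.05,
                              mi_floor = NULL, n_perm = 100L,
                              min_common_genes = 100L, cases_only = TRUE,
                              seed = 1L) {
  missing <- setdiff(diseases, names(cohorts))
  if (length(missing)) {
    abort(paste0("Cohort list lacks disease(s): ", paste(missing, collapse = ", ")))
  }
  parts <- unlist(lapply(cohorts[diseases], function(co) list(co$case, co$control)),
                  recursive = FALSE)
  merged <- integrate_common_genes(parts, min_common_genes = min_common_genes)
  fome <- compute_functionome(merged, collection)

  lab <- fome$labels
  case <- lab$group == "case"
  ctrl <- lab$group == "control"
  p_raw <- vapply(seq_len(ncol(fome$gsr)), function(s) {
    mannwhitney_term(fome$gsr[case, s], fome$gsr[ctrl, s])$p
  }, numeric(1))
  q <- bh_adjust(p_raw)

  rows <- if (cases_only) case else case | ctrl
  X <- fome$gsr[rows, , drop = FALSE]
  M <- mi_matrix(X, k = k, seed = seed)
  if (is.null(mi_floor)) {
    mi_floor <- mi_permutation_floor(X, k = k, n_perm = n_perm, seed = seed)
  }
  net <- aracne_prune(M, dpi_tolerance = dpi_tolerance, mi_floor = mi_floor)
  net$nodes$deregulated <- q < alpha
  net$nodes$q <- q
  net$k_neighbors <- as.integer(k)
  net$mi_floor <- mi_floor
  net
}

#' Largest connected component of an MI network
#'
#' @param network An `mi_network`.
#' @return The `mi_network` restricted to the component with most nodes;
#'   ties broken towards the component containing the lexicographically
#'   smallest node name.
#' @export
largest_subnetwork <- function(network) {
  stopifnot(inherits(network, "mi_network"))
  if (!nrow(network$nodes)) abort("Empty network")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes["name"]
  )
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: pick the component holding the lexicographically smallest member
    firsts <- vapply(best, function(ci) {
      min(names(comp$membership)[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)[1]]
  }
  keep <- names(comp$membership)[comp$membership == best]
  out <- network
  out$nodes <- network$nodes[network$nodes$name %in% keep, ]
  out$edges <- network$edges[network$edges$from %in% keep &
                               network$edges$to %in% keep, ]
  out
}

#' Write an MI network as GML
#'
#' @param network An `mi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_gml <- function(network, path) {
  stopifnot(inherits(network, "mi_network"))
  nodes <- network$nodes
  if ("deregulated" %in% names(nodes)) {
    nodes$deregulated <- as.integer(nodes$deregulated)
  }
  edges <- network$edges
  names(edges)[names(edges) == "mi"] <- "weight"
  write_gml(nodes, edges, path, weight_attr = "mi")
}
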