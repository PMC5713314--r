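#' Integrate datasets on their common genes
#'
#' Restricts each dataset to the gene intersection and concatenates samples,
#' the cross-platform integration step the rank-based statistic makes cheap
#' (orderings transfer across platforms where expression levels do not). An
#' integration whose common-gene count falls below `min_common_genes` is
#' rejected, naming the dataset whose inclusion first pushed the
#' intersection under the threshold; the default mirrors the 8000-gene
#' dataset-selection rule used with genome-scale platforms (synthetic runs
#' pass a scaled value).
#'
#' @param datasets List of [expression_dataset()] objects (length >= 1).
#' @param min_common_genes Minimum acceptable size of the gene intersection.
#' @return A single [expression_dataset()] on the common genes. A single
#'   input dataset is returned unchanged.
#' @export
integrate_common_genes <- function(datasets, min_common_genes = 8000L) {
  if (inherits(datasets, "gsr_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "gsr_dataset")))
  if (length(datasets) == 1L) return(datasets[[1]])
  common <- rownames(datasets[[1]]$values)
  for (i in seq_along(datasets)[-1]) {
    common <- intersect(common, rownames(datasets[[i]]$values))
    if (!length(common)) abort("Gene intersection is empty")
    if (length(common) < min_common_genes) {
      abort(sprintf(
        "Integrating dataset %d ('%s') leaves %d common genes (< %d)",
        i, datasets[[i]]$platform_id, length(common), min_common_genes
      ))
    }
  }
  common <- sort(common)
  values <- do.call(cbind, lapply(datasets, function(d) d$values[common, , drop = FALSE]))
  labels <- dplyr::bind_rows(lapply(datasets, function(d) d$labels))
  if (anyDuplicated(labels$sample_id)) {
    # shared controls may appear in several datasets; keep one copy
    keep <- !duplicated(labels$sample_id)
    values <- values[, keep, drop = FALSE]
    labels <- labels[keep, ]
  }
  expression_dataset(
    values, labels,
    platform_id = paste(unique(vapply(datasets, `[[`, "", "platform_id")), collapse = "+")
  )
}

#' Prune gene sets against the available genes
#'
#' Restricts every set to the genes measured on the platform and drops sets
#' with fewer than `min_set_size` surviving members (pairwise orderings are
#' undefined below two genes). The number of dropped sets is reported; this
#' is how a nominal collection shrinks slightly from platform to platform.
#'
#' @param collection A [gene_set_collection()].
#' @param available_genes Character vector of measured gene symbols.
#' @param min_set_size Minimum surviving set size (>= 2).
#' @return A pruned [gene_set_collection()].
#' @export
prune_gene_sets <- function(collection, available_genes, min_set_size = 2L) {
  stopifnot(inherits(collection, "gsr_collection"), min_set_size >= 2L)
  pruned <- lapply(collection$genes, intersect, available_genes)
  keep <- lengths(pruned) >= min_set_size
  if (!any(keep)) {
    warn("No gene set survives pruning; returning an empty collection")
  }
  dropped <- collection$set_name[!keep]
  if (length(dropped)) {
    inform(sprintf("Dropped %d/%d gene set(s) below size %d after pruning",
                   length(dropped), nrow(collection), min_set_size))
  }
  out <- gene_set_collection(collection$set_name[keep],
                             pruned[keep],
                             collection$description[keep])
  attr(out, "dropped") <- dropped
  out
}

# Per-pair majority template over control columns.
# X: genes x controls submatrix (rows already restricted/sorted).
# Returns list(bits = logical P, n_tie_votes = int). bits[p] TRUE means the
# majority ordering has gene_i > gene_j for pair p (i < j in row order);
# an even split is resolved towards the lexicographically earlier gene.
pair_majority <- function(X) {
  G <- nrow(X)
  pr <- combn_pairs(G)
  votes <- rowSums(X[pr$i, , drop = FALSE] > X[pr$j, , drop = FALSE])
  n <- ncol(X)
  ties <- sum(2L * votes == n)
  list(bits = (2 * votes >= n), n_tie_votes = ties)
}

combn_pairs <- function(G) {
  idx <- utils::combn(G, 2L)
  list(i = idx[1, ], j = idx[2, ])
}

#' Learn a rank template from control samples
#'
#' For every unordered gene pair in the set, the template records which
#' ordering holds in the majority of control samples (the most common
#' expression ordering, learned pair by pair). Within-sample ties count as
#' satisfying neither ordering; an even control split is resolved towards
#' the lexicographically earlier gene and reported.
#'
#' @param controls An [expression_dataset()] of control samples.
#' @param genes Character vector of the set's member symbols.
#' @param set_name Name carried into the template.
#' @return Object of class `rank_template`: list with `set_name`, `genes`
#'   (sorted, platform-restricted), `bits` (logical, one per pair `i < j`,
#'   `TRUE` = gene_i above gene_j), `n_tie_votes`.
#' @export
build_rank_template <- function(controls, genes, set_name = "") {
  stopifnot(inherits(controls, "gsr_dataset"), ncol(controls$values) >= 1L)
  present <- sort(intersect(genes, rownames(controls$values)))
  if (length(present) < 2L) {
    abort(sprintf("Gene set '%s' has %d member(s) on this platform; need >= 2",
                  set_name, length(present)))
  }
  maj <- pair_majority(controls$values[present, , drop = FALSE])
  if (maj$n_tie_votes > 0) {
    inform(sprintf("Template '%s': %d pair vote(s) tied; resolved lexicographically",
                   set_name, maj$n_tie_votes))
  }
  structure(
    list(set_name = set_name, genes = present, bits = maj$bits,
         n_tie_votes = maj$n_tie_votes),
    class = "rank_template"
  )
}

#' @export
print.rank_template <- function(x, ...) {
  cat(sprintf("<rank template '%s': %d genes, %d pairs>\n",
              x$set_name, length(x$genes), length(x$bits)))
  invisible(x)
}

#' Score one profile against a rank template
#'
#' The gene set regularity (GSR) index of a sample: the fraction of the
#' template's gene pairs whose ordering the sample reproduces (ties
#' reproduce neither ordering). 1 means the set's ordering is fully
#' conserved relative to the control majority; 0 means fully reversed.
#'
#' @param profile Named numeric vector of expression values covering the
#'   template's genes.
#' @param template A [build_rank_template()] result.
#' @return A number in `[0, 1]`.
#' @export
rank_matching_score <- function(profile, template) {
  stopifnot(inherits(template, "rank_template"))
  missing <- setdiff(template$genes, names(profile))
  if (length(missing)) {
    abort(paste0("Profile lacks gene(s): ", paste(missing, collapse = ", ")))
  }
  x <- profile[template$genes]
  pr <- combn_pairs(length(template$genes))
  up <- x[pr$i] > x[pr$j]
  down <- x[pr$j] > x[pr$i]
  mean(ifelse(template$bits, up, down))
}

#' Compute the functionome of a cohort
#'
#' Converts an expression dataset into the samples x gene-sets matrix of
#' GSR indices. Templates are learned from the cohort's control samples
#' only; indices are then computed for every sample, cases and controls
#' alike. Sets are pruned against the platform first.
#'
#' @param cohort An [expression_dataset()] containing control samples (and
#'   usually cases).
#' @param collection A [gene_set_collection()].
#' @param min_set_size Minimum surviving set size passed to
#'   [prune_gene_sets()].
#' @param keep_templates Store the learned templates on the result.
#' @return Object of class `functionome`: list with `gsr` (samples x sets
#'   matrix in `[0, 1]`), `labels` (tibble, one row per sample), and
#'   optionally `templates`.
#' @export
compute_functionome <- function(cohort, collection, min_set_size = 2L,
                                keep_templates = FALSE) {
  stopifnot(inherits(cohort, "gsr_dataset"), inherits(collection, "gsr_collection"))
  ctrl <- cohort$labels$group == "control"
  if (!any(ctrl)) abort("No control samples to learn templates from")
  surv <- suppressMessages(
    prune_gene_sets(collection, rownames(cohort$values), min_set_size)
  )
  if (!nrow(surv)) abort("No gene set survives pruning")
  n <- ncol(cohort$values)
  gsr <- matrix(NA_real_, nrow = n, ncol = nrow(surv),
                dimnames = list(colnames(cohort$values), surv$set_name))
  templates <- if (keep_templates) vector("list", nrow(surv)) else NULL
  for (s in seq_len(nrow(surv))) {
    genes <- sort(surv$genes[[s]])
    X <- cohort$values[genes, , drop = FALSE]
    pr <- combn_pairs(length(genes))
    up <- X[pr$i, , drop = FALSE] > X[pr$j, , drop = FALSE]
    down <- X[pr$j, , drop = FALSE] > X[pr$i, , drop = FALSE]
    votes <- rowSums(up[, ctrl, drop = FALSE])
    bits <- (2 * votes >= sum(ctrl))
    match <- up
    match[!bits, ] <- down[!bits, , drop = FALSE]
    gsr[, s] <- colMeans(match)
    if (keep_templates) {
      templates[[s]] <- structure(
        list(set_name = surv$set_name[s], genes = genes, bits = bits,
             n_tie_votes = sum(2L * votes == sum(ctrl))),
        class = "rank_template"
      )
    }
  }
  structure(
    list(gsr = gsr, labels = cohort$labels,
         templates = if (keep_templates) stats::setNames(templates, surv$set_name)),
    class = "functionome"
  )
}

#' @export
print.functionome <- function(x, ...) {
  cat(sprintf("<functionome: %d samples x %d gene sets; diseases: %s>\n",
              nrow(x$gsr), ncol(x$gsr),
              paste(unique(x$labels$disease), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.functionome <- function(x, ...) {
  dplyr::bind_cols(x$labels, tibble::as_tibble(x$gsr, .name_repair = "minimal"))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Combine functionomes on their common gene sets
#'
#' Row-binds samples from several functionomes restricted to the gene sets
#' they share; used to compare diseases whose platforms retained slightly
#' different set universes.
#'
#' @param fomes List of [compute_functionome()] results.
#' @return A `functionome` over the common sets.
#' @export
combine_functionomes <- function(fomes) {
  stopifnot(length(fomes) >= 1L, all(vapply(fomes, inherits, TRUE, "functionome")))
  common <- Reduce(intersect, lapply(fomes, function(f) colnames(f$gsr)))
  if (!length(common)) abort("Functionomes share no gene sets")
  gsr <- do.call(rbind, lapply(fomes, function(f) f$gsr[, common, drop = FALSE]))
  labels <- dplyr::bind_rows(lapply(fomes, `[[`, "labels"))
  keep <- !duplicated(labels$sample_id)
  structure(list(gsr = gsr[keep, , drop = FALSE], labels = labels[keep, ],
                 templates = NULL),
            class = "functionome")
}
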