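#' Run the whole functionome pipeline on a synthetic design
#'
#' Chains every stage through on-disk artifacts under `out_dir`:
#' simulation (expression/label TSVs, GMT, GO edge list), GSR functionomes
#' (TSV per disease), deregulation tables (TSV) with the top-fraction Venn
#' partition (JSON), binary and multiclass classification reports (JSON),
#' per-disease factor analysis (loadings TSV, assignment JSON) with the
#' GO-tree cluster summary (JSON), progressive-deregulation records and
#' ranking paths (TSV), and the merged-carcinoma MI network (GML). All
#' randomness derives from `seed`, so identical calls produce
#' byte-identical artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param design A [simulation_design()]; defaults to
#'   [default_eaoc_design()] under `seed`.
#' @param seed Integer master seed.
#' @param alpha Significance level on BH-adjusted values.
#' @param top_fraction Fraction for the deregulation set operations.
#' @param cv_repeats Cross-validation repeats for the classification stage.
#' @param network_diseases Diseases merged for the network stage.
#' @return Invisibly, a list with the main in-memory results and the
#'   artifact paths.
#' @export
run_pipeline <- function(out_dir, design = NULL, seed = 1L, alpha = 0.01,
                         top_fraction = 0.10, cv_repeats = 10L,
                         network_diseases = c("CCC", "EC")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  design <- design %||% default_eaoc_design(seed)
  path <- function(...) file.path(out_dir, paste0(...))
  wjson <- function(x, file) {
    jsonlite::write_json(x, path(file), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  # -- simulate ------------------------------------------------------------
  collection <- gen_gene_sets(design$n_genes, design$n_sets,
                              design$set_size_range, seed = seed)
  cohorts <- gen_cohort(design, collection, seed = seed)
  dag <- gen_godag(collection$set_name, branching = 2L, seed = seed + 1L)
  write_gmt(collection, path("gene_sets.gmt"))
  write_godag(dag, path("go_dag.tsv"))
  for (d in names(cohorts)) {
    merged <- integrate_common_genes(list(cohorts[[d]]$case, cohorts[[d]]$control),
                                     min_common_genes = 2L)
    write_expression(merged, path("expression_", d, ".tsv"),
                     path("labels_", d, ".tsv"))
  }

  # -- gsr -----------------------------------------------------------------
  fomes <- lapply(names(cohorts), function(d) {
    merged <- integrate_common_genes(list(cohorts[[d]]$case, cohorts[[d]]$control),
                                     min_common_genes = 2L)
    fo <- compute_functionome(merged, collection)
    readr::write_tsv(as_tibble(fo), path("functionome_", d, ".tsv"),
                     progress = FALSE)
    fo
  })
  names(fomes) <- names(cohorts)
  readr::write_tsv(group_summary(combine_functionomes(fomes)),
                   path("group_summary.tsv"), progress = FALSE)

  # -- deregulation --------------------------------------------------------
  tables <- lapply(names(fomes), function(d) {
    tb <- dereg_table(fomes[[d]], d, alpha = alpha)
    readr::write_tsv(tb, path("deregulation_", d, ".tsv"), progress = FALSE)
    tb
  })
  names(tables) <- names(fomes)
  top <- lapply(tables, select_top_fraction, fraction = top_fraction)
  venn_top <- venn_partition(top)
  wjson(list(regions = purrr::pmap(venn_top, function(region, count, names) {
    list(region = region, count = count, names = names)
  })), "venn_top_fraction.json")

  # -- classification ------------------------------------------------------
  reports <- list()
  for (d in names(fomes)) {
    lab <- fomes[[d]]$labels
    rep_d <- crossval_binary(fomes[[d]]$gsr, lab$group, seed = seed + 10L,
                             n_repeats = cv_repeats)
    reports[[d]] <- rep_d
  }
  combined <- combine_functionomes(fomes)
  y_multi <- ifelse(combined$labels$group == "case",
                    combined$labels$disease, "control")
  reports$multiclass <- crossval_multiclass(combined$gsr, y_multi,
                                            seed = seed + 11L,
                                            n_repeats = cv_repeats)
  wjson(lapply(reports, function(r) as.list(glance(r))), "classification.json")
  clustering <- cluster_group_profiles(combined)
  wjson(list(leaf_order = clustering$hclust$labels[clustering$hclust$order],
             heights = clustering$hclust$height,
             first_merge = as.list(first_merge(clustering))),
        "clustering.json")

  # -- factor analysis + GO tree -------------------------------------------
  elements <- list()
  for (d in names(fomes)) {
    sig <- tables[[d]]$set_name[tables[[d]]$significant]
    sig <- intersect(sig, colnames(fomes[[d]]$gsr))
    if (length(sig) < 3L) {
      inform(sprintf("Skipping factor analysis for %s: %d significant term(s)",
                     d, length(sig)))
      elements[[d]] <- sig
      next
    }
    X <- fomes[[d]]$gsr[, sig, drop = FALSE]
    nf <- max(1L, min(as.integer(parallel_analysis(X, seed = seed + 20L)),
                      length(sig) - 1L))
    sol <- promax_rotate(fit_efa(X, nf))
    asg <- assign_elements(sol)
    readr::write_tsv(tidy(sol), path("efa_loadings_", d, ".tsv"),
                     progress = FALSE)
    wjson(list(n_factors = nf,
               assignment = split(asg$assignment$term, asg$assignment$factor),
               unassigned = asg$unassigned),
          paste0("efa_assignment_", d, ".json"))
    elements[[d]] <- unique(asg$assignment$term)
  }
  venn_efa <- venn_partition(elements)
  coexisting <- venn_efa$names[[which(venn_efa$region == paste(names(elements), collapse = "&"))]]
  merged_elements <- sort(unique(unlist(elements)))
  if (length(merged_elements)) {
    clusters <- suppressWarnings(map_to_dag(merged_elements, dag))
    wjson(purrr::pmap(clusters, function(cluster, ancestor_id, ancestor_name,
                                         member_terms, n_members) {
      list(cluster = cluster, ancestor_id = ancestor_id,
           ancestor_name = ancestor_name, member_terms = member_terms)
    }), "go_clusters.json")
  }

  # -- progression ---------------------------------------------------------
  records <- progressive_filter(tables$ES, tables$CCC, tables$EC)
  readr::write_tsv(records, path("progression_records.tsv"), progress = FALSE)
  core <- if (length(coexisting) && any(records$passed)) {
    core_intersection(coexisting, records)
  } else character(0)
  wjson(list(coexisting = coexisting, core = core), "core_functions.json")
  if (any(records$passed)) {
    readr::write_tsv(ranking_paths(records), path("ranking_paths.tsv"),
                     progress = FALSE)
  }

  # -- network -------------------------------------------------------------
  net <- merge_and_network(cohorts, collection, diseases = network_diseases,
                           alpha = alpha, min_common_genes = 2L,
                           seed = seed + 30L)
  sub <- largest_subnetwork(net)
  write_network_gml(sub, path("network_largest.gml"))
  wjson(as.list(glance(sub)), "network_summary.json")

  invisible(list(
    design = design, collection = collection, functionomes = fomes,
    tables = tables, venn_top = venn_top, reports = reports,
    clustering = clustering, elements = elements, coexisting = coexisting,
    records = records, core = core, network = net, largest = sub,
    out_dir = out_dir
  ))
}
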