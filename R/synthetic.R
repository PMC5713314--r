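#' Define a synthetic cohort design
#'
#' A simulation design describes the cohorts the generator produces: the
#' gene/set universe, per-disease sample sizes and tissues, which sets are
#' deregulated in which disease and how strongly, per-disease platform gene
#' coverage, and the measurement noise level.
#'
#' Deregulation is modelled as within-set ordering scrambling: for a case
#' sample, a random `ceiling(f * set size)` subset of the set's member
#' values is permuted among themselves. Because the GSR statistic consumes
#' orderings only, this is the direct effect-size dial: `f = 0` leaves
#' cases exchangeable with controls and `f = 1` randomises the whole
#' within-set ordering.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_sets Number of gene sets.
#' @param set_size_range Length-2 integer vector `(min, max)` of set sizes.
#' @param diseases Data frame with columns `name`, `n_case`, `n_control`,
#'   `tissue`.
#' @param deregulation_plan Data frame with columns `disease`, `set_name`,
#'   `scramble_fraction` (in `[0, 1]`).
#' @param platform_plan Data frame with columns `disease`, `coverage`
#'   (fraction of the gene universe measured on that disease's platform,
#'   in `(0, 1]`).
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise around each gene's baseline.
#' @param severity_range Range of the per-case-sample severity multiplier
#'   applied to every scramble fraction of that sample (one draw per
#'   sample, shared across its deregulated sets, so co-deregulated terms
#'   co-vary). `c(1, 1)` disables it.
#' @param seed Integer seed; every generator consuming the design is
#'   reproducible under it.
#'
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes, n_sets, set_size_range, diseases,
                              deregulation_plan, platform_plan,
                              noise_sd = 0.5, severity_range = c(0.6, 1.4),
                              seed = 1L) {
  diseases <- tibble::as_tibble(diseases)
  deregulation_plan <- tibble::as_tibble(deregulation_plan)
  platform_plan <- tibble::as_tibble(platform_plan)
  stopifnot(
    length(set_size_range) == 2L, set_size_range[1] >= 2L,
    set_size_range[2] >= set_size_range[1],
    all(c("name", "n_case", "n_control", "tissue") %in% names(diseases)),
    all(c("disease", "set_name", "scramble_fraction") %in% names(deregulation_plan)),
    all(c("disease", "coverage") %in% names(platform_plan))
  )
  if (set_size_range[2] > n_genes) {
    abort("Maximum set size exceeds the gene universe")
  }
  f <- deregulation_plan$scramble_fraction
  if (any(f < 0 | f > 1)) abort("scramble_fraction must lie in [0, 1]")
  cov <- platform_plan$coverage
  if (any(cov <= 0 | cov > 1)) abort("coverage must lie in (0, 1]")
  if (length(severity_range) != 2L || any(severity_range <= 0) ||
      severity_range[1] > severity_range[2]) {
    abort("severity_range must be an increasing pair of positive numbers")
  }
  if (!all(deregulation_plan$disease %in% diseases$name)) {
    abort("deregulation_plan names a disease not in `diseases`")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
      set_size_range = as.integer(set_size_range), diseases = diseases,
      deregulation_plan = deregulation_plan, platform_plan = platform_plan,
      noise_sd = noise_sd, severity_range = as.numeric(severity_range),
      seed = as.integer(seed)
    ),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "<simulation design: %d genes, %d sets (size %d-%d), %d diseases, noise_sd %.3g, seed %d>\n",
    x$n_genes, x$n_sets, x$set_size_range[1], x$set_size_range[2],
    nrow(x$diseases), x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Generate a random gene set collection
#'
#' Draws `n_sets` sets uniformly without replacement from a synthetic gene
#' universe `G0001 ... G<n_genes>`; set sizes are uniform on
#' `set_size_range`.
#'
#' @inheritParams simulation_design
#' @param seed Integer seed; identical seeds give identical collections.
#' @return A [gene_set_collection()] with sets named `SET_001 ...`.
#' @export
gen_gene_sets <- function(n_genes, n_sets, set_size_range, seed = 1L) {
  if (set_size_range[2] > n_genes) {
    abort("Maximum set size exceeds the gene universe")
  }
  stopifnot(set_size_range[1] >= 2L)
  universe <- sprintf("G%04d", seq_len(n_genes))
  set.seed(seed)
  sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
  gene_set_collection(
    set_name = sprintf("SET_%03d", seq_len(n_sets)),
    description = sprintf("synthetic gene set of size %d", sizes),
    genes = lapply(sizes, function(s) sample(universe, s))
  )
}

#' Generate tissue-matched case/control cohorts
#'
#' Every gene receives one baseline level (fixing a canonical within-set
#' ordering shared by all samples); a sample's value is baseline plus
#' Gaussian noise. Case samples additionally have their deregulated sets
#' scrambled per the design's plan, degrading rank conservation
#' monotonically in the scramble fraction. Each disease's platform measures
#' a random `coverage` fraction of the gene universe, forcing common-gene
#' integration downstream.
#'
#' @param design A [simulation_design()].
#' @param collection A [gene_set_collection()] over the design's universe.
#' @param seed Integer seed; defaults to the design's.
#' @return Named list, one element per disease: `list(case =, control =)`
#'   of [expression_dataset()] objects.
#' @export
gen_cohort <- function(design, collection, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(collection, "gsr_collection"))
  missing_sets <- setdiff(design$deregulation_plan$set_name, collection$set_name)
  if (length(missing_sets)) {
    abort(paste0("deregulation_plan names unknown set(s): ",
                 paste(utils::head(missing_sets, 5), collapse = ", ")))
  }
  set.seed(seed)
  universe <- sprintf("G%04d", seq_len(design$n_genes))
  mu <- stats::setNames(rnorm(design$n_genes, 0, 1), universe)
  members <- stats::setNames(collection$genes, collection$set_name)

  out <- list()
  for (d in seq_len(nrow(design$diseases))) {
    di <- design$diseases[d, ]
    cov <- design$platform_plan$coverage[design$platform_plan$disease == di$name]
    if (!length(cov)) cov <- 1
    keep <- sort(sample(universe, ceiling(cov * design$n_genes)))
    plan <- design$deregulation_plan[design$deregulation_plan$disease == di$name, ]

    draw <- function(n, prefix, group) {
      vals <- matrix(
        rnorm(length(keep) * n, mean = mu[keep], sd = design$noise_sd),
        nrow = length(keep), ncol = n,
        dimnames = list(keep, sprintf("%s_%s_%03d", di$name, prefix, seq_len(n)))
      )
      if (group == "case" && nrow(plan)) {
        # per-sample severity: one multiplier shared by all of a sample's
        # deregulated sets, so co-deregulated terms co-vary across cases
        sr <- design$severity_range %||% c(1, 1)
        severity <- runif(n, sr[1], sr[2])
        for (j in seq_len(n)) {
          for (p in seq_len(nrow(plan))) {
            mem <- intersect(members[[plan$set_name[p]]], keep)
            f_eff <- min(1, plan$scramble_fraction[p] * severity[j])
            m <- ceiling(f_eff * length(mem))
            if (m >= 2L) {
              sub <- sample(mem, m)
              vals[sub, j] <- vals[sample(sub), j]
            }
          }
        }
      }
      labels <- tibble::tibble(
        sample_id = colnames(vals), group = group,
        disease = di$name, tissue = di$tissue
      )
      expression_dataset(vals, labels, platform_id = paste0("sim_", di$name))
    }
    out[[di$name]] <- list(
      case = draw(di$n_case, "case", "case"),
      control = draw(di$n_control, "ctrl", "control")
    )
  }
  out
}

#' Generate a random rooted GO-like DAG
#'
#' The first term is the root; every later term receives between 1 and
#' `branching` parents drawn among earlier terms, so the result is acyclic
#' by construction (and a tree when `branching = 1`).
#'
#' @param terms Character vector of term ids (order fixes the topology
#'   layering).
#' @param branching Maximum number of parents per term (>= 1).
#' @param seed Integer seed.
#' @return A [go_dag()].
#' @export
gen_godag <- function(terms, branching = 2L, seed = 1L) {
  if (!length(terms)) abort("Empty term list")
  stopifnot(branching >= 1L)
  set.seed(seed)
  child <- character(0); parent <- character(0)
  for (i in seq_along(terms)[-1]) {
    k <- sample(seq_len(min(branching, i - 1L)), 1L)
    pa <- sample(terms[seq_len(i - 1L)], k)
    child <- c(child, rep(terms[i], k)); parent <- c(parent, pa)
  }
  go_dag(tibble::tibble(id = terms, name = terms),
         tibble::tibble(child = child, parent = parent))
}

#' Default three-disease study design
#'
#' Mirrors a tissue-matched endometriosis / clear cell carcinoma /
#' endometrioid carcinoma (ES / CCC / EC) study at desk scale: 2000 genes,
#' 200 gene sets of 5-15 members, 40 cases and 100 controls per disease,
#' ES on endometrium and CCC/EC on ovary. The deregulated-set architecture
#' has 20 ES-only sets (scramble fraction 0.7), 8 CCC-and-EC shared sets
#' (0.6), and 6 ES-CCC-EC "transformation" sets with graded strength (0.4
#' in ES, 0.85 in CCC/EC) so progressive-deregulation ranking is
#' exercisable: the stronger ES-only sets occupy the top ES ranks, leaving
#' the transformation sets room to move upward in rank from ES into the
#' carcinomas while staying significant in all three diseases. Per-disease
#' platforms cover 92/88/85% of the gene universe.
#'
#' @param seed Integer seed stored in the design.
#' @return A [simulation_design()].
#' @export
default_eaoc_design <- function(seed = 1L) {
  es_only <- sprintf("SET_%03d", 1:20)
  shared <- sprintf("SET_%03d", 21:28)
  transf <- sprintf("SET_%03d", 29:34)
  plan <- dplyr::bind_rows(
    tibble::tibble(disease = "ES", set_name = es_only, scramble_fraction = 0.7),
    tibble::tibble(disease = "CCC", set_name = shared, scramble_fraction = 0.6),
    tibble::tibble(disease = "EC", set_name = shared, scramble_fraction = 0.6),
    tibble::tibble(disease = "ES", set_name = transf, scramble_fraction = 0.4),
    tibble::tibble(disease = "CCC", set_name = transf, scramble_fraction = 0.85),
    tibble::tibble(disease = "EC", set_name = transf, scramble_fraction = 0.85)
  )
  simulation_design(
    n_genes = 2000L, n_sets = 200L, set_size_range = c(5L, 15L),
    diseases = tibble::tibble(
      name = c("ES", "CCC", "EC"),
      n_case = 40L, n_control = 100L,
      tissue = c("endometrium", "ovary", "ovary")
    ),
    deregulation_plan = plan,
    platform_plan = tibble::tibble(
      disease = c("ES", "CCC", "EC"), coverage = c(0.92, 0.88, 0.85)
    ),
    noise_sd = 0.5, seed = seed
  )
}

#' Deregulated sets of a design, by disease
#'
#' Convenience accessor used when checking recovery of the planted
#' architecture.
#'
#' @param design A [simulation_design()].
#' @return Tibble with columns `disease`, `set_name`, `scramble_fraction`.
#' @export
planted_sets <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  design$deregulation_plan
}
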