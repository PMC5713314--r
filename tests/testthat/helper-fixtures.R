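# Shared fixtures and independent oracles for the test suite.

# Small expression dataset from a plain matrix (all one tissue).
make_dataset <- function(values, group = rep("control", ncol(values)),
                         disease = "D", tissue = "t", platform = "p1") {
  labels <- tibble::tibble(
    sample_id = colnames(values), group = group,
    disease = disease, tissue = tissue
  )
  expression_dataset(values, labels, platform_id = platform)
}

# Noise-free dataset whose every sample follows the baseline ordering
# mu; rownames G1..Gn, colnames s1..sk.
constant_dataset <- function(mu, n_samples, group = "control", ...) {
  values <- matrix(rep(mu, n_samples), ncol = n_samples,
                   dimnames = list(names(mu), paste0("s", seq_len(n_samples))))
  make_dataset(values, group = rep(group, n_samples), ...)
}

# Desk-scale version of the default three-disease design, for tests that
# only need the architecture, not the full cohort size.
small_design <- function(seed = 1L) {
  es_only <- sprintf("SET_%03d", 1:6)
  shared <- sprintf("SET_%03d", 7:10)
  transf <- sprintf("SET_%03d", 11:13)
  plan <- dplyr::bind_rows(
    tibble::tibble(disease = "ES", set_name = es_only, scramble_fraction = 0.7),
    tibble::tibble(disease = "CCC", set_name = shared, scramble_fraction = 0.6),
    tibble::tibble(disease = "EC", set_name = shared, scramble_fraction = 0.6),
    tibble::tibble(disease = "ES", set_name = transf, scramble_fraction = 0.4),
    tibble::tibble(disease = "CCC", set_name = transf, scramble_fraction = 0.85),
    tibble::tibble(disease = "EC", set_name = transf, scramble_fraction = 0.85)
  )
  simulation_design(
    n_genes = 400L, n_sets = 50L, set_size_range = c(5L, 10L),
    diseases = tibble::tibble(
      name = c("ES", "CCC", "EC"), n_case = 20L, n_control = 30L,
      tissue = c("endometrium", "ovary", "ovary")
    ),
    deregulation_plan = plan,
    platform_plan = tibble::tibble(
      disease = c("ES", "CCC", "EC"), coverage = c(0.95, 0.9, 0.88)
    ),
    noise_sd = 0.5, seed = seed
  )
}

# One disease's functionome from a cohort list.
fome_of <- function(cohorts, disease, collection) {
  merged <- integrate_common_genes(
    list(cohorts[[disease]]$case, cohorts[[disease]]$control),
    min_common_genes = 2L
  )
  compute_functionome(merged, collection)
}

# Brute-force GSR oracle: explicit loop over all gene pairs, independent
# of the package's vectorised path.
gsr_brute <- function(profile, template) {
  g <- template$genes
  hits <- 0L
  total <- 0L
  idx <- 0L
  for (i in seq_along(g)[-length(g)]) {
    for (j in (i + 1L):length(g)) {
      idx <- idx + 1L
      total <- total + 1L
      xi <- profile[[g[i]]]; xj <- profile[[g[j]]]
      ok <- if (template$bits[idx]) xi > xj else xj > xi
      hits <- hits + as.integer(ok)
    }
  }
  hits / total
}

# Step-up BH oracle written from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pairwise concordance AUC oracle (explicit double loop).
auc_brute <- function(scores, is_positive) {
  pos <- scores[is_positive]; neg <- scores[!is_positive]
  conc <- 0
  for (a in pos) for (b in neg) {
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  conc / (length(pos) * length(neg))
}

# Minimal deregulation table for progression fixtures.
fake_dereg_table <- function(set_name, rank, q, mean_case,
                             significant = q < 0.01) {
  out <- tibble::tibble(
    set_name = set_name, U = NA_real_, p = q, q = q, rank = rank,
    significant = significant, mean_case = mean_case,
    sd_case = NA_real_, mean_control = NA_real_, sd_control = NA_real_,
    delta = NA_real_
  )
  class(out) <- c("dereg_table", class(out))
  out
}
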