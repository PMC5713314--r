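test_that("generators are deterministic under a seed", {
  c1 <- gen_gene_sets(100, 10, c(5, 15), seed = 1)
  c2 <- gen_gene_sets(100, 10, c(5, 15), seed = 1)
  expect_identical(c1, c2)
  expect_false(identical(c1, gen_gene_sets(100, 10, c(5, 15), seed = 2)))

  d <- small_design()
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  expect_identical(gen_cohort(d, col, seed = 3), gen_cohort(d, col, seed = 3))

  dag1 <- gen_godag(letters[1:10], branching = 2, seed = 5)
  expect_identical(dag1, gen_godag(letters[1:10], branching = 2, seed = 5))
})

test_that("gene set generation respects the universe and feasibility", {
  expect_error(gen_gene_sets(100, 5, c(50, 200)), "exceeds the gene universe")
  col <- gen_gene_sets(100, 20, c(5, 15), seed = 1)
  universe <- sprintf("G%04d", 1:100)
  expect_true(all(unlist(col$genes) %in% universe))
  expect_true(all(lengths(col$genes) >= 5 & lengths(col$genes) <= 15))
})

test_that("design validation rejects out-of-range fractions and unknown names", {
  d <- small_design()
  expect_error(
    simulation_design(100, 10, c(5, 10), d$diseases,
                      tibble::tibble(disease = "ES", set_name = "S",
                                     scramble_fraction = 1.2),
                      d$platform_plan),
    "scramble_fraction"
  )
  expect_error(
    simulation_design(100, 10, c(5, 10), d$diseases, d$deregulation_plan[0, ],
                      tibble::tibble(disease = "ES", coverage = 0)),
    "coverage"
  )
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, 1)
  bad <- d
  bad$deregulation_plan$set_name[1] <- "SET_999"
  expect_error(gen_cohort(bad, col), "SET_999")
})

test_that("null cohorts (f = 0) leave cases exchangeable with controls", {
  d <- small_design()
  d$deregulation_plan <- d$deregulation_plan[0, ]
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  co <- gen_cohort(d, col, seed = 1)
  fo <- fome_of(co, "ES", col)
  case_mean <- mean(fo$gsr[fo$labels$group == "case", ])
  ctrl_mean <- mean(fo$gsr[fo$labels$group == "control", ])
  expect_lt(abs(case_mean - ctrl_mean), 0.02)
})

test_that("full scrambling of a noise-free set gives mean GSR near 1/2", {
  # with f = 1 and noise_sd = 0, a case's within-set ordering is a uniform
  # random permutation; the expected pair-match fraction is 0.5
  plan <- tibble::tibble(disease = "D", set_name = "SET_001",
                         scramble_fraction = 1)
  d <- simulation_design(
    n_genes = 300L, n_sets = 5L, set_size_range = c(8L, 10L),
    diseases = tibble::tibble(name = "D", n_case = 300L, n_control = 20L,
                              tissue = "t"),
    deregulation_plan = plan,
    platform_plan = tibble::tibble(disease = "D", coverage = 1),
    noise_sd = 0, severity_range = c(1, 1), seed = 1
  )
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  co <- gen_cohort(d, col, seed = 1)
  fo <- fome_of(co, "D", col)
  case_gsr <- fo$gsr[fo$labels$group == "case", "SET_001"]
  expect_lt(abs(mean(case_gsr) - 0.5), 0.03)
  # sets sharing no gene with the scrambled one stay perfectly regular
  untouched <- col$set_name[!vapply(col$genes, function(g) {
    any(g %in% col$genes[[1]])
  }, logical(1))]
  expect_gt(length(untouched), 0L)
  expect_equal(unname(as.vector(fo$gsr[, untouched])),
               rep(1, nrow(fo$gsr) * length(untouched)))
})

test_that("expected GSR of a scrambled set is non-increasing in f", {
  means <- vapply(c(0, 0.25, 0.5, 1), function(f) {
    plan <- if (f == 0) {
      tibble::tibble(disease = character(), set_name = character(),
                     scramble_fraction = numeric())
    } else {
      tibble::tibble(disease = "D", set_name = "SET_001", scramble_fraction = f)
    }
    d <- simulation_design(
      n_genes = 60L, n_sets = 3L, set_size_range = c(10L, 12L),
      diseases = tibble::tibble(name = "D", n_case = 220L, n_control = 30L,
                                tissue = "t"),
      deregulation_plan = plan,
      platform_plan = tibble::tibble(disease = "D", coverage = 1),
      noise_sd = 0.3, severity_range = c(1, 1), seed = 1
    )
    col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 2)
    co <- gen_cohort(d, col, seed = 7)
    fo <- fome_of(co, "D", col)
    mean(fo$gsr[fo$labels$group == "case", "SET_001"])
  }, numeric(1))
  expect_true(all(diff(means) < 0.01))  # non-increasing up to MC noise
  expect_lt(means[4], means[1] - 0.2)   # and substantially decreasing overall
})

test_that("random GO DAGs are acyclic; branching 1 yields a tree", {
  dag <- gen_godag(paste0("T", 1:7), branching = 1, seed = 3)
  expect_equal(nrow(dag$edges), 6L)
  for (s in 1:5) {
    dag_s <- gen_godag(paste0("T", 1:12), branching = 3, seed = s)
    g <- igraph::graph_from_data_frame(dag_s$edges, directed = TRUE)
    expect_true(igraph::is_dag(g))
  }
  expect_error(gen_godag(character(0)), "Empty")
})

test_that("the default study design validates and encodes the overlap architecture", {
  d <- default_eaoc_design(seed = 42)
  expect_s3_class(d, "simulation_design")
  plan <- planted_sets(d)
  by_disease <- split(plan$set_name, plan$disease)
  transf <- Reduce(intersect, by_disease)
  expect_length(transf, 6L)
  # CCC and EC share everything they deregulate; ES overlaps only in the
  # transformation sets
  expect_setequal(by_disease$CCC, by_disease$EC)
  expect_setequal(intersect(by_disease$ES, by_disease$CCC), transf)
  # graded strength: ES milder than the carcinomas on the shared sets
  f_es <- plan$scramble_fraction[plan$disease == "ES" & plan$set_name %in% transf]
  f_cc <- plan$scramble_fraction[plan$disease == "CCC" & plan$set_name %in% transf]
  expect_true(all(f_es < f_cc))
})

test_that("platform coverage restricts genes per disease", {
  d <- small_design()
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  co <- gen_cohort(d, col, seed = 1)
  n_es <- nrow(co$ES$case$values)
  n_ec <- nrow(co$EC$case$values)
  expect_equal(n_es, ceiling(0.95 * d$n_genes))
  expect_equal(n_ec, ceiling(0.88 * d$n_genes))
  expect_identical(rownames(co$ES$case$values), rownames(co$ES$control$values))
})
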