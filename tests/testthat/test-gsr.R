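test_that("common-gene integration intersects, thresholds, and passes singletons", {
  v1 <- matrix(rnorm(10), 5, 2, dimnames = list(c("A", "B", "C", "D", "E"),
                                                c("s1", "s2")))
  v2 <- matrix(rnorm(10), 5, 2, dimnames = list(c("C", "D", "E", "F", "G"),
                                                c("s3", "s4")))
  d1 <- make_dataset(v1); d2 <- make_dataset(v2, platform = "p2")
  out <- integrate_common_genes(list(d1, d2), min_common_genes = 2)
  expect_setequal(rownames(out$values), c("C", "D", "E"))
  expect_equal(ncol(out$values), 4L)
  expect_error(integrate_common_genes(list(d1, d2), min_common_genes = 4),
               "'p2'.*3 common genes")
  expect_identical(integrate_common_genes(list(d1)), d1)
})

test_that("set pruning restricts members and drops undersized sets", {
  col <- gene_set_collection(c("S1", "S2", "S3"),
                             list(c("X", "Y", "Z"), c("X", "W"), c("P", "Q")))
  out <- suppressMessages(prune_gene_sets(col, c("X", "Y", "W")))
  expect_equal(out$set_name, c("S1", "S2"))
  expect_equal(out$genes[[1]], c("X", "Y"))  # Z unavailable
  expect_equal(attr(out, "dropped"), "S3")
  expect_warning(empty <- prune_gene_sets(col, character(0)), "No gene set")
  expect_equal(nrow(suppressMessages(empty)), 0L)
})

test_that("template majority vote follows the worked example and handles ties", {
  # controls' (A, B) values: (5,3), (4,5), (1,2) -> A>B in 1 of 3 -> B above A
  vals <- matrix(c(5, 3, 4, 5, 1, 2), nrow = 2,
                 dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  tpl <- build_rank_template(make_dataset(vals), c("A", "B"), "S")
  expect_false(tpl$bits)  # bit says B > A
  expect_equal(rank_matching_score(c(A = 1, B = 9), tpl), 1)
  expect_equal(rank_matching_score(c(A = 9, B = 1), tpl), 0)

  # unanimous ordering A > B > C reproduces itself
  mu <- c(A = 3, B = 2, C = 1)
  tpl3 <- build_rank_template(constant_dataset(mu, 3), names(mu), "S3")
  expect_equal(rank_matching_score(mu, tpl3), 1)

  # 1-1 split resolved deterministically towards the earlier gene, reported
  vals2 <- matrix(c(1, 2, 2, 1), nrow = 2,
                  dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_message(tpl2 <- build_rank_template(make_dataset(vals2), c("A", "B")),
                 "tied")
  expect_true(tpl2$bits)  # A > B by the lexicographic rule
  expect_equal(tpl2$n_tie_votes, 1L)
})

test_that("rank matching score matches hand-enumerated pairs and handles ties", {
  mu <- c(A = 3, B = 2, C = 1)  # template A > B > C
  tpl <- build_rank_template(constant_dataset(mu, 2), names(mu))
  # sample B=5, A=3, C=1: (A,B) flipped, (A,C) ok, (B,C) ok -> 2/3
  expect_equal(rank_matching_score(c(A = 3, B = 5, C = 1), tpl), 2 / 3)
  # full reversal -> 0
  expect_equal(rank_matching_score(c(A = 1, B = 2, C = 3), tpl), 0)
  # a within-sample tie satisfies neither ordering
  expect_equal(rank_matching_score(c(A = 2, B = 2, C = 1), tpl), 2 / 3)
  expect_error(rank_matching_score(c(A = 1, B = 2), tpl), "lacks gene")
})

test_that("vectorised GSR equals the brute-force pair oracle on random instances", {
  set.seed(11)
  for (rep in 1:300) {
    G <- sample(3:8, 1)
    genes <- paste0("g", sample(100, G))
    n_ctrl <- sample(2:6, 1)
    ctrl_vals <- matrix(rnorm(G * n_ctrl), G,
                        dimnames = list(genes, paste0("c", 1:n_ctrl)))
    tpl <- build_rank_template(make_dataset(ctrl_vals), genes)
    profile <- stats::setNames(rnorm(G), genes)
    expect_equal(rank_matching_score(profile, tpl), gsr_brute(profile, tpl))
  }
})

test_that("one adjacent transposition costs exactly one pair", {
  for (G in c(3, 5, 8)) {
    mu <- stats::setNames(seq(G, 1), paste0("g", 1:G))
    tpl <- build_rank_template(constant_dataset(mu, 2), names(mu))
    expect_equal(rank_matching_score(mu, tpl), 1)
    swapped <- mu
    k <- sample(G - 1, 1)
    swapped[c(k, k + 1)] <- swapped[c(k + 1, k)]
    expect_equal(rank_matching_score(swapped, tpl), 1 - 1 / choose(G, 2))
  }
})

test_that("the per-pair majority template maximises mean control matching", {
  set.seed(21)
  G <- 6
  genes <- paste0("g", 1:G)
  ctrl_vals <- matrix(rnorm(G * 9), G, dimnames = list(genes, paste0("c", 1:9)))
  ctrl <- make_dataset(ctrl_vals)
  tpl <- build_rank_template(ctrl, genes)
  score_with_bits <- function(bits) {
    alt <- tpl; alt$bits <- bits
    mean(apply(ctrl_vals, 2, rank_matching_score, template = alt))
  }
  best <- score_with_bits(tpl$bits)
  for (r in 1:100) {
    expect_gte(best, score_with_bits(sample(c(TRUE, FALSE), length(tpl$bits),
                                            replace = TRUE)))
  }
})

test_that("functionome entries live in [0, 1] and noise-free controls score 1", {
  mu <- stats::setNames(rnorm(30), paste0("G", 1:30))
  col <- gene_set_collection(c("S1", "S2"),
                             list(names(mu)[1:6], names(mu)[10:17]))
  ds <- constant_dataset(mu, 5)
  fo <- compute_functionome(ds, col)
  expect_equal(unname(as.vector(fo$gsr)), rep(1, 10))

  d <- small_design()
  colr <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  co <- gen_cohort(d, colr, seed = 2)
  fo2 <- fome_of(co, "CCC", colr)
  expect_true(all(fo2$gsr >= 0 & fo2$gsr <= 1))
  expect_error(compute_functionome(co$CCC$case, colr), "No control samples")
})

test_that("scrambled sets score lower in cases than controls", {
  d <- small_design()
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  hits <- vapply(1:10, function(s) {
    co <- gen_cohort(d, col, seed = s)
    fo <- fome_of(co, "CCC", col)
    scr <- planted_sets(d)
    scr <- scr$set_name[scr$disease == "CCC"]
    scr <- intersect(scr, colnames(fo$gsr))
    case <- fo$labels$group == "case"
    all(colMeans(fo$gsr[case, scr, drop = FALSE]) <
          colMeans(fo$gsr[!case, scr, drop = FALSE]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("functionome templates learned from controls are reusable", {
  d <- small_design()
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  co <- gen_cohort(d, col, seed = 1)
  merged <- integrate_common_genes(list(co$ES$case, co$ES$control), 2)
  fo <- compute_functionome(merged, col, keep_templates = TRUE)
  tpl <- fo$templates[[1]]
  s <- rank_matching_score(merged$values[, 1], tpl)
  expect_equal(unname(fo$gsr[1, tpl$set_name]), s)
})

test_that("functionome combination restricts to shared sets", {
  d <- small_design()
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  co <- gen_cohort(d, col, seed = 1)
  fo <- lapply(c(ES = "ES", CCC = "CCC"), fome_of, cohorts = co, collection = col)
  both <- combine_functionomes(fo)
  expect_true(all(colnames(both$gsr) %in%
                    intersect(colnames(fo$ES$gsr), colnames(fo$CCC$gsr))))
  expect_equal(nrow(both$gsr), nrow(fo$ES$gsr) + nrow(fo$CCC$gsr))
})
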