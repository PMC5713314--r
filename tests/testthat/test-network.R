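test_that("KSG estimates match the Gaussian closed form", {
  set.seed(31)
  for (rho in c(0.5, 0.9)) {
    x <- rnorm(2000)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(2000)
    mi <- knn_mutual_information(x, y, k = 3)
    expect_lt(abs(mi - (-0.5 * log(1 - rho^2))), 0.1)
  }
})

test_that("KSG estimates vanish for independent variables", {
  set.seed(32)
  mis <- vapply(1:10, function(s) {
    knn_mutual_information(rnorm(2000), rnorm(2000), seed = s)
  }, numeric(1))
  expect_lte(median(mis), 0.05)
})

test_that("KSG input contracts: ties, constants, length", {
  x <- rep(c(1, 2, 3, 4), 10)
  expect_error(knn_mutual_information(x, x + 1, jitter = FALSE), "Tied")
  expect_error(knn_mutual_information(rep(1, 40), rnorm(40)), "Constant")
  expect_error(knn_mutual_information(rnorm(10), rnorm(11)), "equal length")
  expect_error(knn_mutual_information(rnorm(6), rnorm(6), k = 3), "2k")
  # y = x with jitter: large but finite
  z <- rnorm(100)
  mi <- knn_mutual_information(z, z, jitter = TRUE)
  expect_true(is.finite(mi))
  expect_gt(mi, 2)
})

test_that("KSG agrees with an independent plug-in histogram estimator", {
  # binned plug-in MI on large Gaussian samples (fine enough bins to keep
  # the discretisation bias below the comparison tolerance)
  plugin_mi <- function(x, y, bins = 20) {
    cx <- cut(x, bins); cy <- cut(y, bins)
    pxy <- table(cx, cy) / length(x)
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  }
  set.seed(33)
  for (rho in c(0.3, 0.6, 0.9)) {
    x <- rnorm(5000)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(5000)
    ksg <- knn_mutual_information(x, y)
    expect_lt(abs(ksg - plugin_mi(x, y)), 0.1)
  }
})

test_that("DPI pruning removes the weak chain edge but spares triangles", {
  M <- matrix(c(0, 0.8, 0.3,
                0.8, 0, 0.7,
                0.3, 0.7, 0), 3, 3,
              dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  net <- aracne_prune(M, dpi_tolerance = 0.05, mi_floor = 0.01)
  kept <- paste(net$edges$from, net$edges$to)
  expect_setequal(kept, c("X Y", "Y Z"))  # X-Z: 0.3 < 0.7 * 0.95

  # equilateral triangle survives within tolerance
  E <- matrix(0.5, 3, 3); diag(E) <- 0
  dimnames(E) <- list(letters[1:3], letters[1:3])
  expect_equal(nrow(aracne_prune(E, 0.05, 0.01)$edges), 3L)

  # floor above the maximum leaves no edges
  expect_equal(nrow(aracne_prune(M, 0.05, mi_floor = 1)$edges), 0L)
  expect_error(aracne_prune(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("DPI removals are justified, sparing each triangle's strongest edge", {
  # an edge is removed only when it is the strict weakest of some floored
  # triangle (so the removal can never strike that triangle's strongest
  # edge); the globally strongest edge therefore always survives
  set.seed(34)
  for (r in 1:10) {
    p <- 8
    M <- matrix(0, p, p)
    M[upper.tri(M)] <- runif(p * (p - 1) / 2)
    M <- M + t(M)
    dimnames(M) <- list(paste0("v", 1:p), paste0("v", 1:p))
    floor_val <- 0.2
    tol <- 0.05
    net <- aracne_prune(M, tol, floor_val)
    kept <- matrix(FALSE, p, p, dimnames = dimnames(M))
    for (e in seq_len(nrow(net$edges))) {
      kept[net$edges$from[e], net$edges$to[e]] <- TRUE
      kept[net$edges$to[e], net$edges$from[e]] <- TRUE
    }
    floored <- M >= floor_val; diag(floored) <- FALSE
    # pruned edges are a subset of floored edges (which are a subset of
    # all pairs)
    expect_true(all(!kept | floored))
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      if (!floored[i, j]) next
      ks <- setdiff(which(floored[i, ] & floored[j, ]), c(i, j))
      justified <- length(ks) > 0 &&
        any(M[i, j] < pmin(M[i, ks], M[j, ks]) * (1 - tol))
      expect_equal(!kept[i, j], justified)
    }
    # globally strongest floored edge always survives
    strongest <- which(M == max(M[floored]) & floored, arr.ind = TRUE)[1, ]
    expect_true(kept[strongest[1], strongest[2]])
  }

  # in an isolated triangle the strongest edge is never removed
  for (r in 1:20) {
    tri <- sort(runif(3), decreasing = TRUE)
    M3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    M3[upper.tri(M3)] <- tri
    M3 <- M3 + t(M3)
    net3 <- aracne_prune(M3, 0.05, 0)
    kept3 <- paste(net3$edges$from, net3$edges$to)
    expect_true("a b" %in% kept3)  # (a, b) holds the largest value
  }
})

test_that("largest component extraction follows size then the name tie-break", {
  net <- funcgsr:::new_mi_network(
    nodes = tibble::tibble(name = c("A", "B", "C", "D", "E")),
    edges = tibble::tibble(from = c("A", "B", "D"), to = c("B", "C", "E"),
                           mi = c(1, 1, 1)),
    dpi_tolerance = 0.05, k_neighbors = 3L
  )
  big <- largest_subnetwork(net)
  expect_setequal(big$nodes$name, c("A", "B", "C"))

  tie <- funcgsr:::new_mi_network(
    nodes = tibble::tibble(name = c("C", "D", "A", "B")),
    edges = tibble::tibble(from = c("C", "A"), to = c("D", "B"), mi = c(1, 1)),
    dpi_tolerance = 0.05, k_neighbors = 3L
  )
  expect_setequal(largest_subnetwork(tie)$nodes$name, c("A", "B"))

  empty <- funcgsr:::new_mi_network(tibble::tibble(name = character()),
                                    tibble::tibble(from = character(),
                                                   to = character(),
                                                   mi = numeric()),
                                    0.05, 3L)
  expect_error(largest_subnetwork(empty), "Empty")
})

test_that("the merged-cohort network links co-deregulated terms, not null pairs", {
  d <- small_design()
  col <- gen_gene_sets(d$n_genes, d$n_sets, d$set_size_range, seed = 1)
  plan <- planted_sets(d)
  dereg_cc <- unique(plan$set_name[plan$disease %in% c("CCC", "EC")])
  linked <- c(); null_deg <- c(); flags_ok <- c()
  for (s in 1:3) {
    co <- gen_cohort(d, col, seed = s)
    net <- merge_and_network(co, col, diseases = c("CCC", "EC"),
                             min_common_genes = 2, seed = s)
    expect_true(all(net$edges$from != net$edges$to))
    touched <- c(net$edges$from, net$edges$to)
    linked <- c(linked, dereg_cc %in% touched)
    null_sets <- setdiff(net$nodes$name, plan$set_name)
    null_edges <- net$edges$from %in% null_sets & net$edges$to %in% null_sets
    null_deg <- c(null_deg, sum(null_edges) / choose(length(null_sets), 2))
    flags_ok <- c(flags_ok,
                  mean(net$nodes$deregulated[net$nodes$name %in% dereg_cc]))
  }
  expect_gte(mean(linked), 0.8)        # co-deregulated terms in the network
  # independent unscrambled pairs stay unconnected after floor + DPI
  expect_gte(1 - mean(null_deg), 0.8)
  expect_gte(mean(flags_ok), 0.8)      # deregulation flags on planted sets
  d0 <- small_design()
  col0 <- gen_gene_sets(d0$n_genes, d0$n_sets, d0$set_size_range, seed = 1)
  co0 <- gen_cohort(d0, col0, seed = 1)
  expect_error(merge_and_network(co0, col0, diseases = c("CCC", "nope")),
               "nope")
})

test_that("MI networks round-trip through GML with attributes", {
  net <- funcgsr:::new_mi_network(
    nodes = tibble::tibble(name = c("S1", "S2"), deregulated = c(TRUE, FALSE),
                           q = c(0.001, 0.7)),
    edges = tibble::tibble(from = "S1", to = "S2", mi = 0.42),
    dpi_tolerance = 0.05, k_neighbors = 3L
  )
  path <- withr::local_tempfile(fileext = ".gml")
  write_network_gml(net, path)
  back <- read_gml(path)
  expect_setequal(back$nodes$name, c("S1", "S2"))
  expect_equal(sort(back$nodes$deregulated), c(0, 1))
  expect_equal(back$edges$mi, 0.42)
})
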