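#' Mann-Whitney U test for one gene set's GSR indices
#'
#' Two-sided case-vs-control comparison of one term's GSR values. The p
#' value is exact (full enumeration of the U distribution) when
#' `n_case * n_control <= 400` and the data are tie-free; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param case_gsr,control_gsr Numeric vectors of GSR indices (each
#'   non-empty).
#' @return List with `U` (statistic, case vs control orientation) and `p`
#'   (two-sided).
#' @export
mannwhitney_term <- function(case_gsr, control_gsr) {
  if (!length(case_gsr) || !length(control_gsr)) {
    abort("Both groups must be non-empty")
  }
  pooled <- c(case_gsr, control_gsr)
  if (max(pooled) == min(pooled)) {
    # all values tied: no ordering evidence either way
    return(list(U = length(case_gsr) * length(control_gsr) / 2, p = 1))
  }
  exact <- length(case_gsr) * length(control_gsr) <= 400L &&
    !anyDuplicated(pooled)
  wt <- suppressWarnings(
    stats::wilcox.test(case_gsr, control_gsr, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false discovery rate control: `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1, mapped back to input order.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("p values must be numeric in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-term deregulation table for one disease
#'
#' Tests every gene set's GSR indices between one disease's cases and the
#' tissue-matched controls, adjusts by Benjamini-Hochberg, and ranks terms
#' by ascending p (ties broken by set name for determinism). Significance
#' is flagged at `alpha` on the BH-adjusted value by default (`on = "p"`
#' switches to raw p).
#'
#' @param functionome A [compute_functionome()] result containing the
#'   disease's cases and matched controls.
#' @param disease Disease label to test.
#' @param alpha Significance level (default 0.01).
#' @param on `"q"` (default) or `"p"`: scale on which `alpha` applies.
#' @return A tibble of class `dereg_table` with columns `set_name`, `U`,
#'   `p`, `q`, `rank`, `significant`, `mean_case`, `sd_case`,
#'   `mean_control`, `sd_control`, `delta` (case minus control mean; the
#'   deregulation direction, negative = depressed regularity).
#' @export
dereg_table <- function(functionome, disease, alpha = 0.01, on = c("q", "p")) {
  stopifnot(inherits(functionome, "functionome"))
  on <- match.arg(on)
  lab <- functionome$labels
  case <- lab$disease == disease & lab$group == "case"
  if (!any(case)) abort(sprintf("No case samples for disease '%s'", disease))
  tissue <- unique(lab$tissue[case])
  ctrl <- lab$group == "control" & lab$tissue %in% tissue
  if (!any(ctrl)) abort(sprintf("No matched controls for disease '%s'", disease))

  G <- functionome$gsr
  res <- purrr::map(colnames(G), function(s) {
    mw <- mannwhitney_term(G[case, s], G[ctrl, s])
    tibble::tibble(
      set_name = s, U = mw$U, p = mw$p,
      mean_case = mean(G[case, s]), sd_case = sd(G[case, s]),
      mean_control = mean(G[ctrl, s]), sd_control = sd(G[ctrl, s])
    )
  })
  out <- dplyr::bind_rows(res)
  out$q <- bh_adjust(out$p)
  out$delta <- out$mean_case - out$mean_control
  ord <- order(out$p, out$set_name)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out$significant <- (if (on == "q") out$q else out$p) < alpha
  out <- dplyr::arrange(out, .data$rank)
  out <- out[, c("set_name", "U", "p", "q", "rank", "significant",
                 "mean_case", "sd_case", "mean_control", "sd_control", "delta")]
  class(out) <- c("dereg_table", class(out))
  attr(out, "disease") <- disease
  attr(out, "alpha") <- alpha
  attr(out, "on") <- on
  out
}

#' Select the top fraction of deregulated terms
#'
#' The `floor(fraction * m)` lowest-p terms (the table's deterministic
#' rank order, ties already broken by name), or an absolute `top_k`
#' override.
#'
#' @param table A [dereg_table()].
#' @param fraction Fraction of terms to keep, in `(0, 1]`.
#' @param top_k Optional absolute count overriding `fraction`.
#' @return Character vector of set names.
#' @export
select_top_fraction <- function(table, fraction = 0.10, top_k = NULL) {
  stopifnot(inherits(table, "dereg_table"))
  if (is.null(top_k)) {
    stopifnot(fraction > 0, fraction <= 1)
    top_k <- floor(fraction * nrow(table))
  }
  table$set_name[order(table$rank)][seq_len(min(top_k, nrow(table)))]
}

#' Exclusive Venn regions of 2-3 named sets
#'
#' Partitions the union of the inputs into the `2^k - 1` exclusive regions
#' (counts sum to the union size).
#'
#' @param lists Named list of 2 or 3 character vectors.
#' @return Tibble with columns `region` (member names joined by `&`),
#'   `count`, and `names` (list-column of the region's elements, sorted).
#' @export
venn_partition <- function(lists) {
  k <- length(lists)
  if (k < 2L || k > 3L) abort("venn_partition supports 2 or 3 sets")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- LETTERS[seq_len(k)]
  }
  lists <- lapply(lists, unique)
  universe <- sort(Reduce(union, lists))
  membership <- vapply(lists, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(combos)), function(r) {
    mask <- as.logical(combos[r, ])
    inside <- apply(membership, 1L, function(m) all(m == mask))
    tibble::tibble(
      region = paste(names(lists)[mask], collapse = "&"),
      count = sum(inside),
      names = list(universe[inside])
    )
  })
}

#' Group-level summary of GSR indices
#'
#' Pools every GSR entry within each disease's case and control group and
#' reports sample counts, means, standard deviations, and a Mann-Whitney p
#' on the pooled indices — the cohort-level view showing whether functions
#' are globally deregulated.
#'
#' @param functionome A [compute_functionome()] result.
#' @return Tibble with one row per disease: `disease`, `n_case`,
#'   `n_control`, `mean_case`, `sd_case`, `mean_control`, `sd_control`,
#'   `p`.
#' @export
group_summary <- function(functionome) {
  stopifnot(inherits(functionome, "functionome"))
  lab <- functionome$labels
  diseases <- unique(lab$disease[lab$group == "case"])
  purrr::map_dfr(diseases, function(d) {
    case <- lab$disease == d & lab$group == "case"
    tissue <- unique(lab$tissue[case])
    ctrl <- lab$group == "control" & lab$tissue %in% tissue
    x <- as.vector(functionome$gsr[case, , drop = FALSE])
    y <- as.vector(functionome$gsr[ctrl, , drop = FALSE])
    p <- if (length(y)) {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    } else NA_real_
    tibble::tibble(
      disease = d, n_case = sum(case), n_control = sum(ctrl),
      mean_case = mean(x), sd_case = sd(x),
      mean_control = if (length(y)) mean(y) else NA_real_,
      sd_control = if (length(y)) sd(y) else NA_real_,
      p = p
    )
  })
}
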