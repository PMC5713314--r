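#' Progressive-deregulation filter across the disease transition
#'
#' Traces every term's deregulation rank from the precursor disease (ES)
#' to the two carcinomas (CCC, EC) and flags the terms whose deregulation
#' is progressive. The criteria, on the tables' common term universe:
#'
#' 1. significant in all three diseases (the tables' significance flag);
#' 2. `|rank_CCC - rank_EC| < rank_gap` (default 100, strict);
#' 3. `(rank_CCC + rank_EC) / 2 < rank_mean_max` (default 300, strict);
#' 4. rank moves upward from ES into the carcinomas:
#'    `rank_ES - rank_CCC > 0` and `rank_ES - rank_EC > 0` (`"and"`,
#'    default) or either (`"or"`);
#' 5. (optional, on by default) case-group GSR is depressed:
#'    `mean_gsr_CCC < mean_gsr_ES` and `mean_gsr_EC < mean_gsr_ES`.
#'
#' @param table_es,table_ccc,table_ec [dereg_table()] results for the three
#'   diseases.
#' @param rank_gap,rank_mean_max Criterion 2 and 3 thresholds.
#' @param upward `"and"` (default) or `"or"`: how criterion 4 combines the
#'   two carcinomas.
#' @param require_depression Apply criterion 5.
#' @return Tibble of class `progression_records`: per common term,
#'   `set_name`, ranks, `q` values, case-group mean GSR per disease,
#'   per-criterion `pass_*` flags and overall `passed`.
#' @export
progressive_filter <- function(table_es, table_ccc, table_ec,
                               rank_gap = 100, rank_mean_max = 300,
                               upward = c("and", "or"),
                               require_depression = TRUE) {
  stopifnot(inherits(table_es, "dereg_table"),
            inherits(table_ccc, "dereg_table"),
            inherits(table_ec, "dereg_table"))
  upward <- match.arg(upward)
  pick <- function(tb, suffix) {
    out <- tb[, c("set_name", "rank", "q", "significant", "mean_case")]
    names(out)[-1] <- paste0(c("rank_", "q_", "sig_", "mean_gsr_"), suffix)
    tibble::as_tibble(out)
  }
  rec <- dplyr::inner_join(pick(table_es, "ES"), pick(table_ccc, "CCC"), by = "set_name")
  rec <- dplyr::inner_join(rec, pick(table_ec, "EC"), by = "set_name")
  if (!nrow(rec)) abort("The three tables share no terms")

  rec <- dplyr::mutate(
    rec,
    pass_significant = .data$sig_ES & .data$sig_CCC & .data$sig_EC,
    pass_rank_gap = abs(.data$rank_CCC - .data$rank_EC) < rank_gap,
    pass_rank_mean = (.data$rank_CCC + .data$rank_EC) / 2 < rank_mean_max,
    pass_upward = if (upward == "and") {
      (.data$rank_ES - .data$rank_CCC > 0) & (.data$rank_ES - .data$rank_EC > 0)
    } else {
      (.data$rank_ES - .data$rank_CCC > 0) | (.data$rank_ES - .data$rank_EC > 0)
    }
  )
  if (require_depression) {
    rec <- dplyr::mutate(
      rec,
      pass_depressed = .data$mean_gsr_CCC < .data$mean_gsr_ES &
        .data$mean_gsr_EC < .data$mean_gsr_ES
    )
  }
  flags <- dplyr::select(rec, dplyr::starts_with("pass_"))
  rec$passed <- purrr::reduce(flags, `&`)
  rec <- dplyr::select(rec, -dplyr::starts_with("sig_"))
  class(rec) <- c("progression_records", class(rec))
  attr(rec, "upward") <- upward
  rec
}

#' Core transformation functions
#'
#' Intersects the terms coexisting across the three diseases' factor
#' elements (the triple region of their Venn partition) with the
#' progressively deregulated terms, yielding the core functions of the
#' malignant transformation. Sorted by the mean of the three ranks,
#' ascending.
#'
#' @param coexisting_terms Character vector (e.g. the triple Venn region of
#'   per-disease factor elements).
#' @param records A [progressive_filter()] result.
#' @return Character vector of set names.
#' @export
core_intersection <- function(coexisting_terms, records) {
  stopifnot(inherits(records, "progression_records"))
  if (!length(coexisting_terms) || !nrow(records)) {
    abort("Both inputs must be non-empty")
  }
  passed <- records[records$passed, ]
  common <- intersect(coexisting_terms, passed$set_name)
  if (!length(common)) {
    warn("Coexisting and progressive term lists are disjoint")
    return(character(0))
  }
  sub <- passed[match(common, passed$set_name), ]
  mean_rank <- (sub$rank_ES + sub$rank_CCC + sub$rank_EC) / 3
  sub$set_name[order(mean_rank, sub$set_name)]
}

#' Rank-change paths from ES to the carcinomas
#'
#' Long-format table of each passed term's rank (and case-mean GSR) across
#' the three diseases, plus an `average` path over the passed records —
#' the line-chart view of progressive deregulation.
#'
#' @param records A [progressive_filter()] result with >= 1 passed term.
#' @param passed_only Restrict to passed records (default TRUE).
#' @return Tibble with columns `set_name`, `disease` (ordered
#'   ES, CCC, EC), `rank`, `mean_gsr`; the across-record average appears as
#'   `set_name == "average"`.
#' @export
ranking_paths <- function(records, passed_only = TRUE) {
  stopifnot(inherits(records, "progression_records"))
  rec <- if (passed_only) records[records$passed, ] else records
  if (!nrow(rec)) abort("No records to trace (no term passed the filter?)")
  long <- tidyr::pivot_longer(
    dplyr::select(rec, "set_name", dplyr::starts_with("rank_"),
                  dplyr::starts_with("mean_gsr_")),
    -"set_name",
    names_to = c(".value", "disease"),
    names_pattern = "(rank|mean_gsr)_(.*)"
  )
  avg <- long |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(rank = mean(.data$rank), mean_gsr = mean(.data$mean_gsr),
                     .groups = "drop") |>
    dplyr::mutate(set_name = "average")
  out <- dplyr::bind_rows(long, avg)
  out$disease <- factor(out$disease, levels = c("ES", "CCC", "EC"))
  dplyr::arrange(out, .data$set_name != "average", .data$set_name, .data$disease)
}
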