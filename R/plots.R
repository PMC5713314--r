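#' Heatmap of group-mean GSR profiles
#'
#' @param object A [compute_functionome()] result.
#' @param include_controls Add control-tissue rows.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.functionome <- function(object, include_controls = TRUE, ...) {
  lab <- object$labels
  grp <- ifelse(lab$group == "case", lab$disease, paste0("control_", lab$tissue))
  keep <- if (include_controls) rep(TRUE, nrow(lab)) else lab$group == "case"
  df <- tibble::tibble(group = grp[keep]) |>
    dplyr::bind_cols(tibble::as_tibble(object$gsr[keep, , drop = FALSE],
                                       .name_repair = "minimal")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    tidyr::pivot_longer(-"group", names_to = "set_name", values_to = "gsr")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_name, y = .data$group,
                                   fill = .data$gsr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "mean GSR") +
    ggplot2::labs(x = "gene set", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Significance-rank plot of a deregulation table
#'
#' @param object A [dereg_table()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dereg_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = -log10(.data$q),
                                       colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
                                 name = "significant") +
    ggplot2::labs(x = "rank (ascending p)", y = expression(-log[10](q)),
                  title = attr(object, "disease")) +
    ggplot2::theme_minimal()
}

#' Line chart of rank-change paths from ES to the carcinomas
#'
#' Each passed term is a thin grey path over the disease axis; the
#' across-term average is the coarse red line.
#'
#' @param paths A [ranking_paths()] tibble.
#' @param what `"rank"` or `"mean_gsr"`.
#' @return A ggplot object.
#' @export
plot_ranking_paths <- function(paths, what = c("rank", "mean_gsr")) {
  what <- match.arg(what)
  is_avg <- paths$set_name == "average"
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$disease, y = .data[[what]],
                                      group = .data$set_name)) +
    ggplot2::geom_line(data = paths[!is_avg, ], colour = "grey65", linewidth = 0.3) +
    ggplot2::geom_line(data = paths[is_avg, ], colour = "#c0392b", linewidth = 1.4) +
    ggplot2::labs(x = NULL, y = if (what == "rank") "deregulation rank" else "case-mean GSR") +
    ggplot2::theme_minimal()
}

#' ROC curve of pooled held-out decision values
#'
#' @param object A binary [crossval_binary()] report.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.classification_report <- function(object, ...) {
  if (object$task != "binary") abort("ROC curves require a binary report")
  sc <- object$scores
  ord <- order(sc$score, decreasing = TRUE)
  truth <- sc$truth[ord] == object$positive
  df <- tibble::tibble(
    tpr = c(0, cumsum(truth) / sum(truth)),
    fpr = c(0, cumsum(!truth) / sum(!truth))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.4f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
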