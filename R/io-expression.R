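#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with per-sample labels and a
#' platform identifier. Datasets must be complete: any missing value is an
#' error, mirroring the study-selection rule that discards series with
#' missing data.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = symbols),
#'   samples in columns (unique colnames).
#' @param labels Data frame with one row per sample and columns `sample_id`,
#'   `group` (`"case"` or `"control"`), `disease`, `tissue`.
#' @param platform_id Single string naming the (possibly synthetic) platform.
#'
#' @return An object of class `gsr_dataset`: a list with elements `values`
#'   (matrix), `labels` (tibble) and `platform_id`.
#' @export
expression_dataset <- function(values, labels, platform_id = "platform") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Gene symbols must be unique within a dataset")
  }
  if (anyDuplicated(colnames(values))) abort("Sample ids must be unique")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing value at gene '%s', sample '%s' (datasets with missing data are rejected)",
      rownames(values)[idx[1]], colnames(values)[idx[2]]
    ))
  }
  labels <- tibble::as_tibble(labels)
  req <- c("sample_id", "group", "disease", "tissue")
  miss <- setdiff(req, names(labels))
  if (length(miss)) abort(paste("Label columns missing:", paste(miss, collapse = ", ")))
  unlabelled <- setdiff(colnames(values), labels$sample_id)
  if (length(unlabelled)) {
    abort(paste0("Sample(s) absent from labels: ", paste(unlabelled, collapse = ", ")))
  }
  if (!all(labels$group %in% c("case", "control"))) {
    abort("`group` must be 'case' or 'control'")
  }
  labels <- labels[match(colnames(values), labels$sample_id), ]
  structure(
    list(values = values, labels = labels, platform_id = as.character(platform_id)[1]),
    class = "gsr_dataset"
  )
}

#' @export
print.gsr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression dataset '%s': %d genes x %d samples (%d case / %d control)>\n",
    x$platform_id, nrow(x$values), ncol(x$values),
    sum(x$labels$group == "case"), sum(x$labels$group == "control")
  ))
  invisible(x)
}

#' Read a tabular expression dataset with sample labels
#'
#' Reads the package's tabular expression dialect: a TSV whose first column
#' is named `gene` and whose remaining columns are sample ids, plus a label
#' TSV with columns `sample`, `group`, `disease`, `tissue` and optionally
#' `platform`. Parsing is strict: missing-value tokens are rejected with
#' their coordinates, and every matrix sample must be labelled.
#'
#' @param path Path to the expression TSV.
#' @param label_path Path to the label TSV.
#' @return A [expression_dataset()].
#' @export
read_expression <- function(path, label_path) {
  stopifnot(file.exists(path), file.exists(label_path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(tab)[1] != "gene") abort("First expression column must be named 'gene'")
  if (anyNA(tab)) {
    idx <- which(is.na(as.matrix(tab[-1])), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing/non-numeric value at row %d (gene '%s'), column '%s'",
      idx[1], tab$gene[idx[1]], names(tab)[idx[2] + 1L]
    ))
  }
  values <- as.matrix(tab[-1])
  rownames(values) <- tab$gene

  lab <- readr::read_tsv(label_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"sample" %in% names(lab)) abort("Label file must have a 'sample' column")
  lab <- dplyr::rename(lab, sample_id = "sample")
  platform <- if ("platform" %in% names(lab)) lab$platform[1] else "platform"
  expression_dataset(values, lab, platform_id = platform)
}

#' Write an expression dataset and its labels as TSV
#'
#' Inverse of [read_expression()].
#'
#' @param dataset A [expression_dataset()].
#' @param path Output path for the expression TSV.
#' @param label_path Output path for the label TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, label_path) {
  stopifnot(inherits(dataset, "gsr_dataset"))
  tab <- tibble::as_tibble(dataset$values, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(gene = rownames(dataset$values)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  lab <- dplyr::rename(dataset$labels, sample = "sample_id")
  lab$platform <- dataset$platform_id
  readr::write_tsv(lab, label_path, progress = FALSE)
  invisible(path)
}
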