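#' Construct a gene set collection
#'
#' A gene set collection is a tibble with one row per set and columns
#' `set_name` (unique), `description`, and `genes` (a list-column of unique
#' member symbols). This is the in-memory form of a GMT file.
#'
#' @param set_name Character vector of unique set names.
#' @param genes List of character vectors of member gene symbols. Duplicate
#'   symbols within a set are removed, keeping the first occurrence.
#' @param description Character vector of free-text descriptions (recycled).
#'
#' @return A tibble of class `gsr_collection`.
#' @export
#' @examples
#' gene_set_collection(c("GO_A", "GO_B"), list(c("X", "Y"), c("Y", "Z")))
gene_set_collection <- function(set_name, genes, description = "") {
  stopifnot(is.character(set_name), is.list(genes))
  if (anyDuplicated(set_name)) {
    abort(paste0(
      "Duplicate set name(s): ",
      paste(unique(set_name[duplicated(set_name)]), collapse = ", ")
    ))
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  out <- tibble::tibble(
    set_name = set_name,
    description = rep_len(as.character(description), length(set_name)),
    genes = genes
  )
  class(out) <- c("gsr_collection", class(out))
  out
}

#' Read a GMT gene set file
#'
#' Parses the standard MSigDB-style GMT format: one set per line,
#' tab-separated fields `name`, `description`, then one or more gene symbols.
#' Duplicate genes within a line are dropped (first kept); duplicate set
#' names are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()] tibble with sets in file order.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    abort(sprintf(
      "Malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
      bad[1], length(fields[[bad[1]]])
    ))
  }
  gene_set_collection(
    set_name = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a gene set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gsr_collection"))
  lines <- purrr::pmap_chr(
    list(collection$set_name, collection$description, collection$genes),
    function(nm, ds, gs) paste(c(nm, ds, gs), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gsr_collection <- function(x, ...) {
  sizes <- lengths(x$genes)
  cat(sprintf(
    "<gene set collection: %d sets, member sizes %d-%d>\n",
    nrow(x), if (nrow(x)) min(sizes) else 0L, if (nrow(x)) max(sizes) else 0L
  ))
  NextMethod()
}
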