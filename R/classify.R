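# Exact concordance AUC: P(score_pos > score_neg) + 0.5 P(tie),
# computed from ranks over all positive-negative pairs.
auc_concordance <- function(scores, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so class ratios per fold differ by at most one sample.
make_folds <- function(y, n_folds, stratify = TRUE) {
  fold <- integer(length(y))
  if (stratify) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample(seq_along(y))] <- rep_len(seq_len(n_folds), length(y))
  }
  fold
}

svm_fit <- function(X, y, C) {
  kernlab::ksvm(X, y, kernel = "vanilladot", C = C, scaled = FALSE,
                kpar = list())
}

#' Cross-validated binary classification of functionome rows
#'
#' Evaluates how informative GSR profiles are for separating two groups:
#' stratified 5-fold cross-validation repeated 10 times with reshuffled
#' folds, a linear-kernel maximum-margin classifier (cost `C = 1`) per
#' training split, sensitivity/specificity/accuracy from each repeat's
#' cumulative confusion matrix (means and SDs across repeats), and AUC from
#' the held-out decision values pooled over all folds and repeats.
#'
#' @param X Numeric matrix (or data frame), samples x features — typically
#'   `functionome$gsr`.
#' @param y Factor (or vector) of two class labels.
#' @param seed Integer seed controlling fold shuffles.
#' @param positive Label treated as the positive class (default `"case"`
#'   when present, else the first level).
#' @param n_folds,n_repeats Cross-validation geometry.
#' @param C Soft-margin cost of the linear classifier.
#' @param stratify Stratify folds by class (default TRUE).
#' @return Object of class `classification_report`.
#' @export
crossval_binary <- function(X, y, seed = 1L, positive = NULL,
                            n_folds = 5L, n_repeats = 10L, C = 1,
                            stratify = TRUE) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) abort("Binary classification needs exactly 2 classes")
  if (min(table(y)) < n_folds) {
    abort(sprintf("Each class needs >= %d samples for %d-fold CV", n_folds, n_folds))
  }
  positive <- positive %||% if ("case" %in% levels(y)) "case" else levels(y)[1]
  stopifnot(positive %in% levels(y))
  negative <- setdiff(levels(y), positive)

  set.seed(seed)
  per_repeat <- vector("list", n_repeats)
  scores <- numeric(0); score_truth <- character(0)
  confusion <- matrix(0L, 2, 2, dimnames = list(pred = c(positive, negative),
                                                truth = c(positive, negative)))
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(y, n_folds, stratify)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    dec <- numeric(length(y))
    for (k in seq_len(n_folds)) {
      te <- fold == k
      fit <- svm_fit(X[!te, , drop = FALSE], y[!te], C)
      pred[te] <- kernlab::predict(fit, X[te, , drop = FALSE])
      d <- as.numeric(kernlab::predict(fit, X[te, , drop = FALSE], type = "decision"))
      # orient decision values so larger = more positive-class, using the
      # model's own predictions on its training data (no truth involved)
      ptr <- kernlab::predict(fit, X[!te, , drop = FALSE])
      dtr <- as.numeric(kernlab::predict(fit, X[!te, , drop = FALSE], type = "decision"))
      if (any(ptr == positive) && any(ptr == negative) &&
          mean(dtr[ptr == positive]) < mean(dtr[ptr == negative])) {
        d <- -d
      }
      dec[te] <- d
    }
    tp <- sum(pred == positive & y == positive)
    fn <- sum(pred == negative & y == positive)
    tn <- sum(pred == negative & y == negative)
    fp <- sum(pred == positive & y == negative)
    confusion <- confusion + matrix(c(tp, fn, fp, tn), 2, 2)
    per_repeat[[r]] <- tibble::tibble(
      repeat_id = r,
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      accuracy = (tp + tn) / length(y)
    )
    scores <- c(scores, dec); score_truth <- c(score_truth, as.character(y))
  }
  metrics <- dplyr::bind_rows(per_repeat)
  structure(
    list(
      task = "binary", positive = positive, levels = c(positive, negative),
      metrics = metrics,
      sensitivity = mean(metrics$sensitivity), sensitivity_sd = sd(metrics$sensitivity),
      specificity = mean(metrics$specificity), specificity_sd = sd(metrics$specificity),
      accuracy = mean(metrics$accuracy), accuracy_sd = sd(metrics$accuracy),
      auc = auc_concordance(scores, score_truth == positive),
      scores = tibble::tibble(score = scores, truth = score_truth),
      confusion = confusion,
      n_folds = n_folds, n_repeats = n_repeats, C = C, seed = seed
    ),
    class = "classification_report"
  )
}

#' Cross-validated multiclass classification
#'
#' Same cross-validation protocol as [crossval_binary()], with one-vs-one
#' linear classifiers; accuracy is the fraction of correct held-out
#' predictions, cumulated per repeat.
#'
#' @inheritParams crossval_binary
#' @param y Factor of >= 3 class labels, each class with >= 5 samples.
#' @return Object of class `classification_report`.
#' @export
crossval_multiclass <- function(X, y, seed = 1L, n_folds = 5L, n_repeats = 10L,
                                C = 1, stratify = TRUE) {
  X <- as.matrix(X)
  y <- as.factor(y)
  counts <- table(droplevels(y))
  if (nlevels(y) < 3L || length(counts) < 3L) {
    abort("Multiclass classification needs >= 3 observed classes")
  }
  if (min(counts) < 5L) {
    abort(paste0("Class(es) with < 5 samples: ",
                 paste(names(counts)[counts < 5L], collapse = ", ")))
  }
  y <- droplevels(y)
  set.seed(seed)
  K <- nlevels(y)
  confusion <- matrix(0L, K, K, dimnames = list(pred = levels(y), truth = levels(y)))
  per_repeat <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(y, n_folds, stratify)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (k in seq_len(n_folds)) {
      te <- fold == k
      fit <- svm_fit(X[!te, , drop = FALSE], y[!te], C)
      pred[te] <- kernlab::predict(fit, X[te, , drop = FALSE])
    }
    confusion <- confusion + table(pred = pred, truth = y)
    per_repeat[[r]] <- tibble::tibble(repeat_id = r, accuracy = mean(pred == y))
  }
  metrics <- dplyr::bind_rows(per_repeat)
  structure(
    list(
      task = "multiclass", levels = levels(y), metrics = metrics,
      accuracy = mean(metrics$accuracy), accuracy_sd = sd(metrics$accuracy),
      confusion = confusion,
      n_folds = n_folds, n_repeats = n_repeats, C = C, seed = seed
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  if (x$task == "binary") {
    cat(sprintf(
      "<binary classification (positive = '%s'): accuracy %.4f (SD %.4f), sens %.4f, spec %.4f, AUC %.4f>\n",
      x$positive, x$accuracy, x$accuracy_sd, x$sensitivity, x$specificity, x$auc
    ))
  } else {
    cat(sprintf("<multiclass classification (%d classes): accuracy %.4f (SD %.4f)>\n",
                length(x$levels), x$accuracy, x$accuracy_sd))
  }
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) {
  if (x$task == "binary") {
    tibble::tibble(
      metric = c("sensitivity", "specificity", "accuracy", "auc"),
      estimate = c(x$sensitivity, x$specificity, x$accuracy, x$auc),
      sd = c(x$sensitivity_sd, x$specificity_sd, x$accuracy_sd, NA_real_)
    )
  } else {
    tibble::tibble(metric = "accuracy", estimate = x$accuracy, sd = x$accuracy_sd)
  }
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    task = x$task, accuracy = x$accuracy, accuracy_sd = x$accuracy_sd,
    auc = if (x$task == "binary") x$auc else NA_real_,
    n_folds = x$n_folds, n_repeats = x$n_repeats, C = x$C, seed = x$seed
  )
}

#' Hierarchical clustering of group-mean GSR profiles
#'
#' Averages GSR indices per group (case samples grouped by disease;
#' controls, when included, by tissue), then clusters the group profiles
#' agglomeratively with Euclidean distance and complete linkage. The merge
#' structure mirrors which diseases share deregulation patterns.
#'
#' @param functionome A [compute_functionome()] result (often
#'   [combine_functionomes()] output spanning several diseases).
#' @param include_controls Add one profile per control tissue.
#' @return Object of class `profile_clustering`: list with `hclust`, the
#'   group `profiles` matrix (rows reordered to leaf order), and
#'   `distance`/`linkage` metadata.
#' @export
cluster_group_profiles <- function(functionome, include_controls = FALSE) {
  stopifnot(inherits(functionome, "functionome"))
  lab <- functionome$labels
  grp <- ifelse(lab$group == "case", lab$disease, paste0("control_", lab$tissue))
  if (!include_controls) {
    keep <- lab$group == "case"
  } else {
    keep <- rep(TRUE, nrow(lab))
  }
  groups <- sort(unique(grp[keep]))
  if (length(groups) < 2L) abort("Need >= 2 groups to cluster")
  profiles <- t(vapply(
    groups,
    function(g) colMeans(functionome$gsr[keep & grp == g, , drop = FALSE]),
    numeric(ncol(functionome$gsr))
  ))
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "complete")
  structure(
    list(hclust = hc, profiles = profiles[hc$order, , drop = FALSE],
         distance = "euclidean", linkage = "complete"),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<group-profile clustering: %d groups (%s distance, %s linkage)>\n",
              nrow(x$profiles), x$distance, x$linkage))
  cat("leaf order:", paste(x$hclust$labels[x$hclust$order], collapse = ", "), "\n")
  invisible(x)
}

#' First-merged pair of a profile clustering
#'
#' @param clustering A [cluster_group_profiles()] result.
#' @return Character vector of the two group labels merged at the lowest
#'   height (both singletons), or `NA` if the first merge joins a cluster.
#' @export
first_merge <- function(clustering) {
  stopifnot(inherits(clustering, "profile_clustering"))
  m <- clustering$hclust$merge[1, ]
  if (any(m > 0)) return(NA_character_)
  clustering$hclust$labels[-m]
}
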