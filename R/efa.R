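#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' position-wise quantile of eigenvalues from `n_resamples` same-shape
#' standard-normal datasets; the factor count is the number of observed
#' eigenvalues exceeding their null quantile.
#'
#' @param X Numeric matrix or data frame, samples x variables (e.g. the
#'   GSR submatrix of significantly deregulated terms).
#' @param n_resamples Number of null datasets (default 100).
#' @param quantile_prob Null quantile compared against (default 0.95).
#' @param seed Integer seed for the resamples.
#' @return Integer factor count (>= 0), with the observed and null
#'   eigenvalues attached as attributes `eigen` and `null_eigen`.
#' @export
parallel_analysis <- function(X, n_resamples = 100L, quantile_prob = 0.95,
                              seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) abort("Need >= 2 variables")
  if (nrow(X) <= 3L) abort("Need more than 3 samples")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant column(s): ",
                 paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", ")))
  }
  obs <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  null_eig <- vapply(seq_len(n_resamples), function(b) {
    Z <- matrix(rnorm(nrow(X) * ncol(X)), nrow(X), ncol(X))
    eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
  }, numeric(ncol(X)))
  thresh <- apply(null_eig, 1L, quantile, probs = quantile_prob)
  # leading-run rule: count components until the first eigenvalue that
  # fails to beat its null quantile (later exceedances are noise)
  above <- obs > thresh
  n_factors <- if (all(above)) length(above) else which(!above)[1] - 1L
  structure(as.integer(n_factors), eigen = obs, null_eigen = thresh)
}

#' Principal-axis exploratory factor analysis
#'
#' Iterated principal-axis factoring: communalities start at the squared
#' multiple correlations, the reduced correlation matrix (communalities on
#' the diagonal) is eigen-decomposed, and communalities are updated from
#' the loadings until the largest change falls below `tol` (default 1e-4)
#' or `max_iter` iterations. Heywood communalities (> 1) are clipped with
#' a warning.
#'
#' @param X Samples x variables matrix, or a correlation matrix when
#'   `is_cor = TRUE`.
#' @param n_factors Number of factors to extract (< number of variables).
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @param is_cor Treat `X` as an already-computed correlation matrix.
#' @return Object of class `factor_solution`: list with `loadings`
#'   (variables x factors), `communalities`, `uniquenesses`, `n_factors`,
#'   `phi` (factor correlations, identity for an unrotated solution),
#'   `rotation = "none"`, `converged`, `iterations`.
#' @export
fit_efa <- function(X, n_factors, tol = 1e-4, max_iter = 100L, is_cor = FALSE) {
  R <- if (is_cor) as.matrix(X) else cor(as.matrix(X))
  p <- ncol(R)
  if (n_factors >= p) abort("n_factors must be smaller than the number of variables")
  if (n_factors < 1L) abort("n_factors must be >= 1")
  vars <- colnames(R) %||% paste0("V", seq_len(p))

  # squared multiple correlations as starting communalities
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(Rinv)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(Rinv), 0), 1)

  converged <- FALSE
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- e$values[seq_len(n_factors)]
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(pmax(lam, 0)), n_factors)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      warn(sprintf("Heywood case: %d communality(ies) > 1 clipped", sum(h2_new > 1)))
      h2_new <- pmin(h2_new, 1)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("funcgsr_efa_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "Principal-axis factoring did not converge in %d iterations (last max change %.2e)",
        max_iter, delta
      ), call = NULL, loadings = L, communalities = h2)
    )
    stop(cond)
  }
  dimnames(L) <- list(vars, paste0("F", seq_len(n_factors)))
  structure(
    list(loadings = L, communalities = h2, uniquenesses = 1 - h2,
         n_factors = as.integer(n_factors),
         phi = diag(n_factors), rotation = "none",
         converged = converged, iterations = it),
    class = "factor_solution"
  )
}

#' Promax oblique rotation of a factor solution
#'
#' Varimax pre-rotation followed by the target-matrix (element-wise power,
#' sign-preserving) least-squares oblique transform; the factor correlation
#' matrix is returned alongside the pattern loadings. A one-factor solution
#' is returned unchanged. The reproduced correlation matrix
#' `loadings %*% phi %*% t(loadings)` is invariant under the rotation.
#'
#' @param solution A [fit_efa()] result.
#' @param power Promax power (default 4).
#' @return A `factor_solution` with `rotation = "promax"` and oblique
#'   `phi`.
#' @export
promax_rotate <- function(solution, power = 4) {
  stopifnot(inherits(solution, "factor_solution"))
  if (solution$n_factors == 1L) {
    out <- solution
    out$rotation <- "promax"
    return(out)
  }
  pm <- tryCatch(
    stats::promax(solution$loadings, m = power),
    error = function(e) abort(paste("Promax transform failed:", conditionMessage(e)))
  )
  rotmat <- pm$rotmat
  if (abs(det(rotmat)) < 1e-12) abort("Singular promax transform")
  L <- unclass(pm$loadings)
  phi <- solve(crossprod(rotmat))
  dimnames(phi) <- list(colnames(L), colnames(L))
  out <- solution
  out$loadings <- L
  out$phi <- phi
  out$rotation <- "promax"
  out
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor solution: %d factors over %d terms (%s rotation)>\n",
              x$n_factors, nrow(x$loadings), x$rotation))
  invisible(x)
}

#' @export
tidy.factor_solution <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "factor", values_to = "loading")
}

#' @export
glance.factor_solution <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors, n_terms = nrow(x$loadings),
    rotation = x$rotation, converged = x$converged, iterations = x$iterations,
    mean_communality = mean(x$communalities)
  )
}

#' Assign terms to factors by salient loadings
#'
#' A term is assigned to every factor on which its absolute pattern
#' loading reaches `threshold` (multi-assignment allowed); terms salient
#' nowhere are listed separately.
#'
#' @param solution A (typically rotated) [fit_efa()] solution.
#' @param threshold Salience cutoff on `|loading|` (default 0.4).
#' @return List with `assignment` (tibble `factor`, `term`, `loading`) and
#'   `unassigned` (character vector).
#' @export
assign_elements <- function(solution, threshold = 0.4) {
  stopifnot(inherits(solution, "factor_solution"), threshold > 0)
  L <- solution$loadings
  hits <- which(abs(L) >= threshold, arr.ind = TRUE)
  assignment <- tibble::tibble(
    factor = colnames(L)[hits[, 2]],
    term = rownames(L)[hits[, 1]],
    loading = L[hits]
  ) |> dplyr::arrange(.data$factor, dplyr::desc(abs(.data$loading)))
  unassigned <- setdiff(rownames(L), assignment$term)
  if (!nrow(assignment)) {
    warn("No loading reaches the salience threshold; empty assignment")
  }
  list(assignment = assignment, unassigned = unassigned)
}
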