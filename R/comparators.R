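#' Pearson pairwise correlation network
#'
#' The classical thresholding estimator: regions `j` and `k` are linked when
#' the absolute Pearson correlation of their columns reaches the threshold,
#' `|rho_jk| >= tau` (inclusive).
#'
#' @param B data matrix, participants in rows, regions in columns; every
#'   column must have positive variance.
#' @param tau threshold in (0, 1).
#' @return binary adjacency matrix.
#' @export
ppc_network <- function(B, tau) {
  check_residual_matrix(B)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("`tau` must be a single value in (0, 1)", call. = FALSE)
  sds <- apply(B, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  A <- (abs(stats::cor(B)) >= tau) * 1
  diag(A) <- 0
  A
}

#' Graphical-lasso network
#'
#' Estimates the sparse precision matrix by the graphical lasso
#' ([glasso_fit()]) on the sample covariance of `B`, then binarises its
#' off-diagonal support: a link wherever `|Theta_jk|` exceeds `zero_tol`
#' (numerical solvers return tiny non-zeros rather than exact zeros).
#'
#' @param B data matrix, participants in rows, regions in columns.
#' @param lambda sparsity penalty, >= 0.
#' @param zero_tol magnitude below which a precision entry counts as zero.
#' @param ... further arguments passed to [glasso_fit()].
#' @return binary adjacency matrix.
#' @export
glasso_network <- function(B, lambda, zero_tol = 1e-8, ...) {
  check_residual_matrix(B)
  S <- stats::cov(B)
  fit <- glasso_fit(S, lambda, ...)
  if (!fit$converged)
    stop(sprintf(
      "graphical lasso did not converge at lambda = %g after %d cycles",
      lambda, fit$iterations), call. = FALSE)
  A <- (abs(fit$Theta) > zero_tol) * 1
  diag(A) <- 0
  A
}

#' Score an estimated network against the truth
#'
#' Counts true/false positives and negatives over the strict upper triangle
#' (the matrices are symmetric, so each pair is counted once). Sensitivity
#' is the proportion of true links recovered, specificity the proportion of
#' true non-links recovered; a ratio with an empty denominator is reported
#' as `NA`, not 0.
#'
#' @param estimate,truth adjacency matrices of the same size.
#' @return list of class `recovery_score` with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @export
score_network <- function(estimate, truth) {
  validate_adjacency(estimate, "estimate")
  validate_adjacency(truth, "truth")
  if (!identical(dim(estimate), dim(truth)))
    stop("`estimate` and `truth` differ in size", call. = FALSE)
  ut <- upper.tri(truth)
  e <- estimate[ut]; t_ <- truth[ut]
  tp <- sum(e == 1 & t_ == 1); fp <- sum(e == 1 & t_ == 0)
  tn <- sum(e == 0 & t_ == 0); fn <- sum(e == 0 & t_ == 1)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf("recovery: tp=%d fp=%d tn=%d fn=%d  sens=%s spec=%s\n",
              x$tp, x$fp, x$tn, x$fn,
              format(x$sensitivity, digits = 4),
              format(x$specificity, digits = 4)))
  invisible(x)
}

#' Recovery scores of a comparator along its tuning grid
#'
#' Runs the chosen estimator at each tuning value and scores it against the
#' true network, reproducing the sensitivity/specificity trade-off curves in
#' tabular form. The conventional grids are `tau` in `seq(0.1, 0.85, 0.05)`
#' for the correlation network and `lambda` in `seq(0.1, 1.7, 0.05)` for the
#' graphical lasso.
#'
#' @param B data matrix.
#' @param truth true adjacency matrix.
#' @param method `"ppc"` or `"glasso"`.
#' @param grid numeric vector of tuning values in the method's domain.
#' @param ... passed to the underlying estimator.
#' @return data.frame with one row per tuning value: `method`, `tuning`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
grid_evaluate <- function(B, truth, method = c("ppc", "glasso"), grid, ...) {
  method <- match.arg(method)
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  rows <- lapply(grid, function(val) {
    A <- switch(method,
                ppc = ppc_network(B, val),
                glasso = glasso_network(B, val, ...))
    sc <- score_network(A, truth)
    data.frame(method = method, tuning = val, tp = sc$tp, fp = sc$fp,
               tn = sc$tn, fn = sc$fn, sensitivity = sc$sensitivity,
               specificity = sc$specificity)
  })
  do.call(rbind, rows)
}
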