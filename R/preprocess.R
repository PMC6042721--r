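#' Residualise ROI measurements on covariates and standardise
#'
#' For each region-of-interest column, fits an ordinary least-squares
#' regression of the measurements on the covariates (with intercept),
#' takes the residuals and standardises them by their own empirical mean
#' and standard deviation (denominator `N - 1`). The output columns all
#' have mean 0 and standard deviation 1, putting every region on the same
#' scale while preserving the between-region correlation structure net of
#' the covariates. With no covariates this reduces to centring and scaling
#' each column.
#'
#' @param roi numeric matrix or data.frame of ROI measurements,
#'   participants in rows, regions in columns (e.g. mean cortical thickness
#'   in mm).
#' @param covariates optional data.frame of per-participant covariates
#'   (e.g. age, sex, carrier status); factors and characters are expanded
#'   to dummy variables.
#' @return numeric matrix of standardised residuals with the ROI column
#'   names; attribute `"model"` holds the design column names.
#' @export
residualize <- function(roi, covariates = NULL) {
  Y <- as.matrix(roi)
  if (!is.numeric(Y)) stop("`roi` must be numeric", call. = FALSE)
  if (anyNA(Y)) stop("`roi` contains missing values; complete cases only",
                     call. = FALSE)
  N <- nrow(Y)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    X <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != N)
      stop("`covariates` and `roi` disagree on the number of participants",
           call. = FALSE)
    if (anyNA(cv)) stop("`covariates` contains missing values", call. = FALSE)
    X <- stats::model.matrix(~ ., data = cv)
  }
  if (N <= ncol(X))
    stop("need more participants than design columns", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "),
         call. = FALSE)
  res <- stats::lm.fit(X, Y)$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = ncol(Y))
  sds <- apply(res, 2, stats::sd)
  sds[sds < sqrt(.Machine$double.eps) * (1 + abs(colMeans(Y)))] <- 0
  if (any(sds == 0))
    stop("zero residual variance in ROI column(s): ",
         paste(colnames(Y)[sds == 0], collapse = ", "), call. = FALSE)
  out <- scale(res)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  colnames(out) <- colnames(Y)
  attr(out, "model") <- colnames(X)
  out
}

#' Moran's I spatial autocorrelation statistic
#'
#' \deqn{I = \frac{K}{\sum_{jk} w_{jk}}
#'   \frac{\sum_{jk} w_{jk}(x_j - \bar x)(x_k - \bar x)}
#'        {\sum_j (x_j - \bar x)^2},}
#' with both sums running over all ordered pairs. Values near the null
#' expectation `-1/(K-1)` indicate no spatial correlation on the graph;
#' positive values indicate that linked regions co-vary. Invariant to
#' affine transformations of `x`.
#'
#' @param x numeric vector of length `K` (one value per region), not
#'   constant.
#' @param W adjacency matrix with at least one link.
#' @return the statistic (single number).
#' @export
morans_i <- function(x, W) {
  validate_adjacency(W)
  if (length(x) != nrow(W))
    stop("`x` and `W` disagree on the number of regions", call. = FALSE)
  s0 <- sum(W)
  if (s0 == 0) stop("`W` has no links; Moran's I is undefined", call. = FALSE)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("`x` is constant; Moran's I is undefined", call. = FALSE)
  (length(x) / s0) * drop(crossprod(z, W %*% z)) / denom
}

#' Residual diagnostics of a fitted MNL model
#'
#' Under the fitted model \eqn{b_i \sim MVN(0, \hat\sigma^2 Q)}, the
#' whitened vectors \eqn{r_i = \hat\sigma^{-1} U b_i} - with `U` the upper
#' Cholesky factor of the fitted precision, \eqn{Q^{-1} = U'U} - are i.i.d.
#' standard normal, so they are the natural residuals of the model. For
#' each participant the function reports Moran's I of the residual vector
#' against the estimated network: a good fit leaves residuals with no
#' spatial structure on the graph, i.e. values near `-1/(K-1)`.
#'
#' @param B data matrix the model was fitted to.
#' @param fit an `mnl_fit` (from [fit_mnl()]).
#' @param whiten compute Moran's I on the whitened residuals (default); set
#'   to `FALSE` to diagnose the raw observations instead.
#' @return list with `morans_i` (per participant), `median_morans_i`,
#'   `null_expectation` (`-1/(K-1)`), `residuals` (the whitened matrix) and
#'   `roi_sd` (per-region residual standard deviations, near 1 when the
#'   model fits).
#' @export
residual_diagnostics <- function(B, fit, whiten = TRUE) {
  check_residual_matrix(B)
  W <- fit$W_hat
  K <- ncol(B)
  if (ncol(W) != K)
    stop("`fit` and `B` disagree on the number of regions", call. = FALSE)
  if (sum(W) == 0)
    stop("the fitted network has no links, so Moran's I against it is ",
         "undefined", call. = FALSE)
  P <- build_precision(W, fit$gamma)
  U <- chol(P)
  R <- if (whiten) B %*% t(U) / sqrt(fit$sigma2_hat) else B
  mi <- apply(R, 1, morans_i, W = W)
  list(morans_i = mi,
       median_morans_i = stats::median(mi),
       null_expectation = -1 / (K - 1),
       residuals = R,
       roi_sd = apply(R, 2, stats::sd))
}
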