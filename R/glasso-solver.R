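#' Graphical lasso: L1-penalised sparse precision estimation
#'
#' Maximises \eqn{\log|\Theta| - \mathrm{trace}(S\Theta) - \lambda\|\Theta\|_1}
#' over positive-definite precision matrices by block coordinate descent on
#' the covariance estimate (one lasso subproblem per column, solved by
#' coordinate descent with warm starts), the standard algorithm for this
#' objective. The diagonal of the working covariance is fixed at
#' `diag(S) + lambda`.
#'
#' At `lambda = 0` the objective is the unpenalised Gaussian likelihood and
#' the solution is `solve(S)` (requires `S` positive definite), returned
#' directly.
#'
#' @param S sample covariance matrix (symmetric, non-negative diagonal).
#' @param lambda sparsity penalty, >= 0.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance, relative to the average off-diagonal magnitude
#'   of `S`.
#' @param maxit maximum number of outer cycles over the columns.
#' @return list with `Theta` (estimated precision, exact zeros preserved),
#'   `Sigma` (working covariance), `iterations`, `converged`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, maxit = 200L) {
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("`S` must be symmetric", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  K <- ncol(S)
  if (lambda == 0) {
    Theta <- tryCatch(chol2inv(chol(S)), error = function(e)
      stop("`S` is not positive definite; lambda = 0 needs the unpenalised ",
           "MLE to exist (N > K, well-conditioned data)", call. = FALSE))
    return(list(Theta = 0.5 * (Theta + t(Theta)), Sigma = S,
                iterations = 0L, converged = TRUE))
  }
  Sig <- S
  diag(Sig) <- diag(S) + lambda
  Beta <- matrix(0, K - 1L, K)          # per-column lasso coefficients
  off <- mean(abs(S[upper.tri(S)]))
  thresh <- tol * max(off, .Machine$double.eps)
  it <- 0L; converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    max_change <- 0
    for (j in seq_len(K)) {
      idx <- seq_len(K)[-j]
      W11 <- Sig[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- lasso_cd(W11, s12, lambda, Beta[, j])
      Beta[, j] <- beta
      w12 <- drop(W11 %*% beta)
      max_change <- max(max_change, mean(abs(Sig[idx, j] - w12)))
      Sig[idx, j] <- w12
      Sig[j, idx] <- w12
    }
    if (max_change < thresh) { converged <- TRUE; break }
  }
  # recover the precision from the column solutions:
  # theta_jj = 1 / (sigma_jj - w12' beta), theta_12 = -beta * theta_jj
  Theta <- matrix(0, K, K)
  for (j in seq_len(K)) {
    idx <- seq_len(K)[-j]
    beta <- Beta[, j]
    t22 <- 1 / (Sig[j, j] - sum(Sig[idx, j] * beta))
    Theta[j, j] <- t22
    Theta[idx, j] <- -beta * t22
  }
  # the exact zeros of beta are the estimate's zeros; symmetrise by the
  # AND rule so a link needs support in both columns
  zero <- (Theta == 0) | (t(Theta) == 0)
  Theta <- 0.5 * (Theta + t(Theta))
  Theta[zero] <- 0
  list(Theta = Theta, Sigma = Sig, iterations = it, converged = converged)
}

# Coordinate descent for min_beta  1/2 beta' W beta - s' beta + lambda |beta|_1
# with warm start; maintains c = W beta for O(K) updates per coordinate.
lasso_cd <- function(W, s, lambda, beta, tol = 1e-9, maxit = 1000L) {
  p <- length(s)
  if (p == 0L) return(beta)
  cvec <- drop(W %*% beta)
  for (iter in seq_len(maxit)) {
    max_d <- 0
    for (m in seq_len(p)) {
      b_old <- beta[m]
      r <- s[m] - (cvec[m] - W[m, m] * b_old)
      b_new <- soft_threshold(r, lambda) / W[m, m]
      if (b_new != b_old) {
        beta[m] <- b_new
        cvec <- cvec + W[, m] * (b_new - b_old)
        max_d <- max(max_d, abs(b_new - b_old))
      }
    }
    if (max_d < tol) break
  }
  beta
}

soft_threshold <- function(x, lambda) sign(x) * max(abs(x) - lambda, 0)
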