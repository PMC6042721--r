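#' Configuration of the MNL search
#'
#' @param sweeps maximum number of passes over all edges per restart.
#' @param restarts number of random restarts; the restart with the highest
#'   final log-likelihood wins.
#' @param gamma spatial-dependence strength, fixed during the search. The
#'   conventional value for cortical covariance work is 0.9, and recovery is
#'   robust to it, so it is not estimated.
#' @param init_density Bernoulli probability of a link in the random
#'   starting network.
#' @param init_sigma2 small positive starting value of the scale variance;
#'   it is replaced by the first quasi-Newton update conditional on the
#'   starting network before any edge is evaluated.
#' @param sigma2_lower_bound lower box bound of the quasi-Newton update.
#' @param seed master seed; each restart draws its start from an independent
#'   stream derived from `(seed, restart)`.
#' @param early_stop stop a restart once a sweep accepts no flip and the
#'   variance update moves the log-likelihood by less than `1e-8`.
#' @return list of class `mnl_config`.
#' @export
mnl_config <- function(sweeps = 20L, restarts = 10L, gamma = 0.9,
                       init_density = 0.5, init_sigma2 = 0.1,
                       sigma2_lower_bound = 1e-8, seed = 1L,
                       early_stop = TRUE) {
  stopifnot(sweeps >= 1, restarts >= 1,
            init_density >= 0, init_density < 1,
            init_sigma2 > 0, sigma2_lower_bound > 0)
  check_gamma(gamma)
  structure(list(sweeps = as.integer(sweeps), restarts = as.integer(restarts),
                 gamma = gamma, init_density = init_density,
                 init_sigma2 = init_sigma2,
                 sigma2_lower_bound = sigma2_lower_bound,
                 seed = as.integer(seed), early_stop = isTRUE(early_stop)),
            class = "mnl_config")
}

# Deterministic sub-seed for a restart (or any indexed stream); kept within
# the 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 69069 + i * 104729 + 1) %% 2147483647
  as.integer(s)
}

#' Random starting network and variance for one restart
#'
#' Upper-triangle entries are independent Bernoulli(`init_density`) draws
#' from a stream fully determined by `(config$seed, restart_index)`, then
#' reflected to the lower triangle; the starting variance is
#' `config$init_sigma2`.
#'
#' @param K number of regions.
#' @param config an [mnl_config()].
#' @param restart_index 1-based restart number.
#' @return list with `W` and `sigma2`.
#' @export
random_start <- function(K, config, restart_index = 1L) {
  stopifnot(K >= 2)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(config$seed, restart_index))
  n_ut <- K * (K - 1L) / 2L
  ut <- stats::rbinom(n_ut, 1L, config$init_density)
  list(W = symmetrise_upper(K, ut), sigma2 = config$init_sigma2)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' One greedy pass over all candidate edges
#'
#' Visits each unordered pair in `order` once; a flip is committed if and
#' only if it strictly increases the log-likelihood (ties keep the
#' incumbent). Commits take effect immediately and influence later
#' evaluations within the same pass, so the log-likelihood is non-decreasing
#' across the sweep.
#'
#' @param state a [likelihood_state()]; updated in place.
#' @param order integer matrix of pairs as from [upper_tri_pairs()]; must
#'   enumerate every pair `j < k` exactly once.
#' @return number of accepted flips.
#' @export
mnl_sweep <- function(state, order = upper_tri_pairs(state$K)) {
  check_sweep_order(order, state$K)
  accepted <- 0L
  for (m in seq_len(nrow(order))) {
    j <- order[m, 1L]; k <- order[m, 2L]
    inc <- flip_delta(state, j, k)
    if (is.finite(inc$delta) && inc$delta > 0) {
      commit_flip(state, j, k, inc)
      accepted <- accepted + 1L
    }
  }
  accepted
}

check_sweep_order <- function(order, K) {
  if (!is.matrix(order) || ncol(order) != 2L)
    stop("`order` must be a two-column matrix of index pairs", call. = FALSE)
  if (any(order[, 1L] >= order[, 2L]) || any(order < 1L) || any(order > K))
    stop("`order` must list pairs (j, k) with 1 <= j < k <= K", call. = FALSE)
  key <- (order[, 1L] - 1L) * K + order[, 2L]
  if (anyDuplicated(key) || nrow(order) != K * (K - 1L) / 2L)
    stop("`order` must enumerate each unordered pair exactly once",
         call. = FALSE)
  invisible(order)
}

#' Maximisation of the network likelihood (MNL)
#'
#' Estimates the binary covariance network of `ncol(B)` regions by greedy
#' coordinate ascent on the Leroux CAR log-likelihood. Each of
#' `config$restarts` restarts begins at a random network; every iteration
#' runs the bounded quasi-Newton variance update conditional on the current
#' network and then one sweep over all edges, committing exactly the flips
#' that strictly increase the log-likelihood. The restart with the highest
#' final log-likelihood is returned.
#'
#' The variance update precedes the sweep within an iteration so that the
#' nominal small starting variance is immediately replaced by its
#' conditional optimum; with the opposite unroll the first sweep is
#' evaluated at a grossly mis-scaled variance and strips the network to the
#' empty graph, from which single-edge ascent cannot escape.
#'
#' @param B numeric matrix of observations, participants in rows, regions in
#'   columns; typically the output of [residualize()].
#' @param config an [mnl_config()].
#' @return object of class `mnl_fit`: list with `W_hat`, `sigma2_hat`,
#'   `delta_star`, `gamma`, `trace` (one row per restart x sweep with the
#'   log-likelihood and acceptance count), `winning_restart`, `config`.
#' @export
#' @examples
#' S <- band_network(8)
#' B <- sample_data(network_to_covariance(S, covariance_spec()), 200, seed = 1)
#' fit <- fit_mnl(B, mnl_config(restarts = 2, seed = 1))
#' fit$delta_star
fit_mnl <- function(B, config = mnl_config()) {
  check_residual_matrix(B)
  N <- nrow(B); K <- ncol(B)
  if (K < 2) stop("need at least two regions", call. = FALSE)
  if (N < 2) warning("a single participant carries almost no information ",
                     "about the network", call. = FALSE)
  best <- NULL
  trace <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    start <- random_start(K, config, r)
    st <- likelihood_state(B, start$W, config$gamma, start$sigma2)
    rows <- vector("list", config$sweeps)
    for (sw in seq_len(config$sweeps)) {
      s2_old <- st$sigma2
      delta_old <- st$delta
      st$sigma2 <- update_sigma2_qn(st$quad, N, K, st$sigma2,
                                    config$sigma2_lower_bound)
      delta_new <- state_loglik(st)
      if (delta_new < delta_old) {      # keep ascent exact near convergence
        st$sigma2 <- s2_old
        delta_new <- delta_old
      }
      sigma2_gain <- delta_new - delta_old
      st$delta <- delta_new
      accepted <- mnl_sweep(st)
      if (!is.finite(st$delta))
        stop("non-finite log-likelihood during sweep ", sw, call. = FALSE)
      rows[[sw]] <- data.frame(restart = r, sweep = sw, delta = st$delta,
                               accepted = accepted, sigma2 = st$sigma2)
      if (config$early_stop && accepted == 0L && abs(sigma2_gain) < 1e-8)
        break
    }
    # final variance update so the reported sigma2 is conditional on W_hat
    s2_old <- st$sigma2
    delta_old <- st$delta
    st$sigma2 <- update_sigma2_qn(st$quad, N, K, st$sigma2,
                                  config$sigma2_lower_bound)
    st$delta <- state_loglik(st)
    if (st$delta < delta_old) {
      st$sigma2 <- s2_old
      st$delta <- delta_old
    }
    trace[[r]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(best) || st$delta > best$delta) {
      best <- list(W = st$W, sigma2 = st$sigma2, delta = st$delta, restart = r)
    }
  }
  structure(list(W_hat = best$W, sigma2_hat = best$sigma2,
                 delta_star = best$delta, gamma = config$gamma,
                 trace = do.call(rbind, trace),
                 winning_restart = best$restart, config = config),
            class = "mnl_fit")
}

#' @export
print.mnl_fit <- function(x, ...) {
  K <- ncol(x$W_hat)
  links <- sum(x$W_hat[upper.tri(x$W_hat)])
  cat("MNL network fit\n")
  cat(sprintf("  regions:        %d (%d of %d possible links)\n",
              K, links, K * (K - 1) / 2))
  cat(sprintf("  log-likelihood: %.4f (restart %d of %d)\n",
              x$delta_star, x$winning_restart, x$config$restarts))
  cat(sprintf("  sigma2_hat:     %.6g   gamma: %.3g\n", x$sigma2_hat, x$gamma))
  invisible(x)
}
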