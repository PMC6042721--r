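#' Synthetic cortical-thickness cohort
#'
#' Emulates a baseline cohort table for pipeline testing: `K` regional mean
#' cortical thickness values (mm) per participant, generated as a grand
#' mean plus linear covariate effects (age, sex, risk-carrier status) plus
#' spatially correlated noise drawn from the CAR model on a known solution
#' network. Because the covariate effects are linear and independent of the
#' noise, [residualize()] applied to the table recovers the noise
#' correlation structure, and the generating network is returned as the
#' ground truth.
#'
#' @param N participants.
#' @param K regions.
#' @param p_extra extra-link probability of the generating network.
#' @param strength CAR dependence of the noise.
#' @param noise_sd marginal standard deviation of the spatial noise (mm).
#' @param seed reproducibility seed.
#' @return list with `roi` (data.frame, `participant_id` + K ROI columns),
#'   `covariates` (data.frame, `participant_id`, `age`, `sex`, `carrier`),
#'   `truth` (the generating adjacency matrix).
#' @export
synthetic_cohort <- function(N = 200, K = 68, p_extra = 0.1, strength = 0.9,
                             noise_sd = 0.12, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(derive_seed(seed, 17L))
  S <- generate_solution_network(K, p_extra)
  Omega <- network_to_covariance(
    S, covariance_spec(strength = strength, scale = noise_sd^2))
  noise <- MASS::mvrnorm(N, rep(0, K), Omega)
  age <- stats::rnorm(N, 73, 6)
  sex <- stats::rbinom(N, 1, 0.45)
  carrier <- stats::rbinom(N, 1, 0.35)
  base <- stats::runif(K, 2.2, 3.2)          # per-region mean thickness, mm
  Y <- matrix(rep(base, each = N), N, K) -
    0.01 * (age - 73) + 0.03 * sex - 0.04 * carrier + noise
  labels <- paste0("ROI", seq_len(K))
  colnames(Y) <- labels
  dimnames(S) <- list(labels, labels)
  ids <- sprintf("P%04d", seq_len(N))
  list(roi = data.frame(participant_id = ids, Y, check.names = FALSE),
       covariates = data.frame(participant_id = ids, age = age, sex = sex,
                               carrier = carrier),
       truth = S)
}
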