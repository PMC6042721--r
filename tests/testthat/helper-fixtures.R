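# shared fixture builders and independent oracles

# chain graph: links (j, j+1) only
chain_network <- function(K) {
  S <- matrix(0, K, K)
  for (j in seq_len(K - 1)) S[j, j + 1] <- S[j + 1, j] <- 1
  S
}

# random symmetric zero-diagonal binary matrix
random_adjacency <- function(K, p = 0.5) {
  symmetrise_upper(K, stats::rbinom(K * (K - 1) / 2, 1, p))
}

# brute-force multivariate normal log-density: explicit covariance inverse
# and determinant, deliberately naive (the independent oracle for the
# Cholesky-based likelihood)
naive_mvn_loglik <- function(B, Sigma) {
  K <- ncol(Sigma)
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  sum(apply(B, 1, function(b)
    -0.5 * (K * log(2 * pi) + ld + drop(t(b) %*% Sinv %*% b))))
}

# full profiled log-likelihood for exhaustive network enumeration
profiled_loglik <- function(W, B, gamma) {
  s2 <- profile_sigma2(B, W, gamma)
  log_network_likelihood(B, W, gamma, s2)
}

# data drawn from the CAR model itself on a given network
car_data <- function(S, N, strength = 0.9, seed = 1) {
  sample_data(network_to_covariance(S, covariance_spec(strength = strength)),
              N, seed = seed)
}
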