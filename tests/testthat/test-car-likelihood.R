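test_that("build_precision matches the closed form on simple networks", {
  # gamma = 0 collapses to the identity whatever the network
  W <- random_adjacency(6)
  expect_equal(build_precision(W, 0), diag(6))

  # single-link pair, gamma 0.9: direct substitution
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(build_precision(W2, 0.9),
               matrix(c(1, -0.9, -0.9, 1), 2, 2))

  # empty network: Laplacian vanishes, ridge remains
  expect_equal(build_precision(matrix(0, 4, 4), 0.9), 0.1 * diag(4))
})

test_that("build_precision rejects invalid inputs", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(build_precision(W, 1), "gamma")
  expect_error(build_precision(W, -0.1), "gamma")
  expect_error(build_precision(matrix(c(0, 1, 0, 0), 2, 2), 0.5), "symmetric")
  expect_error(build_precision(matrix(c(1, 1, 1, 0), 2, 2), 0.5), "diagonal")
})

test_that("precision is positive definite across random networks and gamma", {
  set.seed(101)
  for (i in seq_len(10000)) {
    K <- sample(2:10, 1)
    gamma <- stats::runif(1, 0, 0.999)
    P <- build_precision(random_adjacency(K, stats::runif(1, 0.1, 0.9)), gamma)
    lmin <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(lmin, (1 - gamma) - 1e-10)
  }
})

test_that("log-likelihood agrees with the naive MVN density oracle", {
  set.seed(102)
  for (i in seq_len(20)) {
    K <- sample(2:10, 1)
    N <- sample(5:25, 1)
    W <- random_adjacency(K)
    gamma <- stats::runif(1, 0, 0.95)
    sigma2 <- stats::runif(1, 0.2, 3)
    B <- matrix(stats::rnorm(N * K), N, K)
    Sigma <- sigma2 * solve(build_precision(W, gamma))
    expect_equal(log_network_likelihood(B, W, gamma, sigma2),
                 naive_mvn_loglik(B, Sigma), tolerance = 1e-8)
  }
})

test_that("log-likelihood has the closed form for a single region", {
  N <- 7; gamma <- 0.6; sigma2 <- 1.7
  B <- matrix(0, N, 1)
  W <- matrix(0, 1, 1)
  expect_equal(log_network_likelihood(B, W, gamma, sigma2),
               N * (-0.5 * log(2 * pi * sigma2 / (1 - gamma))))
})

test_that("scaling data by sqrt(2) and doubling sigma2 shifts only the normaliser", {
  set.seed(103)
  B <- matrix(stats::rnorm(60), 10, 6)
  W <- random_adjacency(6)
  l1 <- log_network_likelihood(B, W, 0.9, 0.8)
  l2 <- log_network_likelihood(sqrt(2) * B, W, 0.9, 1.6)
  expect_equal(l2 - l1, -(10 * 6 / 2) * log(2), tolerance = 1e-10)
})

test_that("log-likelihood validates inputs", {
  B <- matrix(stats::rnorm(20), 5, 4)
  expect_error(log_network_likelihood(B, random_adjacency(3), 0.9, 1),
               "columns")
  B[2, 2] <- NA
  expect_error(log_network_likelihood(B, random_adjacency(4), 0.9, 1),
               "missing|non-finite")
})

test_that("flip_delta matches full recomputation over many random flips", {
  set.seed(104)
  K <- 10; N <- 50
  B <- matrix(stats::rnorm(N * K), N, K)
  st <- likelihood_state(B, random_adjacency(K), 0.9, 0.7)
  for (i in seq_len(200)) {
    jk <- sort(sample(K, 2))
    inc <- flip_delta(st, jk[1], jk[2])
    before <- log_network_likelihood(B, st$W, st$gamma, st$sigma2)
    W2 <- st$W
    W2[jk[1], jk[2]] <- W2[jk[2], jk[1]] <- 1 - W2[jk[1], jk[2]]
    after <- log_network_likelihood(B, W2, st$gamma, st$sigma2)
    expect_equal(inc$delta, after - before, tolerance = 1e-8)
    if (i %% 3 == 0) commit_flip(st, jk[1], jk[2], inc)  # drift the state
  }
  # cache coherence after all the committed flips
  expect_equal(st$delta,
               log_network_likelihood(B, st$W, st$gamma, st$sigma2),
               tolerance = 1e-8)
})

test_that("flipping an edge twice sums to zero change", {
  set.seed(105)
  B <- matrix(stats::rnorm(200), 20, 10)
  st <- likelihood_state(B, random_adjacency(10), 0.9, 1.1)
  inc1 <- flip_delta(st, 2, 7)
  commit_flip(st, 2, 7, inc1)
  inc2 <- flip_delta(st, 2, 7)
  expect_equal(inc1$delta + inc2$delta, 0, tolerance = 1e-8)
  expect_error(flip_delta(st, 3, 3), "differ")
})

test_that("at gamma = 0 the network does not enter the likelihood", {
  set.seed(106)
  B <- matrix(stats::rnorm(80), 10, 8)
  st <- likelihood_state(B, random_adjacency(8), 0, 0.5)
  expect_equal(flip_delta(st, 1, 5)$delta, 0)
})

test_that("profile_sigma2 is the closed-form maximiser", {
  set.seed(107)
  K <- 8; N <- 40
  B <- matrix(stats::rnorm(N * K), N, K)
  W <- random_adjacency(K)

  # gamma = 0: mean of squared entries
  expect_equal(profile_sigma2(B, W, 0), mean(B^2))

  # quadratic scaling in the data
  expect_equal(profile_sigma2(3 * B, W, 0.9),
               9 * profile_sigma2(B, W, 0.9))

  # beats every value on a fine grid
  s2_hat <- profile_sigma2(B, W, 0.9)
  ll_hat <- log_network_likelihood(B, W, 0.9, s2_hat)
  for (s2 in seq(0.2 * s2_hat, 3 * s2_hat, length.out = 60))
    expect_gte(ll_hat, log_network_likelihood(B, W, 0.9, s2))

  expect_error(profile_sigma2(matrix(0, 5, 3), chain_network(3), 0.5),
               "degenerate")
})

test_that("quasi-Newton variance update agrees with the closed form", {
  set.seed(108)
  for (i in seq_len(10)) {
    K <- sample(3:10, 1); N <- sample(10:60, 1)
    B <- matrix(stats::rnorm(N * K), N, K)
    W <- random_adjacency(K)
    gamma <- stats::runif(1, 0, 0.95)
    quad <- sum(build_precision(W, gamma) * crossprod(B))
    qn <- mnlnet:::update_sigma2_qn(quad, N, K, sigma2 = 0.1)
    expect_equal(qn, profile_sigma2(B, W, gamma), tolerance = 1e-6)
  }
})
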