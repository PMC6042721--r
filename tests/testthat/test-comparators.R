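test_that("correlation thresholding is inclusive at the threshold", {
  set.seed(301)
  B <- matrix(stats::rnorm(400), 100, 4)
  r13 <- abs(stats::cor(B[, 1], B[, 3]))
  eps <- 1e-6
  expect_equal(ppc_network(B, r13 - eps)[1, 3], 1)   # tau below |rho|
  expect_equal(ppc_network(B, r13 + eps)[1, 3], 0)   # tau above |rho|
  # exactly at the threshold the link is kept (>= rule)
  A <- abs(stats::cor(B)) >= r13
  expect_equal(ppc_network(B, r13)[1, 3], 1)
})

test_that("a duplicated column is linked at any threshold below one", {
  set.seed(302)
  B <- matrix(stats::rnorm(300), 100, 3)
  B <- cbind(B, B[, 2])
  for (tau in c(0.1, 0.5, 0.99))
    expect_equal(ppc_network(B, tau)[2, 4], 1)
  B[, 1] <- 2
  expect_error(ppc_network(B, 0.5), "zero-variance.*1")
})

test_that("near-zero thresholds saturate the network on noisy data", {
  set.seed(303)
  B <- matrix(stats::rnorm(50 * 10), 50, 10)
  A <- ppc_network(B, 0.01)
  expect_gt(mean(A[upper.tri(A)]), 0.95)
})

test_that("glasso matches the two-variable closed form", {
  # for K = 2 the penalised precision has a zero off-diagonal exactly when
  # |s12| <= lambda; otherwise the working covariance soft-thresholds s12
  set.seed(304)
  B <- matrix(stats::rnorm(600), 300, 2)
  B[, 2] <- B[, 2] + 0.8 * B[, 1]
  S <- stats::cov(B)
  s12 <- S[1, 2]
  above <- glasso_fit(S, abs(s12) * 0.9)
  below <- glasso_fit(S, abs(s12) * 1.1)
  expect_true(above$Theta[1, 2] != 0)
  expect_equal(below$Theta[1, 2], 0)
  # closed form of the linked case: Sigma = S + lambda I on diagonal,
  # off-diagonal soft-thresholded
  lam <- abs(s12) * 0.9
  Sig_expect <- matrix(c(S[1, 1] + lam, sign(s12) * (abs(s12) - lam),
                         sign(s12) * (abs(s12) - lam), S[2, 2] + lam), 2, 2)
  expect_equal(above$Sigma, Sig_expect, tolerance = 1e-6)
  expect_equal(above$Theta, solve(Sig_expect), tolerance = 1e-6)
})

test_that("glasso solutions satisfy the optimality conditions", {
  set.seed(305)
  S0 <- generate_solution_network(8, 0.1, seed = 4)
  B <- sample_data(network_to_covariance(S0, covariance_spec(strength = 0.8)),
                   200, seed = 5)
  S <- stats::cov(B)
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- glasso_fit(S, lam)
    expect_true(fit$converged)
    G <- solve(fit$Theta) - S
    nz <- fit$Theta != 0 & row(fit$Theta) != col(fit$Theta)
    if (any(nz))
      expect_lt(max(abs(G[nz] - lam * sign(fit$Theta[nz]))), 1e-5)
    z <- fit$Theta == 0
    if (any(z)) expect_lt(max(abs(G[z])), lam + 1e-5)
    expect_lt(max(abs(diag(G) - lam)), 1e-5)
  }
})

test_that("glasso network is empty at large lambda and dense at lambda zero", {
  set.seed(306)
  S0 <- generate_solution_network(10, 0.1, seed = 6)
  B <- sample_data(network_to_covariance(S0, covariance_spec(strength = 0.85)),
                   120, seed = 7)
  A_big <- glasso_network(B, 50)
  expect_equal(sum(A_big), 0)
  A_zero <- glasso_network(B, 0)
  expect_gt(mean(A_zero[upper.tri(A_zero)]), 0.9)
})

test_that("score_network counts the upper triangle correctly", {
  t4 <- matrix(0, 4, 4)
  t4[1, 2] <- t4[2, 1] <- 1; t4[2, 3] <- t4[3, 2] <- 1
  e4 <- matrix(0, 4, 4)
  e4[1, 2] <- e4[2, 1] <- 1; e4[1, 4] <- e4[4, 1] <- 1
  sc <- score_network(e4, t4)
  expect_identical(c(sc$tp, sc$fn, sc$fp, sc$tn), c(1L, 1L, 1L, 3L))
  expect_equal(sc$sensitivity, 0.5)
  expect_equal(sc$specificity, 0.75)
  expect_equal(sc$tp + sc$fp + sc$tn + sc$fn, 4 * 3 / 2)

  perfect <- score_network(t4, t4)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  flipped <- 1 - t4; diag(flipped) <- 0
  worst <- score_network(flipped, t4)
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$specificity, 0)

  # undefined ratios are NA, not zero
  empty <- matrix(0, 4, 4)
  expect_true(is.na(score_network(empty, empty)$sensitivity))
  expect_error(score_network(e4, chain_network(3)), "size")
})

test_that("scoring is invariant under joint relabelling of regions", {
  set.seed(307)
  truth <- random_adjacency(7, 0.3)
  est <- random_adjacency(7, 0.4)
  perm <- sample(7)
  sc1 <- score_network(est, truth)
  sc2 <- score_network(est[perm, perm], truth[perm, perm])
  expect_identical(sc1, sc2)
})

test_that("grid evaluation reproduces the trade-off curves", {
  set.seed(308)
  S0 <- generate_solution_network(12, 0.1, seed = 8)
  B <- sample_data(network_to_covariance(S0, covariance_spec(strength = 0.9)),
                   200, seed = 9)
  g <- grid_evaluate(B, S0, "ppc", seq(0.05, 0.9, by = 0.05))
  expect_true(all(diff(g$sensitivity) <= 0))   # non-increasing in tau
  expect_true(all(diff(g$specificity) >= 0))   # non-decreasing in tau

  # link count along an ascending lasso path: non-increasing up to solver
  # tolerance (the lasso path is not strictly monotone in general)
  gl <- grid_evaluate(B, S0, "glasso", c(0.1, 0.4, 0.8, 1.6))
  links <- gl$tp + gl$fp
  expect_true(all(diff(links) <= 2))
  expect_lt(links[4], links[1])

  single <- grid_evaluate(B, S0, "ppc", 0.3)
  direct <- score_network(ppc_network(B, 0.3), S0)
  expect_equal(single$sensitivity, direct$sensitivity)
  expect_equal(single$tp, direct$tp)
  expect_error(grid_evaluate(B, S0, "ppc", numeric(0)), "non-empty")
})
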