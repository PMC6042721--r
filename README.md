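# mnlnet

Consistent estimation of binary brain covariance networks by
**maximisation of the network likelihood (MNL)**.

## The problem

Structural covariance networks link brain regions of interest (ROIs) whose
measurements — typically mean cortical thickness — co-vary across
subjects. The two workhorse estimators are unsatisfying: thresholded
Pearson pairwise correlations (PPC) ignore all other regions when judging
a pair, and graphical-lasso (gLASSO) binarisation of a sparse precision
matrix is not a consistent network estimator; both swing wildly with
their tuning parameter. `mnlnet` instead treats the network itself as the
parameter of a proper joint model and estimates it by maximum likelihood,
which is consistent (the estimate converges to the generating network as
the sample grows) and robust to its single fixed tuning value.

## The model and algorithm

Each participant's vector of standardised regional residuals
$b_i \in \mathbb{R}^K$ is modelled by the multivariate Leroux CAR
distribution

$$ b_i \sim \mathrm{MVN}\!\left(0, \sigma_s^2 Q\right), \qquad
   Q^{-1} = \gamma(\hat W - W) + (1 - \gamma) I, $$

where $W$ is the binary, symmetric, zero-diagonal adjacency matrix to be
estimated, $\hat W$ the diagonal matrix of its row sums (so
$\hat W - W$ is the graph Laplacian), $\gamma$ (fixed at the conventional
0.9) the spatial-dependence strength and $\sigma_s^2$ a scale variance.
The precision is positive definite for every $W$ and $\gamma \in [0, 1)$.

`fit_mnl()` performs greedy single-edge ascent on the log-likelihood:
sweep over all $K(K-1)/2$ edge indicators, commit exactly the flips that
strictly increase the log-likelihood, update $\sigma_s^2$ by a bounded
quasi-Newton step between sweeps, and repeat from multiple random starting
networks, returning the restart with the highest final log-likelihood.
Candidate flips are evaluated incrementally (a flip is a rank-one
perturbation of the precision), which makes a full $K = 68$ fit a matter
of seconds.

## Worked example

Estimate a network from a synthetic 20-region cohort with known truth:

```r
library(mnlnet)

cohort <- synthetic_cohort(N = 300, K = 20, p_extra = 0.1, seed = 42)
B <- residualize(as.matrix(cohort$roi[, -1]), cohort$covariates[, -1])
fit <- fit_mnl(B, mnl_config(sweeps = 20, restarts = 5, seed = 1))
fit
#> MNL network fit
#>   regions:        20 (60 of 190 possible links)
#>   log-likelihood: -5293.8163 (restart 5 of 5)
#>   sigma2_hat:     1.49099   gamma: 0.9

score_network(unname(fit$W_hat), unname(cohort$truth))
#> recovery: tp=50 fp=10 tn=124 fn=6  sens=0.8929 spec=0.9254

dg <- residual_diagnostics(B, fit)
sprintf("median Moran's I: %.3f (null expectation %.3f)",
        dg$median_morans_i, dg$null_expectation)
#> "median Moran's I: -0.036 (null expectation -0.053)"
```

The fit recovers 50 of the 56 true links while rejecting 124 of the 134
non-links, and the whitened residuals show no leftover spatial structure
on the estimated graph (Moran's I near its null expectation
$-1/(K-1)$ — the model has absorbed the spatial covariance).

Comparators and the recovery simulation framework use the same
vocabulary:

```r
A_ppc <- ppc_network(B, tau = 0.3)          # |correlation| >= 0.3
A_gl  <- glasso_network(B, lambda = 0.5)    # nonzero penalised precision
res   <- run_simulation_study(study_config(replicates = 3, seed = 1))
summarise_study(res)                        # sensitivity/specificity per cell
```

A thin command-line wrapper (`inst/cli/mnlnet-cli.R`) exposes the same
pipeline as `preprocess`, `fit`, `simulate` and `compare` subcommands over
delimited text files.

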