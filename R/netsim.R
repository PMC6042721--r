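#' Second-order band network
#'
#' The deterministic backbone of the simulated networks: regions adjacent on
#' the cortex strip are linked up to second order, `|j - k| <= 2`.
#'
#' @param K number of regions (>= 3).
#' @return adjacency matrix with `(K - 1) + (K - 2)` links.
#' @export
band_network <- function(K) {
  stopifnot(K >= 3)
  S <- matrix(0, K, K)
  d <- abs(row(S) - col(S))
  S[d == 1 | d == 2] <- 1
  S
}

#' Generate a solution network: second-order band plus random links
#'
#' Combines the second-order band backbone with an independent-links random
#' graph: every non-band pair receives a link with probability `p_extra`.
#' The conventional study configurations are `p_extra = 0.1` (semi-sparse,
#' "S1") and `p_extra = 0.05` (sparse, "S2") at `K = 68`.
#'
#' @param K number of regions.
#' @param p_extra Bernoulli link probability among non-band pairs, in
#'   `[0, 1)`.
#' @param seed optional seed making the draw reproducible.
#' @return adjacency matrix.
#' @export
generate_solution_network <- function(K, p_extra = 0.1, seed = NULL) {
  stopifnot(K >= 3, p_extra >= 0, p_extra < 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(derive_seed(seed))
  }
  S <- band_network(K)
  extra <- which(upper.tri(S) & S == 0)
  S[extra[stats::runif(length(extra)) < p_extra]] <- 1
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Specification of the network-to-covariance conversion
#'
#' Two constructions are available to turn a binary solution network into a
#' positive-definite covariance:
#'
#' * `family = "car"` (the study default): the covariance is the inverse of
#'   the Leroux CAR precision built from the network at dependence
#'   `strength`, rescaled to diagonal `scale`. It is positive definite for
#'   every network and every `strength < 1`, and the data it generates carry
#'   exactly the kind of conditional-dependence signal the network encodes;
#'   `strength` sets how strong the link correlations are (the calibration
#'   knob of the simulation study) and `scale` sets the measurement
#'   variance, which only matters to scale-sensitive estimators such as the
#'   graphical lasso.
#' * `family = "sparse"`: the literal sparse construction
#'   `Omega = offdiag_const * S` off the diagonal and
#'   `diag_const` on it, with the diagonal-dominance default
#'   `diag_const = offdiag_const * max(degree) + 1` guaranteeing positive
#'   definiteness. Its off-diagonal support equals the network exactly, but
#'   diagonal dominance caps the attainable link correlation at
#'   `1 / max(degree)`, which is far below what the CAR likelihood at
#'   `gamma = 0.9` recognises as a link - hence it is not used for the
#'   recovery study (see the methods vignette).
#'
#' @param family `"car"` or `"sparse"`.
#' @param strength CAR dependence in `[0, 1)` (car family).
#' @param scale diagonal (variance) of the covariance (car family).
#' @param offdiag_const positive constant on linked pairs (sparse family).
#' @param diag_const positive diagonal constant, or `NULL` for the
#'   diagonal-dominance rule (sparse family).
#' @return list of class `covariance_spec`.
#' @export
covariance_spec <- function(family = c("car", "sparse"), strength = 0.9,
                            scale = 1, offdiag_const = 0.3,
                            diag_const = NULL) {
  family <- match.arg(family)
  if (family == "car") check_gamma(strength)
  stopifnot(scale > 0, offdiag_const > 0, is.null(diag_const) || diag_const > 0)
  structure(list(family = family, strength = strength, scale = scale,
                 offdiag_const = offdiag_const, diag_const = diag_const),
            class = "covariance_spec")
}

#' Convert a binary network into a positive-definite covariance
#'
#' @param S binary solution network.
#' @param spec a [covariance_spec()].
#' @return covariance matrix; a failed Cholesky check raises an error
#'   reporting the smallest eigenvalue.
#' @export
network_to_covariance <- function(S, spec = covariance_spec()) {
  validate_adjacency(S, "S")
  Omega <- if (spec$family == "car") {
    P <- build_precision(S, spec$strength)
    Q <- chol2inv(chol(P))
    d <- 1 / sqrt(diag(Q))
    spec$scale * (Q * outer(d, d))
  } else {
    d0 <- if (is.null(spec$diag_const))
      spec$offdiag_const * max(rowSums(S)) + 1 else spec$diag_const
    O <- spec$offdiag_const * S
    diag(O) <- d0
    O
  }
  ok <- tryCatch({ chol(Omega); TRUE }, error = function(e) FALSE)
  if (!ok) {
    ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "constructed covariance is not positive definite (smallest eigenvalue %g)",
      ev), call. = FALSE)
  }
  Omega
}

#' Sample multivariate normal data from a covariance
#'
#' Draws `N` independent mean-zero rows from `MVN(0, Omega)`, reproducibly
#' for a given seed.
#'
#' @param Omega positive-definite covariance matrix.
#' @param N number of rows (participants).
#' @param seed optional seed.
#' @return `N x K` numeric matrix.
#' @export
sample_data <- function(Omega, N, seed = NULL) {
  stopifnot(N >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(derive_seed(seed))
  }
  B <- MASS::mvrnorm(N, mu = rep(0, ncol(Omega)), Sigma = Omega)
  if (N == 1L) B <- matrix(B, nrow = 1L)
  B
}

#' Configuration of the recovery simulation study
#'
#' Defines the full factorial recovery experiment: for each network
#' configuration, sample size and replicate, a fresh solution network is
#' drawn, converted to a covariance, data are sampled and each requested
#' method is scored against the truth. The default network configurations
#' are the semi-sparse (`p_extra = 0.1`) and sparse (`p_extra = 0.05`)
#' second-order band networks at `K = 68` with their calibrated covariance
#' constants (see the methods vignette for the calibration).
#'
#' @param K number of regions.
#' @param sample_sizes vector of participant counts.
#' @param replicates independent data sets per cell.
#' @param networks named list; each element has `p_extra` and a
#'   [covariance_spec()].
#' @param mnl an [mnl_config()] or `NULL` to skip the MNL fit. The study
#'   default uses 3 restarts and up to 30 sweeps, which matches the
#'   10-restart search on these problems at a third of the cost.
#' @param ppc_grid,glasso_grid tuning grids, or `NULL` to skip the method.
#' @param include_truth also score the true network against itself (pipeline
#'   identity check).
#' @param seed master seed; every cell derives an independent stream from
#'   `(seed, network, N, replicate)` so any single cell is reproducible in
#'   isolation.
#' @return list of class `study_config`.
#' @export
study_config <- function(K = 68,
                         sample_sizes = c(100, 250, 500, 1000),
                         replicates = 10,
                         networks = list(
                           S1 = list(p_extra = 0.10,
                                     cov = covariance_spec(strength = 0.90)),
                           S2 = list(p_extra = 0.05,
                                     cov = covariance_spec(strength = 0.75,
                                                           scale = 4.2))),
                         mnl = mnl_config(sweeps = 30, restarts = 3),
                         ppc_grid = NULL, glasso_grid = NULL,
                         include_truth = FALSE, seed = 1L) {
  stopifnot(all(sample_sizes >= 2), replicates >= 1, length(networks) >= 1)
  structure(list(K = K, sample_sizes = sample_sizes, replicates = replicates,
                 networks = networks, mnl = mnl, ppc_grid = ppc_grid,
                 glasso_grid = glasso_grid, include_truth = include_truth,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the network recovery simulation study
#'
#' Executes the experiment defined by a [study_config()]. Within a cell the
#' raw multivariate-normal draws are handed to each method in the form it
#' expects: the MNL fit receives column-standardised data (the scale-free
#' form the estimator is defined on), the correlation network is scale-free
#' by construction, and the graphical lasso receives the raw draws so its
#' penalty acts on the sample covariance.
#'
#' A replicate whose fit fails is recorded with `NA` scores and an `error`
#' message rather than dropped.
#'
#' @param study a [study_config()].
#' @param verbose print one line per cell.
#' @return data.frame with one row per network x N x replicate x method x
#'   tuning value: counts, sensitivity, specificity and an `error` column;
#'   the drawn truth networks are attached as `attr(, "truths")` (a named
#'   list indexed by `network.N.replicate`).
#' @export
run_simulation_study <- function(study, verbose = FALSE) {
  rows <- list(); truths <- list()
  for (net_name in names(study$networks)) {
    net <- study$networks[[net_name]]
    for (N in study$sample_sizes) {
      for (rep_i in seq_len(study$replicates)) {
        cell_seed <- derive_seed(study$seed, match(net_name, names(study$networks)),
                                 N, rep_i)
        S <- generate_solution_network(study$K, net$p_extra, seed = cell_seed)
        Omega <- network_to_covariance(S, net$cov)
        B <- sample_data(Omega, N, seed = cell_seed + 1L)
        truths[[paste(net_name, N, rep_i, sep = ".")]] <- S
        add_row <- function(method, tuning, sc, err = NA_character_) {
          rows[[length(rows) + 1L]] <<- data.frame(
            network = net_name, N = N, replicate = rep_i, method = method,
            tuning = tuning,
            tp = if (is.null(sc)) NA else sc$tp,
            fp = if (is.null(sc)) NA else sc$fp,
            tn = if (is.null(sc)) NA else sc$tn,
            fn = if (is.null(sc)) NA else sc$fn,
            sensitivity = if (is.null(sc)) NA_real_ else sc$sensitivity,
            specificity = if (is.null(sc)) NA_real_ else sc$specificity,
            error = err)
        }
        if (study$include_truth)
          add_row("truth", NA_real_, score_network(S, S))
        if (!is.null(study$mnl)) {
          cfg <- study$mnl
          cfg$seed <- cell_seed + 2L
          res <- tryCatch(score_network(
            fit_mnl(scale(B), cfg)$W_hat, S), error = identity)
          if (inherits(res, "error")) add_row("mnl", NA_real_, NULL,
                                              conditionMessage(res))
          else add_row("mnl", NA_real_, res)
        }
        if (!is.null(study$ppc_grid)) {
          g <- tryCatch(grid_evaluate(B, S, "ppc", study$ppc_grid),
                        error = identity)
          if (inherits(g, "error")) add_row("ppc", NA_real_, NULL,
                                            conditionMessage(g))
          else for (i in seq_len(nrow(g)))
            add_row("ppc", g$tuning[i], as.list(g[i, ]))
        }
        if (!is.null(study$glasso_grid)) {
          g <- tryCatch(grid_evaluate(B, S, "glasso", study$glasso_grid),
                        error = identity)
          if (inherits(g, "error")) add_row("glasso", NA_real_, NULL,
                                            conditionMessage(g))
          else for (i in seq_len(nrow(g)))
            add_row("glasso", g$tuning[i], as.list(g[i, ]))
        }
        if (verbose)
          message(sprintf("%s N=%d replicate %d done", net_name, N, rep_i))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truths") <- truths
  out
}

#' Replicate-averaged recovery per study cell
#'
#' @param results output of [run_simulation_study()].
#' @return data.frame averaged over replicates, one row per
#'   network x N x method x tuning.
#' @export
summarise_study <- function(results) {
  tuning_key <- ifelse(is.na(results$tuning), "-", format(results$tuning))
  key <- interaction(results$network, results$N, results$method,
                     tuning_key, drop = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(network = d$network[1], N = d$N[1], method = d$method[1],
               tuning = d$tuning[1], replicates = nrow(d),
               sensitivity = mean(d$sensitivity, na.rm = TRUE),
               specificity = mean(d$specificity, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out[order(out$network, out$method, out$tuning, out$N), ]
}
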