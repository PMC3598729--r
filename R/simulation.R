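#' Configuration for the block-covariance simulator
#'
#' Describes a joint Gaussian model for predictors and a latent response:
#' the predictors fall into `L` groups, each internally equicorrelated
#' (correlation `group_correlations[l]`, unit variances, so the predictor
#' covariance matrix is a block-diagonal correlation matrix), groups are
#' mutually uncorrelated, and every variable in group `l` has covariance
#' `group_covariances[l]` with a standard-normal latent response. The
#' defaults reproduce a 14-group design with 500 variables in which only
#' the first four groups carry signal.
#'
#' Validity of the implied joint correlation matrix is checked in closed
#' form: for equicorrelated blocks, the residual variance of the latent
#' response given all predictors is
#' `1 - sum_l k_l c_l^2 / (1 + (k_l - 1) rho_l)`, which must be
#' non-negative.
#'
#' @param group_sizes integer vector `k_1..k_L` of variables per group.
#' @param group_correlations within-group correlations `rho_l`, each in
#'   `[0, 1)`.
#' @param group_covariances covariance of each group's variables with the
#'   latent response, each in `(-1, 1)`.
#' @param n_samples number of samples to draw.
#' @param seed optional seed stored in the config and used by
#'   [sim_lpls_data()].
#' @return An object of class `"sim_config"`; a validated list of the
#'   above plus `n_groups`, `n_variables` and the closed-form
#'   `residual_variance`.
#' @export
sim_config <- function(group_sizes = c(10, 10, 10, 100, 10, 10, 10, 10,
                                       10, 10, 10, 100, 100, 100),
                       group_correlations = c(0.5, 0.5, 0.5, 0.2,
                                              rep(0, 10)),
                       group_covariances = c(0.35, -0.3, 0.25, 0.2,
                                             rep(0, 10)),
                       n_samples = 100, seed = NULL) {
  l <- length(group_sizes)
  if (length(group_correlations) != l || length(group_covariances) != l)
    stop("'group_sizes', 'group_correlations' and 'group_covariances' ",
         "must have equal length")
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  if (any(group_correlations < 0 | group_correlations >= 1))
    stop("within-group correlations must lie in [0, 1)")
  if (any(abs(group_covariances) >= 1))
    stop("group covariances with the response must lie in (-1, 1)")
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  rv <- 1 - sum(group_sizes * group_covariances^2 /
                  (1 + (group_sizes - 1) * group_correlations))
  if (rv < -1e-10)
    stop("invalid design: the implied joint correlation matrix is not ",
         "positive semidefinite (residual variance of the latent response ",
         "= ", format(rv), " < 0); reduce the covariances or increase the ",
         "within-group correlations")
  structure(list(
    group_sizes = as.integer(group_sizes),
    group_correlations = group_correlations,
    group_covariances = group_covariances,
    n_samples = as.integer(n_samples),
    seed = seed,
    n_groups = l,
    n_variables = as.integer(sum(group_sizes)),
    residual_variance = rv
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Block-covariance simulation design\n")
  cat("  groups:", x$n_groups, " variables:", x$n_variables,
      " samples:", x$n_samples, "\n")
  cat("  relevant groups:", paste(which(x$group_covariances != 0),
                                  collapse = ", "), "\n")
  cat("  residual variance of latent response:",
      format(x$residual_variance, digits = 4), "\n")
  invisible(x)
}

#' Joint correlation matrix of predictors and latent response
#'
#' Builds the `(K+1) x (K+1)` correlation matrix of the stacked vector
#' `(x, y~)`: a block-diagonal equicorrelated predictor block with unit
#' diagonal, bordered by the per-variable covariances with the latent
#' response (bottom-right entry 1). The matrix is verified to be
#' symmetric positive semidefinite.
#'
#' @param config a [sim_config()].
#' @return A symmetric PSD matrix of order `config$n_variables + 1`.
#' @export
build_joint_sigma <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k_tot <- config$n_variables
  S <- matrix(0, k_tot + 1, k_tot + 1)
  pos <- 0L
  for (l in seq_len(config$n_groups)) {
    kl <- config$group_sizes[l]
    idx <- pos + seq_len(kl)
    S[idx, idx] <- config$group_correlations[l]
    diag(S)[idx] <- 1
    S[idx, k_tot + 1] <- config$group_covariances[l]
    S[k_tot + 1, idx] <- config$group_covariances[l]
    pos <- pos + kl
  }
  S[k_tot + 1, k_tot + 1] <- 1
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10)
    stop("joint correlation matrix is not PSD (smallest eigenvalue ",
         format(ev_min), "); residual variance of the latent response is ",
         format(config$residual_variance))
  S
}

#' Group-membership background matrix
#'
#' Encodes the simulated grouping as a binary background matrix: entry
#' `(l, k)` is 1 exactly when variable `k` belongs to group `l`. Every
#' column contains a single 1 (each variable belongs to one group).
#'
#' @param config a [sim_config()].
#' @return An `n_groups x n_variables` 0/1 matrix.
#' @export
encode_group_z <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  Z <- matrix(0, config$n_groups, config$n_variables)
  pos <- 0L
  for (l in seq_len(config$n_groups)) {
    Z[l, pos + seq_len(config$group_sizes[l])] <- 1
    pos <- pos + config$group_sizes[l]
  }
  rownames(Z) <- paste0("group", seq_len(config$n_groups))
  colnames(Z) <- paste0("x", seq_len(config$n_variables))
  Z
}

#' Draw a simulated (X, y, Z) dataset
#'
#' Samples `n_samples` i.i.d. draws of the joint Gaussian vector
#' `(x, y~)` defined by [build_joint_sigma()], binarises the latent
#' response by its sign into a -1/+1 class code, and attaches the
#' group-membership background matrix. The indices of the variables (and
#' groups) with non-zero response covariance — the ground truth a
#' selection method should recover — are returned alongside.
#'
#' @param config a [sim_config()].
#' @param seed seed for the draw; defaults to `config$seed`.
#' @return An object of class `"lpls_sim"`: list with `X`
#'   (`n_samples x K`), latent `y_latent`, binarised `y` (-1/+1), `Z`
#'   (`L x K` 0/1), `relevant_x`, `relevant_z` (index sets), and the
#'   `config`.
#' @export
sim_lpls_data <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  S <- build_joint_sigma(config)
  ## the closed-form PSD check in sim_config() guarantees chol works except
  ## exactly on the PSD boundary, where a symmetric square root is used
  R <- tryCatch(chol(S), error = function(e) {
    eg <- eigen(S, symmetric = TRUE)
    t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors)))
  })
  n <- config$n_samples
  k_tot <- config$n_variables
  H <- matrix(stats::rnorm(n * (k_tot + 1)), n) %*% R
  X <- H[, seq_len(k_tot), drop = FALSE]
  colnames(X) <- paste0("x", seq_len(k_tot))
  y_latent <- H[, k_tot + 1]
  y <- ifelse(y_latent >= 0, 1, -1)
  relevant_z <- which(config$group_covariances != 0)
  grp <- rep(seq_len(config$n_groups), config$group_sizes)
  structure(list(
    X = X, y = y, y_latent = y_latent, Z = encode_group_z(config),
    relevant_x = which(grp %in% relevant_z),
    relevant_z = relevant_z,
    config = config
  ), class = "lpls_sim")
}

#' @export
print.lpls_sim <- function(x, ...) {
  cat("Simulated three-block dataset\n")
  cat("  X:", nrow(x$X), "x", ncol(x$X), "  Z:", nrow(x$Z), "x", ncol(x$Z),
      "\n")
  cat("  relevant variables:", length(x$relevant_x), "of", ncol(x$X),
      " (groups ", paste(x$relevant_z, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Monte Carlo power analysis of the two-stage selection
#'
#' For each value of the mixing weight `alpha`, runs the two-stage
#' selection on `n_replicates` simulated datasets and reports the power
#' (mean fraction of truly relevant X variables that are selected) and the
#' false positive rate (mean fraction of irrelevant X variables selected).
#' One dataset is drawn per replicate and reused across the whole `alpha`
#' grid, so the comparison across `alpha` is paired. Group-level power is
#' also reported, both as "any member selected" and "majority of members
#' selected", since recovering annotated groups of variables is often the
#' quantity of interest.
#'
#' @param config a [sim_config()] describing the data-generating design.
#' @param alpha_grid mixing weights to profile (default
#'   `c(0, 0.3, 0.6, 0.9)`); `alpha = 0` is the no-background baseline.
#' @param u,f,d,ncomp,cv_folds selection parameters (see [lpls_select()]).
#'   By default the cutoff sits at its upper limit (`u = 10`) so that
#'   every variable is an elimination candidate and the amount of
#'   elimination is governed by the rejection level `d` alone, with
#'   `d = 0.80` (the gentlest conventional level) so the chosen models
#'   stay near the cross-validated optimum rather than maximally sparse.
#' @param n_replicates simulated datasets per `alpha` (default 50).
#' @param seed seed for the whole experiment.
#' @return A `data.frame` with one row per `alpha`: `power`, `fpr`,
#'   `group_power_any`, `group_power_majority`.
#' @export
power_analysis <- function(config, alpha_grid = c(0, 0.3, 0.6, 0.9),
                           u = 10, f = 0.5, d = 0.80, ncomp = 3,
                           cv_folds = 10, n_replicates = 50, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max,
                                 2L * n_replicates), ncol = 2)
  grp <- rep(seq_len(config$n_groups), config$group_sizes)
  power <- fpr <- g_any <- g_maj <- matrix(
    NA_real_, n_replicates, length(alpha_grid))
  for (r in seq_len(n_replicates)) {
    sim <- sim_lpls_data(config, seed = sub_seeds[r, 1])
    irrelevant <- setdiff(seq_len(ncol(sim$X)), sim$relevant_x)
    for (j in seq_along(alpha_grid)) {
      sel <- lpls_select(sim$y, sim$X, sim$Z, u = u, f = f, d = d,
                         alpha = alpha_grid[j], ncomp = ncomp,
                         cv_folds = cv_folds, seed = sub_seeds[r, 2])
      power[r, j] <- mean(sim$relevant_x %in% sel$selected_x)
      fpr[r, j] <- if (length(irrelevant))
        mean(irrelevant %in% sel$selected_x) else 0
      hit_frac <- vapply(sim$relevant_z, function(l)
        mean(which(grp == l) %in% sel$selected_x), numeric(1))
      g_any[r, j] <- mean(hit_frac > 0)
      g_maj[r, j] <- mean(hit_frac > 0.5)
    }
  }
  data.frame(
    alpha = alpha_grid,
    power = colMeans(power),
    fpr = colMeans(fpr),
    group_power_any = colMeans(g_any),
    group_power_majority = colMeans(g_maj)
  )
}
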