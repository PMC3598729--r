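#' Root mean square error
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length")
  sqrt(mean((y_true - y_pred)^2))
}

#' Repeated random test/training splits
#'
#' Draws `n_repeats` independent random partitions of the samples into a
#' held-out test set (a fraction `test_fraction` of the samples) and a
#' training set. Successive repeats are sampled independently, so their
#' test sets generally overlap partially. Repeated random splitting is the
#' outer level of the cross-model validation scheme; it is not recommended
#' for very small sample sizes, and a warning is issued below `min_n`.
#'
#' @param n_samples number of samples.
#' @param n_repeats number of repeated splits (default 10).
#' @param test_fraction share of samples held out per repeat (default 0.25).
#' @param seed optional seed; identical seeds give identical splits.
#' @param min_n sample-size floor below which a warning is issued
#'   (default 12).
#' @return A list of `n_repeats` lists, each with integer vectors `train`
#'   and `test` partitioning `1:n_samples`.
#' @export
make_splits <- function(n_samples, n_repeats = 10, test_fraction = 0.25,
                        seed = NULL, min_n = 12) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("'test_fraction' must lie strictly between 0 and 1")
  n_test <- round(n_samples * test_fraction)
  if (n_test < 1 || n_test >= n_samples)
    stop("degenerate split: ", n_test, " test samples out of ", n_samples)
  if (n_samples < min_n)
    warning("only ", n_samples, " samples; repeated splitting is ",
            "unreliable at this size, prefer predefined parameters")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    test <- sort(sample.int(n_samples, n_test))
    list(train = setdiff(seq_len(n_samples), test), test = test)
  })
}

# Cumulative coefficient paths: beta for every model size 1..A from a
# single A-component fit (used to price all component counts with one fit
# per cross-validation segment).
.beta_path <- function(fit) {
  A <- fit$ncomp
  vapply(seq_len(A), function(a) {
    s <- seq_len(a)
    PtW <- crossprod(fit$Px[, s, drop = FALSE], fit$Wx[, s, drop = FALSE])
    drop(fit$Wx[, s, drop = FALSE] %*% solve(PtW, fit$Py[s]))
  }, numeric(unname(fit$dims["k"])))
}

# Leave-one-out RMSE of plain L-PLS fits for every (alpha, ncomp) pair.
# Returns a matrix, rows = ncomp 1..a_max, cols = alpha values.
.loo_rmse_grid <- function(y, X, Z, alpha_grid, a_max) {
  n <- length(y)
  a_max <- min(a_max, n - 2L, ncol(X))
  err <- array(0, dim = c(a_max, length(alpha_grid), n))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    for (j in seq_along(alpha_grid)) {
      fit <- .lpls_safe(Xi, yi, Z, a_max, alpha_grid[j])
      bp <- .beta_path(fit)
      cs <- fit$centering
      xnew <- X[i, ]
      x00 <- xnew - cs$x_col_means - mean(xnew) + cs$x_grand_mean
      pred <- cs$y_mean + drop(crossprod(bp, x00))
      if (length(pred) < a_max) pred <- c(pred, rep(pred[length(pred)],
                                                    a_max - length(pred)))
      err[, j, i] <- (y[i] - pred)^2
    }
  }
  structure(sqrt(apply(err, c(1, 2), mean)),
            dimnames = list(seq_len(a_max), alpha_grid))
}

#' Tune L-PLS and elimination parameters by nested cross-validation
#'
#' Implements the two cross-validation levels used inside the training
#' data: first a leave-one-out cross-validation over the `(alpha, ncomp)`
#' grid of the plain L-PLS fit, then a `inner_folds`-fold cross-validation
#' of the full two-stage selection over the `(f, d)` grid, run at the
#' chosen `(alpha, ncomp)`. The elimination cutoff is fixed at the upper
#' limit `u_max`, so the amount of elimination is governed by the
#' rejection level `d` alone. Ties are broken parsimoniously: smaller
#' `ncomp` first, then smaller `alpha`; for `(f, d)` the first grid entry
#' among the minima is kept. All tuning uses only the data passed in, so
#' wrapping this in an outer test/training split yields a full
#' cross-model validation.
#'
#' @param y,X,Z the training blocks.
#' @param f_grid candidate step fractions (default `c(0.1, 0.5, 1)`).
#' @param d_grid candidate rejection levels
#'   (default `c(0.80, 0.90, 0.95, 0.99)`).
#' @param alpha_grid candidate mixing weights (default `seq(0, 1, 0.01)`).
#' @param a_max maximum number of components considered (default 10).
#' @param u_max VIP cutoff used during elimination (default 10).
#' @param inner_folds folds for the `(f, d)` level (default 10).
#' @param seed optional seed (fold construction).
#' @return A list with the selected `f`, `d`, `u`, `alpha`, `ncomp`, the
#'   leave-one-out RMSE grid (`loo_rmse`), and the `(f, d)` RMSE table
#'   (`fd_rmse`).
#' @export
lpls_tune <- function(y, X, Z, f_grid = c(0.1, 0.5, 1),
                      d_grid = c(0.80, 0.90, 0.95, 0.99),
                      alpha_grid = seq(0, 1, by = 0.01),
                      a_max = 10, u_max = 10, inner_folds = 10,
                      seed = NULL) {
  validate_blocks(y, X, Z)
  if (length(f_grid) < 1 || length(d_grid) < 1 || length(alpha_grid) < 1)
    stop("all tuning grids must be non-empty")
  if (any(f_grid <= 0 | f_grid > 1)) stop("'f_grid' values must be in (0, 1]")
  if (any(d_grid <= 0 | d_grid >= 1)) stop("'d_grid' values must be in (0, 1)")
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop("'alpha_grid' values must be in [0, 1]")
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  n <- length(y)
  if (inner_folds > n) stop("'inner_folds' exceeds the number of samples")
  if (!is.null(seed)) set.seed(seed)

  ## level: leave-one-out over (alpha, ncomp)
  loo <- .loo_rmse_grid(y, X, Z, alpha_grid, a_max)
  # grid ordered ncomp-major then alpha, so the first minimum is the most
  # parsimonious (smallest ncomp, then smallest alpha)
  flat <- as.vector(t(loo))                       # ncomp-major
  best <- which.min(flat) - 1L
  ncomp_best <- best %/% length(alpha_grid) + 1L
  alpha_best <- alpha_grid[best %% length(alpha_grid) + 1L]

  ## level: k-fold CV of the full two-stage selection over (f, d)
  folds <- .cv_folds(n, inner_folds)
  fd <- expand.grid(f = f_grid, d = d_grid)
  fd$rmse <- NA_real_
  for (r in seq_len(nrow(fd))) {
    res <- numeric(n)
    for (fold in folds) {
      sel <- lpls_select(y[-fold], X[-fold, , drop = FALSE], Z,
                         u = u_max, f = fd$f[r], d = fd$d[r],
                         alpha = alpha_best, ncomp = ncomp_best,
                         cv_folds = min(10, n - length(fold)))
      Xte <- X[fold, sel$selected_x, drop = FALSE]
      res[fold] <- y[fold] - predict(sel$model, Xte)
    }
    fd$rmse[r] <- sqrt(mean(res^2))
  }
  r_best <- which.min(fd$rmse)

  list(f = fd$f[r_best], d = fd$d[r_best], u = u_max,
       alpha = alpha_best, ncomp = ncomp_best,
       loo_rmse = loo, fd_rmse = fd)
}

#' Selectivity scores over repeated selections
#'
#' A variable selected as one of `m` variables in one data split earns a
#' score of `1/m` from that split; scores are summed over splits. Within
#' each split the scores over selected variables sum to exactly 1, so the
#' total score mass equals the number of (non-empty) splits. Variables
#' with large selectivity scores are repeatedly selected among few — the
#' stable core of the selection.
#'
#' @param selections list of integer vectors, one per split, each the
#'   selected variable indices in that split.
#' @param n_variables total number of variables scores are defined over.
#' @return Numeric vector of length `n_variables` of accumulated scores,
#'   with attribute `"n_splits"` (number of non-empty splits counted).
#' @export
selectivity <- function(selections, n_variables) {
  scores <- numeric(n_variables)
  n_used <- 0L
  for (sel in selections) {
    if (length(sel) == 0) {
      warning("a split selected no variables; it contributes no score")
      next
    }
    if (any(sel < 1 | sel > n_variables))
      stop("selected index outside 1..n_variables")
    scores[sel] <- scores[sel] + 1 / length(sel)
    n_used <- n_used + 1L
  }
  attr(scores, "n_splits") <- n_used
  scores
}

#' Repeated-split selection stability
#'
#' Runs the two-stage selection once per repeated random test/training
#' split (selection sees only the training samples; the full background
#' block is used throughout) and accumulates selectivity scores for the X
#' variables and the Z rows, together with the held-out test RMSE of each
#' split's final model.
#'
#' @param y,X,Z the data blocks.
#' @param n_repeats,test_fraction,seed passed to [make_splits()].
#' @param u,f,d,alpha,ncomp,cv_folds passed to [lpls_select()].
#' @return An object of class `"lpls_stability"`: list with `splits`,
#'   per-split `selections_x` / `selections_z`, selectivity `score_x` /
#'   `score_z`, and `test_rmse`.
#' @export
lpls_stability <- function(y, X, Z, n_repeats = 10, test_fraction = 0.25,
                           u = 1, f = 0.5, d = 0.95, alpha = 0.5,
                           ncomp = 2, cv_folds = 10, seed = NULL) {
  validate_blocks(y, X, Z)
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  if (!is.null(seed)) set.seed(seed)
  splits <- make_splits(length(y), n_repeats, test_fraction)
  sel_x <- vector("list", n_repeats)
  sel_z <- vector("list", n_repeats)
  test_rmse <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    sel <- lpls_select(y[tr], X[tr, , drop = FALSE], Z,
                       u = u, f = f, d = d, alpha = alpha, ncomp = ncomp,
                       cv_folds = min(cv_folds, length(tr)))
    sel_x[[r]] <- sel$selected_x
    sel_z[[r]] <- sel$selected_z
    pred <- predict(sel$model, X[te, sel$selected_x, drop = FALSE])
    test_rmse[r] <- rmse(y[te], pred)
  }
  structure(list(
    splits = splits,
    selections_x = sel_x, selections_z = sel_z,
    score_x = selectivity(sel_x, ncol(X)),
    score_z = selectivity(sel_z, nrow(Z)),
    test_rmse = test_rmse
  ), class = "lpls_stability")
}

#' @export
print.lpls_stability <- function(x, ...) {
  cat("Repeated-split L-PLS selection (", length(x$splits), " splits)\n",
      sep = "")
  cat("  mean held-out RMSE:", format(mean(x$test_rmse), digits = 4), "\n")
  top <- order(x$score_x, decreasing = TRUE)[seq_len(min(5, length(x$score_x)))]
  cat("  top X selectivity scores:",
      paste0(top, " (", format(x$score_x[top], digits = 3), ")",
             collapse = ", "), "\n")
  invisible(x)
}

#' Permutation null for selectivity scores
#'
#' Repeats the full repeated-split selection pipeline with the response
#' randomly permuted before each run, pooling the resulting per-variable
#' selectivity scores into null distributions for X variables and Z rows.
#' The returned thresholds are quantiles of the pooled null scores;
#' observed scores above them are unlikely under "no genotype-phenotype
#' association".
#'
#' @inheritParams lpls_stability
#' @param n_permutations number of permuted-response pipeline runs
#'   (default 100).
#' @param prob quantile used for the significance threshold (default 0.95).
#' @return A list with matrices `null_x` (`n_permutations` x K) and
#'   `null_z` (`n_permutations` x L) of null scores, and scalar
#'   `threshold_x`, `threshold_z` at quantile `prob`.
#' @export
permutation_null <- function(y, X, Z, n_repeats = 10, test_fraction = 0.25,
                             u = 1, f = 0.5, d = 0.95, alpha = 0.5,
                             ncomp = 2, cv_folds = 10,
                             n_permutations = 100, prob = 0.95,
                             seed = NULL) {
  if (n_permutations < 1) stop("'n_permutations' must be at least 1")
  validate_blocks(y, X, Z)
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_permutations)
  null_x <- matrix(0, n_permutations, ncol(X))
  null_z <- matrix(0, n_permutations, nrow(Z))
  for (b in seq_len(n_permutations)) {
    set.seed(sub_seeds[b])
    y_b <- sample(y)
    st <- lpls_stability(y_b, X, Z, n_repeats = n_repeats,
                         test_fraction = test_fraction, u = u, f = f, d = d,
                         alpha = alpha, ncomp = ncomp, cv_folds = cv_folds)
    null_x[b, ] <- st$score_x
    null_z[b, ] <- st$score_z
  }
  list(null_x = null_x, null_z = null_z,
       threshold_x = unname(stats::quantile(null_x, prob)),
       threshold_z = unname(stats::quantile(null_z, prob)),
       prob = prob)
}
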