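## Two-stage stepwise regularized backward elimination.
##
## Stage 1 ranks the columns of X by VIP_X and iteratively removes the worst
## ones (which removes the matching columns of Z as well, since X and Z must
## describe the same variables). Stage 2 then ranks the rows of the reduced
## Z by VIP_Z and eliminates background variables the same way. Each
## iteration records a cross-validated RMSE; a rejection level d finally
## trades error against sparsity via a paired t-test on held-out residuals.

# k-fold partition of 1:n, sizes as equal as possible.
.cv_folds <- function(n, k) {
  k <- max(2L, min(as.integer(k), n))
  idx <- sample.int(n)
  split(idx, rep_len(seq_len(k), n))
}

# Fit lpls, backing off on ncomp when the data cannot support the requested
# number of components (small active sets late in an elimination).
.lpls_safe <- function(X, y, Z, ncomp, alpha) {
  a_max <- min(ncomp, nrow(X) - 1L, ncol(X))
  for (a in rev(seq_len(a_max))) {
    fit <- tryCatch(lpls(X, y, Z, ncomp = a, alpha = alpha),
                    error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
  }
  stop("L-PLS fit failed even with a single component: ",
       conditionMessage(fit))
}

# Held-out residuals over a fixed fold partition. Returns a length-n vector
# in sample order.
.cv_residuals <- function(y, X, Z, folds, ncomp, alpha) {
  res <- numeric(length(y))
  for (fold in folds) {
    fit <- .lpls_safe(X[-fold, , drop = FALSE], y[-fold], Z, ncomp, alpha)
    res[fold] <- y[fold] - predict(fit, X[fold, , drop = FALSE])
  }
  res
}

#' One stage of VIP-based stepwise backward elimination
#'
#' Repeatedly fits a cross-validated L-PLS model on the active variables,
#' ranks them with the stage's VIP criterion, and eliminates the worst. At
#' each iteration the number of VIP values strictly below the cutoff `u` is
#' `M`; if `M = 0` the elimination terminates, otherwise the
#' `S = ceiling(f * M)` variables with the smallest VIP are removed (ties
#' broken by original index). In stage 1 the active variables are columns
#' of `X`, and removing column k drops column k of `Z` too; in stage 2 they
#' are rows of `Z`, with `X` held fixed. The trace stops when at most one
#' variable would remain.
#'
#' @param y,X,Z the data blocks (see [lpls()]).
#' @param stage `1` to eliminate X columns with [vip_x()], `2` to eliminate
#'   Z rows with [vip_z()].
#' @param u VIP cutoff; only variables with VIP `< u` are candidates.
#' @param f step fraction in `(0, 1]`; the share of below-cutoff variables
#'   removed per iteration.
#' @param alpha,ncomp L-PLS parameters used for every refit (`ncomp` is
#'   capped automatically when the active set becomes small).
#' @param cv_folds folds for the per-iteration cross-validated RMSE.
#' @param folds optional pre-built fold partition (list of index vectors);
#'   when supplied it overrides `cv_folds` and is reused across iterations,
#'   which is what makes the later paired model comparison valid.
#' @param seed optional seed for fold construction.
#' @return An object of class `"lpls_trace"`: a list with `stage`,
#'   `folds`, and `iterations`, each iteration holding the active index
#'   set, its VIP values, `M`, `S` (number actually eliminated), the
#'   cross-validated RMSE `E_g`, the held-out residual vector, and
#'   (after [choose_model()]) a p-value against the optimum.
#' @export
lpls_eliminate <- function(y, X, Z, stage = 1, u = 1, f = 0.5,
                           alpha = 0.5, ncomp = 2, cv_folds = 10,
                           folds = NULL, seed = NULL) {
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) stop("'stage' must be 1 or 2")
  if (!is.numeric(f) || f <= 0 || f > 1) stop("'f' must lie in (0, 1]")
  if (!is.numeric(u) || u < 0) stop("'u' must be non-negative")
  validate_blocks(y, X, Z)
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- .cv_folds(length(y), cv_folds)

  p_total <- if (stage == 1L) ncol(X) else nrow(Z)
  active <- seq_len(p_total)
  iterations <- list()

  repeat {
    if (stage == 1L) {
      Xg <- X[, active, drop = FALSE]
      Zg <- Z[, active, drop = FALSE]
    } else {
      Xg <- X
      Zg <- Z[active, , drop = FALSE]
    }
    fit <- .lpls_safe(Xg, y, Zg, ncomp, alpha)
    ## a background block that is constant across the surviving columns
    ## row-centers to zero and cannot be ranked; the stage then terminates
    ## with the current active set
    vip <- if (stage == 1L) vip_x(fit) else
      tryCatch(suppressWarnings(vip_z(fit)), error = function(e) NULL)
    res <- .cv_residuals(y, Xg, Zg, folds, ncomp, alpha)
    e_g <- sqrt(mean(res^2))

    if (is.null(vip)) {
      iterations[[length(iterations) + 1L]] <- list(
        active = active, vip = rep(NA_real_, length(active)),
        M = 0L, S = 0L, E_g = e_g, cv_residuals = res, p_value = NA_real_
      )
      break
    }

    m <- sum(vip < u)
    s_raw <- if (m > 0) ceiling(f * m) else 0L
    ## the double-centering makes a 1-column X (and a 1-row Z) identically
    ## zero, so a model needs at least 2 active variables: cap the step so
    ## the trace never goes below that floor
    s <- min(s_raw, length(active) - 2L)
    s <- max(s, 0L)

    iterations[[length(iterations) + 1L]] <- list(
      active = active, vip = vip, M = m, S = s,
      E_g = e_g, cv_residuals = res, p_value = NA_real_
    )

    if (m == 0L || s == 0L) break
    ord <- order(vip, seq_along(active))   # ascending VIP, index tie-break
    active <- sort(active[-ord[seq_len(s)]])
  }

  structure(list(stage = stage, folds = folds, u = u, f = f,
                 alpha = alpha, ncomp = ncomp,
                 iterations = iterations,
                 optimum_index = NA_integer_, chosen_index = NA_integer_),
            class = "lpls_trace")
}

#' Pick a model from an elimination trace at rejection level d
#'
#' Locates the iteration with the minimal cross-validated RMSE (the optimum
#' `E*`), then, for every sparser (later) iteration, runs a paired
#' two-sided t-test between that iteration's and the optimum's held-out
#' squared residuals (the same cross-validation folds were used throughout
#' the trace, so the pairing is by sample). The chosen model is the
#' sparsest iteration whose p-value exceeds `1 - d`, i.e. whose error is
#' not significantly worse than the optimum at level `1 - d`. Larger `d`
#' therefore buys sparser models.
#'
#' @param trace an `"lpls_trace"` from [lpls_eliminate()].
#' @param d rejection level in `(0, 1)`; conventional choices are 0.80,
#'   0.90, 0.95, 0.99.
#' @return The input trace with `p_value` filled in for post-optimum
#'   iterations (1 at the optimum by convention), and `optimum_index` /
#'   `chosen_index` set.
#' @export
choose_model <- function(trace, d = 0.95) {
  if (!inherits(trace, "lpls_trace")) stop("'trace' must be an \"lpls_trace\"")
  if (!is.numeric(d) || d <= 0 || d >= 1) stop("'d' must lie in (0, 1)")
  g_n <- length(trace$iterations)
  if (g_n < 1L) stop("empty elimination trace")
  e <- vapply(trace$iterations, `[[`, numeric(1), "E_g")
  opt <- which.min(e)
  trace$iterations[[opt]]$p_value <- 1
  chosen <- opt
  if (opt < g_n) {
    sq_opt <- trace$iterations[[opt]]$cv_residuals^2
    for (g in seq(opt + 1L, g_n)) {
      sq_g <- trace$iterations[[g]]$cv_residuals^2
      dif <- sq_g - sq_opt
      p <- if (all(abs(dif) < 1e-14)) 1 else
        stats::t.test(sq_g, sq_opt, paired = TRUE)$p.value
      trace$iterations[[g]]$p_value <- p
    }
    ok <- which(vapply(trace$iterations, `[[`, numeric(1), "p_value") > 1 - d)
    chosen <- max(ok)
  }
  trace$optimum_index <- opt
  trace$chosen_index <- chosen
  trace
}

#' @export
print.lpls_trace <- function(x, ...) {
  cat("L-PLS elimination trace (stage ", x$stage, ", ",
      length(x$iterations), " iterations)\n", sep = "")
  df <- as.data.frame(x, long = FALSE)
  print(df, row.names = FALSE)
  if (!is.na(x$chosen_index))
    cat("optimum: iteration", x$optimum_index,
        " chosen:", x$chosen_index, "\n")
  invisible(x)
}

#' Tidy view of an elimination trace
#'
#' @param x an `"lpls_trace"`.
#' @param row.names,optional ignored (S3 signature).
#' @param long if `TRUE`, one row per (iteration, variable) with its VIP
#'   and an eliminated flag; if `FALSE`, one summary row per iteration.
#' @param ... unused.
#' @return A `data.frame`.
#' @export
as.data.frame.lpls_trace <- function(x, row.names = NULL, optional = FALSE,
                                     long = TRUE, ...) {
  its <- x$iterations
  if (!long) {
    return(data.frame(
      iteration = seq_along(its),
      stage = x$stage,
      n_active = vapply(its, function(i) length(i$active), integer(1)),
      M = vapply(its, `[[`, integer(1), "M"),
      S = vapply(its, function(i) as.integer(i$S), integer(1)),
      E_g = vapply(its, `[[`, numeric(1), "E_g"),
      p_value = vapply(its, `[[`, numeric(1), "p_value")
    ))
  }
  do.call(rbind, lapply(seq_along(its), function(g) {
    it <- its[[g]]
    nxt <- if (g < length(its)) its[[g + 1L]]$active else it$active
    data.frame(
      iteration = g, stage = x$stage, variable = it$active,
      vip = unname(it$vip),
      eliminated = g < length(its) & !(it$active %in% nxt),
      E_g = it$E_g, p_value = it$p_value
    )
  }))
}

#' Two-stage variable selection by regularized elimination
#'
#' Runs stage 1 (elimination of X columns, dropping the matching Z
#' columns), picks a model at rejection level `d`, then runs stage 2
#' (elimination of Z rows on the reduced blocks) and picks again. The same
#' cross-validation folds are used throughout so that model comparisons
#' are paired. A final L-PLS model is refitted on the surviving blocks.
#'
#' @inheritParams lpls_eliminate
#' @param d rejection level passed to [choose_model()] for both stages.
#' @param seed optional seed controlling fold construction.
#' @return An object of class `"lpls_selection"`: a list with
#'   `selected_x` (indices of retained X columns), `selected_z` (indices
#'   of retained Z rows), the two annotated traces, the refitted final
#'   `model`, `final_rmse` (the chosen stage-2 iteration's cross-validated
#'   RMSE), and the tuning parameters used.
#' @examples
#' sim <- sim_lpls_data(sim_config(group_sizes = rep(4, 4),
#'   group_correlations = c(0.5, 0.5, 0, 0),
#'   group_covariances = c(0.4, -0.4, 0, 0),
#'   n_samples = 40, seed = 7))
#' sel <- lpls_select(sim$y, sim$X, sim$Z, u = 1, f = 0.5, d = 0.95,
#'                    alpha = 0.5, ncomp = 2, cv_folds = 5, seed = 1)
#' sel$selected_x
#' @export
lpls_select <- function(y, X, Z, u = 1, f = 0.5, d = 0.95, alpha = 0.5,
                        ncomp = 2, cv_folds = 10, seed = NULL) {
  validate_blocks(y, X, Z)
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  if (!is.null(seed)) set.seed(seed)
  folds <- .cv_folds(length(y), cv_folds)

  trace1 <- lpls_eliminate(y, X, Z, stage = 1, u = u, f = f, alpha = alpha,
                           ncomp = ncomp, folds = folds)
  trace1 <- choose_model(trace1, d)
  selected_x <- trace1$iterations[[trace1$chosen_index]]$active
  if (length(selected_x) < 1L)
    stop("stage 1 left no surviving X variables; inspect the trace")

  X2 <- X[, selected_x, drop = FALSE]
  Z2 <- Z[, selected_x, drop = FALSE]

  trace2 <- lpls_eliminate(y, X2, Z2, stage = 2, u = u, f = f, alpha = alpha,
                           ncomp = ncomp, folds = folds)
  trace2 <- choose_model(trace2, d)
  selected_z <- trace2$iterations[[trace2$chosen_index]]$active
  if (length(selected_z) < 1L)
    stop("stage 2 left no surviving Z rows; inspect the trace")

  final <- .lpls_safe(X2, y, Z2[selected_z, , drop = FALSE], ncomp, alpha)

  structure(list(
    selected_x = selected_x,
    selected_z = selected_z,
    trace_x = trace1, trace_z = trace2,
    model = final,
    final_rmse = trace2$iterations[[trace2$chosen_index]]$E_g,
    tuned = list(u = u, f = f, d = d, alpha = alpha, ncomp = ncomp)
  ), class = "lpls_selection")
}

#' @export
print.lpls_selection <- function(x, ...) {
  cat("Two-stage L-PLS variable selection\n")
  cat("  retained X variables:", length(x$selected_x),
      " retained Z rows:", length(x$selected_z), "\n")
  cat("  parameters: u =", x$tuned$u, " f =", x$tuned$f, " d =", x$tuned$d,
      " alpha =", x$tuned$alpha, " components =", x$tuned$ncomp, "\n")
  cat("  cross-validated RMSE of chosen model:",
      format(x$final_rmse, digits = 4), "\n")
  invisible(x)
}
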