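## NIPALS-style component extraction for the three-block layout.
## With a single response the latent directions have a closed form, so no
## inner iteration is required: the X-driven direction is proportional to
## X'y and the Z-informed direction is that direction projected through the
## row space of Z. An optional refinement loop (refine = TRUE) re-projects
## the mixed weight through Z until the direction stabilises.

# Relative tolerance used to declare a vector numerically zero.
.zero_tol <- function(M) 1e-12 * max(1, norm(as.matrix(M), "F"))

# Latent v-vectors for the current (deflated) blocks.
# Returns unit-norm vx2 (proportional to Xa' ya, sign-fixed so its first
# non-zero entry is positive) and unit-norm vz1 (proportional to
# Za' (Za vx2)); vz1 is the zero vector when Z carries no signal in that
# direction.
.vvectors <- function(ya, Xa, Za) {
  v <- drop(crossprod(Xa, ya))
  nv <- sqrt(sum(v^2))
  if (nv <= .zero_tol(Xa) * max(1, sqrt(sum(ya^2)))) {
    stop("no extractable component: X'y is numerically zero ",
         "(the number of components may be too large for these data)")
  }
  v <- v / nv
  j <- which(abs(v) > 1e-12)[1]
  if (v[j] < 0) v <- -v
  u <- drop(crossprod(Za, drop(Za %*% v)))
  nu <- sqrt(sum(u^2))
  if (nu <= 1e-12 * max(1, sum(Za^2))) {
    u <- numeric(length(v))
  } else {
    u <- u / nu
  }
  list(vx2 = v, vz1 = u)
}

# Mix the Z-informed and X-driven directions and renormalise (unit norm).
.combine_weights <- function(vz1, vx2, alpha) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  w <- alpha * vz1 + (1 - alpha) * vx2
  nw <- sqrt(sum(w^2))
  if (nw <= 1e-12) {
    stop("degenerate weight direction: alpha * vz1 + (1 - alpha) * vx2 ",
         "is numerically zero")
  }
  w / nw
}

#' Fit a three-block L-PLS regression
#'
#' Extracts `ncomp` latent components relating a single response `y` to a
#' predictor matrix `X`, with a background matrix `Z` (rows are annotation
#' variables describing the columns of `X`) steering the component weights.
#' The mixing parameter `alpha` sets the influence of `Z`: `alpha = 0`
#' reduces exactly to ordinary univariate NIPALS PLS on the double-centered
#' data (the background block is then provably inert), while `alpha = 1`
#' uses only the Z-informed direction.
#'
#' For each component the X-driven direction `vx2` (proportional to
#' `X'y`) and the Z-informed direction `vz1` (its projection through the
#' row space of `Z`) are mixed as `w = alpha * vz1 + (1 - alpha) * vx2`
#' and renormalised. X-scores are `t = X w`; the weights themselves serve
#' as the scores for `Z`. Loadings are least-squares projections on the
#' scores, after which all three blocks are deflated by their rank-one
#' reconstructions. Regression coefficients on the centered scale are
#' assembled as `W (P'W)^{-1} p_y`.
#'
#' @param X numeric predictor matrix, N samples x K variables.
#' @param y numeric response vector of length N (continuous or -1/+1).
#' @param Z numeric background matrix, L x K.
#' @param ncomp number of latent components A, `1 <= A <= min(N - 1, K)`.
#' @param alpha mixing weight in `[0, 1]` for the background information.
#' @param refine logical; if `TRUE`, iterate the weight extraction
#'   (re-projecting the mixed weight through `Z`) until the direction
#'   changes by less than `1e-10`.
#' @return An object of class `"lpls"`: a list with the weight matrix `Wx`
#'   (K x A, unit-norm columns), scores `Tx` (N x A) and `Tz` (= `Wx`),
#'   loadings `Py` (length A), `Px` (K x A), `Pz` (L x A), the raw latent
#'   directions `vx2`/`vz1`, coefficients `beta` (length K, centered
#'   scale), the centering statistics, fitted values and residuals on the
#'   original response scale, and the call.
#' @seealso [coef.lpls()], [predict.lpls()], [vip_x()], [lpls_select()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X[, 1] - X[, 3] + rnorm(10, sd = 0.1)
#' Z <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
#' fit <- lpls(X, y, Z, ncomp = 2, alpha = 0.5)
#' coef(fit)
#' @export
lpls <- function(X, y, Z, ncomp = 2L, alpha = 0.5, refine = FALSE) {
  dims <- validate_blocks(y, X, Z)
  n <- dims$n; k <- dims$k; l <- dims$l
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, k)) {
    stop("'ncomp' must lie in 1..min(N - 1, K) = 1..", min(n - 1, k))
  }
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)

  cen <- lpls_center(y, X, Z)
  ya <- cen$y0; Xa <- cen$X00; Za <- cen$Z0

  Wx <- matrix(0, k, ncomp)
  Tx <- matrix(0, n, ncomp)
  Py <- numeric(ncomp)
  Px <- matrix(0, k, ncomp)
  Pz <- matrix(0, l, ncomp)
  Vx2 <- matrix(0, k, ncomp)
  Vz1 <- matrix(0, k, ncomp)

  for (a in seq_len(ncomp)) {
    vv <- tryCatch(.vvectors(ya, Xa, Za), error = function(e) e)
    if (inherits(vv, "error")) {
      stop("component extraction failed at component ", a,
           "; the largest achievable number of components is ", a - 1,
           " (", conditionMessage(vv), ")")
    }
    w <- .combine_weights(vv$vz1, vv$vx2, alpha)
    if (refine && alpha > 0) {
      for (it in seq_len(100)) {
        u <- drop(crossprod(Za, drop(Za %*% w)))
        nu <- sqrt(sum(u^2))
        if (nu <= 1e-12 * max(1, sum(Za^2))) break
        w_new <- .combine_weights(u / nu, vv$vx2, alpha)
        if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; break }
        w <- w_new
      }
    }
    tx <- drop(Xa %*% w)
    tt <- sum(tx^2)
    if (tt <= .zero_tol(Xa)^2) {
      stop("component extraction failed at component ", a,
           "; the largest achievable number of components is ", a - 1,
           " (X-score collapsed to zero)")
    }
    py <- sum(ya * tx) / tt
    px <- drop(crossprod(Xa, tx)) / tt
    pz <- drop(Za %*% w)        # t_z = w has unit norm

    ya <- ya - tx * py
    Xa <- Xa - tcrossprod(tx, px)
    Za <- Za - tcrossprod(pz, w)

    Wx[, a] <- w; Tx[, a] <- tx; Py[a] <- py
    Px[, a] <- px; Pz[, a] <- pz
    Vx2[, a] <- vv$vx2; Vz1[, a] <- vv$vz1
  }

  PtW <- crossprod(Px, Wx)
  beta <- tryCatch(drop(Wx %*% solve(PtW, Py)), error = function(e) {
    stop("P_x' W_x is numerically singular; reduce 'ncomp' (",
         conditionMessage(e), ")")
  })
  fitted <- cen$stats$y_mean + drop(cen$X00 %*% beta)

  structure(list(
    Wx = Wx, Tx = Tx, Tz = Wx, Py = Py, Px = Px, Pz = Pz,
    vx2 = Vx2, vz1 = Vz1,
    beta = beta, alpha = alpha, ncomp = ncomp,
    centering = cen$stats,
    fitted.values = fitted, residuals = y - fitted, y = y,
    dims = c(n = n, k = k, l = l),
    var_names = colnames(X), z_names = rownames(Z),
    call = match.call()
  ), class = "lpls")
}

#' Regression coefficients of an L-PLS fit
#'
#' Returns the coefficient vector on the centered predictor scale,
#' `beta = W_x (P_x' W_x)^{-1} p_y`, optionally truncated to the first
#' `ncomp` components.
#'
#' @param object an `"lpls"` fit.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return Numeric vector of length K.
#' @export
coef.lpls <- function(object, ncomp = object$ncomp, ...) {
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > object$ncomp)
    stop("'ncomp' must lie in 1..", object$ncomp)
  if (ncomp == object$ncomp) {
    b <- object$beta
  } else {
    a <- seq_len(ncomp)
    PtW <- crossprod(object$Px[, a, drop = FALSE],
                     object$Wx[, a, drop = FALSE])
    b <- drop(object$Wx[, a, drop = FALSE] %*% solve(PtW, object$Py[a]))
  }
  names(b) <- object$var_names
  b
}

#' Predict from an L-PLS fit
#'
#' New rows are centered with the convention used in training: the training
#' column means and grand mean, together with each new row's own row mean,
#' are removed before applying the coefficients; the training response mean
#' is added back.
#'
#' @param object an `"lpls"` fit.
#' @param newdata numeric matrix (M x K) or vector (length K) of new
#'   samples; must have the training number of columns.
#' @param ncomp number of components to use.
#' @param ... unused.
#' @return Numeric vector of length M of predicted responses.
#' @export
predict.lpls <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (missing(newdata)) return(fitted(object))
  if (is.vector(newdata) && !is.list(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  k <- unname(object$dims["k"])
  if (ncol(newdata) != k) {
    stop("'newdata' has ", ncol(newdata), " columns but the model was ",
         "fitted with ", k)
  }
  cs <- object$centering
  X00 <- newdata - rep(cs$x_col_means, each = nrow(newdata)) -
    rowMeans(newdata) + cs$x_grand_mean
  drop(cs$y_mean + X00 %*% coef(object, ncomp = ncomp))
}

#' @export
fitted.lpls <- function(object, ...) object$fitted.values

#' @export
residuals.lpls <- function(object, ...) object$residuals

#' @export
print.lpls <- function(x, ...) {
  cat("Three-block L-PLS regression\n")
  cat("  samples:", x$dims["n"], " X variables:", x$dims["k"],
      " Z rows:", x$dims["l"], "\n")
  cat("  components:", x$ncomp, "  alpha:", format(x$alpha), "\n")
  cat("  in-sample RMSE:", format(sqrt(mean(x$residuals^2)), digits = 4), "\n")
  invisible(x)
}

#' Summarize an L-PLS fit
#'
#' Reports the fraction of response variance captured cumulatively by the
#' components and the in-sample RMSE at each model size.
#'
#' @param object an `"lpls"` fit.
#' @param ... unused.
#' @return An object of class `"summary.lpls"`.
#' @export
summary.lpls <- function(object, ...) {
  ssy <- sum((object$y - mean(object$y))^2)
  ss_comp <- object$Py^2 * colSums(object$Tx^2)
  rmse_a <- vapply(seq_len(object$ncomp), function(a) {
    yhat <- object$centering$y_mean +
      drop(object$Tx[, seq_len(a), drop = FALSE] %*% object$Py[seq_len(a)])
    sqrt(mean((object$y - yhat)^2))
  }, numeric(1))
  structure(list(
    fit = object,
    explained = cumsum(ss_comp) / ssy,
    rmse = rmse_a
  ), class = "summary.lpls")
}

#' @export
print.summary.lpls <- function(x, ...) {
  print(x$fit)
  tab <- data.frame(
    ncomp = seq_along(x$rmse),
    `cumulative R2(y)` = round(x$explained, 4),
    RMSE = round(x$rmse, 4),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Score plot for an L-PLS fit
#'
#' Plots the first two X-score vectors (or the single score against the
#' response when only one component was fitted), with points keyed by the
#' sign of the response.
#'
#' @param x an `"lpls"` fit.
#' @param comps length-2 integer vector of components to display.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.lpls <- function(x, comps = c(1, 2), ...) {
  pch <- ifelse(x$y >= mean(x$y), 19, 1)
  if (x$ncomp == 1 || length(comps) < 2) {
    graphics::plot(x$Tx[, 1], x$y, xlab = "t1", ylab = "y", pch = pch, ...)
  } else {
    graphics::plot(x$Tx[, comps[1]], x$Tx[, comps[2]],
                   xlab = paste0("t", comps[1]), ylab = paste0("t", comps[2]),
                   pch = pch, ...)
    graphics::abline(h = 0, v = 0, col = "grey", lty = 3)
  }
  invisible(x)
}
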