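# Centering, component extraction, fitting, coefficients and prediction.

test_that("centering removes the declared means from every block", {
  X <- matrix(c(1, 3, 2, 5), 2, 2)
  cen <- lpls_center(c(1, -1), X, matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(cen$X00, matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2))
  expect_equal(cen$Z0, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  expect_equal(sum(cen$y0), 0)

  # constant X double-centers to zero
  cen2 <- lpls_center(c(2, 1, 0), matrix(7, 3, 4), matrix(1, 2, 4))
  expect_true(all(cen2$X00 == 0))

  # row/column sums vanish and the grand mean ties the margins together
  set.seed(4)
  tri <- rand_triple(11, 7, 3)
  cen3 <- lpls_center(tri$y, tri$X, tri$Z)
  expect_equal(colSums(cen3$X00), rep(0, 7), tolerance = 1e-12)
  expect_equal(rowSums(cen3$X00), rep(0, 11), tolerance = 1e-12)
  expect_equal(rowSums(cen3$Z0), rep(0, 3), tolerance = 1e-12)
  expect_equal(cen3$stats$x_grand_mean, mean(cen3$stats$x_col_means))
  expect_equal(cen3$stats$x_grand_mean, mean(cen3$stats$x_row_means))

  # against the definition written out element by element
  ref <- ref_center(tri$y, tri$X)
  expect_equal(cen3$X00, ref$X00, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("block validation rejects malformed input by name", {
  X <- matrix(rnorm(12), 4, 3)
  Z <- matrix(1, 2, 3)
  expect_error(lpls_center(c(1, 2, 3), X, Z), "'y'")
  expect_error(lpls_center(rnorm(4), X, matrix(1, 2, 4)), "'Z'")
  Xna <- X; Xna[2, 2] <- NA
  expect_error(lpls_center(rnorm(4), Xna, Z), "missing values.*'X'")
  expect_error(lpls_center(rnorm(1), X[1, , drop = FALSE], Z), "2 samples")
})

test_that("latent directions follow X'y and its projection through Z", {
  # identity Z'Z leaves the X-driven direction untouched
  Xa <- matrix(c(1, -1, 0, 0), 2, 2)
  ya <- c(1, -1)
  vv <- lplsr:::.vvectors(ya, Xa, diag(2))
  expect_equal(vv$vx2, c(1, 0))
  expect_equal(vv$vz1, c(1, 0))

  # orthogonal response has no extractable component
  expect_error(lplsr:::.vvectors(c(1, 1), Xa, diag(2)), "no extractable")

  # a Z with empty row space gives a zero vz1
  vv0 <- lplsr:::.vvectors(ya, Xa, matrix(0, 1, 2))
  expect_equal(vv0$vz1, c(0, 0))
})

test_that("weight mixing interpolates between the two directions", {
  vx <- c(0, 1); vz <- c(1, 0)
  expect_equal(lplsr:::.combine_weights(vz, vx, 0), vx)
  expect_equal(lplsr:::.combine_weights(vz, vx, 1), vz)
  expect_equal(lplsr:::.combine_weights(vz, vx, 0.5),
               c(1, 1) / sqrt(2))
  expect_error(lplsr:::.combine_weights(-vx, vx, 0.5), "degenerate")
})

test_that("alpha = 0 reproduces ordinary NIPALS PLS and Z is inert", {
  for (seed in 1:5) {
    tri <- rand_triple(15, 12, 4, seed = seed)
    for (A in c(1, 3)) {
      fit <- lpls(tri$X, tri$y, tri$Z, ncomp = A, alpha = 0)
      cen <- ref_center(tri$y, tri$X)
      ref <- ref_pls1(cen$X00, cen$y0, A)
      expect_equal(fit$beta, ref$beta, tolerance = 1e-8)
      expect_equal(fit$Wx, ref$W, tolerance = 1e-8)
      expect_equal(fit$Tx, ref$T, tolerance = 1e-8)
      expect_equal(fit$Px, ref$P, tolerance = 1e-8)
      expect_equal(fit$Py, ref$q, tolerance = 1e-8)
      # a different Z must not change anything at alpha = 0
      Z2 <- matrix(rnorm(3 * 12), 3, 12)
      fit2 <- lpls(tri$X, tri$y, Z2, ncomp = A, alpha = 0)
      expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)
    }
  }
})

test_that("fitted values, orthogonality and deflation identities hold for all alpha", {
  # at alpha = 1 every component consumes one rank of the row-centered Z,
  # so Z needs at least ncomp + 1 rows there
  for (alpha in c(0, 0.4, 1)) {
    tri <- rand_triple(18, 10, 6, seed = 7 + round(10 * alpha))
    fit <- lpls(tri$X, tri$y, tri$Z, ncomp = 4, alpha = alpha)
    cen <- lpls_center(tri$y, tri$X, tri$Z)
    # fitted-value identity
    expect_equal(drop(cen$X00 %*% fit$beta),
                 drop(fit$Tx %*% fit$Py), tolerance = 1e-8)
    # pairwise score orthogonality
    G <- crossprod(fit$Tx)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
    # unit-norm weights, Tz == Wx
    expect_equal(colSums(fit$Wx^2), rep(1, 4), tolerance = 1e-12)
    expect_identical(fit$Tz, fit$Wx)
    # residual orthogonality after deflation: rebuild residual blocks
    Xa <- cen$X00; ya <- cen$y0
    for (a in 1:4) {
      Xa <- Xa - tcrossprod(fit$Tx[, a], fit$Px[, a])
      ya <- ya - fit$Tx[, a] * fit$Py[a]
      expect_lt(max(abs(crossprod(Xa, fit$Tx[, a]))), 1e-8)
      expect_lt(abs(sum(ya * fit$Tx[, a])), 1e-8)
    }
  }
})

test_that("a noiseless rank-one problem is solved by a single component", {
  set.seed(9)
  t0 <- rnorm(12)
  w0 <- rnorm(6); w0 <- w0 / sqrt(sum(w0^2))
  X <- tcrossprod(t0, w0)
  y <- 2 * t0
  Z <- matrix(rbinom(18, 1, 0.5), 3, 6)
  fit <- lpls(X, y, Z, ncomp = 1, alpha = 0)
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-10)
})

test_that("in-sample RMSE is non-increasing in the number of components", {
  tri <- rand_triple(20, 15, 4, seed = 21)
  for (alpha in c(0, 0.6)) {
    fit <- lpls(tri$X, tri$y, tri$Z, ncomp = 6, alpha = alpha)
    expect_true(all(diff(summary(fit)$rmse) <= 1e-10))
  }
})

test_that("column permutations permute coefficients and preserve fits", {
  tri <- rand_triple(16, 9, 3, seed = 33)
  fit <- lpls(tri$X, tri$y, tri$Z, ncomp = 3, alpha = 0.5)
  perm <- sample(9)
  fitp <- lpls(tri$X[, perm], tri$y, tri$Z[, perm], ncomp = 3, alpha = 0.5)
  expect_equal(fitp$beta, fit$beta[perm], tolerance = 1e-10)
  expect_equal(fitted(fitp), fitted(fit), tolerance = 1e-10)
})

test_that("coefficients satisfy the component-wise reconstruction", {
  set.seed(10)
  tri <- rand_triple(10, 6, 3)
  fit <- lpls(tri$X, tri$y, tri$Z, ncomp = 3, alpha = 0.3)
  cen <- lpls_center(tri$y, tri$X, tri$Z)
  expect_equal(drop(cen$X00 %*% coef(fit)),
               drop(fit$Tx %*% fit$Py), tolerance = 1e-8)
  # A = 1: beta reduces to w * py / (px' w)
  fit1 <- lpls(tri$X, tri$y, tri$Z, ncomp = 1, alpha = 0.3)
  expect_equal(unname(coef(fit1)),
               fit1$Wx[, 1] * fit1$Py[1] / sum(fit1$Px[, 1] * fit1$Wx[, 1]),
               tolerance = 1e-12)
  # a centered-to-zero response gives zero coefficients
  fit0 <- tryCatch(lpls(tri$X, rep(5, 10), tri$Z, ncomp = 1), error = identity)
  expect_true(inherits(fit0, "error"))  # X'y0 = 0: no component exists
})

test_that("prediction reproduces training fits and is deterministic", {
  tri <- rand_triple(14, 8, 3, seed = 5)
  fit <- lpls(tri$X, tri$y, tri$Z, ncomp = 3, alpha = 0.7)
  expect_equal(predict(fit, tri$X), fitted(fit), tolerance = 1e-10)
  xnew <- tri$X[3, , drop = FALSE]
  expect_identical(predict(fit, xnew), predict(fit, xnew))
  expect_equal(predict(fit, rbind(xnew, xnew)),
               rep(predict(fit, xnew), 2))
  expect_error(predict(fit, tri$X[, 1:5]), "columns")
  # constant new sample: only the training column means contribute
  p_const <- predict(fit, rep(3, 8))
  cs <- fit$centering
  x00 <- -cs$x_col_means + mean(cs$x_col_means)
  expect_equal(p_const, unname(cs$y_mean + sum(x00 * coef(fit))),
               tolerance = 1e-10)
})

test_that("component overrun is reported with the achievable count", {
  # one informative direction only: the second component has nothing left
  set.seed(2)
  t0 <- rnorm(10)
  X <- tcrossprod(t0, c(3, 4) / 5)
  err <- tryCatch(lpls(X, t0, diag(2), ncomp = 2, alpha = 0),
                  error = identity)
  expect_match(conditionMessage(err), "largest achievable")
  expect_match(conditionMessage(err), "1")
})
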