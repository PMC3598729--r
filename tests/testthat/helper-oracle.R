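# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain textbook formulas, loop-based.

# Textbook univariate NIPALS PLS1 on data that is ALREADY centered.
# Signs follow the same convention as the package (first non-zero entry of
# each weight vector positive) so scores/loadings are directly comparable.
ref_pls1 <- function(X0, y0, ncomp) {
  Xa <- X0
  ya <- y0
  W <- matrix(0, ncol(X0), ncomp)
  Tt <- matrix(0, nrow(X0), ncomp)
  P <- matrix(0, ncol(X0), ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(t(Xa) %*% ya)
    w <- w / sqrt(sum(w^2))
    j <- which(abs(w) > 1e-12)[1]
    if (w[j] < 0) w <- -w
    tt <- drop(Xa %*% w)
    ss <- sum(tt^2)
    p <- drop(t(Xa) %*% tt) / ss
    qa <- sum(ya * tt) / ss
    Xa <- Xa - tt %*% t(p)
    ya <- ya - tt * qa
    W[, a] <- w; Tt[, a] <- tt; P[, a] <- p; q[a] <- qa
  }
  beta <- drop(W %*% solve(t(P) %*% W) %*% q)
  list(W = W, T = Tt, P = P, q = q, beta = beta)
}

# Double centering written out directly from the definition.
ref_center <- function(y, X) {
  n <- nrow(X); k <- ncol(X)
  X00 <- matrix(0, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    X00[i, j] <- X[i, j] - mean(X[, j]) - mean(X[i, ]) + mean(X)
  }
  list(y0 = y - mean(y), X00 = X00)
}

# Naive double-loop VIP evaluation from a fitted lpls object.
ref_vip_x <- function(fit) {
  A <- fit$ncomp
  K <- nrow(fit$Wx)
  ss <- numeric(A)
  for (a in seq_len(A)) ss[a] <- fit$Py[a]^2 * sum(fit$Tx[, a]^2)
  out <- numeric(K)
  for (k in seq_len(K)) {
    acc <- 0
    for (a in seq_len(A)) {
      wn <- sqrt(sum(fit$Wx[, a]^2))
      acc <- acc + ss[a] * (fit$Wx[k, a] / wn)^2
    }
    out[k] <- sqrt(K * acc / sum(ss))
  }
  out
}

ref_vip_z <- function(fit) {
  A <- fit$ncomp
  L <- nrow(fit$Pz)
  ss <- numeric(A)
  for (a in seq_len(A)) ss[a] <- fit$Py[a]^2 * sum(fit$Tx[, a]^2)
  out <- numeric(L)
  for (l in seq_len(L)) {
    acc <- 0
    for (a in seq_len(A)) {
      pn <- sqrt(sum(fit$Pz[, a]^2))
      acc <- acc + ss[a] * (fit$Pz[l, a] / pn)^2
    }
    out[l] <- sqrt(L * acc / sum(ss))
  }
  out
}

# Random test triple: Gaussian X, y correlated with the first columns,
# binary-membership Z.
rand_triple <- function(n = 20, k = 50, l = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  y <- drop(X[, seq_len(min(3, k)), drop = FALSE] %*%
              seq_len(min(3, k))) + rnorm(n)
  grp <- rep_len(seq_len(l), k)
  Z <- matrix(0, l, k)
  Z[cbind(grp, seq_len(k))] <- 1
  list(y = y, X = X, Z = Z)
}

# Small simulation design used when a cheap informative dataset is needed.
small_config <- function(n = 50, seed = NULL) {
  sim_config(group_sizes = rep(5, 8),
             group_correlations = c(0.5, 0.5, 0.5, 0.2, rep(0, 4)),
             group_covariances = c(0.35, -0.3, 0.25, 0.2, rep(0, 4)),
             n_samples = n, seed = seed)
}
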