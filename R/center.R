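#' Validate a (y, X, Z) data triple
#'
#' Checks the dimensional contract of the three-block layout: the response
#' `y` has one entry per row of the predictor matrix `X`, and the background
#' matrix `Z` describes the columns of `X`, so `X` and `Z` must share their
#' column count. Missing values are rejected outright; no imputation is
#' attempted.
#'
#' @param y numeric response vector, length N (continuous or -1/+1 coded).
#' @param X numeric predictor matrix, N x K.
#' @param Z numeric background matrix, L x K (typically 0/1 annotation
#'   membership).
#' @return Invisibly, a list with `n`, `k`, `l`.
#' @keywords internal
validate_blocks <- function(y, X, Z) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  if (anyNA(y)) stop("missing values in block 'y' are not allowed")
  if (anyNA(X)) stop("missing values in block 'X' are not allowed")
  if (anyNA(Z)) stop("missing values in block 'Z' are not allowed")
  if (!is.numeric(X)) stop("block 'X' must be numeric")
  if (!is.numeric(Z)) stop("block 'Z' must be numeric")
  n <- nrow(X); k <- ncol(X); l <- nrow(Z)
  if (length(y) != n)
    stop("block 'y' has length ", length(y), " but block 'X' has ", n, " rows")
  if (ncol(Z) != k)
    stop("block 'Z' has ", ncol(Z), " columns but block 'X' has ", k,
         " (they must describe the same variables)")
  if (n < 2) stop("block 'X' needs at least 2 samples (rows)")
  if (k < 1) stop("block 'X' needs at least 1 variable (column)")
  if (l < 1) stop("block 'Z' needs at least 1 row")
  invisible(list(n = n, k = k, l = l))
}

#' Center the three blocks for L-PLS
#'
#' The response is mean-centered, the predictor matrix is double-centered
#' (row, column and grand mean removed, so every row and every column of the
#' result sums to zero), and the background matrix is centered within each of
#' its rows. All means are returned so centering can be re-applied to new
#' samples at prediction time.
#'
#' @inheritParams validate_blocks
#' @return A list with components
#'   \item{y0}{centered response,}
#'   \item{X00}{double-centered predictor matrix,}
#'   \item{Z0}{row-centered background matrix,}
#'   \item{stats}{list of the removed means: `y_mean`, `x_col_means`
#'     (length K), `x_row_means` (length N), `x_grand_mean`, `z_row_means`
#'     (length L).}
#' @examples
#' cen <- lpls_center(c(1, -1), matrix(c(1, 3, 2, 5), 2), diag(2))
#' colSums(cen$X00)  # zero
#' rowSums(cen$X00)  # zero
#' @export
lpls_center <- function(y, X, Z) {
  validate_blocks(y, X, Z)
  y <- as.numeric(y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  y_mean <- mean(y)
  x_col <- colMeans(X)
  x_row <- rowMeans(X)
  x_grand <- mean(X)
  z_row <- rowMeans(Z)
  X00 <- X - rep(x_col, each = nrow(X)) - x_row + x_grand
  Z0 <- Z - z_row
  list(
    y0 = y - y_mean,
    X00 = X00,
    Z0 = Z0,
    stats = list(y_mean = y_mean, x_col_means = x_col, x_row_means = x_row,
                 x_grand_mean = x_grand, z_row_means = z_row)
  )
}
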