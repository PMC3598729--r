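#' Variable importance on projection for X columns
#'
#' Computes the VIP score of every predictor column from a fitted L-PLS
#' model. Each component contributes its squared (unit-norm) weight entry,
#' weighted by the share of response variance that component explains:
#' \deqn{VIP_{Xk} = \sqrt{K \sum_a SS_a (w_{ak}/\|w_a\|)^2 / \sum_a SS_a}}
#' with \eqn{SS_a = p_{ya}^2 \, t_a' t_a}. The scores are normalised so
#' that the sum of squared VIPs equals the number of variables; the
#' conventional "VIP < 1" reading (below-average importance) applies.
#'
#' @param model an `"lpls"` fit.
#' @return Numeric vector of length K of non-negative importance scores.
#' @seealso [vip_z()], [lpls_eliminate()]
#' @export
vip_x <- function(model) {
  if (!inherits(model, "lpls")) stop("'model' must be an \"lpls\" fit")
  k <- unname(model$dims["k"])
  ss <- model$Py^2 * colSums(model$Tx^2)
  if (all(ss <= 0)) {
    stop("the model explains no response variance; VIP is undefined")
  }
  wn <- sqrt(colSums(model$Wx^2))      # unit by construction
  W2 <- sweep(model$Wx, 2, wn, "/")^2
  v <- sqrt(k * drop(W2 %*% ss) / sum(ss))
  names(v) <- model$var_names
  v
}

#' Variable importance on projection for Z rows
#'
#' The analogue of [vip_x()] for the rows of the background matrix. The
#' per-component coordinate of a background row is taken from the Z-loading
#' vector (normalised to unit length per component), weighted by the same
#' explained-variance shares. A component whose Z-loading is entirely zero
#' carries no background signal and contributes nothing (with a warning);
#' if that holds for all components the VIP is undefined.
#'
#' @param model an `"lpls"` fit.
#' @return Numeric vector of length L of non-negative importance scores;
#'   the sum of squares equals L.
#' @export
vip_z <- function(model) {
  if (!inherits(model, "lpls")) stop("'model' must be an \"lpls\" fit")
  l <- unname(model$dims["l"])
  ss <- model$Py^2 * colSums(model$Tx^2)
  if (all(ss <= 0)) {
    stop("the model explains no response variance; VIP is undefined")
  }
  pn <- sqrt(colSums(model$Pz^2))
  live <- pn > 1e-12 * max(1, max(pn))
  if (!any(live)) {
    stop("all Z-loadings are zero: the background block carries no signal")
  }
  if (!all(live)) {
    warning(sum(!live), " component(s) have zero Z-loadings and ",
            "contribute nothing to VIP_Z")
  }
  P2 <- sweep(model$Pz[, live, drop = FALSE], 2, pn[live], "/")^2
  v <- sqrt(l * drop(P2 %*% ss[live]) / sum(ss[live]))
  names(v) <- model$z_names
  v
}
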