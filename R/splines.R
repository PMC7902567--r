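#' Restricted cubic spline basis (truncated-power construction)
#'
#' Builds the Harrell-style restricted cubic spline basis for a continuous
#' covariate: a linear term plus `k - 2` nonlinear terms, constrained so that
#' the fitted function is linear beyond the boundary knots. With `k` knots the
#' basis has `k - 1` columns.
#'
#' The j-th nonlinear column (j = 1, ..., k-2) is
#' \deqn{B_j(x) = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3 \, (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 \, (t_{k-1}-t_j)/(t_k-t_{k-1})}{(t_k-t_1)^2}}
#' which vanishes for \eqn{x \le t_1} and is linear for \eqn{x \ge t_k}; the
#' divisor keeps the nonlinear columns on the scale of the linear term.
#'
#' @param x numeric vector (finite values).
#' @param knots strictly increasing numeric vector of at least 3 knot
#'   positions on the scale of `x`.
#' @return numeric matrix with `length(knots) - 1` columns named
#'   `"x'"`, `"x''"`, ... ; attribute `"knots"` carries the knots used.
#' @examples
#' b <- rcs_basis(seq(0, 10, 0.5), knots = c(1, 5, 9))
#' ncol(b)  # 2
#' @export
rcs_basis <- function(x, knots) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric", call. = FALSE)
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  if (k < 3 || anyDuplicated(knots))
    stop("restricted cubic splines need >= 3 distinct knots; ",
         "use the raw linear term instead", call. = FALSE)
  t1 <- knots[1]; tk1 <- knots[k - 1]; tk <- knots[k]
  norm2 <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(out) <- paste0("x", strrep("'", seq_len(k - 1)))
  attr(out, "knots") <- knots
  out
}

#' Default knot positions for a restricted cubic spline
#'
#' Places knots at fixed sample quantiles of the covariate, the standard
#' convention when positions are not prespecified. For `k = 3` the knots sit
#' at the 10th, 50th and 90th percentiles; for larger `k` the outer knots sit
#' at the 5th/95th percentiles with the rest equally spaced in probability.
#'
#' @param x numeric vector with enough distinct values.
#' @param k number of knots (>= 3), default 3.
#' @return numeric vector of `k` strictly increasing knot positions.
#' @examples
#' default_knots(1:100)  # c(10.9, 50.5, 90.1)
#' @export
default_knots <- function(x, k = 3) {
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  x <- x[is.finite(x)]
  probs <- if (k == 3) c(0.10, 0.50, 0.90) else seq(0.05, 0.95, length.out = k)
  kn <- unname(stats::quantile(x, probs, type = 7))
  if (anyDuplicated(kn))
    stop("ties in `x` give non-distinct knots; try fewer knots", call. = FALSE)
  kn
}
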