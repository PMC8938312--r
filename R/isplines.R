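#' I-spline (integrated M-spline) basis on [0, 1]
#'
#' Monotone regression basis: each basis function is non-decreasing, equals
#' 0 at `x = 0` and 1 at `x = 1`. Built as reversed cumulative sums of a
#' B-spline basis of degree `degree` on the augmented knot vector, which is
#' the standard identity linking I-splines of order `degree` to B-splines
#' one order higher. With `degree = 2` and one interior knot there are
#' three basis functions per predictor.
#'
#' @param x numeric vector with values in `[0, 1]`; values beyond the
#'   interval by more than 1e-9 are an error, closer ones are clipped with
#'   a warning.
#' @param degree spline order of the underlying M-splines (default 2, i.e.
#'   piecewise-quadratic I-splines).
#' @param interior_knots numeric vector of interior knot positions in
#'   (0, 1) (default 0.5). The number of basis functions is
#'   `degree + length(interior_knots)`.
#' @return Matrix with `length(x)` rows and `degree + length(interior_knots)`
#'   columns; attribute `knots` records the interior knots.
#' @export
ispline_basis <- function(x, degree = 2, interior_knots = 0.5) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  if (any(x < -1e-9) || any(x > 1 + 1e-9))
    stop("x must lie in [0, 1]", call. = FALSE)
  if (any(x < 0 | x > 1)) {
    warning("clipping x values within 1e-9 of [0, 1]", call. = FALSE)
    x <- pmin(pmax(x, 0), 1)
  }
  interior_knots <- sort(interior_knots)
  if (length(interior_knots) &&
      (any(interior_knots <= 0) || any(interior_knots >= 1)))
    stop("interior knots must lie strictly inside (0, 1)", call. = FALSE)
  ord <- degree + 1L  # B-spline order one above the M-spline order
  knots <- c(rep(0, ord), interior_knots, rep(1, ord))
  B <- splines::splineDesign(knots, x, ord = ord, outer.ok = FALSE)
  p <- ncol(B)
  # tail sums of the B-spline basis: T_j = sum_{m >= j} B_m; T_1 == 1,
  # T_2..T_p are the monotone I-splines running 0 -> 1
  Tmat <- t(apply(B, 1, function(r) rev(cumsum(rev(r)))))
  if (length(x) == 1L) Tmat <- matrix(Tmat, nrow = 1)
  out <- Tmat[, -1, drop = FALSE]
  colnames(out) <- paste0("I", seq_len(p - 1))
  attr(out, "knots") <- interior_knots
  attr(out, "degree") <- degree
  out
}
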