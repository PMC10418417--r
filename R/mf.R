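#' Triangular membership function
#'
#' Builds a triangular fuzzy membership curve from its three abscissae: left
#' foot `a`, peak `b`, right foot `c`. The usual shoulder conventions apply:
#' when `a == b` the left side is a shoulder (full membership for `x <= b`),
#' and when `b == c` the right side is a shoulder (full membership for
#' `x >= b`). Shoulders are how the extreme "low" and "high" terms of a
#' linguistic variable keep full membership at the edges of its domain.
#'
#' @param a,b,c Numeric scalars with `a <= b <= c`, in the units of the
#'   variable the function describes.
#'
#' @return An object of class `tri_mf`.
#' @examples
#' low <- tri_mf(0, 0, 400)
#' mf_degree(low, 13.7)
#' @export
tri_mf <- function(a, b, c) {
  if (!all(is.finite(c(a, b, c)))) {
    abort("membership function parameters must be finite numbers",
          class = "aquafis_config_error")
  }
  if (a == c) {
    abort("degenerate membership function: a == b == c has empty support",
          class = "aquafis_config_error")
  }
  if (a > b || b > c) {
    abort(sprintf(
      "malformed membership function: need a <= b <= c, got (%g, %g, %g)",
      a, b, c), class = "aquafis_config_error")
  }
  structure(list(a = a, b = b, c = c), class = "tri_mf")
}

#' @export
print.tri_mf <- function(x, ...) {
  cat(sprintf("<tri_mf (%g, %g, %g)>\n", x$a, x$b, x$c))
  invisible(x)
}

#' Membership degree under a triangular fuzzy set
#'
#' Piecewise-linear interpolation between the feet and the peak, clamped to
#' \[0, 1\]. Points outside the support get degree 0; `x` may lie anywhere on
#' the real line. Vectorised over `x`.
#'
#' @param mf A [tri_mf()] (or a length-3 numeric `(a, b, c)`).
#' @param x Numeric vector of crisp values, in the variable's units.
#'
#' @return Numeric vector of degrees in \[0, 1\], same length as `x`.
#' @export
mf_degree <- function(mf, x) {
  if (!inherits(mf, "tri_mf")) mf <- tri_mf(mf[[1]], mf[[2]], mf[[3]])
  # A shoulder side saturates: only the sloped side constrains the degree.
  up <- if (mf$a == mf$b) 1 else (x - mf$a) / (mf$b - mf$a)
  dn <- if (mf$b == mf$c) 1 else (mf$c - x) / (mf$c - mf$b)
  pmin(pmax(pmin(up, dn), 0), 1)
}

# Sampled curve of one MF, for export and plotting.
mf_curve <- function(mf, from, to, n = 201) {
  x <- seq(from, to, length.out = n)
  tibble(x = x, degree = mf_degree(mf, x))
}
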