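#' Sensitivity surface of a fuzzy model
#'
#' Sweeps two input variables over their domains on an `n` by `n` grid while
#' holding the third input fixed, scoring every grid point. This mirrors the
#' surface-viewer exploration of how two parameters jointly drive the score.
#'
#' @param fis A [wq_fis()] with three inputs.
#' @param x,y Names of the two inputs to sweep.
#' @param fixed Value for the remaining input (named or bare).
#' @param n Grid size per axis (>= 2).
#' @param method Defuzzification method.
#' @param resolution Universe resolution (defaults to the model's).
#'
#' @return A long tibble with the two swept coordinates and `score`.
#' @examples
#' wq_surface(wq_submodel("FWQ2"), "ca", "mg", fixed = 0.0118, n = 5)
#' @export
wq_surface <- function(fis, x, y, fixed, n = 25, method = "centroid",
                       resolution = NULL) {
  stopifnot(inherits(fis, "wq_fis"), n >= 2)
  vars <- names(fis$inputs)
  for (v in c(x, y)) {
    if (!v %in% vars) {
      abort(sprintf("unknown input variable '%s' (model has: %s)", v,
                    paste(vars, collapse = ", ")),
            class = "aquafis_eval_error")
    }
  }
  if (x == y) abort("x and y must name different inputs",
                    class = "aquafis_eval_error")
  zvar <- setdiff(vars, c(x, y))
  fixed <- unname(fixed)
  grid <- tidyr::expand_grid(
    !!x := seq(fis$inputs[[x]]$domain[1], fis$inputs[[x]]$domain[2],
               length.out = n),
    !!y := seq(fis$inputs[[y]]$domain[1], fis$inputs[[y]]$domain[2],
               length.out = n))
  grid$score <- purrr::map2_dbl(grid[[x]], grid[[y]], function(xi, yi) {
    fis_eval(fis, setNames(c(xi, yi, fixed), c(x, y, zvar)),
             method = method, resolution = resolution)
  })
  grid
}

#' Plot a sensitivity surface as a filled raster
#'
#' @param grid Output of [wq_surface()].
#' @return A ggplot.
#' @export
plot_wq_surface <- function(grid) {
  nms <- names(grid)[1:2]
  ggplot2::ggplot(grid, ggplot2::aes(.data[[nms[1]]], .data[[nms[2]]],
                                     fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(fill = "quality (%)") +
    ggplot2::theme_minimal()
}
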