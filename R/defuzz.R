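#' Aggregate fired rules into one output fuzzy set
#'
#' Mamdani max aggregation with clipping implication: the aggregate's
#' membership at each point of the discretised output universe is the maximum
#' over fired rules of `min(strength, consequent degree)`. An empty rule list
#' yields a degenerate all-zero set, which [defuzzify()] refuses to collapse.
#'
#' @param fired Tibble from [fire_rules()] (columns `then`, `strength`).
#' @param output The output [lvar()].
#' @param resolution Number of uniformly spaced universe points (>= 2).
#'
#' @return A `wq_agg`: list with `universe`, `membership`, `resolution` and
#'   the output variable's name.
#' @export
fuzzy_aggregate <- function(fired, output, resolution = 1001) {
  stopifnot(inherits(output, "wq_lvar"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2) {
    abort("resolution must be at least 2", class = "aquafis_config_error")
  }
  bad <- setdiff(fired$then, output$terms$term)
  if (length(bad)) {
    abort(sprintf("fired consequent '%s' is not a term of '%s'",
                  bad[1], output$name), class = "aquafis_eval_error")
  }
  u <- seq(output$domain[1], output$domain[2], length.out = resolution)
  mu <- rep(0, resolution)
  for (i in seq_len(nrow(fired))) {
    mu <- pmax(mu, pmin(fired$strength[i],
                        mf_degree(output$mfs[[fired$then[i]]], u)))
  }
  structure(list(universe = u, membership = mu, resolution = resolution,
                 output = output$name),
            class = "wq_agg")
}

#' Defuzzify an aggregated fuzzy set
#'
#' Collapses the output fuzzy set to a crisp value by one of five methods:
#' \describe{
#'   \item{centroid}{Centre of area, \eqn{\int x f(x) dx / \int f(x) dx},
#'     by trapezoidal quadrature on the sampled universe.}
#'   \item{bisector}{The abscissa splitting the area under the curve into two
#'     equal halves.}
#'   \item{mom, som, lom}{Mean, smallest and largest of the maximising set:
#'     all universe points whose degree is within `plateau_tol` of the
#'     maximum.}
#' }
#'
#' @param agg A [fuzzy_aggregate()] result.
#' @param method Defuzzification method.
#' @param plateau_tol Degrees within this distance of the maximum count as
#'   maximising (guards against floating-point near-ties on flat tops).
#'
#' @return A crisp value within the output universe.
#' @export
defuzzify <- function(agg, method = c("centroid", "bisector", "mom", "som", "lom"),
                      plateau_tol = 1e-6) {
  stopifnot(inherits(agg, "wq_agg"))
  method <- match.arg(method)
  u <- agg$universe
  mu <- agg$membership
  if (max(mu) <= 0) {
    abort("no rule fired: aggregated membership is zero everywhere",
          class = "aquafis_empty_aggregate")
  }
  if (method == "centroid") {
    return(pracma::trapz(u, mu * u) / pracma::trapz(u, mu))
  }
  if (method == "bisector") {
    A <- pracma::cumtrapz(u, mu)[, 1]
    half <- A[length(A)] / 2
    i <- which(A >= half)[1]
    if (i == 1) return(u[1])
    # linear interpolation inside the crossing cell
    return(u[i - 1] + (half - A[i - 1]) / (A[i] - A[i - 1]) * (u[i] - u[i - 1]))
  }
  idx <- which(mu >= max(mu) - plateau_tol)
  switch(method,
         som = u[min(idx)],
         lom = u[max(idx)],
         mom = mean(u[idx]))
}

#' @export
print.wq_agg <- function(x, ...) {
  cat(sprintf("<wq_agg on '%s' [%g, %g], %d points, max degree %.3f>\n",
              x$output, min(x$universe), max(x$universe), x$resolution,
              max(x$membership)))
  invisible(x)
}

#' @export
as_tibble.wq_agg <- function(x, ...) {
  tibble(x = x$universe, degree = x$membership)
}

#' Plot an aggregated output fuzzy set
#'
#' Draws the post-aggregation membership curve; optionally marks the crisp
#' values obtained by each requested defuzzifier.
#'
#' @param object A `wq_agg`.
#' @param methods Defuzzifiers to mark as vertical lines (NULL for none).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wq_agg <- function(object, methods = c("centroid", "mom"), ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$degree)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = object$output, y = "membership degree") +
    ggplot2::theme_minimal()
  if (length(methods)) {
    marks <- tibble(method = methods,
                    value = vapply(methods, function(m) defuzzify(object, m),
                                   numeric(1)))
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, linetype = .data$method),
      colour = "grey25")
  }
  p
}
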