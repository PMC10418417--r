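#' Linguistic variable
#'
#' A measured quantity described by labelled fuzzy terms over a closed domain.
#' Each term carries a triangular membership function and optional quality
#' points (0 = poor, 1 = moderate, 2 = good) used when rule bases are derived
#' automatically (see [default_rules()]).
#'
#' @param name Variable name (e.g. `"alkalinity"`).
#' @param domain Length-2 numeric `c(lo, hi)` closed interval of valid values.
#' @param terms A data frame with columns `term` (label), `a`, `b`, `c`
#'   (membership feet/peak) and optionally `quality` (integer 0/1/2).
#' @param units Measurement units; `"mg/L"` for concentrations, `""` for pH,
#'   `"%"` for quality scores.
#'
#' @details Construction validates that every membership function is well
#' formed (`a <= b <= c`), that feet and peaks lie within the domain, that
#' term labels are unique, and that the terms cover the domain (every point
#' has positive membership in at least one term).
#'
#' @return An object of class `wq_lvar`.
#' @examples
#' ph <- lvar("pH", c(0, 14), tibble::tribble(
#'   ~term,     ~a,  ~b,   ~c, ~quality,
#'   "low",      0,   0,    7, 0L,
#'   "medium", 5.5, 7.5,  9.5, 2L,
#'   "high",     7,  14,   14, 1L), units = "")
#' fuzzify(ph, 7.4)
#' @export
lvar <- function(name, domain, terms, units = "mg/L") {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(domain), length(domain) == 2, domain[1] < domain[2])
  terms <- as_tibble(terms)
  if (!all(c("term", "a", "b", "c") %in% names(terms))) {
    abort("`terms` needs columns term, a, b, c", class = "aquafis_config_error")
  }
  if (!"quality" %in% names(terms)) terms$quality <- NA_integer_
  terms <- terms[c("term", "a", "b", "c", "quality")]
  if (anyDuplicated(terms$term)) {
    abort(sprintf("duplicate term labels in variable '%s'", name),
          class = "aquafis_config_error")
  }
  mfs <- purrr::pmap(terms[c("a", "b", "c")], tri_mf)
  feet <- c(terms$a, terms$c)
  if (any(feet < domain[1] - 1e-9) || any(feet > domain[2] + 1e-9)) {
    abort(sprintf("term support outside domain for variable '%s'", name),
          class = "aquafis_config_error")
  }
  # coverage: every domain point must belong to at least one term
  grid <- seq(domain[1], domain[2], length.out = 512)
  degmax <- purrr::reduce(purrr::map(mfs, mf_degree, x = grid), pmax)
  if (any(degmax <= 0)) {
    abort(sprintf("terms of variable '%s' do not cover its domain", name),
          class = "aquafis_config_error")
  }
  structure(list(name = name, units = units, domain = as.numeric(domain),
                 terms = terms, mfs = setNames(mfs, terms$term)),
            class = "wq_lvar")
}

#' @export
print.wq_lvar <- function(x, ...) {
  cat(sprintf("<wq_lvar '%s'%s on [%g, %g], %d terms: %s>\n",
              x$name, if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              x$domain[1], x$domain[2], nrow(x$terms),
              paste(x$terms$term, collapse = ", ")))
  invisible(x)
}

#' Fuzzify a crisp measurement
#'
#' Maps a single crisp value to its membership degree in every term of a
#' linguistic variable. Values outside the variable's domain are rejected
#' (not silently clamped); pass `clamp = TRUE` to truncate them to the domain
#' with a warning.
#'
#' @param var A [lvar()].
#' @param x A single numeric value in the variable's units.
#' @param clamp Clamp out-of-domain values instead of erroring?
#'
#' @return Named numeric vector of degrees, one per term.
#' @export
fuzzify <- function(var, x, clamp = FALSE) {
  stopifnot(inherits(var, "wq_lvar"), is.numeric(x), length(x) == 1)
  if (is.na(x)) {
    abort(sprintf("missing value for variable '%s'", var$name),
          class = "aquafis_domain_error")
  }
  if (x < var$domain[1] || x > var$domain[2]) {
    if (!clamp) {
      abort(sprintf("%s = %g is outside its domain [%g, %g]",
                    var$name, x, var$domain[1], var$domain[2]),
            class = "aquafis_domain_error")
    }
    xc <- min(max(x, var$domain[1]), var$domain[2])
    warn(sprintf("clamping %s = %g to %g", var$name, x, xc),
         class = "aquafis_clamped")
    x <- xc
  }
  vapply(var$mfs, mf_degree, numeric(1), x = x)
}

#' Sample the membership curves of a variable
#'
#' Long-format curves suitable for plotting or for export as a two-column
#' (per term) tabular file.
#'
#' @param var A [lvar()].
#' @param n Number of sample points across the domain.
#' @return A tibble with columns `variable`, `term`, `x`, `degree`.
#' @export
membership_curves <- function(var, n = 201) {
  stopifnot(inherits(var, "wq_lvar"))
  purrr::map2_dfr(var$terms$term, var$mfs, function(label, mf) {
    dplyr::mutate(mf_curve(mf, var$domain[1], var$domain[2], n),
                  variable = var$name, term = label, .before = 1)
  })
}

#' @describeIn lvar Tidy the term table of a variable.
#' @param x A `wq_lvar`.
#' @param ... Unused.
#' @export
tidy.wq_lvar <- function(x, ...) {
  dplyr::mutate(x$terms, variable = x$name, units = x$units,
                domain_lo = x$domain[1], domain_hi = x$domain[2], .before = 1)
}

#' Plot membership functions of a linguistic variable
#'
#' @param object A [lvar()].
#' @param n Sample points per curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wq_lvar <- function(object, n = 201, ...) {
  df <- membership_curves(object, n)
  df$term <- factor(df$term, levels = object$terms$term)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$degree, colour = .data$term)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = if (nzchar(object$units))
                        sprintf("%s (%s)", object$name, object$units)
                      else object$name,
                  y = "membership degree", colour = "term") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
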