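#' Mamdani fuzzy inference model
#'
#' Bundles input variables, an output variable and a complete rule base into
#' an evaluable model. Inference is the classic Mamdani pipeline: fuzzify the
#' crisp inputs, fire every rule with min implication, aggregate the clipped
#' consequents with max, then defuzzify.
#'
#' @param name Model name, e.g. `"FWQ1"`.
#' @param inputs List of input [lvar()]s.
#' @param output Output [lvar()].
#' @param rules A [wq_rules()] table; defaults to the quality-point scheme of
#'   [default_rules()].
#' @param resolution Default universe resolution for aggregation.
#'
#' @return An object of class `wq_fis`.
#' @export
wq_fis <- function(name, inputs, output, rules = default_rules(inputs, output),
                   resolution = 1001) {
  stopifnot(is.character(name), length(name) == 1)
  inputs <- setNames(inputs, vapply(inputs, function(v) v$name, character(1)))
  rules <- wq_rules(inputs, output, rules)  # revalidate against these variables
  structure(list(name = name, inputs = inputs, output = output,
                 rules = rules, resolution = as.integer(resolution)),
            class = "wq_fis")
}

#' @export
print.wq_fis <- function(x, ...) {
  cat(sprintf("<wq_fis '%s': %s -> %s; %d rules, resolution %d>\n",
              x$name, paste(names(x$inputs), collapse = " + "),
              x$output$name, nrow(x$rules), x$resolution))
  invisible(x)
}

#' Evaluate a fuzzy model at one crisp input vector
#'
#' @param fis A [wq_fis()] model.
#' @param x Numeric values for the inputs, either named after the input
#'   variables or positional in the model's input order.
#' @param method Defuzzification method (see [defuzzify()]).
#' @param resolution Universe resolution; defaults to the model's.
#' @param clamp Clamp out-of-domain inputs instead of erroring?
#' @param detail Return the intermediate stages instead of just the score?
#'
#' @return The crisp output value; or, with `detail = TRUE`, a list with
#'   `fuzzified`, `fired`, `aggregate` and `value`.
#' @examples
#' fis_eval(wq_submodel("FWQ1"), c(alkalinity = 435, pH = 7.4, hardness = 329))
#' @export
fis_eval <- function(fis, x, method = "centroid", resolution = NULL,
                     clamp = FALSE, detail = FALSE) {
  stopifnot(inherits(fis, "wq_fis"))
  vars <- names(fis$inputs)
  if (is.null(names(x)) || !all(nzchar(names(x)))) {
    if (length(x) != length(vars)) {
      abort(sprintf("model '%s' expects %d inputs (%s)", fis$name,
                    length(vars), paste(vars, collapse = ", ")),
            class = "aquafis_eval_error")
    }
    names(x) <- vars
  }
  missing <- setdiff(vars, names(x))
  if (length(missing)) {
    abort(sprintf("missing input(s) for model '%s': %s", fis$name,
                  paste(missing, collapse = ", ")),
          class = "aquafis_eval_error")
  }
  fz <- lapply(fis$inputs, function(v) fuzzify(v, x[[v$name]], clamp = clamp))
  fired <- fire_rules(fis$rules, fz)
  agg <- fuzzy_aggregate(fired, fis$output, resolution %||% fis$resolution)
  value <- defuzzify(agg, method)
  if (!detail) return(value)
  list(fuzzified = fz, fired = fired, aggregate = agg, value = value)
}

#' @describeIn wq_fis Tidy the rule table (one row per rule).
#' @param x A `wq_fis`.
#' @param ... Unused.
#' @export
tidy.wq_fis <- function(x, ...) {
  out <- as_tibble(x$rules)
  class(out) <- setdiff(class(out), "wq_rulebase")
  attr(out, "input_vars") <- NULL
  attr(out, "output_name") <- NULL
  dplyr::mutate(out, model = x$name, .before = 1)
}

#' @describeIn wq_fis One-row model summary.
#' @export
glance.wq_fis <- function(x, ...) {
  tibble(model = x$name,
         inputs = paste(names(x$inputs), collapse = ", "),
         n_inputs = length(x$inputs),
         n_rules = nrow(x$rules),
         n_output_terms = nrow(x$output$terms),
         resolution = x$resolution)
}
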