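#' Rule base for a three-input Mamdani model
#'
#' A complete conjunctive ("and") rule table: exactly one rule for every
#' combination of input term labels, each mapping to one output term. For
#' three inputs with three terms each this is the familiar 27-rule base.
#'
#' @param inputs Named list of input [lvar()]s (antecedent order matters).
#' @param output The output [lvar()] whose terms are the allowed consequents.
#' @param rules A data frame with one column per input variable (term labels)
#'   plus a `then` column naming the consequent term.
#'
#' @return A `wq_rulebase`: a tibble of rules with attributes `input_vars`
#'   and `output_name`.
#' @seealso [default_rules()] for the quality-point construction used by the
#'   shipped water-quality models.
#' @export
wq_rules <- function(inputs, output, rules) {
  stopifnot(is.list(inputs), inherits(output, "wq_lvar"))
  vars <- vapply(inputs, function(v) v$name, character(1))
  rules <- as_tibble(rules)
  if (!setequal(names(rules), c(vars, "then"))) {
    abort(sprintf("rule table must have columns %s",
                  paste(c(vars, "then"), collapse = ", ")),
          class = "aquafis_config_error")
  }
  rules <- rules[c(vars, "then")]
  for (v in inputs) {
    bad <- setdiff(rules[[v$name]], v$terms$term)
    if (length(bad)) {
      abort(sprintf("unknown term '%s' for variable '%s' in rule table",
                    bad[1], v$name), class = "aquafis_config_error")
    }
  }
  bad <- setdiff(rules$then, output$terms$term)
  if (length(bad)) {
    abort(sprintf("unknown consequent term '%s'", bad[1]),
          class = "aquafis_config_error")
  }
  combos <- prod(vapply(inputs, function(v) nrow(v$terms), integer(1)))
  ante <- do.call(paste, c(rules[vars], sep = "\r"))
  if (anyDuplicated(ante)) {
    abort("duplicate rule antecedents", class = "aquafis_config_error")
  }
  if (nrow(rules) != combos) {
    abort(sprintf("rule base must cover all %d antecedent combinations (got %d)",
                  combos, nrow(rules)), class = "aquafis_config_error")
  }
  structure(rules, class = c("wq_rulebase", class(rules)),
            input_vars = unname(vars), output_name = output$name)
}

#' Derive the default rule base from quality points
#'
#' Every input term carries quality points (0 poor, 1 moderate, 2 good). A
#' rule's consequent is the output class whose index equals the sum of its
#' three antecedent quality points: sums 0..6 map onto the seven classes
#' VVL, VL, L, M, H, VH, VVH. The worst combination (all poor) therefore
#' lands on "very, very low" and the best (all good) on "very, very high".
#'
#' @inheritParams wq_rules
#' @return A `wq_rulebase` with `3^k` rules.
#' @export
default_rules <- function(inputs, output) {
  for (v in inputs) {
    if (anyNA(v$terms$quality)) {
      abort(sprintf("variable '%s' has terms without quality points", v$name),
            class = "aquafis_config_error")
    }
  }
  grid <- tidyr::expand_grid(
    !!!setNames(purrr::map(inputs, function(v) v$terms$term),
                purrr::map_chr(inputs, "name")))
  qp <- purrr::map(inputs, function(v) setNames(v$terms$quality, v$terms$term))
  score <- purrr::reduce(seq_along(inputs), .init = rep(0L, nrow(grid)),
                         function(acc, i) acc + qp[[i]][grid[[i]]])
  nmax <- sum(purrr::map_int(inputs, function(v) max(v$terms$quality)))
  if (nrow(output$terms) != nmax + 1) {
    abort(sprintf(
      "output needs %d terms to span quality sums 0..%d (got %d)",
      nmax + 1, nmax, nrow(output$terms)), class = "aquafis_config_error")
  }
  grid$then <- output$terms$term[score + 1L]
  wq_rules(inputs, output, grid)
}

#' Fire the rules of a rule base
#'
#' Conjunctive firing with "min" implication: each rule's strength is the
#' minimum of its antecedent membership degrees. Rules with zero strength
#' are dropped by default.
#'
#' @param rules A [wq_rules()] table.
#' @param fuzzified Named list, one element per input variable, each a named
#'   degree vector as returned by [fuzzify()].
#' @param drop_zero Drop rules with zero strength?
#'
#' @return A tibble with columns `then` (consequent term) and `strength`.
#' @export
fire_rules <- function(rules, fuzzified, drop_zero = TRUE) {
  vars <- attr(rules, "input_vars")
  missing <- setdiff(vars, names(fuzzified))
  if (length(missing)) {
    abort(sprintf("fuzzified degrees missing for variable(s): %s",
                  paste(missing, collapse = ", ")),
          class = "aquafis_eval_error")
  }
  strength <- purrr::reduce(vars, .init = rep(1, nrow(rules)),
                            function(acc, v) pmin(acc, fuzzified[[v]][rules[[v]]]))
  out <- tibble(then = rules$then, strength = unname(strength))
  if (drop_zero) out <- out[out$strength > 0, ]
  out
}

#' Render a rule base as readable if-then statements
#'
#' @param fis A [wq_fis()] model.
#' @return Character vector, one statement per rule.
#' @examples
#' head(export_rules(wq_submodel("FWQ2")), 3)
#' @export
export_rules <- function(fis) {
  stopifnot(inherits(fis, "wq_fis"))
  vars <- attr(fis$rules, "input_vars")
  ante <- purrr::map(vars, function(v) sprintf("%s is %s", v, fis$rules[[v]]))
  sprintf("If %s then %s is %s",
          purrr::reduce(ante, paste, sep = " and "),
          fis$output$name, fis$rules$then)
}
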