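# YAML serialisation of the model configuration. The schema (all keys
# required unless marked optional):
#
#   resolution: <int>          universe resolution
#   defuzz: <method>           centroid | bisector | mom | som | lom
#   clamp: <bool>              clamp out-of-domain measurements
#   fwq3: calibrated|catalog   which FWQ3 term ranges are in use
#   catalog:                   the nine measured variables
#     limits: [{parameter, units, limit, c_min}, ...]
#     variables: [<variable>, ...]
#   models: [<model>, ...]     FWQ1, FWQ2, FWQ3, FWQ
#   ahp: (optional)            {parameters: [...], rows: [[...], ...]}
#
# <variable>: {name, units, domain: [lo, hi],
#              terms: [{term, a, b, c, quality}, ...]}
# <model>:    {name, resolution, inputs: [<variable>, ...],
#              output: <variable>,
#              rules: ["<t1> & <t2> & <t3> -> <then>", ...]}

lvar_to_config <- function(v) {
  list(name = v$name, units = v$units, domain = as.list(v$domain),
       terms = purrr::pmap(v$terms, function(term, a, b, c, quality) {
         out <- list(term = term, a = a, b = b, c = c)
         if (!is.na(quality)) out$quality <- as.integer(quality)
         out
       }))
}

lvar_from_config <- function(l) {
  terms <- purrr::map_dfr(l$terms, function(t) {
    tibble(term = t$term, a = t$a, b = t$b, c = t$c,
           quality = as.integer(t$quality %||% NA_integer_))
  })
  lvar(l$name, unlist(l$domain), terms, units = l$units %||% "mg/L")
}

fis_to_config <- function(f) {
  vars <- attr(f$rules, "input_vars")
  ante <- do.call(paste, c(unclass(f$rules)[vars], sep = " & "))
  list(name = f$name, resolution = f$resolution,
       inputs = purrr::map(unname(f$inputs), lvar_to_config),
       output = lvar_to_config(f$output),
       rules = as.list(paste(ante, "->", f$rules$then)))
}

fis_from_config <- function(l) {
  inputs <- purrr::map(l$inputs, lvar_from_config)
  output <- lvar_from_config(l$output)
  parts <- strsplit(unlist(l$rules), "->", fixed = TRUE)
  ante <- strsplit(trimws(vapply(parts, `[`, character(1), 1)), " & ",
                   fixed = TRUE)
  rules <- as_tibble(do.call(rbind, ante), .name_repair = "minimal")
  names(rules) <- vapply(inputs, function(v) v$name, character(1))
  rules$then <- trimws(vapply(parts, `[`, character(1), 2))
  wq_fis(l$name, inputs, output, rules, resolution = l$resolution %||% 1001)
}

#' Write a model configuration to YAML
#'
#' Serialises a full hierarchy (catalog, per-model variables and rule tables,
#' output partition, defuzzifier, resolution, clamping flag, optional AHP
#' matrix) to a structured YAML file. The file header in `R/config.R`
#' documents the schema. [wq_config_read()] restores an equivalent hierarchy.
#'
#' @param model A [wq_hierarchy()].
#' @param path Output file path.
#' @param ahp Optional [ahp_matrix()] to embed.
#' @return `path`, invisibly.
#' @export
wq_config_write <- function(model, path, ahp = NULL) {
  stopifnot(inherits(model, "wq_hierarchy"))
  cfg <- list(
    resolution = model$resolution, defuzz = model$defuzz,
    clamp = model$clamp, fwq3 = model$fwq3,
    catalog = list(
      limits = purrr::pmap(attr(model$catalog, "limits"),
                           function(parameter, units, limit, c_min) {
                             list(parameter = parameter, units = units,
                                  limit = limit, c_min = c_min)
                           }),
      variables = purrr::map(unclass(model$catalog), lvar_to_config)),
    models = purrr::map(unname(model$models), fis_to_config))
  if (!is.null(ahp)) {
    ahp <- ahp_matrix(ahp)
    cfg$ahp <- list(parameters = rownames(ahp),
                    rows = purrr::map(seq_len(nrow(ahp)),
                                      function(i) as.list(unname(ahp[i, ]))))
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' @param path A YAML file written by [wq_config_write()] (or hand-edited to
#'   the same schema).
#' @return A [wq_hierarchy()]. If the file embeds an AHP matrix it is
#'   attached as the `ahp` attribute.
#' @export
wq_config_read <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("cannot parse %s as YAML: %s", path, conditionMessage(e)),
          class = "aquafis_config_error")
  })
  if (!is.list(cfg)) {
    abort(sprintf("%s does not hold a model configuration", path),
          class = "aquafis_config_error")
  }
  for (key in c("resolution", "defuzz", "catalog", "models")) {
    if (is.null(cfg[[key]])) {
      abort(sprintf("configuration is missing the '%s' field", key),
            class = "aquafis_config_error")
    }
  }
  vars <- purrr::map(cfg$catalog$variables, lvar_from_config)
  limits <- purrr::map_dfr(cfg$catalog$limits, as_tibble)
  catalog <- structure(setNames(vars, purrr::map_chr(vars, "name")),
                       limits = limits, class = "wq_catalog")
  models <- purrr::map(cfg$models, fis_from_config)
  names(models) <- purrr::map_chr(cfg$models, "name")
  h <- structure(list(models = models, catalog = catalog,
                      fwq3 = cfg$fwq3 %||% "calibrated",
                      resolution = as.integer(cfg$resolution),
                      defuzz = cfg$defuzz, clamp = isTRUE(cfg$clamp)),
                 class = "wq_hierarchy")
  if (!is.null(cfg$ahp)) {
    m <- do.call(rbind, purrr::map(cfg$ahp$rows, unlist))
    attr(h, "ahp") <- ahp_matrix(m, parameters = unlist(cfg$ahp$parameters))
  }
  h
}
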