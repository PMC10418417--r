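#' Read water samples from a delimited file
#'
#' Expects a header with the nine parameter names (`ph`, `alkalinity`,
#' `hardness`, `ca`, `mg`, `fe`, `fluoride`, `nitrate`, `sulfate`;
#' case-insensitive, with `sulphate`/`nitrates`/`iron`/`calcium`/`magnesium`
#' accepted as aliases). Extra columns (ids, location tags) pass through
#' untouched. Parse problems are reported with their row number.
#'
#' @param path CSV file path.
#' @param delim Field delimiter.
#' @return A tibble of typed samples.
#' @export
read_water_samples <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "aquafis_parse_error")
  }
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (nrow(data) == 0) {
    abort(sprintf("no sample rows in %s", path), class = "aquafis_parse_error")
  }
  names(data) <- normalise_sample_names(names(data))
  missing <- setdiff(wq_param_names(), names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "aquafis_parse_error")
  }
  for (p in wq_param_names()) {
    col <- data[[p]]
    if (!is.numeric(col)) {
      # readr leaves non-numeric columns as character; locate the culprit
      as_num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(as_num) & !is.na(col))
      abort(sprintf("column '%s' has a non-numeric value at row %s", p,
                    if (length(bad)) bad[1] else "?"),
            class = "aquafis_parse_error")
    }
    bad <- which(is.na(col))
    if (length(bad)) {
      abort(sprintf("column '%s' has a missing value at row %d", p, bad[1]),
            class = "aquafis_parse_error")
    }
  }
  data
}

#' Write membership curves to a delimited file
#'
#' Exports the sampled membership curves of one or more variables in long
#' format (`variable`, `term`, `x`, `degree`) for external plotting.
#'
#' @param vars A [lvar()], a list of them, or a [wq_catalog()].
#' @param path Output CSV path.
#' @param n Sample points per curve.
#' @return `path`, invisibly.
#' @export
write_membership_curves <- function(vars, path, n = 201) {
  if (inherits(vars, "wq_lvar")) vars <- list(vars)
  curves <- purrr::map_dfr(unclass(vars), membership_curves, n = n)
  readr::write_csv(curves, path)
  invisible(path)
}
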