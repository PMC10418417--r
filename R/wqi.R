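#' Saaty pairwise-comparison matrix
#'
#' Validates an analytic-hierarchy-process (AHP) judgment matrix: square,
#' positive, unit diagonal, reciprocal (`m[j, i] == 1 / m[i, j]`) and with
#' entries on Saaty's 1/9..9 scale.
#'
#' @param m Numeric matrix (or data frame) of pairwise importance judgments.
#' @param parameters Optional parameter names (defaults to dimnames).
#' @param tol Tolerance for the reciprocity check.
#'
#' @return The validated matrix with class `wq_ahp`.
#' @export
ahp_matrix <- function(m, parameters = NULL, tol = 1e-6) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n != ncol(m) || n < 2) {
    abort("AHP matrix must be square with at least two parameters",
          class = "aquafis_ahp_error")
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("AHP matrix entries must be positive numbers",
          class = "aquafis_ahp_error")
  }
  if (any(abs(diag(m) - 1) > tol)) {
    abort("AHP matrix must have a unit diagonal", class = "aquafis_ahp_error")
  }
  if (max(abs(m * t(m) - 1)) > tol) {
    abort("AHP matrix is not reciprocal: m[j, i] must equal 1 / m[i, j]",
          class = "aquafis_ahp_error")
  }
  if (any(m > 9 + tol) || any(m < 1 / 9 - tol)) {
    abort("AHP judgments must lie on Saaty's scale [1/9, 9]",
          class = "aquafis_ahp_error")
  }
  parameters <- parameters %||% rownames(m) %||% paste0("p", seq_len(n))
  dimnames(m) <- list(parameters, parameters)
  structure(m, class = c("wq_ahp", "matrix", "array"))
}

#' AHP weights by column normalisation and row averaging
#'
#' Normalises each column of the comparison matrix by its column sum, then
#' averages across each row. For a perfectly consistent matrix this recovers
#' the underlying priority vector exactly.
#'
#' @param m An [ahp_matrix()] (or anything it accepts).
#' @return A tibble with `parameter` and `weight`; weights are non-negative
#'   and sum to 1.
#' @examples
#' ahp_weights(matrix(1, 3, 3))
#' @export
ahp_weights <- function(m) {
  m <- ahp_matrix(m)
  norm <- sweep(m, 2, colSums(m), "/")
  w <- rowMeans(norm)
  tibble(parameter = rownames(m), weight = unname(w / sum(w)))
}

#' @describeIn ahp_weights Tidy method for a validated AHP matrix.
#' @param x A `wq_ahp`.
#' @param ... Unused.
#' @export
tidy.wq_ahp <- function(x, ...) ahp_weights(x)

# Saaty's random consistency indices for n = 1..10
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Consistency ratio of an AHP matrix
#'
#' `CR = ((lambda_max - n) / (n - 1)) / RI(n)` with the principal eigenvalue
#' `lambda_max` and Saaty's random index `RI`. Judgment sets with `CR > 0.1`
#' are conventionally considered too incoherent to use; a warning is raised.
#'
#' @inheritParams ahp_weights
#' @return The consistency ratio (0 for a perfectly consistent matrix).
#' @export
consistency_ratio <- function(m) {
  m <- ahp_matrix(m)
  n <- nrow(m)
  if (n > 10) {
    abort("consistency ratio is only tabulated up to 10 parameters",
          class = "aquafis_ahp_error")
  }
  if (n <= 2) return(0)  # 2x2 reciprocal matrices are always consistent
  lambda <- max(Re(eigen(m, only.values = TRUE)$values))
  cr <- ((lambda - n) / (n - 1)) / saaty_ri[n]
  cr <- max(cr, 0)  # clip the tiny negative values numerical noise can give
  if (cr > 0.1) {
    warn(sprintf("AHP judgments are inconsistent (CR = %.3f > 0.1)", cr),
         class = "aquafis_inconsistent_ahp")
  }
  cr
}

#' Water-quality sub-index of one parameter
#'
#' `I = (C_s - C_i) / (C_s - C_min)`: 1 when the observed concentration sits
#' at the best-quality value `C_min`, 0 at the desirable limit `C_s`, and
#' negative beyond the limit. Negative values are preserved (the index has no
#' clamp) unless `clamp = TRUE` truncates to \[0, 1\].
#'
#' @param c_i Observed concentration(s).
#' @param c_s Desirable limit concentration.
#' @param c_min Best-quality concentration (0 for all parameters except pH,
#'   whose optimum is 7).
#' @param clamp Truncate the sub-index to \[0, 1\]?
#' @return Numeric vector of sub-indices.
#' @examples
#' wq_subindex(7.4, c_s = 8.5, c_min = 7)
#' @export
wq_subindex <- function(c_i, c_s, c_min = 0, clamp = FALSE) {
  if (any(c_s == c_min)) {
    abort("C_s must differ from C_min", class = "aquafis_wqi_error")
  }
  i <- (c_s - c_i) / (c_s - c_min)
  if (clamp) i <- pmin(pmax(i, 0), 1)
  i
}

#' Weighted water-quality index
#'
#' `WQI = sum_i W_i I_i`: the weighted sum of per-parameter sub-indices.
#'
#' @param weights Numeric weight vector, or the tibble from [ahp_weights()].
#' @param indices Numeric sub-index vector in the same parameter order.
#' @return The index as a fraction (multiply by 100 for percent).
#' @export
wqi <- function(weights, indices) {
  if (is.data.frame(weights)) weights <- weights$weight
  if (length(weights) != length(indices)) {
    abort("weights and sub-indices must have the same length",
          class = "aquafis_wqi_error")
  }
  sum(weights * indices)
}

#' Per-sample water-quality index
#'
#' Computes the nine sub-indices from the catalog's desirable limits and
#' aggregates them with the given weights. With no weights, all nine
#' parameters count equally. Sub-indices go negative where a measurement
#' exceeds its desirable limit; `clamp_subindex = TRUE` truncates them to
#' \[0, 1\] instead (with a note).
#'
#' @param data Data frame of samples (same columns as [wq_score()]).
#' @param weights Optional [ahp_weights()] tibble or named weight vector over
#'   the nine parameters.
#' @param clamp_subindex Truncate sub-indices to \[0, 1\]?
#' @return The input tibble with a `wqi` column (fraction) appended.
#' @examples
#' wq_index(rome_sample())
#' @export
wq_index <- function(data, weights = NULL, clamp_subindex = FALSE) {
  data <- check_sample_frame(data)
  lim <- wq_limits()
  w <- wq_resolve_weights(weights)
  if (clamp_subindex) {
    rlang::inform("sub-indices truncated to [0, 1]",
                  class = "aquafis_subindex_clamped")
  }
  data$wqi <- vapply(seq_len(nrow(data)), function(r) {
    idx <- wq_subindex(as.numeric(data[r, lim$parameter]),
                       lim$limit, lim$c_min, clamp = clamp_subindex)
    wqi(w, idx)
  }, numeric(1))
  data
}

# weights in catalog parameter order; NULL -> equal weights
wq_resolve_weights <- function(weights) {
  params <- wq_param_names()
  if (is.null(weights)) return(rep(1 / length(params), length(params)))
  if (is.data.frame(weights)) {
    weights <- setNames(weights$weight, normalise_sample_names(weights$parameter))
  } else if (!is.null(names(weights))) {
    names(weights) <- normalise_sample_names(names(weights))
  }
  if (!is.null(names(weights))) {
    missing <- setdiff(params, names(weights))
    if (length(missing)) {
      abort(sprintf("weights missing for parameter(s): %s",
                    paste(missing, collapse = ", ")),
            class = "aquafis_wqi_error")
    }
    weights <- weights[params]
  } else if (length(weights) != length(params)) {
    abort(sprintf("need %d weights (one per parameter)", length(params)),
          class = "aquafis_wqi_error")
  }
  if (any(weights < 0)) {
    abort("weights must be non-negative", class = "aquafis_wqi_error")
  }
  unname(weights / sum(weights))
}

#' Cross-validate fuzzy scores against the water-quality index
#'
#' Scores each sample with the hierarchical fuzzy model and with the
#' deterministic weighted index, and reports both on their native scales
#' together with the absolute difference on the fraction scale.
#'
#' @inheritParams wq_index
#' @param model A [wq_hierarchy()].
#' @param method Defuzzification method for the fuzzy score.
#' @param clamp Clamp out-of-domain measurements for the fuzzy model?
#' @return Tibble with the sample columns plus `fwq` (%), `wqi` (fraction),
#'   `wqi_pct` and `difference` (`|fwq/100 - wqi|`).
#' @export
wq_validate <- function(data, weights = NULL, model = wq_hierarchy(),
                        method = "centroid", clamp = FALSE,
                        clamp_subindex = FALSE) {
  scored <- wq_score(data, model, method, clamp = clamp)
  indexed <- wq_index(data, weights, clamp_subindex)
  out <- dplyr::bind_cols(check_sample_frame(data),
                          fwq = scored$fwq, wqi = indexed$wqi)
  dplyr::mutate(out, wqi_pct = 100 * .data$wqi,
                difference = abs(.data$fwq / 100 - .data$wqi))
}
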