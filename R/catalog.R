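# Guideline-based term ranges, desirable limits and dataset averages for the
# nine physicochemical parameters. Low/high terms are shoulders at the domain
# edges; each medium term peaks at the midpoint of its range, which coincides
# with the low/high boundary (e.g. alkalinity medium 100-700 peaks at 400).
wq_parameter_table <- function() {
  tibble::tribble(
    ~parameter,   ~units, ~lo, ~hi,   ~low_hi, ~med_lo, ~med_hi, ~high_lo, ~q_low, ~q_med, ~q_high, ~limit, ~c_min, ~rome,
    "ph",         "",       0,   14,        7,     5.5,     9.5,        7,     0L,     2L,      1L,    8.5,      7,    7.4,
    "alkalinity", "mg/L",   0,  800,      400,     100,     700,      400,     2L,     1L,      0L,    200,      0,    435,
    "hardness",   "mg/L",   0, 1200,      500,     100,     900,      500,     2L,     1L,      0L,    300,      0,    329,
    "ca",         "mg/L",   0,  300,      150,      50,     250,      150,     2L,     1L,      0L,     75,      0,  100.6,
    "mg",         "mg/L",   0,  120,       60,      20,     100,       60,     2L,     1L,      0L,     30,      0,     19,
    "fe",         "mg/L",   0,  1.2,      0.6,     0.2,       1,      0.6,     2L,     1L,      0L,    0.3,      0, 0.0118,
    "fluoride",   "mg/L",   0,    6,        3,       1,       5,        3,     2L,     1L,      0L,    1.5,      0,   0.14,
    "nitrate",    "mg/L",   0,  180,       80,      20,     140,       80,     2L,     1L,      0L,     45,      0,    3.5,
    "sulfate",    "mg/L",   0,  800,      400,     150,     650,      400,     2L,     1L,      0L,    200,      0,   13.7
  )
}

# three-term low/medium/high variable from a parameter-table row
lvar_from_row <- function(row) {
  lvar(row$parameter, c(row$lo, row$hi), tibble::tibble(
    term    = c("low", "medium", "high"),
    a       = c(row$lo, row$med_lo, row$high_lo),
    b       = c(row$lo, (row$med_lo + row$med_hi) / 2, row$hi),
    c       = c(row$low_hi, row$med_hi, row$hi),
    quality = c(row$q_low, row$q_med, row$q_high)),
    units = row$units)
}

#' Catalog of the nine drinking-water parameters
#'
#' Builds the linguistic variables for pH, alkalinity, hardness, calcium,
#' magnesium, iron, fluoride, nitrate and sulfate from drinking-water
#' guideline ranges: each variable has low/medium/high terms with quality
#' points (pH: low poor, medium good, high moderate; all concentrations:
#' low good, medium moderate, high poor) and a desirable regulatory limit.
#'
#' @return A named list of nine [lvar()]s, class `wq_catalog`. The attached
#'   `limits` attribute is a tibble of desirable limits (`limit`) and
#'   best-quality concentrations (`c_min`, 0 everywhere except pH = 7) used
#'   by the water-quality index.
#' @examples
#' cat9 <- wq_catalog()
#' cat9$alkalinity
#' fuzzify(cat9$ph, 7.4)
#' @export
wq_catalog <- function() {
  tab <- wq_parameter_table()
  vars <- purrr::map(seq_len(nrow(tab)), function(i) lvar_from_row(tab[i, ]))
  structure(setNames(vars, tab$parameter),
            limits = tab[c("parameter", "units", "limit", "c_min")],
            class = "wq_catalog")
}

#' @export
print.wq_catalog <- function(x, ...) {
  cat(sprintf("<wq_catalog: %d parameters (%s)>\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @describeIn wq_catalog Tidy the full term table (one row per term).
#' @param x A `wq_catalog`.
#' @param ... Unused.
#' @export
tidy.wq_catalog <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' Desirable limits used by the water-quality index
#'
#' @return Tibble with `parameter`, `units`, `limit` (concentration limit
#'   C_s) and `c_min` (best-quality concentration; 0 for all parameters
#'   except pH, whose optimum is 7).
#' @export
wq_limits <- function() {
  attr(wq_catalog(), "limits")
}

#' Average Rome drinking-water sample
#'
#' The 2018 network-average measurements used throughout the worked examples.
#' The dataset average for calcium is 100.6 mg/L; the sub-model walkthroughs
#' round it to 101 mg/L, which is what the golden scores were produced with —
#' choose via `ca`.
#'
#' @param ca Which calcium average to use: the dataset value (100.6) or the
#'   rounded value (101) used in the reference score calculations.
#' @return A one-row tibble with the nine parameters.
#' @export
rome_sample <- function(ca = c("dataset", "rounded")) {
  ca <- match.arg(ca)
  tab <- wq_parameter_table()
  out <- as_tibble(as.list(setNames(tab$rome, tab$parameter)))
  if (ca == "rounded") out$ca <- 101
  out
}

#' Seven-class output partition of the 0-100 quality scale
#'
#' Uniform triangular partition with peaks every 100/6 points: very, very low
#' (VVL), very low (VL), low (L), medium (M), high (H), very high (VH) and
#' very, very high (VVH). Adjacent supports overlap by one half-width, so the
#' class degrees sum to 1 everywhere on (0, 100).
#'
#' @return A [lvar()] named `"quality"` on \[0, 100\].
#' @export
wq_output_partition <- function() {
  s <- 100 / 6
  labs <- wq_class_labels()
  peaks <- s * (0:6)
  lvar("quality", c(0, 100), tibble::tibble(
    term = labs,
    a = pmax(peaks - s, 0),
    b = peaks,
    c = pmin(peaks + s, 100),
    quality = NA_integer_), units = "%")
}

#' Classify a quality score into its linguistic class
#'
#' Returns the output-partition term with maximal membership at the score;
#' exact ties go to the higher (better) class.
#'
#' @param score Numeric vector of scores in \[0, 100\].
#' @param long Return the spelled-out class name (`"very high"`) instead of
#'   the short label (`"VH"`)?
#' @return Character vector of class labels.
#' @examples
#' wq_classify(c(5, 50, 86.9))
#' @export
wq_classify <- function(score, long = FALSE) {
  part <- wq_output_partition()
  labs <- part$terms$term
  vapply(score, function(s) {
    if (is.na(s) || s < 0 || s > 100) {
      abort(sprintf("score %g outside [0, 100]", s),
            class = "aquafis_domain_error")
    }
    deg <- vapply(part$mfs, mf_degree, numeric(1), x = s)
    lab <- labs[max(which(deg >= max(deg) - 1e-9))]  # exact ties go upward
    if (long) unname(wq_class_names()[lab]) else lab
  }, character(1))
}
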