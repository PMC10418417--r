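#' Generate synthetic water samples
#'
#' Seeded generator emulating a network of drinking-water sampling points.
#' Two sampling laws are available:
#' \describe{
#'   \item{`"rome"`}{Truncated normal per parameter, centred on the Rome
#'     network averages with standard deviation `cv * mean`, truncated to the
#'     parameter's catalog domain (inverse-CDF sampling, so the draw count
#'     per sample is fixed and reproducible). `cv = 0` degenerates to the
#'     averages themselves.}
#'   \item{`"uniform"`}{Uniform over each parameter's full catalog domain.}
#' }
#' A fraction `p_out` of samples deliberately violates one randomly chosen
#' parameter's domain (drawn just above its upper bound) so that error paths
#' and clamping behaviour can be exercised.
#'
#' @param n Number of samples.
#' @param seed Integer seed; identical seed and arguments give identical
#'   samples. The default is the dataset year tag 20180604.
#' @param law Sampling law.
#' @param cv Coefficient of variation for the `"rome"` law.
#' @param p_out Fraction of samples given one out-of-range value.
#' @param catalog Variable catalog supplying domains and averages.
#'
#' @return Tibble with `sample_id` and the nine parameter columns.
#' @examples
#' wq_simulate(3, seed = 1)
#' @export
wq_simulate <- function(n, seed = 20180604, law = c("rome", "uniform"),
                        cv = 0.15, p_out = 0, catalog = wq_catalog()) {
  law <- match.arg(law)
  stopifnot(n >= 1, cv >= 0, p_out >= 0, p_out <= 1)
  tab <- wq_parameter_table()
  withr::with_seed(as.integer(seed), {
    cols <- purrr::map(seq_len(nrow(tab)), function(i) {
      lo <- tab$lo[i]; hi <- tab$hi[i]
      if (law == "uniform") return(stats::runif(n, lo, hi))
      m <- tab$rome[i]; s <- cv * m
      if (s == 0) return(rep(m, n))
      # inverse-CDF truncated normal on [lo, hi]
      p <- stats::runif(n, stats::pnorm(lo, m, s), stats::pnorm(hi, m, s))
      stats::qnorm(p, m, s)
    })
    out <- as_tibble(setNames(cols, tab$parameter))
    if (p_out > 0) {
      bad <- stats::runif(n) < p_out
      which_par <- sample(tab$parameter, n, replace = TRUE)
      for (r in which(bad)) {
        p <- which_par[r]
        hi <- tab$hi[match(p, tab$parameter)]
        out[r, p] <- hi * stats::runif(1, 1.01, 1.5)
      }
    }
    dplyr::mutate(out, sample_id = sprintf("S%04d", seq_len(n)), .before = 1)
  })
}
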