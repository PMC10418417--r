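# Independent oracles used across the test files. These deliberately avoid
# the package's aggregation/quadrature code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Closed-form centroid of a triangle (a, b, c) clipped at height h: exact
# polynomial integrals over the up-ramp, plateau and down-ramp pieces.
clipped_tri_centroid <- function(a, b, c, h) {
  stopifnot(h > 0, h <= 1)
  x1 <- a + h * (b - a)
  x2 <- c - h * (c - b)
  area_up <- if (a == b) 0 else h^2 * (b - a) / 2
  mom_up <- if (a == b) 0 else {
    w <- h * (b - a)
    (w^3 / 3 + a * w^2 / 2) / (b - a)
  }
  area_dn <- if (b == c) 0 else h^2 * (c - b) / 2
  mom_dn <- if (b == c) 0 else {
    w <- h * (c - b)
    (c * w^2 / 2 - w^3 / 3) / (c - b)
  }
  area_mid <- h * (x2 - x1)
  mom_mid <- h * (x2^2 - x1^2) / 2
  (mom_up + mom_mid + mom_dn) / (area_up + area_mid + area_dn)
}

# Random fired-rule sets over the seven-class output partition.
random_fired <- function() {
  labs <- c("VVL", "VL", "L", "M", "H", "VH", "VVH")
  k <- sample(1:7, 1)
  tibble::tibble(then = sample(labs, k),
                 strength = stats::runif(k, min = 0.05))
}

# Rome-average inputs per sub-model (ca rounded to 101 as in the reference
# score calculations).
rome_inputs <- list(
  FWQ1 = c(alkalinity = 435, ph = 7.4, hardness = 329),
  FWQ2 = c(ca = 101, mg = 19, fe = 0.0118),
  FWQ3 = c(sulfate = 13.7, nitrate = 3.5, fluoride = 0.14))
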