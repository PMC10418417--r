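test_that("AHP weights: column-normalise then row-average", {
  # all-equal judgments split the weight evenly
  expect_equal(ahp_weights(matrix(1, 3, 3))$weight, rep(1 / 3, 3))
  # a perfectly consistent matrix recovers its priority vector exactly
  w <- c(0.5, 0.3, 0.2)
  m <- outer(w, w, "/")
  expect_equal(ahp_weights(m)$weight, w, tolerance = 1e-9)
  w9 <- (1:9) / sum(1:9)
  expect_equal(ahp_weights(outer(w9, w9, "/"))$weight, w9, tolerance = 1e-9)
  # weights always sum to one
  withr::local_seed(7)
  for (i in 1:20) {
    v <- stats::runif(4, 0.5, 2)
    m <- outer(v, v, "/")
    expect_equal(sum(ahp_weights(m)$weight), 1, tolerance = 1e-12)
    expect_true(all(ahp_weights(m)$weight >= 0))
  }
})

test_that("AHP weights are permutation-equivariant", {
  v <- c(0.45, 0.25, 0.2, 0.1)
  m <- outer(v, v, "/")
  perm <- c(3, 1, 4, 2)
  expect_equal(ahp_weights(m[perm, perm])$weight,
               ahp_weights(m)$weight[perm], tolerance = 1e-12)
})

test_that("invalid judgment matrices are rejected", {
  expect_error(ahp_matrix(matrix(1, 2, 3)), class = "aquafis_ahp_error")
  m <- matrix(1, 3, 3)
  m[1, 2] <- 3
  expect_error(ahp_matrix(m), class = "aquafis_ahp_error")  # not reciprocal
  m[2, 1] <- 1 / 3
  expect_s3_class(ahp_matrix(m), "wq_ahp")
  m[1, 2] <- -2
  expect_error(ahp_matrix(m), class = "aquafis_ahp_error")
  m[1, 2] <- 20
  m[2, 1] <- 1 / 20
  expect_error(ahp_matrix(m), class = "aquafis_ahp_error")  # off Saaty's scale
})

test_that("consistency ratio is zero for consistent judgments, positive otherwise", {
  expect_equal(consistency_ratio(matrix(1, 4, 4)), 0, tolerance = 1e-9)
  w <- c(0.6, 0.3, 0.1)
  expect_equal(consistency_ratio(outer(w, w, "/")), 0, tolerance = 1e-9)
  m <- outer(w, w, "/")
  m[1, 3] <- 9      # perturb one judgment away from consistency
  m[3, 1] <- 1 / 9
  expect_gt(consistency_ratio(m), 0)
  big <- diag(11) * 0 + 1
  expect_error(consistency_ratio(big), class = "aquafis_ahp_error")
})

test_that("severely inconsistent judgments raise the conventional warning", {
  m <- matrix(c(1, 9, 1 / 9,
                1 / 9, 1, 9,
                9, 1 / 9, 1), 3, 3, byrow = TRUE)  # cyclic preferences
  expect_warning(cr <- consistency_ratio(m), class = "aquafis_inconsistent_ahp")
  expect_gt(cr, 0.1)
})

test_that("the shipped example matrix is valid and near-consistent", {
  path <- system.file("extdata", "ahp_example_synthetic.csv", package = "aquafis")
  m <- ahp_matrix(as.matrix(read.csv(path, row.names = 1)))
  expect_equal(rownames(m)[1], "ph")
  expect_lt(consistency_ratio(m), 0.1)
  w <- ahp_weights(m)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
})

test_that("sub-indices satisfy their boundary identities and monotonicity", {
  expect_equal(wq_subindex(200, c_s = 200), 0)        # at the limit
  expect_equal(wq_subindex(0, c_s = 200), 1)          # at the best value
  expect_equal(wq_subindex(7.4, c_s = 8.5, c_min = 7), 1.1 / 1.5)  # ~0.7333
  # strictly decreasing in the observed concentration
  ci <- seq(0, 400, length.out = 20)
  expect_true(all(diff(wq_subindex(ci, c_s = 200)) < 0))
  # beyond-limit concentrations go negative unless clamped
  expect_lt(wq_subindex(435, c_s = 200), 0)
  expect_equal(wq_subindex(435, c_s = 200, clamp = TRUE), 0)
  expect_error(wq_subindex(1, c_s = 5, c_min = 5), class = "aquafis_wqi_error")
})

test_that("the weighted index is a plain weighted sum", {
  expect_equal(wqi(rep(1 / 9, 9), rep(1, 9)), 1)
  w <- c(1, rep(0, 8))
  idx <- stats::runif(9)
  expect_equal(wqi(w, idx), idx[1])
  # independent summation oracle
  withr::local_seed(11)
  for (i in 1:20) {
    w <- stats::runif(9)
    w <- w / sum(w)
    idx <- stats::runif(9, -0.5, 1)
    acc <- 0
    for (j in 1:9) acc <- acc + w[j] * idx[j]
    expect_equal(wqi(w, idx), acc, tolerance = 1e-12)
  }
  expect_error(wqi(rep(0.5, 2), rep(1, 3)), class = "aquafis_wqi_error")
})

test_that("validation reports fuzzy and index scores side by side", {
  rome <- rome_sample("rounded")
  rep <- wq_validate(rome)
  expect_equal(rep$fwq, wq_score(rome)$fwq)
  expect_equal(rep$difference, abs(rep$fwq / 100 - rep$wqi))
  expect_equal(rep$wqi_pct, 100 * rep$wqi)
  # weights concentrated on one parameter reduce the WQI to its sub-index
  w <- setNames(c(1, rep(0, 8)),
                c("ph", "alkalinity", "hardness", "ca", "mg", "fe",
                  "fluoride", "nitrate", "sulfate"))
  one <- wq_index(rome, weights = w)
  expect_equal(one$wqi, wq_subindex(7.4, 8.5, 7))
  # the equal-weight Rome index is dragged down by the over-limit parameters
  eq <- wq_index(rome)
  expect_lt(eq$wqi, 1)
  clamped <- suppressMessages(wq_index(rome, clamp_subindex = TRUE))
  expect_gte(clamped$wqi, eq$wqi)
})
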