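test_that("the catalog encodes the guideline term ranges and quality labels", {
  cat9 <- wq_catalog()
  expect_named(cat9, c("ph", "alkalinity", "hardness", "ca", "mg", "fe",
                       "fluoride", "nitrate", "sulfate"))
  alk <- tidy(cat9$alkalinity)
  expect_equal(unlist(alk[alk$term == "medium", c("a", "b", "c")]),
               c(a = 100, b = 400, c = 700))
  fe <- tidy(cat9$fe)
  expect_equal(unlist(fe[fe$term == "high", c("a", "b", "c")]),
               c(a = 0.6, b = 1.2, c = 1.2))
  # pH is the only parameter whose medium (not low) range is the good one
  expect_equal(cat9$ph$terms$quality, c(0L, 2L, 1L))
  for (p in setdiff(names(cat9), "ph")) {
    expect_equal(cat9[[p]]$terms$quality, c(2L, 1L, 0L))
  }
  lim <- wq_limits()
  expect_equal(lim$limit[lim$parameter == "fe"], 0.3)
  expect_equal(lim$c_min, c(7, rep(0, 8)))  # pH optimum is 7
})

test_that("the output partition is a uniform seven-class fuzzy partition", {
  part <- wq_output_partition()
  expect_equal(part$terms$term, c("VVL", "VL", "L", "M", "H", "VH", "VVH"))
  expect_equal(part$terms$b, 100 / 6 * (0:6))
  # degrees sum to one everywhere strictly inside the scale
  for (x in seq(0.5, 99.5, length.out = 41)) {
    expect_equal(sum(fuzzify(part, x)), 1, tolerance = 1e-9)
  }
})

test_that("sub-model wiring matches the hierarchy design", {
  expect_named(wq_submodel("FWQ1")$inputs, c("alkalinity", "ph", "hardness"))
  expect_named(wq_submodel("FWQ2")$inputs, c("ca", "mg", "fe"))
  expect_named(wq_submodel("FWQ3")$inputs, c("sulfate", "nitrate", "fluoride"))
  expect_named(wq_final_model()$inputs, c("FWQ1", "FWQ2", "FWQ3"))
  # calibrated FWQ3 keeps the full measurement domains via shoulder terms
  f3 <- wq_submodel("FWQ3")
  expect_equal(f3$inputs$sulfate$domain, c(0, 800))
  expect_equal(mf_degree(f3$inputs$sulfate$mfs$high, 700), 1)
  g <- glance(wq_hierarchy())
  expect_equal(g$n_rules, rep(27, 4))
})

test_that("hierarchical scoring equals composing the sub-models by hand", {
  h <- wq_hierarchy()
  sample <- rome_sample("rounded")
  report <- wq_score(sample, h)
  f1 <- fis_eval(h$models$FWQ1, rome_inputs$FWQ1)
  f2 <- fis_eval(h$models$FWQ2, rome_inputs$FWQ2)
  f3 <- fis_eval(h$models$FWQ3, rome_inputs$FWQ3)
  expect_equal(report$fwq1, f1)
  expect_equal(report$fwq2, f2)
  expect_equal(report$fwq3, f3)
  expect_equal(report$fwq,
               fis_eval(h$models$FWQ, c(FWQ1 = f1, FWQ2 = f2, FWQ3 = f3)))
  expect_equal(report$class, "very high")
})

test_that("boundary samples land in the extreme classes", {
  best <- tibble::tibble(ph = 7.5, alkalinity = 0, hardness = 0, ca = 0,
                         mg = 0, fe = 0, fluoride = 0, nitrate = 0, sulfate = 0)
  worst <- tibble::tibble(ph = 0, alkalinity = 800, hardness = 1200, ca = 300,
                          mg = 120, fe = 1.2, fluoride = 6, nitrate = 180,
                          sulfate = 800)
  expect_gte(wq_score(best)$fwq, 90)
  expect_lte(wq_score(worst)$fwq, 10)
  expect_equal(wq_score(best)$class, "very, very high")
  expect_equal(wq_score(worst)$class, "very, very low")
})

test_that("each sub-model score is non-increasing from good to poor", {
  h <- wq_hierarchy()
  sweeps <- list(
    FWQ1 = list(alkalinity = c(0, 800), ph = c(7.5, 0), hardness = c(0, 1200)),
    FWQ2 = list(ca = c(0, 300), mg = c(0, 120), fe = c(0, 1.2)),
    FWQ3 = list(sulfate = c(0, 800), nitrate = c(0, 180), fluoride = c(0, 6)))
  base <- purrr::imap(rome_inputs, function(x, nm) x)
  for (model in names(sweeps)) {
    fis <- h$models[[model]]
    for (var in names(sweeps[[model]])) {
      rng <- sweeps[[model]][[var]]
      xs <- seq(rng[1], rng[2], length.out = 50)
      scores <- vapply(xs, function(v) {
        inp <- base[[model]]
        inp[var] <- v
        fis_eval(fis, inp)
      }, numeric(1))
      expect_true(all(diff(scores) <= 1.0),
                  info = sprintf("%s sweep of %s", model, var))
    }
  }
})

test_that("score columns respect reporting options and input aliases", {
  sample <- tibble::tibble(pH = 7.4, Alkalinity = 435, hardness = 329,
                           calcium = 101, magnesium = 19, iron = 0.0118,
                           fluoride = 0.14, nitrates = 3.5, sulphate = 13.7)
  report <- wq_score(sample, digits = 1)
  expect_equal(report$fwq1, 69.0)
  expect_equal(report$fwq, 85.8)
  expect_error(wq_score(dplyr::select(sample, -pH)),
               regexp = "ph", class = "aquafis_parse_error")
  # domain violations carry the row number
  bad <- dplyr::bind_rows(rome_sample(), rome_sample())
  bad$hardness[2] <- 5000
  expect_error(wq_score(bad), regexp = "row 2", class = "aquafis_domain_error")
  clamped <- suppressWarnings(wq_score(bad, clamp = TRUE))
  expect_equal(nrow(clamped), 2)
})

test_that("surface grids stay in range and degrade toward the poor corner", {
  f2 <- wq_submodel("FWQ2")
  grid <- wq_surface(f2, "ca", "mg", fixed = 0.0118, n = 7)
  expect_equal(nrow(grid), 49)
  expect_true(all(grid$score >= 0 & grid$score <= 100))
  best_corner <- grid$score[grid$ca == 0 & grid$mg == 0]
  worst_corner <- grid$score[grid$ca == 300 & grid$mg == 120]
  expect_gte(best_corner, worst_corner)
  # scores non-increasing along each axis (within tolerance)
  f1 <- wq_submodel("FWQ1")
  g1 <- wq_surface(f1, "hardness", "alkalinity", fixed = 7.4, n = 10)
  along_x <- g1 |>
    dplyr::group_by(alkalinity) |>
    dplyr::summarise(ok = all(diff(score) <= 1.0))
  expect_true(all(along_x$ok))
  expect_error(wq_surface(f2, "ca", "nope", fixed = 1),
               class = "aquafis_eval_error")
})

test_that("linguistic classification picks the maximal class, ties upward", {
  expect_equal(wq_classify(c(0, 50, 100)), c("VVL", "M", "VVH"))
  # midpoint between two peaks is an exact tie -> higher class wins
  expect_equal(wq_classify(25), "L")
  expect_equal(wq_classify(86.9, long = TRUE), "very high")
  expect_error(wq_classify(101), class = "aquafis_domain_error")
})
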