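test_that("reference coefficient sets load and validate", {
  sel <- reference_model("selection")
  expect_equal(unname(sel$coefficients[["intercept"]]), 2.16)
  expect_equal(unname(sel$coefficients[["generation_linear:regime_low"]]),
               -5.64)
  cr <- reference_model("crosses")
  expect_equal(unname(cr$coefficients[["intercept"]]), 63.93)
  expect_output(print(cr), "crosses")

  expect_error(reference_model("selection", file = "no/such/file.tsv"),
               "not found")
  bad <- tempfile(fileext = ".tsv")
  writeLines("term\testimate\nintercept\t1.0", bad)
  expect_error(reference_model("selection", file = bad), "missing terms")
})

test_that("selection predictions use the estimation-design polynomial basis", {
  m <- reference_model("selection")
  # independent oracle: rebuild the linear predictor from poly() on the
  # 32-lines-per-generation design and the printed coefficients
  pp <- poly(rep(1:5, each = 32), 2)
  P <- unique(round(cbind(pp[, 1], pp[, 2]), 12))
  P <- P[order(P[, 1]), ]
  co <- m$coefficients
  for (g in 1:5) {
    for (reg in c("high", "low")) {
      low <- as.numeric(reg == "low")
      want <- co[["intercept"]] + co[["generation_linear"]] * P[g, 1] +
        co[["generation_quadratic"]] * P[g, 2] + co[["regime_low"]] * low +
        co[["generation_linear:regime_low"]] * P[g, 1] * low +
        co[["generation_quadratic:regime_low"]] * P[g, 2] * low +
        0.5 * co[["block"]]
      expect_equal(predict_selection_response(m, g, reg), unname(want),
                   tolerance = 1e-9)
    }
  }
  # predictions lie on the observable 0-3 scale
  pr <- predict_selection_response(m, rep(1:5, 2), rep(c("high", "low"),
                                                       each = 5))
  expect_true(all(pr > 0 & pr < 3))
  # the five-point contrast basis reproduces the hand-computed high cell
  expect_equal(predict_selection_response(m, 3, "high", basis = "contrast"),
               2.16 + 0.75 * 2 / sqrt(14) - 0.03, tolerance = 1e-9)
  # the linear contrast is symmetric: it cancels over generations 1..5
  B <- dispersim:::generation_basis(1:5, "contrast")
  expect_equal(sum(B[, "linear"]), 0)
  expect_equal(sum(B[, "quadratic"]), 0)
  expect_error(predict_selection_response(m, 6, "high"), "between 1 and 5")
  expect_error(predict_selection_response(m, 2, "mid"), "regime")
})

test_that("cross predictions evaluate the printed cells", {
  m <- reference_model("crosses")
  expect_equal(predict_cross_means(m, "HmLf", "female"), 63.93)
  expect_equal(predict_cross_means(m, "HmHf", "female"), 63.93 + 22.81)
  expect_equal(predict_cross_means(m, "LmLf", "male"),
               63.93 - 21.16 + 0.83 + 2.50)
  cells <- expand.grid(ct = c("HmHf", "HmLf", "LmHf", "LmLf"),
                       sx = c("female", "male"), stringsAsFactors = FALSE)
  pr <- predict_cross_means(m, cells$ct, cells$sx)
  expect_true(all(pr >= 0 & pr <= 100))
  expect_error(predict_cross_means(m, "HfLm", "female"), "unknown cross")
})

test_that("R-squared follows its definition and affine invariance", {
  expect_equal(compute_r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 1, 7, 2)
  expect_equal(compute_r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(compute_r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(compute_r_squared(c(1, 2, 3), c(9, 9, 9)), 0)  # may be negative
  expect_error(compute_r_squared(1:3, 1:4), "equal length")
  expect_error(compute_r_squared(c(2, 2), c(1, 2)), "constant")
  # common affine rescaling of both vectors leaves R-squared unchanged
  set.seed(71)
  for (r in 1:10) {
    o <- rnorm(20); p <- o + rnorm(20, 0, 0.5)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(compute_r_squared(a * o + b, a * p + b),
                 compute_r_squared(o, p), tolerance = 1e-10)
  }
})

test_that("scan scoring is exact on prediction-valued data and bounded by refit", {
  m <- reference_model("selection")
  # a synthetic scan whose observations equal the predictions -> R2 = 1
  fake <- expand.grid(replicate = 1:3, regime = c("high", "low"),
                      generation = 1:5, stringsAsFactors = FALSE)
  fake$scenario <- 1L; fake$n_loci <- 1L; fake$sex_linked <- FALSE
  fake$d <- 0.5; fake$h <- 0.6; fake$A <- 0.8
  fake$mean_dispersals <- predict_selection_response(m, fake$generation,
                                                     fake$regime)
  fake$male_mean <- fake$female_mean <- fake$mean_dispersals
  class(fake) <- c("dispersal_scan", "data.frame")
  sc <- score_scan(fake, m)
  expect_equal(sc$r_squared, 1)
  expect_equal(sc$sex_bias_high, 0)

  # fixed-coefficient predictions can never beat least squares refitting
  grid <- build_parameter_grid(1)[c(35, 60, 85), ]
  scan <- run_parameter_scan(grid, n_repeats = 5, seed = 72)
  sc <- score_scan(scan, m)
  for (i in seq_len(nrow(grid))) {
    sub <- scan[scan$scenario == i, ]
    refit <- fit_selection_model(sub)
    r2_refit <- summary(refit)$r.squared
    expect_lte(sc$r_squared[i], r2_refit + 1e-10)
  }
})

test_that("increasing heritability does not damp the selection response", {
  # response amplitude (generation-5 regime divergence) is monotone-ish in h:
  # check the rank correlation across the h lattice at fixed d and A
  grid <- build_parameter_grid(1, d = 0.5, h = c(0.2, 0.4, 0.6, 0.8, 1),
                               A = 0.8)
  scan <- run_parameter_scan(grid, n_repeats = 8, seed = 73)
  g5 <- scan[scan$generation == 5, ]
  amp <- vapply(split(g5, g5$scenario), function(s)
    mean(s$mean_dispersals[s$regime == "high"]) -
      mean(s$mean_dispersals[s$regime == "low"]), 0)
  hs <- grid$h[as.integer(names(amp))]
  expect_gt(cor(hs, amp, method = "spearman"), 0.9)
})
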