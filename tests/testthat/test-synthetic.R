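test_that("noiseless selection data round-trips the printed coefficients", {
  m <- reference_model("selection")
  dat <- generate_selection_data(m, sigma_line = 0, sigma_res = 0)
  expect_equal(nrow(dat), 160)                       # 32 lines x 5 generations
  expect_equal(attr(dat, "n_truncated"), 0)
  # table equals predictions exactly (per-line block coding)
  pred <- predict_selection_response(m, dat$generation, dat$regime,
                                     block = "average") -
    0.5 * m$coefficients[["block"]] + dat$block * m$coefficients[["block"]]
  expect_equal(dat$mean_dispersals, unname(pred))
  expect_equal(compute_r_squared(dat$mean_dispersals, pred), 1)
  # refitting the same fixed-effect structure recovers every coefficient
  refit <- coef(fit_selection_model(dat))
  expect_equal(refit[names(m$coefficients)], m$coefficients,
               tolerance = 1e-8)
})

test_that("noiseless cross data round-trips the printed coefficients", {
  m <- reference_model("crosses")
  dat <- generate_cross_data(m, sigma_pair = 0, sigma_res = 0)
  expect_equal(nrow(dat), 128)                       # 16 pairs x 4 x 2
  fit <- suppressWarnings(fit_cross_model(dat, "interaction"))  # exact fit
  cf <- coef(fit)
  expect_equal(unname(cf[["(Intercept)"]]),
               unname(m$coefficients[["intercept"]]), tolerance = 1e-8)
  expect_equal(unname(cf[["cross_typeHmHf"]]),
               unname(m$coefficients[["cross_HmHf"]]), tolerance = 1e-8)
  expect_equal(unname(cf[["sexmale"]]),
               unname(m$coefficients[["sex_male"]]), tolerance = 1e-8)
  expect_equal(unname(cf[["cross_typeLmLf:sexmale"]]),
               unname(m$coefficients[["cross_LmLf:sex_male"]]),
               tolerance = 1e-8)
})

test_that("noisy generation recovers coefficients within sampling error", {
  m <- reference_model("selection")
  dat <- generate_selection_data(m, sigma_line = 0.05, sigma_res = 0.2,
                                 seed = 91)
  refit <- fit_selection_model(dat)
  est <- coef(refit)
  se <- sqrt(diag(vcov(refit)))
  z <- (est[names(m$coefficients)] - m$coefficients) / se[names(m$coefficients)]
  expect_true(all(abs(z) < 4))

  # pair-level variance at the printed magnitude leaves fixed effects unbiased
  mc <- reference_model("crosses")
  datc <- suppressMessages(
    generate_cross_data(mc, sigma_pair = 10.78, sigma_res = 5, seed = 92))
  fitc <- fit_cross_model(datc, "interaction")
  cf <- fitc$coefficients
  hmhf <- cf$estimate[cf$term == "cross_typeHmHf"]
  expect_lt(abs(hmhf - mc$coefficients[["cross_HmHf"]]),
            4 * cf$se[cf$term == "cross_typeHmHf"])
})

test_that("interval coverage is nominal across repeated generation", {
  m <- reference_model("selection")
  hits <- vapply(1:500, function(r) {
    dat <- suppressMessages(
      generate_selection_data(m, n_lines = 8, sigma_line = 0,
                              sigma_res = 0.2, seed = 9000 + r))
    refit <- fit_selection_model(dat)
    ci <- suppressMessages(confint(refit, "regime_low", level = 0.95))
    ci[1] <= m$coefficients[["regime_low"]] &&
      m$coefficients[["regime_low"]] <= ci[2]
  }, TRUE)
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("bounded responses are truncated and flagged", {
  m <- reference_model("selection")
  expect_message(
    dat <- generate_selection_data(m, sigma_line = 0, sigma_res = 2,
                                   seed = 93),
    "truncated")
  expect_gt(attr(dat, "n_truncated"), 0)
  expect_true(all(dat$mean_dispersals >= 0 & dat$mean_dispersals <= 3))
  expect_error(generate_selection_data(m, sigma_res = -1), ">= 0")

  # binomial alternative respects bounds by construction
  datb <- generate_cross_data(reference_model("crosses"), seed = 94,
                              family = "binomial")
  expect_true(all(datb$dispersers >= 0 & datb$dispersers <= 100))
  expect_true(all(datb$dispersers == round(datb$dispersers)))
})
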