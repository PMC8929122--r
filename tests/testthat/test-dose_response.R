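test_that("the Hill curve passes through its anchor points", {
  expect_equal(inhibition_model(57.7, 57.7), 50)
  expect_equal(inhibition_model(0, 100), 0)
  expect_equal(inhibition_model(300, 100, h = 1), 75)
  # 50% at the IC50 for any slope; strictly increasing in concentration
  for (h in c(0.5, 1, 2, 4)) {
    expect_equal(inhibition_model(42, 42, h), 50)
    cc <- 10^seq(-2, 4, length.out = 50)
    expect_true(all(diff(inhibition_model(cc, 42, h)) > 0))
  }
})

test_that("simulation is seed-reproducible and exact at zero noise", {
  d1 <- simulate_dose_response(57.7, seed = 7)
  d2 <- simulate_dose_response(57.7, seed = 7)
  expect_identical(d1, d2)

  d0 <- simulate_dose_response(100, noise_sd = 0)
  expect_equal(d0$inhibition_pct,
               inhibition_model(d0$concentration_umol_L, 100))
  # monotone mean response across levels at zero noise
  means <- tapply(d0$inhibition_pct, d0$concentration_umol_L, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  # default design: 8 levels spanning 1-1000, triplicates
  expect_equal(length(unique(d0$concentration_umol_L)), 8L)
  expect_equal(nrow(d0), 24L)
  expect_equal(range(d0$concentration_umol_L), c(1, 1000))
})

test_that("nls recovers exact parameters from noise-free data", {
  for (true in list(c(100, 1), c(57.7, 1.3), c(480.6, 0.8))) {
    d <- simulate_dose_response(true[1], h = true[2], noise_sd = 0,
                                conc_range = c(1, 5000))
    f <- fit_ic50(d, method = "nls")
    expect_equal(f$ic50, true[1], tolerance = 1e-6)
    expect_equal(f$h, true[2], tolerance = 1e-6)
    expect_false(f$extrapolated)
  }
})

test_that("log-linear interpolation reads the 50% crossing off the plot", {
  d <- data.frame(peptide = "x",
                  concentration_umol_L = rep(c(10, 1000), each = 2),
                  inhibition_pct = c(25, 25, 75, 75))
  f <- fit_ic50(d, method = "interpolation")
  expect_equal(f$ic50, 100)
  expect_true(is.na(f$h))

  # non-bracketing data cannot be interpolated
  low <- data.frame(peptide = "x", concentration_umol_L = c(1, 10),
                    inhibition_pct = c(5, 10))
  expect_error(fit_ic50(low, method = "interpolation"), "bracket")

  # agreement with nls on noise-free unit-slope data
  d2 <- simulate_dose_response(75, h = 1, noise_sd = 0)
  r <- fit_ic50(d2, "interpolation")$ic50 / fit_ic50(d2, "nls")$ic50
  expect_true(abs(r - 1) < 0.1)
})

test_that("fitting is scale-equivariant", {
  d <- simulate_dose_response(57.7, h = 1.2, noise_sd = 3, seed = 9)
  f1 <- fit_ic50(d)
  k <- 10
  d$concentration_umol_L <- d$concentration_umol_L * k
  f2 <- fit_ic50(d)
  expect_equal(f2$ic50, k * f1$ic50, tolerance = 1e-6)
  expect_equal(f2$h, f1$h, tolerance = 1e-6)
})

test_that("the fit object behaves like a fitted model", {
  d <- simulate_dose_response(57.7, seed = 5)
  f <- fit_ic50(d)
  expect_s3_class(f, "ic50_fit")
  expect_named(coef(f), c("ic50", "h"))
  expect_length(predict(f), nrow(d))
  expect_equal(predict(f, newdata = data.frame(concentration_umol_L = f$ic50)),
               50, tolerance = 1e-9)
  expect_equal(residuals(f), d$inhibition_pct - predict(f))
  expect_true(all(is.finite(f$se)))
  expect_output(print(f), "IC50")
  expect_output(summary(f), "residual SS")
  # dense data without 4 distinct levels is refused for nls
  d3 <- data.frame(peptide = "x", concentration_umol_L = rep(c(1, 10, 100), 4),
                   inhibition_pct = runif(12, 0, 100))
  expect_error(fit_ic50(d3), "4 distinct")
})

test_that("potency ratios compare fitted IC50s", {
  d1 <- simulate_dose_response(189.0, noise_sd = 0)
  d2 <- simulate_dose_response(57.7, noise_sd = 0)
  f1 <- fit_ic50(d1); f2 <- fit_ic50(d2)
  expect_equal(potency_ratio(f1, f2), 189.0 / 57.7, tolerance = 1e-6)
  expect_equal(potency_ratio(f1, f1), 1)
})

test_that("dose-response CSV round-trips through the reader", {
  d <- simulate_dose_response(100, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, tmp, row.names = FALSE)
  back <- read_dose_response(tmp)
  expect_s3_class(back, "dose_response")
  expect_equal(sort(back$inhibition_pct), sort(d$inhibition_pct))
})
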