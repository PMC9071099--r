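conc8 <- geometric_series(0.10, 21.54, 8)

test_that("fold change divides by the control mean and is scale invariant", {
  cur <- response_curve(conc8, rep(5, 8), c(2, 2, 2))
  fc <- fold_change(cur)
  expect_equal(unique(fc$obs$value), 2.5)
  expect_equal(fc$control_mean, 1)

  # a response equal to the control mean maps to 1
  cur2 <- response_curve(conc8, rep(2, 8), c(2, 2, 2))
  expect_equal(unique(fold_change(cur2)$obs$value), 1)

  # doubling every input leaves fold changes unchanged
  cur3 <- response_curve(conc8, rep(10, 8), c(4, 4, 4))
  expect_equal(fold_change(cur3)$obs$value, fc$obs$value)

  bad <- response_curve(conc8, rep(1, 8), c(-1, 1))
  expect_error(fold_change(bad), "control")
})

test_that("min-max normalisation attains [0,1] and flags constants", {
  expect_equal(as.numeric(min_max_normalize(c(1, 2, 3))), c(0, 0.5, 1))
  z <- min_max_normalize(c(4, 4))
  expect_equal(as.numeric(z), c(0, 0))
  expect_true(attr(z, "degenerate"))
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1))
    y <- min_max_normalize(x)
    expect_equal(range(y), c(0, 1))
  }
})

test_that("loess fitting reproduces lines, constants and Hill curves", {
  # collinear data with full span: the local linear fit IS the line
  y <- 2 * log10(conc8) + 5
  cur <- response_curve(conc8, y, c(5, 5))
  fit <- fit_loess(cur, loess_config(span = 1))
  expect_equal(predict_response(fit, conc8), y, tolerance = 1e-6)

  # constant responses give a constant fit
  flat <- response_curve(conc8, rep(3, 8), c(3, 3))
  ffit <- fit_loess(flat, loess_config())
  expect_equal(predict_response(ffit, conc8), rep(3, 8), tolerance = 1e-9)

  # noiseless Hill data: fit within 5% of the generating curve at the
  # design points (a moderate slope typical of the reporter inductions)
  m <- response_model(baseline = 1, max_fold_change = 3, hill_slope = 1,
    noise_sd = 0, ec50 = 2)
  hy <- model_response(m, conc8)
  hcur <- response_curve(conc8, matrix(rep(hy, 3), 8, 3), c(1, 1, 1))
  hfit <- fit_loess(hcur, loess_config())
  expect_lt(max(abs(predict_response(hfit, conc8) - hy) / hy), 0.05)

  expect_error(
    fit_loess(response_curve(conc8[1:3], 1:3, c(1, 1))),
    "4 distinct"
  )
})

test_that("PoD is undefined for flat curves and recovered for real onsets", {
  set.seed(5)
  flat <- response_curve(conc8, matrix(1 + rnorm(24, 0, 0.01), 8, 3),
    1 + rnorm(16, 0, 0.01))
  p <- compute_pod(flat)
  expect_true(is.na(p$pod))
  expect_equal(p$direction, "none")
  expect_false(p$censored)

  # noiseless curve with known onset c*: the fitted crossing must fall
  # within half a dilution step of c*
  onset <- 1.0
  m <- response_model(baseline = 100, max_fold_change = 3, hill_slope = 2,
    noise_sd = 10, onset_concentration = onset)
  y <- matrix(rep(model_response(m, conc8), 3), 8, 3)
  ctrl <- c(90, 110, 90, 110, 90, 110, 100, 100) # sd 8.86, close to 10
  cur <- response_curve(conc8, y, ctrl)
  p <- compute_pod(cur)
  expect_equal(p$direction, "positive")
  expect_lt(abs(log10(p$pod) - log10(onset)), log10(10^(1 / 6)))

  # mirrored curve: same PoD magnitude, negative direction
  ym <- 2 * 100 - y
  pm <- compute_pod(response_curve(conc8, ym, 2 * 100 - ctrl))
  expect_equal(pm$direction, "negative")
  expect_equal(log10(pm$pod), log10(p$pod), tolerance = 1e-6)
})

test_that("PoD censors at the lowest tested concentration, never extrapolates", {
  # effect already saturated at the lowest concentration
  m <- response_model(baseline = 1, max_fold_change = 5, hill_slope = 2,
    noise_sd = 0.05, ec50 = 0.01)
  y <- matrix(rep(model_response(m, conc8), 3), 8, 3)
  set.seed(9)
  p <- compute_pod(response_curve(conc8, y, 1 + rnorm(16, 0, 0.05)))
  expect_true(p$censored)
  expect_equal(p$pod, conc8[1])
  expect_equal(p$direction, "positive")
})

test_that("PoD grows with the control band and is affine invariant", {
  m <- response_model(baseline = 100, max_fold_change = 3, hill_slope = 1.5,
    noise_sd = 8, onset_concentration = 0.8)
  y <- matrix(rep(model_response(m, conc8), 3), 8, 3)
  set.seed(11)
  ctrl <- 100 + rnorm(16, 0, 8)
  pods <- sapply(c(0.5, 1, 2, 4), function(k) {
    inflated <- mean(ctrl) + (ctrl - mean(ctrl)) * k
    compute_pod(response_curve(conc8, y, inflated))$pod
  })
  defined <- !is.na(pods)
  expect_true(all(diff(pods[defined]) > -1e-9))
  if (any(!defined)) expect_true(all(which(!defined) > which(defined)))

  # joint affine rescaling of responses and controls leaves the PoD alone
  p0 <- compute_pod(response_curve(conc8, y, ctrl), input = "raw")
  p1 <- compute_pod(
    response_curve(conc8, 3.5 * y + 40, 3.5 * ctrl + 40),
    input = "raw"
  )
  expect_equal(p1$pod, p0$pod, tolerance = 1e-9)
  expect_equal(p1$direction, p0$direction)
})

test_that("the residual-SD band alternative is available", {
  m <- response_model(baseline = 100, max_fold_change = 3, hill_slope = 2,
    noise_sd = 10, onset_concentration = 1)
  set.seed(13)
  y <- matrix(model_response(m, conc8), 8, 3) + rnorm(24, 0, 10)
  cur <- response_curve(conc8, y, 100 + rnorm(16, 0, 10))
  pr <- compute_pod(cur, sd_method = "residual")
  expect_true(pr$control_sd > 0)
  # both bands should locate the onset within a dilution step here
  expect_lt(abs(log10(pr$pod) - log10(1)), 1 / 3 + 1e-9)
})

test_that("absolute IC50 is recovered exactly on noiseless log-logistic data", {
  for (true_ic50 in conc8[c(1, 4, 8)]) {
    m <- response_model(baseline = 100, max_fold_change = 2, hill_slope = 1.5,
      noise_sd = 0, direction = "decrease", ec50 = true_ic50)
    y <- model_response(m, conc8)
    r <- compute_ic50(response_curve(conc8, y, c(100, 100, 100)))
    expect_true(r$defined)
    expect_lt(abs(r$ic50 - true_ic50) / true_ic50, 0.01)
  }
})

test_that("absolute IC50 is undefined without a 50% crossing in range", {
  # flat viability at 100%
  r <- compute_ic50(response_curve(conc8, rep(100, 8), c(100, 100)))
  expect_false(r$defined)

  # declining but strictly above 50% everywhere: absolute, not relative
  m <- response_model(baseline = 100, max_fold_change = 1.4, hill_slope = 1,
    noise_sd = 0, direction = "decrease", ec50 = 2)
  y <- model_response(m, conc8) # plateaus near 60% viability, above 50
  expect_gt(min(y), 50)
  r2 <- compute_ic50(response_curve(conc8, y, c(100, 100, 100)))
  expect_false(r2$defined)

  # crossing beyond the highest tested concentration: censored "above"
  m3 <- response_model(baseline = 100, max_fold_change = 2, hill_slope = 1.5,
    noise_sd = 0, direction = "decrease", ec50 = 100)
  r3 <- compute_ic50(response_curve(conc8, model_response(m3, conc8),
    c(100, 100, 100)))
  expect_false(r3$defined)
  expect_equal(r3$censored, "above")
  expect_equal(r3$censored_bound, conc8[8])
})

test_that("condition tables flow through curves_from_table and pod_table", {
  design <- plate_design(c("2D-DMEM", "3D-DMEM"), "BTG2",
    list(cisplatin = conc8), durations = "72h")
  models <- list(
    `2D-DMEM:BTG2:cisplatin` = response_model(baseline = 100,
      max_fold_change = 4, hill_slope = 2, noise_sd = 5,
      onset_concentration = 0.5),
    `3D-DMEM:BTG2:cisplatin` = response_model(baseline = 100,
      max_fold_change = 1, hill_slope = 2, noise_sd = 5, ec50 = 1)
  )
  tbl <- generate_response_table(design, models, seed = 17)
  pods <- pod_table(tbl$wells)
  expect_equal(nrow(pods), 2)
  sensitive <- pods[pods$model == "2D-DMEM", ]
  insensitive <- pods[pods$model == "3D-DMEM", ]
  expect_lt(abs(log10(sensitive$pod_uM) - log10(0.5)), 1 / 3)
  expect_true(is.na(insensitive$pod_uM))
  expect_equal(insensitive$direction, "none")
})
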