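test_that("noise-free decay is recovered exactly", {
  t <- c(6, 12, 24, 48)
  d <- tibble::tibble(t = t, c = 10^(1.4 - 0.02 * t))
  fit <- fit_first_order(d, t, c)
  expect_equal(fit$intercept, 1.4, tolerance = 1e-12)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$half_life, log10(2) / 0.02, tolerance = 1e-12)
  expect_identical(fit$flag, "ok")
})

test_that("two points halving over 10 h give a 10 h half-life", {
  d <- tibble::tibble(t = c(0, 10, 20), c = c(100, 50, 25))
  fit <- fit_first_order(d, t, c)
  expect_equal(fit$half_life, 10, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate series are flagged or rejected", {
  flat <- tibble::tibble(t = c(0, 6, 12), c = rep(8, 3))
  fit <- fit_first_order(flat, t, c)
  expect_identical(fit$flag, "no elimination")
  expect_true(is.na(fit$half_life))
  neg <- tibble::tibble(t = c(0, 6, 12), c = c(5, -1, 2))
  expect_error(fit_first_order(neg, t, c), "positive")
  short <- tibble::tibble(t = c(0, 6), c = c(5, 4))
  expect_error(fit_first_order(short, t, c), "at least 3")
})

test_that("scaling concentrations shifts only the intercept", {
  d <- gen_pk(1.396, 0.0211, noise_sdlog = 0.1, seed = 3)
  f1 <- fit_first_order(d, time_h, concentration)
  d2 <- dplyr::mutate(d, concentration = concentration * 250)
  f2 <- fit_first_order(d2, time_h, concentration)
  expect_equal(f2$intercept, f1$intercept + log10(250), tolerance = 1e-10)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$half_life, f1$half_life, tolerance = 1e-10)
})

test_that("half-life identities and guards", {
  expect_equal(half_life(log10(2)), 1)
  b <- c(0.0211, 0.0203, 0.1)
  expect_equal(half_life(b) * b, rep(log10(2), 3), tolerance = 1e-15)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-0.1), "positive")
})

test_that("peak summary finds the right time, fold-change and tie-break", {
  grid <- c(6, 12, 24, 48)
  ctrl <- tibble::tibble(time = grid, value = 1, group = "control")
  # treated group: 10x the control at 12 h, lower elsewhere
  trt <- tibble::tibble(time = grid, value = c(4, 10, 6, 2), group = "NP")
  d <- dplyr::bind_rows(ctrl, trt)
  ps <- peak_summary(d, time, value, group, control = "control")
  expect_equal(ps$peak_time, 12)
  expect_equal(ps$fold_change, 10)
  # identical to control: fold-change 1 (peak at the earliest tied time)
  same <- dplyr::bind_rows(ctrl, dplyr::mutate(ctrl, group = "copy"))
  ps2 <- peak_summary(same, time, value, group, control = "control")
  expect_equal(ps2$fold_change, 1)
  expect_equal(ps2$peak_time, 6)
  # equal maxima at 6 and 12 h: earliest wins
  tie <- dplyr::bind_rows(
    ctrl, tibble::tibble(time = grid, value = c(9, 9, 3, 1), group = "NP"))
  expect_equal(peak_summary(tie, time, value, group)$peak_time, 6)
  # mismatched grids and zero control are errors
  bad <- dplyr::bind_rows(ctrl,
                          tibble::tibble(time = c(1, 2, 3, 4), value = 1,
                                         group = "NP"))
  expect_error(peak_summary(bad, time, value, group), "mismatched")
  zero <- dplyr::bind_rows(dplyr::mutate(ctrl, value = 0), trt)
  expect_error(peak_summary(zero, time, value, group), "zero")
})
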