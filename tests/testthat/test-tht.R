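theta <- list(F0 = 5, A = 95, k = 0.4, t_half = 18)

make_curve <- function(th = theta, times = seq(0, 48, by = 1), sd = 0,
                       seed = NULL) {
  v <- sigmoid_model(times, th$F0, th$A, th$k, th$t_half)
  if (sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, sd)
  }
  tibble::tibble(time = times, value = v)
}

test_that("sigmoid model: midpoint, asymptotes and closed-form value", {
  expect_equal(sigmoid_model(18, 5, 95, 0.4, 18), 5 + 95 / 2)
  expect_equal(sigmoid_model(1e6, 5, 95, 0.4, 18), 100)
  expect_equal(sigmoid_model(-1e6, 5, 95, 0.4, 18), 5)
  # closed form: A / (1 + e^-2) at two time constants past the midpoint
  expect_equal(sigmoid_model(24, 0, 100, 0.5, 20), 100 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(sigmoid_model(24, 0, 100, 0.5, 20), 88.0797, tolerance = 1e-4)
})

test_that("noise-free curves round-trip through the fitter", {
  grid <- expand.grid(k = c(0.2, 0.4, 0.8), t_half = c(12, 18, 30),
                      A = c(40, 95))
  for (i in seq_len(nrow(grid))) {
    th <- list(F0 = 5, A = grid$A[i], k = grid$k[i], t_half = grid$t_half[i])
    fit <- fit_sigmoid(make_curve(th), time, value)
    expect_true(fit$converged)
    expect_equal(fit$F0, th$F0, tolerance = 1e-6)
    expect_equal(fit$A, th$A, tolerance = 1e-6)
    expect_equal(fit$k, th$k, tolerance = 1e-6)
    expect_equal(fit$t_half, th$t_half, tolerance = 1e-6)
  }
})

test_that("lag time follows the tangent-at-midpoint identity exactly", {
  for (seed in 1:20) {
    fit <- fit_sigmoid(make_curve(sd = 2, seed = seed), time, value)
    expect_true(fit$converged)
    expect_identical(fit$lag_time + 2 / fit$k, fit$t_half)
  }
})

test_that("median rate recovery stays within 10% under plate-reader noise", {
  ks <- vapply(1:200, function(seed) {
    fit_sigmoid(make_curve(sd = 2, seed = seed), time, value)$k
  }, numeric(1))
  expect_lt(abs(stats::median(ks) - theta$k) / theta$k, 0.10)
})

test_that("degenerate and shifted inputs are handled", {
  flat <- tibble::tibble(time = 0:10, value = rep(7, 11))
  expect_error(fit_sigmoid(flat, time, value), "no transition")
  expect_error(fit_sigmoid(make_curve()[1:4, ], time, value),
               "at least 6")
  # uniform time shift of the whole curve moves t_half only
  f0 <- fit_sigmoid(make_curve(), time, value)
  shifted <- dplyr::mutate(make_curve(), time = time + 7)
  f1 <- fit_sigmoid(shifted, time, value)
  expect_equal(f1$t_half, f0$t_half + 7, tolerance = 1e-6)
  expect_equal(f1$k, f0$k, tolerance = 1e-6)
  expect_equal(f1$A, f0$A, tolerance = 1e-6)
  expect_equal(f1$F0, f0$F0, tolerance = 1e-6)
})

test_that("maximum-intensity decrease formula and guards", {
  expect_equal(max_intensity_decrease(100, 100), 0)
  expect_equal(max_intensity_decrease(100, 40), 60)
  expect_equal(max_intensity_decrease(100, 0), 100)
  expect_error(max_intensity_decrease(0, 40), "invalid baseline")
  f_ctrl <- fit_sigmoid(make_curve(), time, value)
  f_trt <- fit_sigmoid(make_curve(list(F0 = 5, A = 38, k = 0.25,
                                       t_half = 28)), time, value)
  expect_equal(max_intensity_decrease(f_ctrl, f_trt), 60, tolerance = 1e-5)
})

test_that("comparison table flags the inhibition direction", {
  d <- gen_tht(noise_sd = 0, n_replicates = 2, seed = 1)
  fits <- fit_tht(d)
  expect_true(all(fits$converged))
  cmp <- compare_fits(fits, control = "control")
  expect_equal(cmp$pct_decrease[cmp$label == "control"], 0)
  trt <- cmp[cmp$label != "control", ]
  expect_true(all(trt$lag_up & trt$k_down & trt$amp_down))
  # graded amplitudes give correspondingly ordered percent decreases
  expect_equal(cmp$pct_decrease[match(c("NP_D", "NP_L", "NP_achiral"),
                                      cmp$label)],
               c(63, 60, 11), tolerance = 1e-4)
  expect_error(compare_fits(fits, control = "missing"), "missing control")
  # control against itself: no inhibition flags
  self <- compare_fits(fits[fits$label == "control", ] |>
                         dplyr::mutate(label = c("control", "copy")),
                       control = "control")
  expect_false(any(self$lag_up[self$label == "copy"] &
                     self$k_down[self$label == "copy"]))
})
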