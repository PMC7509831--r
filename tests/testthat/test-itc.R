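geom <- itc_geometry()

test_that("stoichiometric and degenerate limits of the forward model", {
  # enormous K, early injections: every injected mole binds, so the heat is
  # dH times the moles injected (2 uL of 138 uM, in ucal)
  q <- one_site_heats(50, 1e12, -8, geom)
  moles_per_inj <- 2e-6 * 138e-6
  expect_equal(q[1], -8 * moles_per_inj * 1e9, tolerance = 0.01)
  expect_equal(q[2], -8 * moles_per_inj * 1e9, tolerance = 0.01)
  # zero enthalpy: all heats vanish
  expect_identical(one_site_heats(10, 1e6, 0, geom), rep(0, 20))
})

test_that("closed-form bound fraction matches a mass-action root finder", {
  n0 <- 10; K <- 3e6; dH <- -8
  cc <- npamyloid:::itc_concentrations(geom)
  closed <- npamyloid:::one_site_bound(cc$X_total, cc$M_total, n0, K)
  # independent oracle: solve X_t = X_f + n0 M K X_f / (1 + K X_f) for the
  # free titrant with uniroot, then bound = X_t - X_f
  oracle <- vapply(seq_along(cc$X_total), function(i) {
    Xt <- cc$X_total[i]; M <- cc$M_total[i]
    f <- function(Xf) Xf + n0 * M * K * Xf / (1 + K * Xf) - Xt
    Xf <- stats::uniroot(f, c(0, Xt), tol = 1e-18)$root
    Xt - Xf
  }, numeric(1))
  expect_equal(closed, oracle, tolerance = 1e-6)
})

test_that("cumulative heat saturates at the cell's binding capacity", {
  # long titration driving the sites to saturation
  g <- itc_geometry(injection_volumes_uL = rep(2, 120))
  n0 <- 5; K <- 1e7; dH <- -8
  total <- sum(one_site_heats(n0, K, dH, g))
  # total heat approaches dH * n0 * M0 * V0 adjusted for the material
  # flushed while titrating; conservation within a few percent
  capacity <- dH * n0 * 1.5e-6 * 200e-6 * 1e9
  expect_equal(total, capacity, tolerance = 0.05)
})

test_that("noise-free thermograms round-trip through the fitter", {
  truth <- list(n0 = 10, K = 3e6, dH = -8)
  d <- gen_itc(truth$n0, truth$K, truth$dH, geom, noise_prop = 0, seed = 1)
  fit <- fit_one_site(d, geom)
  expect_true(fit$converged)
  expect_equal(fit$n0, truth$n0, tolerance = 1e-4)
  expect_equal(fit$K, truth$K, tolerance = 1e-4)
  expect_equal(fit$dH, truth$dH, tolerance = 1e-4)
  expect_equal(fit$q_dil, 0, tolerance = 1e-6)
})

test_that("degenerate all-zero thermogram is flagged, not fitted", {
  d <- tibble::tibble(injection = 1:20, volume_uL = 2, heat_ucal = 0)
  fit <- fit_one_site(d, geom)
  expect_false(fit$converged)
  expect_match(fit$message, "degenerate")
})

test_that("c-value outside the reliable window warns but still fits", {
  # c = n0 K M0 far above 1e4
  d <- gen_itc(10, 1e10, -8, geom, noise_prop = 0, seed = 1)
  expect_warning(fit_one_site(d, geom), "c-value")
})

test_that("thermodynamic identities hold to machine precision", {
  expect_equal(derive_thermo(1, -8)$dG, 0)
  th <- derive_thermo(3e6, -8, 298.15)
  expect_equal(th$dG, -1.987e-3 * 298.15 * log(3e6), tolerance = 1e-15)
  expect_equal(th$dG, -8 - 298.15 * th$dS / 1000, tolerance = 1e-12)
  # dH equal to dG leaves no entropic contribution
  dG <- derive_thermo(5e4, 0)$dG
  expect_equal(derive_thermo(5e4, dG)$dS, 0, tolerance = 1e-12)
  # monotonicity: larger K, more favourable dG
  expect_lt(derive_thermo(1e7, -8)$dG, derive_thermo(1e6, -8)$dG)
})

test_that("a 2.5-fold binding-constant ratio is ~0.54 kcal/mol of Gibbs energy", {
  K_L <- itc_truth_default("L")$K
  ddG <- derive_thermo(2.5 * K_L, -8)$dG - derive_thermo(K_L, -8)$dG
  expect_equal(ddG, -1.987e-3 * 298.15 * log(2.5), tolerance = 1e-12)
  expect_equal(abs(ddG), 0.543, tolerance = 0.002)
})
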