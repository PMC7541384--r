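# time-varying elastance chambers and their activation functions

test_that("atrial activation peaks at the component amplitude and the empty
           sum vanishes", {
  # single Gaussian centred at 0.145 s: value at the centre is the amplitude
  expect_equal(activation_sum(0.145, 0.9, 0.038, 0.145, form = "atrial"), 0.9)
  expect_equal(activation_sum(0.3, numeric(0), numeric(0), numeric(0),
                              form = "atrial"), 0)
  expect_equal(activation_sum(0.3, c(0, 0), c(0.1, 0.1), c(0.1, 0.2),
                              form = "ventricular", time_scale = 0.95), 0)
  # linear offset is additive for the atrial form
  expect_equal(activation_sum(0.145, 0.9, 0.038, 0.145, form = "atrial",
                              linear_term = 0.2), 1.1)
})

test_that("both activation forms match the literal Gaussian-sum oracle", {
  p <- default_params_cached()
  rv <- p$chambers$rv
  ph <- seq(0, 0.784, length.out = 97)
  b <- time_scale(0.5)
  expect_digits(
    activation_sum(ph, rv$A, rv$B, rv$C, "ventricular", time_scale = b),
    or_act_vent(ph, rv$A, rv$B, rv$C, b))
  la10 <- p$scenarios$lvdd
  A <- pmax(la10$la_a_0 + la10$la_k_a * 400, 0)
  expect_digits(
    activation_sum(ph, A, la10$la_b, la10$la_c, "atrial", linear_term = 0.05),
    or_act_atr(ph, A, la10$la_b, la10$la_c, 0.05))
  # the ventricular exponent has no 0.5 factor; the atrial one does
  expect_gt(or_act_atr(0.2, 0.9, 0.038, 0.145),
            or_act_vent(0.2, 0.9, 0.038, 0.145, 1))
})

test_that("activation is periodic through the cardiac clock", {
  p <- default_params_cached()
  lv <- p$chambers$lv
  T <- p$simulation$T
  t <- seq(0, T, length.out = 41)
  e0 <- activation_sum(cycle_phase(t, T), lv$A, lv$B, lv$C, "ventricular",
                       time_scale = 0.95)
  e2 <- activation_sum(cycle_phase(t + 2 * T, T), lv$A, lv$B, lv$C,
                       "ventricular", time_scale = 0.95)
  expect_equal(e0, e2)
})

test_that("contractility scale and systolic clock are affine in drive", {
  expect_equal(contractility_scale(0.5), 1.5)
  expect_equal(time_scale(0.5), 0.95)
  expect_equal(contractility_scale(0), -2)
  expect_equal(time_scale(0), 0.7)
  # peak LV end-systolic elastance at reference drive
  expect_equal(contractility_scale(0.5) * 4.3, 6.45)
  expect_error(contractility_scale(2), "\\[0, 1\\]")
})

test_that("ESPVR and EDPVR hit their intercepts and reference values", {
  expect_equal(espvr_pressure(40, 4.3, 40, a = 1.5), 0)
  expect_equal(espvr_pressure(100, 4.3, 40, a = 1.5), 387)
  expect_equal(espvr_pressure(70, 0.3, 20), 15)
  expect_equal(edpvr_pressure(25, 1.7, 0.015, 25), 0)
  expect_equal(edpvr_pressure(125, 1.7, 0.015, 25), 1.7 * (exp(1.5) - 1))
  expect_equal(edpvr_pressure(25, 0.67, 0.015, 25), 0)
  V <- seq(30, 200, by = 5)
  expect_true(all(diff(edpvr_pressure(V, 1.7, 0.015, 25)) > 0))
  expect_true(all(edpvr_pressure(V, 1.7, 0.015, 25) >= 0))
})

test_that("chamber pressure is the activation-weighted ESPVR/EDPVR blend", {
  p <- default_params_cached()
  lv <- p$chambers$lv
  V <- c(60, 100, 140)
  for (phase in c(0.05, 0.3, 0.36, 0.6)) {
    e <- activation_sum(phase, lv$A, lv$B, lv$C, "ventricular",
                        time_scale = time_scale(0.5))
    expect_digits(
      chamber_pressure(V, phase, lv, F_con = 0.5),
      or_chamber(V, e, contractility_scale(0.5), lv$E_es, lv$V_d, lv$M_0,
                 lv$lambda, lv$V_0))
  }
  # diastasis (activation ~ 0 far from the Gaussian centres) -> EDPVR
  expect_equal(chamber_pressure(100, 0.75, lv),
               edpvr_pressure(100, lv$M_0, lv$lambda, lv$V_0),
               tolerance = 1e-6)
  # atria ignore the contractility multiplier
  la <- p$chambers$la
  expect_equal(chamber_pressure(70, 0.145, la, F_con = 0.9),
               chamber_pressure(70, 0.145, la, F_con = 0.1))
})

test_that("for a filled chamber the pressure peak tracks the activation peak", {
  p <- default_params_cached()
  lv <- p$chambers$lv
  ph <- seq(0, 0.78, length.out = 400)
  e <- activation_sum(ph, lv$A, lv$B, lv$C, "ventricular",
                      time_scale = time_scale(0.5))
  pr <- chamber_pressure(rep(120, length(ph)), ph, lv)
  expect_equal(which.max(pr), which.max(e))
})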