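# vessel pressure-volume and resistance laws

test_that("systemic vein law: zero point, operating point, over-fill error", {
  expect_equal(systemic_vein_pressure(3500 / 1.99), 0)   # log10(1) = 0
  expect_equal(systemic_vein_pressure(2610), 18.19, tolerance = 1e-3)
  expect_error(systemic_vein_pressure(3500 / 0.99), "domain")
  expect_error(systemic_vein_pressure(3600), "domain")
  V <- seq(1200, 3400, by = 50)
  expect_true(all(diff(systemic_vein_pressure(V)) > 0))
})

test_that("vena cava law: branch selection, boundary, resistance", {
  expect_equal(vena_cava_pressure(130), 0)           # upper branch at V_vc_0
  expect_equal(vena_cava_pressure(100), -5 + 0.4 * exp(2))
  expect_equal(vena_cava_resistance(350), 0.026)
  # the printed law is discontinuous at the branch point; the boundary value
  # belongs to the upper (linear) branch
  expect_equal(vena_cava_pressure(130 - 1e-9), -5 + 0.4 * exp((130 - 1e-9) / 50),
               tolerance = 1e-6)
  expect_error(vena_cava_pressure(-5), "domain")
  expect_error(vena_cava_resistance(0), "positive")
  V <- seq(60, 340, by = 10)
  expect_true(all(diff(vena_cava_resistance(V)) < 0))
})

test_that("proximal systemic artery law: stressed-volume origin, blend,
           resistance", {
  for (F in c(0, 0.3, 1))
    expect_equal(sap_pressure(210, F_vaso = F), (1 - F) * 0.03)
  expect_equal(sap_pressure(240, F_vaso = 0.5), 192.361, tolerance = 1e-3)
  expect_equal(sap_resistance(250, F_vaso = 0.5), 0.04 * (exp(2) + 1))
  expect_error(sap_pressure(200), "domain")
  expect_error(sap_pressure(240, F_vaso = 2), "\\[0, 1\\]")
  V <- seq(211, 250, by = 1)
  expect_true(all(diff(sap_pressure(V)) > 0))
})

test_that("linear and saturating-log laws", {
  expect_equal(linear_pressure(0, 9), 0)
  expect_equal(linear_pressure(45, 9), 5)
  expect_equal(linear_pressure(90, 9), 2 * linear_pressure(45, 9))
  expect_error(linear_pressure(10, 0), "positive")
  expect_equal(log_vessel_pressure(0, 20, 100), 0)
  expect_equal(log_vessel_pressure(50, 20, 100), -20 * log(0.5))
  expect_error(log_vessel_pressure(100, 20, 100), "domain")
  expect_error(log_vessel_pressure(99.95, 20, 100), "domain") # 0.1% guard
  V <- seq(0, 95, by = 5)
  P <- log_vessel_pressure(V, 20, 100)
  expect_true(all(diff(P) > 0))
  expect_true(all(diff(diff(P)) > 0)) # strictly convex
})

test_that("stenosis radius / resistance arithmetic", {
  expect_equal(stenosis_radius(0), 1)
  expect_equal(stenosed_resistance(0, 0.06), 0.06)
  # halving the radius multiplies the resistance by 1/(0.5)^4 = 16
  t_half <- (2^4 - 1) / 0.018 # r(t) = 0.5
  expect_equal(stenosis_radius(t_half), 0.5)
  expect_equal(stenosed_resistance(t_half, 0.06) / 0.06, 16)
  expect_equal(stenosed_resistance(700, 0.06), (1 + 0.018 * 700) * 0.06)
  t <- seq(0, 700, by = 50)
  expect_true(all(diff(stenosed_resistance(t, 0.06)) > 0))
})

test_that("RC-time decay, stenosed compliance and the R*C identity", {
  expect_equal(stenosed_compliance(0, 0.54, 0.0008, 0.06), 9)
  expect_equal(rc_time(700, 0.54, 0.0008), 0.54 * exp(-0.56))
  t <- seq(0, 700, by = 35)
  expect_equal(stenosed_resistance(t, 0.06) *
                 stenosed_compliance(t, 0.54, 0.0008, 0.06),
               rc_time(t, 0.54, 0.0008), tolerance = 1e-14)
  expect_true(all(diff(stenosed_compliance(t, 0.54, 0.0008, 0.06)) < 0))
  # pressure law is V / C(t)
  expect_equal(stenosed_pressure(18, 700, 0.54, 0.0008, 0.06),
               18 / stenosed_compliance(700, 0.54, 0.0008, 0.06))
})

test_that("pressure-dependent compliance and implied resistance", {
  expect_equal(compliance_from_mpap(0, 14, 0.031), 14)
  expect_equal(compliance_from_mpap(9, 14, 0.031), 14 * exp(-0.279))
  expect_equal(resistance_from_rc(0.54, 14 * exp(-0.279)), 0.051,
               tolerance = 1e-3)
  # resistance non-decreasing in mean pressure for fixed RC-time
  Pm <- seq(0, 60, by = 2)
  R <- resistance_from_rc(0.54, compliance_from_mpap(Pm, 14, 0.031))
  expect_true(all(diff(R) > 0))
  expect_error(resistance_from_rc(0.5, 0), "positive")
})

test_that("every law matches its re-typed oracle at 100 random admissible
           inputs to 12 significant digits", {
  set.seed(42)
  n <- 100
  V <- runif(n, 1000, 3400)
  expect_digits(systemic_vein_pressure(V), or_sv(V))
  V <- runif(n, 55, 345)
  expect_digits(vena_cava_pressure(V), or_vc_p(V))
  expect_digits(vena_cava_resistance(V), or_vc_r(V))
  V <- runif(n, 210.5, 249.5)
  F <- runif(n, 0, 1)
  for (k in seq_len(n)) {
    expect_digits(sap_pressure(V[k], F[k]), or_sap_p(V[k], F[k]))
    expect_digits(sap_resistance(V[k], F[k]), or_sap_r(V[k], F[k]))
  }
  V <- runif(n, 0, 95)
  expect_digits(log_vessel_pressure(V, 20, 100), or_log(V, 20, 100))
  expect_digits(linear_pressure(V, 7), or_lin(V, 7))
  t <- runif(n, 0, 700)
  expect_digits(stenosis_radius(t), or_radius(t))
  expect_digits(stenosed_resistance(t, 0.06), or_sten_R(t, 0.06))
  expect_digits(stenosed_compliance(t, 0.54, 0.0008, 0.06),
                or_sten_C(t, 0.54, 0.0008, 0.06))
  expect_digits(stenosed_pressure(15, t, 0.54, 0.0008, 0.06),
                or_sten_P(15, t, 0.54, 0.0008, 0.06))
  expect_digits(rc_time(t, 1.05, 0.0005), or_tau(t, 1.05, 0.0005))
  Pm <- runif(n, 0, 80)
  expect_digits(compliance_from_mpap(Pm, 20, 0.03), or_C_pm(Pm, 20, 0.03))
})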