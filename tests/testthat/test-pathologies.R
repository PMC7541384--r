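# per-cycle disease-progression schedules

mk_state <- function(p, scenario = "normal") {
  schedule_init(scenario, p, unlist(p$initial$volumes))
}

edge_R <- function(p, name) p$edges$R[match(name, p$edges$name)]

test_that("every scheduled scalar starts at its normal-state value", {
  p <- default_params_cached()
  st <- mk_state(p)
  for (sc in c("dpas", "lvdd", "vsd", "ms")) {
    st$scenario <- sc
    upd <- apply_schedule(p, st, 0)$params
    expect_equal(upd$chambers$rv$E_es, p$chambers$rv$E_es, info = sc)
    if (sc == "dpas") {
      expect_equal(edge_R(upd, "lpad_lpv"), 0.06)
      expect_equal(upd$vessels$rpad$C, 0.54 / 0.06) # tau_0 / R_rpad_0
      expect_equal(upd$vessels$lpap$K, 20)
    }
    if (sc == "lvdd") {
      expect_equal(upd$chambers$lv$M_0, 1.7)
      expect_equal(upd$chambers$lv$lambda, 0.015)
      expect_equal(upd$chambers$la$E_es, 0.3)
      expect_equal(upd$vessels$rpap$K, 20)
      expect_equal(upd$vessels$rpad$K, 15)
      expect_equal(upd$vessels$rpv$K, 5)
    }
    if (sc == "vsd")
      expect_equal(edge_R(upd, "Rltor"), 100)
    if (sc == "ms")
      expect_equal(edge_R(upd, "Dm"), 0.02)
  }
})

test_that("stenosis schedule: growth law, compliance coupling, elastance
           breakpoint continuity", {
  p <- default_params_cached()
  st <- mk_state(p, "dpas")
  u100 <- dpas_update(p, 100, st)
  expect_equal(u100$params$chambers$rv$E_es, 0.8 + 0.0013 * 100)
  u700 <- dpas_update(p, 700, st)
  expect_equal(edge_R(u700$params, "rpad_rpv") / 0.06, 1 + 0.018 * 700)
  expect_equal(u700$params$vessels$rpad$C,
               rc_time(700, 0.54, 0.0008) * stenosis_radius(700)^4 / 0.06)
  # proximal arteries on the saturating log law from onset
  expect_equal(u700$params$vessels$lpap,
               list(law = "log_saturating", K = 20, V_m = 100))
  # distal resistance strictly increases across successive cycle boundaries
  T <- p$simulation$T
  Rs <- sapply((0:40) * T, function(t) edge_R(dpas_update(p, t, st)$params,
                                              "lpad_lpv"))
  expect_true(all(diff(Rs) > 0))
  # both elastance branches agree at the breakpoint time
  st$t_c <- 400
  before <- dpas_update(p, 400 - 1e-9, st)$params$chambers$rv$E_es
  after <- dpas_update(p, 400, st)$params$chambers$rv$E_es
  expect_equal(before, after, tolerance = 1e-9)
  # and grow at the slower post-breakpoint rate afterwards
  e500 <- dpas_update(p, 500, st)$params$chambers$rv$E_es
  expect_equal(e500, 0.8 + 0.0013 * 400 + 0.0008 * 100)
})

test_that("diastolic-dysfunction schedule reaches its printed endpoints with
           clamped pulmonary stiffness", {
  p <- default_params_cached()
  st <- mk_state(p, "lvdd")
  u <- lvdd_update(p, 700, st)$params
  expect_equal(u$chambers$lv$M_0, 4.5)
  expect_equal(u$chambers$lv$lambda, 0.022)
  expect_equal(u$chambers$rv$E_es, 0.8 + 0.0012 * 700)
  expect_equal(u$chambers$la$E_es, 0.3 + 0.0004 * 700)
  expect_equal(u$vessels$rpap$K, 44.5)
  expect_true(u$vessels$rpap$K > 19 && u$vessels$rpap$K < 56)
  expect_equal(u$vessels$rpad$K, 15 + 0.035 * 700)
  expect_equal(u$vessels$rpv$K, 5 + 0.02 * 700)
  # ten-Gaussian atrial activation with scheduled amplitudes, clamped at 0
  expect_length(u$chambers$la$A, 10)
  expect_equal(u$chambers$la$A[3], 0.9 - 0.000655 * 700)
  expect_true(all(u$chambers$la$A >= 0))
  # far extrapolation would drive a_3 negative: clamp holds
  ufar <- lvdd_update(p, 2000, st)$params
  expect_equal(ufar$chambers$la$A[3], 0)
  # resistance law: RC-time over pressure-dependent compliance
  st2 <- st
  st2$Pm$rpad <- 9
  u2 <- lvdd_update(p, 0, st2)$params
  expect_equal(edge_R(u2, "rpad_rpv"), 0.54 / (14 * exp(-0.031 * 9)))
})

test_that("septal-defect schedule: shunt resistance decay and atrial
           activation growth", {
  p <- default_params_cached()
  st <- mk_state(p, "vsd")
  u0 <- vsd_update(p, 0, st)$params
  expect_equal(edge_R(u0, "Rltor"), 100)
  u <- vsd_update(p, 700, st)$params
  expect_equal(edge_R(u, "Rltor"), 100 / (1 + 0.0408 * 700)^2)
  expect_equal(u$chambers$la$A, c(0.9, 0.0392, 0.0392))
  expect_equal(u$chambers$la$B, c(0.038, 0.05, 0.05))
  expect_equal(u$chambers$la$C, c(0.145, 0.37, 0.42))
  expect_equal(u$chambers$rv$E_es, 0.8 + 0.0012 * 700)
  expect_equal(u$chambers$la$E_es, 0.3 + 0.0003 * 700)
  expect_equal(u$vessels$rpv$K, 5 + 0.035 * 700)
})

test_that("mitral-stenosis schedule: valve resistance, atrial stiffening and
           the three-Gaussian-plus-linear activation", {
  p <- default_params_cached()
  st <- mk_state(p, "ms")
  u <- ms_update(p, 700, st)$params
  expect_equal(edge_R(u, "Dm"), 0.23)
  expect_equal(u$chambers$la$E_es, 0.3 + 0.0003 * 700)
  expect_equal(u$chambers$la$M_0, 0.5 + 0.001 * 700)
  expect_equal(u$chambers$la$lambda, 0.025 + 0.0000056 * 700)
  expect_equal(u$chambers$la$A[1], 0.9 - 0.000336 * 700)
  expect_equal(u$chambers$la$A[2], 0.000168 * 700)
  expect_equal(u$chambers$la$linear_term, 0.000336 * 700)
  expect_equal(u$chambers$rv$E_es, 0.8 + 0.0012 * 700)
})

test_that("the driver applies schedules once per completed cycle and the
           normal schedule is the identity", {
  p <- default_params_cached()
  traj <- simulate_circulation("normal", duration = 5, params = p,
                               record_every = 0)
  expect_equal(nrow(traj$snapshots), traj$meta$ncycles)
  expect_equal(traj$meta$ncycles, floor(5 / p$simulation$T))
  expect_true(all(traj$snapshots$E_es_rv == p$chambers$rv$E_es))
  # scenario snapshots carry strictly increasing scheduled resistance
  td <- simulate_circulation("dpas", duration = 5, params = p,
                             record_every = 0)
  expect_true(all(diff(td$snapshots$R_rpad) > 0))
  expect_equal(td$snapshots$t, (seq_len(td$meta$ncycles) - 1) * p$simulation$T)
})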