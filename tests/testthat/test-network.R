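# network assembly, derivative evaluation, fixed-step integration

test_that("diode valve flow clamps reverse bias", {
  expect_equal(valve_flow(-5, 0.02), 0)
  expect_equal(valve_flow(10, 0.02), 500)
  expect_equal(valve_flow(0, 0.02), 0)
  expect_error(valve_flow(5, 0), "positive")
})

test_that("derivatives vanish at pressure equilibrium and conserve volume
           everywhere", {
  topo <- ring_toy(C = c(1, 2, 4), R = c(0.5, 1, 2))
  # equal pressures: volumes proportional to compliances
  d <- circuit_derivatives(topo, V = c(10, 20, 40))
  expect_equal(unname(d$dV), c(0, 0, 0))
  expect_equal(unname(d$P), c(10, 10, 10))
  set.seed(7)
  for (k in 1:25) {
    V <- runif(3, 5, 60)
    d <- circuit_derivatives(topo, V)
    expect_equal(sum(d$dV), 0, tolerance = 1e-13)
  }
  # full model: conservation by construction at a perturbed state
  p <- default_params_cached()
  topo <- build_topology(p)
  V <- unlist(p$initial$volumes)[compartment_names()] * runif(25, 0.97, 1.03)
  d <- circuit_derivatives(topo, V, Q = c(5, 1, 1, 10, 0, 0, 0), phase = 0.31)
  expect_equal(sum(d$dV), 0, tolerance = 1e-10)
})

test_that("two-compartment relaxation matches the closed form with 4th-order
           step-size convergence", {
  C1 <- 1; C2 <- 2; R <- 1
  topo <- rc_toy(C1, C2, R)
  V0 <- c(30, 10)
  k <- (1 / C1 + 1 / C2) / R
  vinf <- sum(V0) * C1 / (C1 + C2)
  exact <- function(t) vinf + (V0[1] - vinf) * exp(-k * t)
  err <- sapply(c(0.02, 0.01), function(dt) {
    n <- round(1 / dt)
    res <- integrate_topology(topo, V0, dt = dt, nsteps = n, record_every = 0)
    abs(res$V[1] - exact(n * dt))
  })
  expect_lt(err[2], 1e-6)
  ratio <- err[1] / err[2]
  expect_gt(ratio, 8)   # classical RK4: global error O(dt^4)
  expect_lt(ratio, 32)
  # forward Euler compatibility mode is only first order
  err_e <- sapply(c(0.02, 0.01), function(dt) {
    n <- round(1 / dt)
    res <- integrate_topology(topo, V0, dt = dt, nsteps = n, record_every = 0,
                              euler = TRUE)
    abs(res$V[1] - exact(n * dt))
  })
  expect_gt(err_e[1] / err_e[2], 1.7)
  expect_lt(err_e[1] / err_e[2], 2.3)
})

test_that("a valveless linear network relaxes to the capacitance-proportional
           equilibrium", {
  topo <- ring_toy(C = c(1, 2, 4), R = c(0.5, 1, 2))
  V0 <- c(50, 10, 10)
  res <- integrate_topology(topo, V0, dt = 0.005, nsteps = 4000,
                            record_every = 0)
  expect_equal(res$V, sum(V0) * c(1, 2, 4) / 7, tolerance = 1e-6)
  expect_equal(sum(res$V), sum(V0), tolerance = 1e-10)
})

test_that("a reverse-biased valve isolates its compartments", {
  topo <- new_topology(
    node_laws = c(n1 = "linear", n2 = "linear"),
    node_params = list(n1 = 1, n2 = 1),
    edges = data.frame(name = "dv", from = "n1", to = "n2", R = 0.1,
                       R_law = "constant", L = 0, valve = TRUE))
  res <- integrate_topology(topo, c(5, 20), dt = 0.01, nsteps = 100,
                            record_every = 10)
  expect_equal(res$V, c(5, 20)) # downstream pressure higher: diode blocks
  expect_true(all(res$rec_F == 0))
})

test_that("integration failure reports the offending node and time", {
  topo <- new_topology(
    node_laws = c(n1 = "linear", n2 = "log_saturating"),
    node_params = list(n1 = 10, n2 = c(5, 30)),
    edges = data.frame(name = "e", from = "n1", to = "n2", R = 0.05,
                       R_law = "constant", L = 0, valve = FALSE))
  # the upstream reservoir holds enough pressure to drive n2 into its
  # 30 ml saturation guard
  expect_error(
    integrate_topology(topo, c(400, 25), dt = 0.01, nsteps = 5000),
    "integration failure at t = .*node 2")
})

test_that("the normal run conserves volume, keeps valve flows one-way and is
           step-size robust", {
  traj <- normal_run_cached()
  tot <- traj$meta$total_volume
  dev <- max(abs(c(traj$cycles$volmin, traj$cycles$volmax) - tot))
  expect_lt(dev / tot, 1e-3)   # closed circuit (in fact ~1e-14 relative)
  p <- default_params_cached()
  topo <- build_topology(p)
  valves <- topo$edge_names[topo$evalve == 1]
  expect_true(all(traj$cycles$qmin[, valves] > -1e-9))
  expect_true(all(traj$samples$flow[, valves] > -1e-9))
  # halving dt changes converged systolic pressures by far less than 0.5%
  t2 <- simulate_circulation("normal", duration = 3, params = p,
                             dt = 0.00025, record_every = 0)
  t1 <- simulate_circulation("normal", duration = 3, params = p,
                             record_every = 0)
  n <- t1$meta$ncycles
  rel <- abs(t2$cycles$pmax[n, ] - t1$cycles$pmax[n, ]) /
    pmax(abs(t1$cycles$pmax[n, ]), 1)
  expect_lt(max(rel), 0.005)
})

test_that("steady-cycle detection finds periodic convergence and rejects
           too-short runs", {
  traj <- normal_run_cached()
  sc <- steady_cycle(traj)
  expect_true(sc >= 2 && sc <= traj$meta$ncycles)
  short <- simulate_circulation("normal", duration = 1,
                                params = default_params_cached(),
                                record_every = 0)
  expect_error(steady_cycle(short), "at least 3 cycles")
})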