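# Independent brute-force oracles: every closed-form law re-typed literally
# from its defining formula, sharing no code with the package implementation.

or_heart_rate <- function(Fs, Fv, h = c(35, 140, 40, 32, 10, 20)) {
  h[1] + h[2] * Fs - h[3] * Fs^2 - h[4] * Fv + h[5] * Fv^2 - h[6] * Fv * Fs
}

or_sv <- function(V, Kv = 40, Vmax = 3500) -Kv * log10(Vmax / V - 0.99)

or_vc_p <- function(V, N1 = 0, K1 = 0.15, Vvc0 = 130, N2 = -5, K2 = 0.4,
                    Vmin = 50) {
  ifelse(V >= Vvc0, N1 + K1 * (V - Vvc0), N2 + K2 * exp(V / Vmin))
}

or_vc_r <- function(V, KR = 0.001, Vmax = 350, R0 = 0.025) KR * Vmax / V + R0

or_sap_p <- function(V, F = 0.5, Kc = 1000, N0 = 50, Kp1 = 0.03, tau = 0.1,
                     Kp2 = 0.2, Vmin = 210) {
  Pa <- Kc * log10((V - Vmin) / N0 + 1)
  Pp <- Kp1 * exp(tau * (V - Vmin)) + Kp2 * (V - Vmin)^2
  F * Pa + (1 - F) * Pp
}

or_sap_r <- function(V, F = 0.5, Kr = 0.04, Vmax = 250) {
  Kr * (exp(4 * F) + (Vmax / V)^2)
}

or_lin <- function(V, C) V / C

or_log <- function(V, K, Vm) -K * log(1 - V / Vm)

or_radius <- function(t, r0 = 1, gr = 0.018) r0 * (1 + gr * t)^(-1 / 4)

or_sten_R <- function(t, R0, r0 = 1, gr = 0.018) {
  (1 / or_radius(t, r0, gr))^4 * R0
}

or_tau <- function(t, tau0, sigma) tau0 * exp(-sigma * t)

or_sten_C <- function(t, tau0, sigma, R0, r0 = 1, gr = 0.018) {
  or_tau(t, tau0, sigma) * or_radius(t, r0, gr)^4 / R0
}

or_sten_P <- function(V, t, tau0, sigma, R0, r0 = 1, gr = 0.018) {
  V * R0 / (or_tau(t, tau0, sigma) * or_radius(t, r0, gr)^4)
}

or_C_pm <- function(Pm, gc, hc) gc * exp(-hc * Pm)

or_act_vent <- function(phase, A, B, C, b) {
  sapply(phase, function(p) sum(A * exp(-((b * p - C) / B)^2)))
}

or_act_atr <- function(phase, A, B, C, lin = 0) {
  sapply(phase, function(p) sum(A * exp(-0.5 * ((p - C) / B)^2)) + lin)
}

or_espvr <- function(V, a, Ees, Vd) a * Ees * (V - Vd)

or_edpvr <- function(V, M0, lam, V0) M0 * abs(exp(lam * (V - V0)) - 1)

or_chamber <- function(V, e, a, Ees, Vd, M0, lam, V0) {
  e * or_espvr(V, a, Ees, Vd) + (1 - e) * or_edpvr(V, M0, lam, V0)
}

expect_digits <- function(actual, expected, digits = 12) {
  scale <- pmax(abs(expected), 1e-300)
  expect_lt(max(abs(actual - expected) / scale), 10^(-digits))
}

# --- toy circuits -----------------------------------------------------------

# two linear compartments joined by one resistor (closed 2-node system):
# volumes relax exponentially toward the capacitance-proportional split
rc_toy <- function(C1 = 1, C2 = 2, R = 1) {
  new_topology(
    node_laws = c(n1 = "linear", n2 = "linear"),
    node_params = list(n1 = C1, n2 = C2),
    edges = data.frame(name = "r12", from = "n1", to = "n2", R = R,
                       R_law = "constant", L = 0, valve = FALSE)
  )
}

# valveless three-compartment ring for conservation / equilibrium properties
ring_toy <- function(C = c(1, 2, 4), R = c(0.5, 1, 2)) {
  new_topology(
    node_laws = c(a = "linear", b = "linear", d = "linear"),
    node_params = list(a = C[1], b = C[2], d = C[3]),
    edges = data.frame(name = c("ab", "bd", "da"),
                       from = c("a", "b", "d"), to = c("b", "d", "a"),
                       R = R, R_law = "constant", L = 0, valve = FALSE)
  )
}

default_params_cached <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_params()
    p
  }
})

# short normal run shared by several test files
normal_run_cached <- local({
  traj <- NULL
  function() {
    if (is.null(traj))
      traj <<- simulate_circulation("normal", duration = 10,
                                    params = default_params_cached())
    traj
  }
})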