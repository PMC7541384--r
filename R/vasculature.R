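# Vessel pressure-volume and resistance laws.
#
# The laws that the network integrator evaluates (linear, systemic-vein,
# vena-cava, proximal-systemic-artery, saturating-log) are routed through
# the compiled evaluators so the exported functions and the solver share one
# implementation.  The disease-progression machinery (stenosis radius,
# RC-time, pressure-dependent compliance) is plain R: it runs once per
# cardiac cycle, between integrations.

law_code <- c(linear = 0L, sv_log10 = 1L, vc_piecewise = 2L, sap_blend = 3L,
              log_saturating = 4L, chamber = 5L)

vessel_eval <- function(law, p, V) {
  out <- cpp_vessel_pressure(law_code[[law]], as.numeric(p), as.numeric(V))
  if (anyNA(out))
    stop("volume outside the admissible domain of the ", law, " pressure law")
  out
}

#' Systemic vein pressure-volume law
#'
#' \eqn{P = -K_v \log_{10}(V_{max}/V - 0.99)}: the veins act as a soft blood
#' reservoir that stiffens sharply as volume approaches its maximum.  The
#' argument of the logarithm must stay positive (an over-filled vein is a
#' domain error).
#'
#' @param V vein volume (ml).
#' @param K_v scaling factor (mmHg).
#' @param V_sv_max maximum systemic vein volume (ml).
#' @return pressure (mmHg).
#' @export
#' @examples
#' systemic_vein_pressure(2610) # about 18 mmHg, the normal operating point
systemic_vein_pressure <- function(V, K_v = 40, V_sv_max = 3500) {
  vessel_eval("sv_log10", c(K_v, V_sv_max), V)
}

#' Vena cava pressure and resistance laws
#'
#' The pressure-volume relation is a two-branch function: linear
#' \eqn{N_1 + K_1 (V - V_{vc,0})} at and above the unstressed volume, and
#' exponential \eqn{N_2 + K_2 e^{V/V_{vc,min}}} below it (a collapsing
#' vessel).  The boundary volume belongs to the upper branch.  The outflow
#' resistance \eqn{R = K_R V_{vc,max}/V + R_0} falls as the cava fills.
#'
#' @param V vena cava volume (ml), positive.
#' @param N_1,K_1,V_vc_0,N_2,K_2,V_vc_min pressure-law constants.
#' @param K_R,R_0,V_vc_max resistance-law constants.
#' @return pressure (mmHg) or resistance (mmHg.s/ml).
#' @export
vena_cava_pressure <- function(V, N_1 = 0, K_1 = 0.15, V_vc_0 = 130,
                               N_2 = -5, K_2 = 0.4, V_vc_min = 50) {
  vessel_eval("vc_piecewise", c(N_1, K_1, V_vc_0, N_2, K_2, V_vc_min), V)
}

#' @rdname vena_cava_pressure
#' @export
vena_cava_resistance <- function(V, K_R = 0.001, R_0 = 0.025, V_vc_max = 350) {
  out <- cpp_edge_resistance(1L, 0, c(K_R, V_vc_max, R_0), as.numeric(V))
  if (anyNA(out)) stop("vena cava volume must be positive")
  out
}

#' Proximal systemic artery pressure and resistance laws
#'
#' Vasoconstriction blends a fully activated logarithmic branch with a
#' passive exponential-plus-quadratic branch:
#' \eqn{P = F_{vaso} P^a + (1 - F_{vaso}) P^p}, both branches written in the
#' stressed volume \eqn{V - V_{sap,min}} (volumes below the minimum are a
#' domain error).  The outflow resistance is
#' \eqn{R = K_r [e^{4 F_{vaso}} + (V_{sap,max}/V)^2]}.
#'
#' @param V artery volume (ml), at least `V_sap_min`.
#' @param F_vaso normalized vasoconstriction frequency in \[0, 1\].
#' @param K_c,N_0,K_p1,tau_aop,K_p2,V_sap_min pressure-law constants.
#' @param K_r,V_sap_max resistance-law constants.
#' @return pressure (mmHg) or resistance (mmHg.s/ml).
#' @export
sap_pressure <- function(V, F_vaso = 0.5, K_c = 1000, N_0 = 50, K_p1 = 0.03,
                         tau_aop = 0.1, K_p2 = 0.2, V_sap_min = 210) {
  if (any(F_vaso < 0 | F_vaso > 1)) stop("F_vaso must lie in [0, 1]")
  vessel_eval("sap_blend", c(F_vaso, K_c, N_0, V_sap_min, K_p1, tau_aop, K_p2),
              V)
}

#' @rdname sap_pressure
#' @export
sap_resistance <- function(V, F_vaso = 0.5, K_r = 0.04, V_sap_max = 250) {
  if (any(F_vaso < 0 | F_vaso > 1)) stop("F_vaso must lie in [0, 1]")
  out <- cpp_edge_resistance(2L, 0, c(K_r, F_vaso, V_sap_max), as.numeric(V))
  if (anyNA(out)) stop("artery volume must be positive")
  out
}

#' Linear compartment pressure
#'
#' \eqn{P = V/C}, the default Windkessel law for vessels without a special
#' nonlinear relation.
#'
#' @param V volume (ml).
#' @param C compliance (ml/mmHg), positive.
#' @return pressure (mmHg).
#' @export
linear_pressure <- function(V, C) {
  if (any(C <= 0)) stop("compliance must be positive")
  vessel_eval("linear", C[1], V)
}

#' Saturating logarithmic vessel law
#'
#' \eqn{P = -K \ln(1 - V/V_m)}: pressure rises without bound as the volume
#' approaches the structural maximum \eqn{V_m}.  Used for the pulmonary
#' vessels once disease drives them out of the linear regime.  States within
#' 0.1% of \eqn{V_m} are rejected as a physiological-limit error rather than
#' returning a near-infinite pressure.
#'
#' @param V volume (ml) in \[0, V_m).
#' @param K stiffness constant (mmHg).
#' @param V_m maximum vessel volume (ml).
#' @return pressure (mmHg), non-negative.
#' @export
#' @examples
#' log_vessel_pressure(50, 20, 100) # 13.86 mmHg
log_vessel_pressure <- function(V, K, V_m) {
  if (any(V_m <= 0)) stop("V_m must be positive")
  vessel_eval("log_saturating", c(K, V_m), V)
}

#' Progressive stenosis of the distal pulmonary arteries
#'
#' Vascular remodelling narrows the lumen over disease time:
#' \eqn{r(t) = r_0 (1 + g_r t)^{-1/4}} (dimensionless radius ratio), and by
#' Poiseuille's law the resistance scales with \eqn{(1/r)^4}, so
#' \eqn{R(t) = (1 + g_r t)\,R_0} for \eqn{r_0 = 1}.  Halving the radius
#' multiplies the resistance by 16.
#'
#' @param t disease time (s, non-negative).
#' @param r_0 initial radius ratio (1 for a healthy vessel).
#' @param g_r narrowing rate (1/s).
#' @param R_0 initial resistance (mmHg.s/ml).
#' @return radius ratio (dimensionless) or resistance (mmHg.s/ml).
#' @export
stenosis_radius <- function(t, r_0 = 1, g_r = 0.018) {
  stopifnot(all(t >= 0))
  r_0 * (1 + g_r * t)^(-1 / 4)
}

#' @rdname stenosis_radius
#' @export
stenosed_resistance <- function(t, R_0, r_0 = 1, g_r = 0.018) {
  (1 / stenosis_radius(t, r_0, g_r))^4 * R_0
}

#' RC-time decay and the stenosed compliance / pressure laws
#'
#' The product of a vascular bed's resistance and compliance (its RC-time)
#' decays as the bed stiffens: \eqn{\tau(t) = \tau_0 e^{-\sigma t}}.
#' Combined with the stenosis law this fixes the compliance
#' \eqn{C(t) = \tau(t) r(t)^4 / R_0} and the pressure
#' \eqn{P = V R_0 / (\tau(t) r(t)^4)}; the identity
#' \eqn{R(t)\,C(t) = \tau(t)} holds to machine precision.
#'
#' @param t disease time (s, non-negative).
#' @param tau_0 initial RC-time (s).
#' @param sigma decay rate (1/s).
#' @param R_0 initial resistance (mmHg.s/ml).
#' @param r_0,g_r stenosis-radius constants, see [stenosis_radius()].
#' @param V volume (ml).
#' @return RC-time (s), compliance (ml/mmHg) or pressure (mmHg).
#' @export
rc_time <- function(t, tau_0, sigma) {
  stopifnot(all(t >= 0))
  tau_0 * exp(-sigma * t)
}

#' @rdname rc_time
#' @export
stenosed_compliance <- function(t, tau_0, sigma, R_0, r_0 = 1, g_r = 0.018) {
  rc_time(t, tau_0, sigma) * stenosis_radius(t, r_0, g_r)^4 / R_0
}

#' @rdname rc_time
#' @export
stenosed_pressure <- function(V, t, tau_0, sigma, R_0, r_0 = 1, g_r = 0.018) {
  V * R_0 / (rc_time(t, tau_0, sigma) * stenosis_radius(t, r_0, g_r)^4)
}

#' Pressure-dependent compliance and the implied resistance
#'
#' Pulmonary vascular compliance decays exponentially with the bed's mean
#' pressure, \eqn{C = g_c e^{-h_c P_m}}; together with the scheduled RC-time
#' this yields the bed resistance \eqn{R = \tau(t)/C}.
#'
#' @param P_m mean compartment pressure over the previous cardiac cycle
#'   (mmHg, non-negative).
#' @param g_c compliance scale (ml/mmHg).
#' @param h_c pressure sensitivity (1/mmHg).
#' @param tau RC-time (s).
#' @param C compliance (ml/mmHg), positive.
#' @return compliance (ml/mmHg) or resistance (mmHg.s/ml).
#' @export
compliance_from_mpap <- function(P_m, g_c, h_c) {
  stopifnot(all(P_m >= 0))
  g_c * exp(-h_c * P_m)
}

#' @rdname compliance_from_mpap
#' @export
resistance_from_rc <- function(tau, C) {
  if (any(C <= 0)) stop("compliance must be positive")
  tau / C
}
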