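# Time-varying elastance chamber models.
#
# A chamber pressure is the activation-weighted blend of an end-systolic
# (linear) and an end-diastolic (exponential) pressure-volume relation.
# Ventricular activation is a four-Gaussian sum whose time axis is stretched
# by the contractility clock b(F_con) and whose exponent is exp[-x^2];
# atrial activation uses exp[-0.5 x^2] (one Gaussian normally, replaced by
# richer sums plus an optional linear term under the disease schedules).
# The asymmetry between the two exponents is deliberate: each form is
# implemented exactly as specified.

#' Gaussian-sum activation function
#'
#' Evaluates the periodic activation weight at a cycle phase.  The
#' `"ventricular"` form is \eqn{\sum_i A_i \exp[-((b\,\phi - C_i)/B_i)^2]}
#' with `time_scale` = b(F_con); the `"atrial"` form is
#' \eqn{\sum_i A_i \exp[-\tfrac12((\phi - C_i)/B_i)^2] + \mathrm{linear\_term}}
#' with unit time scale.  Components centred at the cycle boundary are
#' evaluated without periodic wrap-around (their tails into the next cycle
#' are ignored; widths are small enough that the truncation is negligible).
#'
#' @param phase cycle phase in \[0, T) seconds (vectorized).
#' @param A,B,C amplitudes (dimensionless), widths (s) and centres (s) of the
#'   Gaussian components; equal lengths.
#' @param form `"ventricular"` or `"atrial"`.
#' @param time_scale the clock stretch b(F_con) (ventricular form only).
#' @param linear_term constant offset added to the atrial form (used by the
#'   mitral-stenosis schedule, frozen per cycle).
#' @return activation values, same length as `phase`.
#' @export
#' @examples
#' activation_sum(0.145, A = 0.9, B = 0.038, C = 0.145, form = "atrial") # 0.9
activation_sum <- function(phase, A, B, C, form = c("ventricular", "atrial"),
                           time_scale = 1, linear_term = 0) {
  form <- match.arg(form)
  stopifnot(length(A) == length(B), length(B) == length(C), all(B > 0),
            time_scale > 0)
  if (length(A) == 0) return(rep(linear_term, length(phase)))
  cpp_activation(as.numeric(phase), as.numeric(A), as.numeric(B),
                 as.numeric(C), if (form == "ventricular") 0L else 1L,
                 time_scale, linear_term)
}

#' Contractility scale and systolic clock from sympathetic drive
#'
#' `contractility_scale()` returns \eqn{a = a_{min} + K_a F_{con}}, the
#' multiplier applied to ventricular end-systolic elastance;
#' `time_scale()` returns \eqn{b = b_{min} + K_b F_{con}}, the stretch of
#' the ventricular activation clock (larger b shortens systole).
#'
#' @param F_con normalized sympathetic efferent frequency in \[0, 1\].
#' @param a_min,K_a,b_min,K_b response constants.
#' @return dimensionless scale factor.
#' @export
#' @examples
#' contractility_scale(0.5) # 1.5
#' time_scale(0.5)          # 0.95
contractility_scale <- function(F_con, a_min = -2, K_a = 7) {
  if (any(F_con < 0 | F_con > 1)) stop("F_con must lie in [0, 1]")
  a_min + K_a * F_con
}

#' @rdname contractility_scale
#' @export
time_scale <- function(F_con, b_min = 0.7, K_b = 0.5) {
  if (any(F_con < 0 | F_con > 1)) stop("F_con must lie in [0, 1]")
  b_min + K_b * F_con
}

#' End-systolic pressure-volume relation
#'
#' Linear ESPVR \eqn{P = a\,E_{es}(V - V_d)}; for atria the contractility
#' multiplier `a` is identically 1.
#'
#' @param V chamber volume (ml).
#' @param E_es end-systolic elastance (mmHg/ml).
#' @param V_d volume intercept (ml).
#' @param a contractility multiplier a(F_con).
#' @return pressure (mmHg); negative if V transiently dips below V_d.
#' @export
espvr_pressure <- function(V, E_es, V_d, a = 1) a * E_es * (V - V_d)

#' End-diastolic pressure-volume relation
#'
#' Exponential EDPVR \eqn{P = M_0\,|\exp[\lambda(V - V_0)] - 1|}; zero at
#' the intercept V_0 and strictly increasing above it.
#'
#' @param V chamber volume (ml).
#' @param M_0 pressure intercept (mmHg).
#' @param lambda stiffness constant (1/ml).
#' @param V_0 volume intercept (ml).
#' @return pressure (mmHg), non-negative.
#' @export
edpvr_pressure <- function(V, M_0, lambda, V_0) {
  M_0 * abs(exp(lambda * (V - V_0)) - 1)
}

#' Instantaneous chamber pressure
#'
#' The elastance blend \eqn{P = e\,P_{ES} + (1 - e)\,P_{ED}} with activation
#' e evaluated at the given phase: pure EDPVR at e = 0 (diastasis), pure
#' ESPVR at e = 1.
#'
#' @param V chamber volume (ml), vectorized.
#' @param phase cycle phase (s); scalar or same length as `V`.
#' @param chamber a chamber parameter list with fields `E_es`, `M_0`,
#'   `lambda`, `V_0`, `V_d`, activation vectors `A`, `B`, `C` and `form`
#'   (`"ventricular"` or `"atrial"`), e.g. one entry of
#'   `default_params()$chambers`.
#' @param F_con normalized sympathetic frequency driving a(F_con), b(F_con)
#'   (ventricles; ignored for atria).
#' @param a_min,K_a,b_min,K_b contractility-control constants.
#' @param linear_term constant activation offset (atrial disease schedules).
#' @return pressure (mmHg).
#' @export
chamber_pressure <- function(V, phase, chamber, F_con = 0.5,
                             a_min = -2, K_a = 7, b_min = 0.7, K_b = 0.5,
                             linear_term = 0) {
  vent <- identical(chamber$form, "ventricular")
  a <- if (vent) contractility_scale(F_con, a_min, K_a) else 1
  b <- if (vent) time_scale(F_con, b_min, K_b) else 1
  chp <- c(a, chamber$E_es, chamber$V_d, chamber$M_0, chamber$lambda,
           chamber$V_0)
  cpp_chamber_pressure(as.numeric(V), as.numeric(phase), chp,
                       as.numeric(chamber$A), as.numeric(chamber$B),
                       as.numeric(chamber$C), if (vent) 0L else 1L, b,
                       linear_term)
}
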