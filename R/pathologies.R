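# Disease-progression schedules: deterministic per-cycle parameter updates
# that morph the normal model into each pulmonary hypertension scenario.
# Disease time t is the simulation time in seconds (the chronic progression
# is compressed onto the 700 s run); every schedule is a closed-form
# function of t and of the previous cycle's mean pressures, applied at cycle
# boundaries only and frozen within a cycle.

pap_nodes <- c("lpap", "rpap")
pad_nodes <- c("lpad", "rpad")
pv_nodes <- c("lpv", "rpv")
pulm_nodes <- c(pap_nodes, pad_nodes, pv_nodes)
pulm_out_edge <- c(lpap = "lpap_lpad", rpap = "rpap_rpad",
                   lpad = "lpad_lpv", rpad = "rpad_rpv",
                   lpv = "lpv_la", rpv = "rpv_la")

set_edge_R <- function(params, name, R) {
  i <- match(name, params$edges$name)
  if (is.na(i)) stop("no edge named ", name)
  params$edges$R[i] <- R
  params
}

pulm_group <- function(nm) {
  if (nm %in% pap_nodes) "p" else if (nm %in% pad_nodes) "d" else "v"
}

# pulmonary progression shared by the LVDD / VSD / MS schedules:
# switch the six pulmonary compartments to the saturating-log P-V law with
# linearly growing stiffness K(t), and set their outflow resistances from
# the decaying RC-time and the pressure-dependent compliance of the bed.
pulm_progression <- function(params, sc, t, Pm, kK, Kclamp = NULL) {
  snap <- c()
  for (nm in pulm_nodes) {
    grp <- pulm_group(nm)
    side <- sub("^(l|r).*", "\\1", nm)
    K0 <- sc[[paste0("K_", nm, "_0")]]
    K <- K0 + kK[[grp]] * t
    if (!is.null(Kclamp)) {
      K <- min(max(K, Kclamp[[grp]][1]), Kclamp[[grp]][2])
    }
    params$vessels[[nm]] <- list(law = "log_saturating", K = K,
                                 V_m = sc[[paste0("V_m_", nm)]])
    tau <- rc_time(t, sc[[paste0("tau_", nm, "_0")]],
                   sc[[paste0("sigma_", nm)]])
    C <- compliance_from_mpap(Pm[[nm]], sc[[paste0("g_c", grp)]],
                              sc[[paste0("h_c", grp)]])
    R <- resistance_from_rc(tau, C)
    params <- set_edge_R(params, pulm_out_edge[[nm]], R)
    if (side == "r")
      snap[paste0(c("K_", "R_"), nm)] <- c(K, R)
  }
  list(params = params, snapshot = snap)
}

#' Scenario parameter schedules
#'
#' Each updater maps the base (normal) configuration and a disease time `t`
#' (seconds of simulation time) to the configuration in force for the cycle
#' starting at `t`.  They are pure functions of `t` and the cached per-cycle
#' observations in `state` (previous-cycle mean pulmonary pressures, mean
#' pulmonary artery pressure, and for the stenosis scenario the breakpoint
#' time `t_c` at which mPAP first reached 50 mmHg).
#'
#' * `dpas_update()`: distal pulmonary artery stenosis.  Distal resistances
#'   grow as \eqn{(1 + g_r t) R_0} while their compliances follow the
#'   decaying RC-time; the proximal pulmonary arteries take the saturating
#'   log P-V law; right ventricular elastance rises piecewise-linearly with
#'   a rate break once mPAP reaches 50 mmHg.
#' * `lvdd_update()`: diastolic dysfunction.  LV end-diastolic stiffness
#'   (`M_lv`, `lambda_lv`) rises; all six pulmonary vessels take growing log
#'   laws (stiffness clamped to the admissible ranges); their resistances
#'   follow RC-time over pressure-dependent compliance; the left atrium
#'   stiffens and its activation becomes a scheduled ten-Gaussian sum.
#' * `vsd_update()`: ventricular septal defect.  A resistive shunt branch
#'   between the ventricles opens as \eqn{R_{ltor}(t) = R_0/(1 + k_r t)^2};
#'   pulmonary vessels progress as above; the left atrial activation becomes
#'   a three-Gaussian sum with a growing second peak.
#' * `ms_update()`: mitral stenosis.  The mitral resistance rises linearly;
#'   the left atrium stiffens and its activation becomes three Gaussians
#'   plus a linear term; pulmonary vessels progress as above.
#'
#' Scheduled activation amplitudes are clamped at zero.
#'
#' @param params the base `circ_params` configuration.
#' @param t disease time (s), the cycle-boundary time.
#' @param state schedule state as carried by [simulate_circulation()]:
#'   list with `Pm` (named previous-cycle mean pressures of the six
#'   pulmonary compartments), `mpap`, and `t_c`.
#' @return list with the updated `params` and a named `snapshot` vector of
#'   the scheduled values in force.
#' @name scenario_schedules
NULL

#' @rdname scenario_schedules
#' @export
dpas_update <- function(params, t, state) {
  sc <- params$scenarios$dpas
  for (nm in pap_nodes)
    params$vessels[[nm]] <- list(law = "log_saturating",
                                 K = sc[[paste0("K_", nm, "_0")]],
                                 V_m = sc[[paste0("V_m_", nm)]])
  r <- stenosis_radius(t, sc$r_0, sc$g_r)
  for (nm in pad_nodes) {
    R0 <- sc[[paste0("R_", nm, "_0")]]
    params$vessels[[nm]] <- list(law = "linear",
                                 C = stenosed_compliance(t, sc$tau_0, sc$sigma,
                                                         R0, sc$r_0, sc$g_r))
    params <- set_edge_R(params, pulm_out_edge[[nm]],
                         stenosed_resistance(t, R0, sc$r_0, sc$g_r))
  }
  E0 <- params$chambers$rv$E_es
  E <- if (!is.na(state$t_c) && t >= state$t_c)
    E0 + sc$k_1 * state$t_c + sc$k_2 * (t - state$t_c)
  else E0 + sc$k_1 * t
  params$chambers$rv$E_es <- E
  list(params = params,
       snapshot = c(E_es_rv = E, r = r,
                    R_rpad = stenosed_resistance(t, sc$R_rpad_0, sc$r_0, sc$g_r),
                    C_rpad = params$vessels$rpad$C,
                    mpap = state$mpap, t_c = state$t_c))
}

#' @rdname scenario_schedules
#' @export
lvdd_update <- function(params, t, state) {
  sc <- params$scenarios$lvdd
  params$chambers$lv$M_0 <- params$chambers$lv$M_0 + sc$k_3 * t
  params$chambers$lv$lambda <- params$chambers$lv$lambda + sc$k_4 * t
  params$chambers$rv$E_es <- params$chambers$rv$E_es + sc$k_8 * t
  params$chambers$la$E_es <- params$chambers$la$E_es + sc$k_9 * t
  params$chambers$la$M_0 <- params$chambers$la$M_0 + sc$k_10 * t
  params$chambers$la$lambda <- params$chambers$la$lambda + sc$k_11 * t
  params$chambers$la$A <- pmax(sc$la_a_0 + sc$la_k_a * t, 0)
  params$chambers$la$B <- sc$la_b
  params$chambers$la$C <- sc$la_c
  pg <- pulm_progression(params, sc, t, state$Pm,
                         kK = list(p = sc$k_5, d = sc$k_6, v = sc$k_7),
                         Kclamp = list(p = c(sc$K_pap_min, sc$K_pap_max),
                                       d = c(sc$K_pad_min, sc$K_pad_max),
                                       v = c(sc$K_pv_min, sc$K_pv_max)))
  list(params = pg$params,
       snapshot = c(M_lv = pg$params$chambers$lv$M_0,
                    lambda_lv = pg$params$chambers$lv$lambda,
                    E_es_rv = pg$params$chambers$rv$E_es,
                    E_es_la = pg$params$chambers$la$E_es,
                    a_3 = pg$params$chambers$la$A[3],
                    pg$snapshot, mpap = state$mpap))
}

#' @rdname scenario_schedules
#' @export
vsd_update <- function(params, t, state) {
  sc <- params$scenarios$vsd
  R_ltor <- sc$R_ltor_0 / (1 + sc$k_r * t)^2
  if (!"Rltor" %in% params$edges$name) {
    params$edges <- rbind(params$edges,
                          data.frame(name = "Rltor", from = "lv", to = "rv",
                                     R = R_ltor, R_law = "constant", L = 0,
                                     valve = FALSE))
  } else {
    params <- set_edge_R(params, "Rltor", R_ltor)
  }
  params$chambers$rv$E_es <- params$chambers$rv$E_es + sc$k_rv_v * t
  params$chambers$la$E_es <- params$chambers$la$E_es + sc$k_la_v * t
  alpha <- pmax(sc$alpha_0 + c(0, sc$k_alpha2, sc$k_alpha3) * t, 0)
  params$chambers$la$A <- alpha
  params$chambers$la$B <- sc$beta
  params$chambers$la$C <- sc$omega
  pg <- pulm_progression(params, sc, t, state$Pm,
                         kK = list(p = sc$k_vsd_p, d = sc$k_vsd_d,
                                   v = sc$k_vsd_v))
  list(params = pg$params,
       snapshot = c(R_ltor = R_ltor,
                    E_es_rv = pg$params$chambers$rv$E_es,
                    E_es_la = pg$params$chambers$la$E_es,
                    alpha_2 = alpha[2], alpha_3 = alpha[3],
                    pg$snapshot, mpap = state$mpap))
}

#' @rdname scenario_schedules
#' @export
ms_update <- function(params, t, state) {
  sc <- params$scenarios$ms
  R_m <- sc$R_m_0 + sc$k_12 * t
  params <- set_edge_R(params, "Dm", R_m)
  params$chambers$la$E_es <- params$chambers$la$E_es + sc$k_13 * t
  params$chambers$la$M_0 <- params$chambers$la$M_0 + sc$k_14 * t
  params$chambers$la$lambda <- params$chambers$la$lambda + sc$k_15 * t
  params$chambers$rv$E_es <- params$chambers$rv$E_es + sc$k_rv_m * t
  X <- pmax(sc$X_0 + c(-sc$k_x1, sc$k_x2, sc$k_x3) * t, 0)
  params$chambers$la$A <- X
  params$chambers$la$B <- sc$Y
  params$chambers$la$C <- sc$Z
  # printed linear term of the scheduled activation, frozen at the boundary
  params$chambers$la$linear_term <- sc$k_x1 * t
  pg <- pulm_progression(params, sc, t, state$Pm,
                         kK = list(p = sc$k_ms_p, d = sc$k_ms_d,
                                   v = sc$k_ms_v))
  list(params = pg$params,
       snapshot = c(R_m = R_m, E_es_rv = pg$params$chambers$rv$E_es,
                    E_es_la = pg$params$chambers$la$E_es, X_1 = X[1],
                    pg$snapshot, mpap = state$mpap))
}

#' Apply the active scenario's schedule at a cycle boundary
#'
#' Dispatches to the scenario updater with the boundary time; the normal
#' scenario is the identity.  Called once per completed cardiac cycle by
#' [simulate_circulation()].
#'
#' @inheritParams scenario_schedules
#' @param state schedule state (see [scenario_schedules]).
#' @return list with `params`, `state` and `snapshot`.
#' @export
apply_schedule <- function(params, state, t) {
  upd <- switch(state$scenario,
                normal = list(params = params,
                              snapshot = c(E_es_rv = params$chambers$rv$E_es,
                                           mpap = state$mpap)),
                dpas = dpas_update(params, t, state),
                lvdd = lvdd_update(params, t, state),
                vsd = vsd_update(params, t, state),
                ms = ms_update(params, t, state))
  upd$state <- state
  upd
}

# initial schedule state: previous-cycle means seeded from the initial state
schedule_init <- function(scenario, params, vols) {
  Pm <- numeric(0)
  for (nm in pulm_nodes)
    Pm[nm] <- linear_pressure(vols[[nm]], params$vessels[[nm]]$C)
  pap0 <- mean(Pm[pap_nodes])
  list(scenario = scenario, t_c = NA_real_, Pm = as.list(Pm),
       mpap = mean_pap(pap0, pap0))
}

# cache the finished cycle's observations for the next boundary
schedule_observe <- function(state, params, topo, res, t_next) {
  idx <- match(pulm_nodes, topo$nodes)
  state$Pm <- as.list(pmax(res$pmean[idx] / res$nsteps, 0))
  names(state$Pm) <- pulm_nodes
  ip <- match(pap_nodes, topo$nodes)
  state$mpap <- mean_pap(mean(res$pmax[ip]), mean(res$pmin[ip]))
  if (is.na(state$t_c) && state$mpap >= 50) state$t_c <- t_next
  state
}
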