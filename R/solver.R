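# Network solver: derivative evaluation, fixed-step integration, and the
# scenario driver that applies disease schedules between cardiac cycles.

#' Flow through an ideal diode in series with a resistance
#'
#' \eqn{Q = \Delta P / R} while forward-biased, zero otherwise.
#'
#' @param dP pressure difference upstream minus downstream (mmHg).
#' @param R series resistance (mmHg.s/ml), positive.
#' @return flow (ml/s), non-negative.
#' @export
valve_flow <- function(dP, R) {
  if (any(R <= 0)) stop("valve resistance must be positive")
  ifelse(dP > 0, dP / R, 0)
}

#' Evaluate the circuit right-hand side at a state
#'
#' Computes every node pressure, every edge flow and the state derivative
#' (dV/dt per compartment, dQ/dt per inductive edge) at a given cycle phase.
#' The sum of dV/dt is zero by construction (closed loop).
#'
#' @param topo a `circ_topology`.
#' @param V compartment volumes (ml), in `topo$nodes` order.
#' @param Q inductor flows (ml/s), in `topo$q_edges` order.
#' @param phase cycle phase (s).
#' @return list with `dV`, `dQ`, `P` (named) and `flow` (named by edge).
#' @export
circuit_derivatives <- function(topo, V, Q = numeric(sum(topo$eL > 0)),
                                phase = 0) {
  out <- cpp_derivs(as.numeric(V), as.numeric(Q), phase, topo$nlaw, topo$npar,
                    topo$act, topo$efrom, topo$eto, topo$eRbase, topo$eRlaw,
                    topo$eRpar, topo$eL, topo$evalve)
  names(out$dV) <- topo$nodes
  names(out$P) <- topo$nodes
  names(out$flow) <- topo$edge_names
  if (length(out$dQ)) names(out$dQ) <- topo$q_edges
  out
}

#' Integrate a topology over consecutive fixed-parameter cycles
#'
#' Low-level fixed-step integrator (classical 4th-order Runge-Kutta; forward
#' Euler available for comparison) over `nsteps` steps with all parameters
#' frozen.  Used directly for toy circuits; [simulate_circulation()] drives
#' it cycle by cycle for the full model.
#'
#' @param topo a `circ_topology`.
#' @param V0,Q0 initial volumes and inductor flows.
#' @param dt step size (s).
#' @param nsteps number of steps.
#' @param record_every record every k-th step (0 = no sample storage,
#'   statistics only).
#' @param t0 absolute start time (s), for time stamps.
#' @param euler use forward Euler instead of Runge-Kutta 4.
#' @return raw per-cycle result list (final state, samples, statistics).
#' @export
integrate_topology <- function(topo, V0, Q0 = numeric(sum(topo$eL > 0)),
                               dt, nsteps, record_every = 10, t0 = 0,
                               euler = FALSE) {
  cpp_sim_cycle(as.numeric(V0), as.numeric(Q0), topo$nlaw, topo$npar,
                topo$act, topo$efrom, topo$eto, topo$eRbase, topo$eRlaw,
                topo$eRpar, topo$eL, topo$evalve, dt, as.integer(nsteps),
                as.integer(record_every), t0, as.integer(euler))
}

#' Simulate the closed-loop circulation
#'
#' Runs the full model for `duration` seconds of simulated time: whole
#' cardiac cycles at the configured cycle length T, with the scenario's
#' parameter schedule applied once at each cycle boundary (time-varying
#' parameters are frozen within a cycle).  Disease time is identified with
#' simulation time.
#'
#' @param scenario one of `"normal"`, `"dpas"` (distal pulmonary artery
#'   stenosis), `"lvdd"` (left ventricular diastolic dysfunction), `"vsd"`
#'   (ventricular septal defect), `"ms"` (mitral stenosis).
#' @param duration simulated time (s); only whole cycles are run
#'   (`floor(duration / T)` cycles).
#' @param params a `circ_params` configuration; default the shipped fixture.
#' @param dt integration step (s); must divide the cycle length T.
#' @param record_every store every k-th step in the sample record (default
#'   10, i.e. ~2 ms sampling); 0 keeps only per-cycle statistics.
#' @param euler use forward Euler (comparison mode).
#' @return a `circ_trajectory`: list with `samples` (time grid, volume,
#'   pressure and flow matrices), `cycles` (per-cycle statistics arrays),
#'   `snapshots` (per-cycle scheduled parameter values), and `meta`.
#' @export
#' @examples
#' \donttest{
#' traj <- simulate_circulation("normal", duration = 10)
#' summarize_cycles(traj)
#' }
simulate_circulation <- function(scenario = c("normal", "dpas", "lvdd",
                                              "vsd", "ms"),
                                 duration = 700, params = default_params(),
                                 dt = params$simulation$dt, record_every = 10,
                                 euler = FALSE) {
  scenario <- match.arg(scenario)
  validate_params(params)
  T <- params$simulation$T
  nsteps <- round(T / dt)
  if (abs(nsteps * dt - T) > 1e-9 * T)
    stop("dt must divide the cycle length T exactly")
  ncycles <- floor(duration / T + 1e-9)
  if (ncycles < 1) stop("duration must cover at least one cardiac cycle")

  vols <- unlist(params$initial$volumes)[node_order]
  topo0 <- build_topology(params)
  Q0 <- rep(0, length(topo0$q_edges))
  names(Q0) <- topo0$q_edges
  flows0 <- unlist(params$initial$flows)
  Q0[names(flows0)[names(flows0) %in% names(Q0)]] <-
    flows0[names(flows0) %in% names(Q0)]

  state <- schedule_init(scenario, params, vols)
  n <- length(node_order)

  rec <- record_every > 0
  samples <- if (rec) vector("list", ncycles)
  cyc <- list(t_start = numeric(ncycles),
              pmin = matrix(NA_real_, ncycles, n),
              pmax = matrix(NA_real_, ncycles, n),
              pmean = matrix(NA_real_, ncycles, n),
              vmin = matrix(NA_real_, ncycles, n),
              vmax = matrix(NA_real_, ncycles, n),
              volmin = numeric(ncycles), volmax = numeric(ncycles))
  qstat <- NULL
  snapshots <- vector("list", ncycles)

  V <- as.numeric(vols)
  Q <- as.numeric(Q0)
  for (i in seq_len(ncycles)) {
    t_cyc <- (i - 1) * T
    upd <- apply_schedule(params, state, t_cyc)
    params_i <- upd$params
    state <- upd$state
    snapshots[[i]] <- c(cycle = i, t = t_cyc, upd$snapshot)
    topo <- build_topology(params_i)
    if (length(Q) != sum(topo$eL > 0)) { # topology gained/lost inductors
      Qn <- rep(0, sum(topo$eL > 0))
      Qn[match(topo$q_edges, names(Q0))] <- Q
      Q <- Qn
    }
    res <- integrate_topology(topo, V, Q, dt, nsteps, record_every, t_cyc,
                              euler)
    V <- res$V
    Q <- res$Q
    if (is.null(qstat)) {
      m <- length(topo$edge_names)
      qstat <- list(edge_names = topo$edge_names,
                    qint = matrix(NA_real_, ncycles, m),
                    qmin = matrix(NA_real_, ncycles, m),
                    qmax = matrix(NA_real_, ncycles, m))
    }
    cyc$t_start[i] <- t_cyc
    cyc$pmin[i, ] <- res$pmin
    cyc$pmax[i, ] <- res$pmax
    cyc$pmean[i, ] <- res$pmean / res$nsteps
    cyc$vmin[i, ] <- res$vmin
    cyc$vmax[i, ] <- res$vmax
    cyc$volmin[i] <- res$volmin
    cyc$volmax[i] <- res$volmax
    em <- match(topo$edge_names, qstat$edge_names)
    qstat$qint[i, em] <- res$qint
    qstat$qmin[i, em] <- res$qmin
    qstat$qmax[i, em] <- res$qmax
    if (rec) samples[[i]] <- res[c("rec_t", "rec_V", "rec_P", "rec_F")]

    state <- schedule_observe(state, params, topo, res, t_cyc + T)
  }

  colnames(cyc$pmin) <- colnames(cyc$pmax) <- colnames(cyc$pmean) <-
    colnames(cyc$vmin) <- colnames(cyc$vmax) <- node_order
  colnames(qstat$qint) <- colnames(qstat$qmin) <- colnames(qstat$qmax) <-
    qstat$edge_names
  cyc <- c(cyc, qstat[c("qint", "qmin", "qmax")])

  out <- list(
    samples = if (rec) {
      s <- list(time = unlist(lapply(samples, `[[`, "rec_t")),
                V = do.call(rbind, lapply(samples, `[[`, "rec_V")),
                P = do.call(rbind, lapply(samples, `[[`, "rec_P")),
                flow = do.call(rbind, lapply(samples, `[[`, "rec_F")))
      colnames(s$V) <- colnames(s$P) <- node_order
      colnames(s$flow) <- qstat$edge_names[seq_len(ncol(s$flow))]
      s
    },
    cycles = cyc,
    snapshots = do.call(rbind, lapply(snapshots, function(r)
      as.data.frame(as.list(r)))),
    meta = list(scenario = scenario, T = T, dt = dt, ncycles = ncycles,
                duration = ncycles * T, record_every = record_every,
                total_volume = params$simulation$total_volume,
                nodes = node_order, final_state = list(V = V, Q = Q),
                schedule_state = state))
  class(out) <- "circ_trajectory"
  out
}

#' @export
print.circ_trajectory <- function(x, ...) {
  cat(sprintf("<circ_trajectory> scenario '%s': %d cycles (%.1f s) at dt = %g s\n",
              x$meta$scenario, x$meta$ncycles, x$meta$duration, x$meta$dt))
  dev <- max(abs(c(x$cycles$volmin, x$cycles$volmax) - x$meta$total_volume))
  cat(sprintf("  total volume %.0f ml (max deviation %.2g ml)\n",
              x$meta$total_volume, dev))
  last <- x$meta$ncycles
  cat(sprintf("  last cycle: LV %0.f/%0.f, aortic %0.f/%0.f, RV %0.f/%0.f mmHg\n",
              x$cycles$pmax[last, "lv"], x$cycles$pmin[last, "lv"],
              x$cycles$pmax[last, "aop"], x$cycles$pmin[last, "aop"],
              x$cycles$pmax[last, "rv"], x$cycles$pmin[last, "rv"]))
  invisible(x)
}

#' First cycle at which the run is periodically converged
#'
#' Returns the first cycle index after which the largest relative change of
#' any compartment's per-cycle systolic or diastolic pressure between
#' consecutive cycles stays below `tolerance` (pressures are compared on a
#' 1 mmHg floor so near-zero venous pressures do not dominate).
#'
#' @param traj a `circ_trajectory` spanning at least 3 cycles.
#' @param tolerance maximum allowed relative cycle-to-cycle change.
#' @return converged cycle index.
#' @export
steady_cycle <- function(traj, tolerance = 0.005) {
  nc <- traj$meta$ncycles
  if (nc < 3) stop("trajectory must span at least 3 cycles")
  ps <- cbind(traj$cycles$pmax, traj$cycles$pmin)
  rel <- abs(ps[-1, , drop = FALSE] - ps[-nc, , drop = FALSE]) /
    pmax(abs(ps[-nc, , drop = FALSE]), 1)
  worst <- apply(rel, 1, max)
  ok <- which(worst < tolerance)
  if (!length(ok)) stop("no periodic convergence within ", nc, " cycles (",
                        "max relative change ", signif(min(worst), 3), ")")
  ok[1] + 1
}
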