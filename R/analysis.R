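# Hemodynamic read-outs: per-cycle summaries, P-V loops, CSV export.

#' Per-cycle hemodynamic summary
#'
#' One row per completed cardiac cycle: systolic (per-cycle maximum),
#' diastolic (minimum) and mean pressure of the key compartments; left and
#' right ventricular end-diastolic / end-systolic volumes, stroke volume and
#' ejection fraction; cardiac output (LV stroke volume times heart rate);
#' mean pulmonary artery pressure (from the proximal pulmonary extrema via
#' [mean_pap()]); and, when the septal shunt branch is active, the shunted
#' volume per cycle.
#'
#' @param traj a `circ_trajectory`.
#' @return a data frame with one row per cycle.
#' @export
summarize_cycles <- function(traj) {
  cy <- traj$cycles
  hr <- 60 / traj$meta$T
  pap_s <- (cy$pmax[, "lpap"] + cy$pmax[, "rpap"]) / 2
  pap_d <- (cy$pmin[, "lpap"] + cy$pmin[, "rpap"]) / 2
  out <- data.frame(
    cycle = seq_len(traj$meta$ncycles),
    t_start = cy$t_start,
    hr = hr,
    lv_sys = cy$pmax[, "lv"], lv_dia = cy$pmin[, "lv"],
    aop_sys = cy$pmax[, "aop"], aop_dia = cy$pmin[, "aop"],
    aop_mean = cy$pmean[, "aop"],
    la_sys = cy$pmax[, "la"], la_dia = cy$pmin[, "la"],
    rv_sys = cy$pmax[, "rv"], rv_dia = cy$pmin[, "rv"],
    ra_mean = cy$pmean[, "ra"],
    pap_sys = pap_s, pap_dia = pap_d,
    mpap = mean_pap(pap_s, pap_d),
    sv_mean = cy$pmean[, "sv"], vc_mean = cy$pmean[, "vc"],
    lv_edv = cy$vmax[, "lv"], lv_esv = cy$vmin[, "lv"],
    rv_edv = cy$vmax[, "rv"], rv_esv = cy$vmin[, "rv"]
  )
  out$lv_sv <- out$lv_edv - out$lv_esv
  out$rv_sv <- out$rv_edv - out$rv_esv
  out$lv_ef <- out$lv_sv / out$lv_edv
  out$co <- out$lv_sv * hr
  if ("Rltor" %in% colnames(cy$qint)) out$shunt_ml <- cy$qint[, "Rltor"]
  out
}

#' Per-cycle pressure summary for every compartment
#'
#' Long-format systolic/diastolic/mean pressure table, one row per cycle and
#' compartment.
#'
#' @param traj a `circ_trajectory`.
#' @return data frame with columns `cycle`, `node`, `systolic`, `diastolic`,
#'   `mean`.
#' @export
cycle_pressures <- function(traj) {
  cy <- traj$cycles
  nodes <- colnames(cy$pmax)
  nc <- traj$meta$ncycles
  data.frame(cycle = rep(seq_len(nc), times = length(nodes)),
             node = rep(nodes, each = nc),
             systolic = as.vector(cy$pmax),
             diastolic = as.vector(cy$pmin),
             mean = as.vector(cy$pmean))
}

#' Pressure-volume loop of one chamber for one cycle
#'
#' The ordered (volume, pressure) path of a chamber over a single cardiac
#' cycle, closed with the first sample of the following cycle when
#' available.  In periodic steady state the path closes on itself; a closure
#' gap above `tolerance` (relative to the cycle's volume range) raises a
#' warning reporting the gap.
#'
#' @param traj a `circ_trajectory` recorded with `record_every > 0`.
#' @param chamber compartment name (typically `"lv"`, `"la"`, `"rv"`,
#'   `"ra"`).
#' @param cycle cycle index, fully contained in the trajectory.
#' @param tolerance closure warning threshold (fraction of volume range).
#' @return data frame with columns `time`, `volume`, `pressure`.
#' @export
pv_loop <- function(traj, chamber = "lv", cycle, tolerance = 0.01) {
  if (is.null(traj$samples)) stop("trajectory was run without sample storage")
  if (missing(cycle)) cycle <- traj$meta$ncycles
  if (cycle < 1 || cycle > traj$meta$ncycles)
    stop("cycle not contained in trajectory")
  T <- traj$meta$T
  t0 <- (cycle - 1) * T
  tm <- traj$samples$time
  sel <- which(tm >= t0 - 1e-9 & tm < t0 + T - 1e-9)
  if (length(sel) < 2) stop("cycle has fewer than two samples")
  nxt <- sel[length(sel)] + 1 # first sample of the next cycle closes the loop
  if (nxt <= length(tm)) sel <- c(sel, nxt)
  loop <- data.frame(time = tm[sel],
                     volume = traj$samples$V[sel, chamber],
                     pressure = traj$samples$P[sel, chamber])
  rng <- diff(range(loop$volume))
  gap <- abs(loop$volume[nrow(loop)] - loop$volume[1])
  if (rng > 0 && gap / rng > tolerance)
    warning(sprintf("open P-V path: closure gap %.3g ml (%.1f%% of range)",
                    gap, 100 * gap / rng))
  loop
}

#' Count significant self-intersections of a P-V path
#'
#' Detects the "two-loop" (figure-eight) shape of a diseased atrial
#' pressure-volume path.  Proper crossings between non-adjacent segments of
#' the closed (volume, pressure) polyline are counted, but only when the
#' sub-loop cut off by the crossing encloses a significant area (at least
#' `min_area` of the path's bounding box, after rescaling both axes to the
#' unit square).  The area filter matters: a healthy atrium retraces its
#' passive filling curve during diastasis, which produces many zero-area
#' self-overlaps that are not lobes.  A single-lobed loop returns 0; a
#' genuine two-lobed path returns at least 1.
#'
#' @param loop data frame with `volume` and `pressure` columns (e.g. from
#'   [pv_loop()]).
#' @param max_points decimate the path to at most this many vertices before
#'   the quadratic pair scan.
#' @param min_area minimum enclosed sub-loop area (fraction of the unit
#'   bounding box) for a crossing to count as a lobe boundary.
#' @return integer count of area-significant crossings.
#' @export
loop_crossings <- function(loop, max_points = 250, min_area = 0.01) {
  V <- loop$volume
  P <- loop$pressure
  n <- length(V)
  if (n > max_points) {
    idx <- unique(round(seq(1, n, length.out = max_points)))
    V <- V[idx]
    P <- P[idx]
    n <- length(V)
  }
  V <- (V - min(V)) / max(diff(range(V)), 1e-12)
  P <- (P - min(P)) / max(diff(range(P)), 1e-12)
  ns <- n - 1
  if (ns < 3) return(0L)
  pr <- which(outer(seq_len(ns), seq_len(ns), function(i, j) j > i + 1),
              arr.ind = TRUE)
  i <- pr[, 1]
  j <- pr[, 2]
  keep <- !(i == 1 & j == ns) # segments sharing the closure vertex
  i <- i[keep]
  j <- j[keep]
  cross <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- cross(V[i], P[i], V[i + 1], P[i + 1], V[j], P[j])
  d2 <- cross(V[i], P[i], V[i + 1], P[i + 1], V[j + 1], P[j + 1])
  d3 <- cross(V[j], P[j], V[j + 1], P[j + 1], V[i], P[i])
  d4 <- cross(V[j], P[j], V[j + 1], P[j + 1], V[i + 1], P[i + 1])
  hit <- which(d1 * d2 < 0 & d3 * d4 < 0)
  if (!length(hit)) return(0L)
  # shoelace area of the sub-loop between the two crossing segments
  cumA <- c(0, cumsum(V[1:(n - 1)] * P[2:n] - V[2:n] * P[1:(n - 1)]))
  count <- 0L
  for (k in hit) {
    a <- i[k]
    b <- j[k]
    # vertices a+1 .. b closed through the (approximate) crossing point
    area <- 0.5 * abs((cumA[b + 1] - cumA[a + 1]) +
                        (V[b] * P[a + 1] - V[a + 1] * P[b]))
    if (area >= min_area) count <- count + 1L
  }
  count
}

#' Export a trajectory to CSV files
#'
#' Writes `trajectory.csv` (tidy: `time_s`, `node`, `pressure_mmHg`,
#' `volume_ml`), `flows.csv` (`time_s`, `edge`, `flow_ml_s`),
#' `cycles.csv` (the [summarize_cycles()] table) and `snapshots.csv`
#' (per-cycle scheduled parameters).  Deterministic: re-running the same
#' configuration byte-reproduces the files.
#'
#' @param traj a `circ_trajectory`.
#' @param dir output directory (created if needed).
#' @param thin keep every `thin`-th stored sample row in the waveform files
#'   (cycle summaries are never thinned).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(traj, dir, thin = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(traj$samples)) {
    keep <- seq(1, length(traj$samples$time), by = thin)
    tm <- traj$samples$time[keep]
    nodes <- colnames(traj$samples$P)
    tidy <- data.frame(
      time_s = rep(tm, times = length(nodes)),
      node = rep(nodes, each = length(tm)),
      pressure_mmHg = as.vector(traj$samples$P[keep, ]),
      volume_ml = as.vector(traj$samples$V[keep, ]))
    write.csv(tidy, file.path(dir, "trajectory.csv"), row.names = FALSE)
    edges <- colnames(traj$samples$flow)
    flows <- data.frame(
      time_s = rep(tm, times = length(edges)),
      edge = rep(edges, each = length(tm)),
      flow_ml_s = as.vector(traj$samples$flow[keep, ]))
    write.csv(flows, file.path(dir, "flows.csv"), row.names = FALSE)
  }
  write.csv(summarize_cycles(traj), file.path(dir, "cycles.csv"),
            row.names = FALSE)
  write.csv(traj$snapshots, file.path(dir, "snapshots.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Plot a chamber P-V loop
#'
#' Convenience base-graphics plot of one or more cycles of a chamber's
#' pressure-volume path.
#'
#' @param traj a `circ_trajectory`.
#' @param chamber compartment name.
#' @param cycles cycle indices to draw.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the last loop drawn.
#' @export
plot_pv_loop <- function(traj, chamber = "lv", cycles = traj$meta$ncycles,
                         ...) {
  loops <- lapply(cycles, function(cc) pv_loop(traj, chamber, cc))
  xr <- range(unlist(lapply(loops, `[[`, "volume")))
  yr <- range(unlist(lapply(loops, `[[`, "pressure")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "volume (ml)",
                 ylab = "pressure (mmHg)",
                 main = paste0(toupper(chamber), " P-V loop"), ...)
  cols <- grDevices::hcl.colors(max(length(loops), 2), "Zissou 1")
  for (k in seq_along(loops))
    graphics::lines(loops[[k]]$volume, loops[[k]]$pressure, col = cols[k])
  invisible(loops[[length(loops)]])
}
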