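# Parameter registry, configuration I/O, heart-rate law, cardiac clock.
#
# Units are fixed package-wide: pressure mmHg, volume ml, time s, hence
# resistance mmHg.s/ml, compliance ml/mmHg, inductance mmHg.s^2/ml.

#' Heart rate from autonomic drive
#'
#' Quadratic response surface mapping normalized sympathetic (`F_Hrs`) and
#' vagal (`F_Hrv`) efferent frequencies to heart rate:
#' \deqn{Hr = h_1 + h_2 F_{Hrs} - h_3 F_{Hrs}^2 - h_4 F_{Hrv} + h_5 F_{Hrv}^2
#'       - h_6 F_{Hrv} F_{Hrs}.}
#' At the reference operating point (both frequencies 0.5) the default
#' constants give 76.5 beats per minute.
#'
#' @param F_Hrs,F_Hrv normalized frequencies in \[0, 1\].
#' @param h numeric vector of the six constants `h1..h6` (beats per minute
#'   scale).
#' @return heart rate in beats per minute.
#' @export
#' @examples
#' heart_rate(0.5, 0.5) # 76.5
heart_rate <- function(F_Hrs, F_Hrv, h = c(35, 140, 40, 32, 10, 20)) {
  if (any(F_Hrs < 0 | F_Hrs > 1) || any(F_Hrv < 0 | F_Hrv > 1))
    stop("normalized frequencies must lie in [0, 1]")
  stopifnot(length(h) == 6)
  h[1] + h[2] * F_Hrs - h[3] * F_Hrs^2 - h[4] * F_Hrv + h[5] * F_Hrv^2 -
    h[6] * F_Hrv * F_Hrs
}

#' Phase within the cardiac cycle
#'
#' Remainder of `t` after division by the cycle length `T`, mapping absolute
#' simulation time onto \[0, T).
#'
#' @param t time in seconds (vectorized).
#' @param T cycle duration in seconds, must be positive.
#' @return phase in \[0, T).
#' @export
cycle_phase <- function(t, T) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0)
    stop("cycle duration T must be a positive scalar")
  t %% T
}

#' Mean pulmonary artery pressure from systolic and diastolic values
#'
#' The clinical estimate mPAP = sPAP/3 + 2 dPAP/3.
#'
#' @param sPAP,dPAP systolic and diastolic pulmonary artery pressure (mmHg);
#'   requires `sPAP >= dPAP` elementwise.
#' @return mean pulmonary artery pressure (mmHg), in \[dPAP, sPAP\].
#' @export
#' @examples
#' mean_pap(20, 12) # 14.67 mmHg, the normal state
mean_pap <- function(sPAP, dPAP) {
  if (any(sPAP < dPAP))
    stop("systolic pressure must not be below diastolic pressure")
  sPAP / 3 + 2 * dPAP / 3
}

node_order <- c("lv", "la", "rv", "ra",
                "aop", "haa", "lna", "lca", "rica", "rula", "lica", "lula",
                "sap", "sv", "vc", "rsv", "rijv", "lijv", "lsv",
                "lpap", "rpap", "lpad", "rpad", "lpv", "rpv")

#' Compartment names in canonical state order
#'
#' The fixed node ordering used for state vectors, trajectory matrices and
#' configuration files: the four chambers first, then systemic arteries,
#' systemic veins and the pulmonary compartments.
#' @return character vector of 25 compartment names.
#' @export
compartment_names <- function() node_order

default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "circph",
              mustWork = TRUE)
}

#' Load (and merge) a model configuration
#'
#' Reads a JSON configuration holding every model constant: chamber elastance
#' parameters and activation tables, vessel law constants, per-edge
#' resistances/inductances, initial volumes and flows, regulation constants
#' and the four scenario coefficient blocks.  Any key missing from `path` is
#' filled from the shipped calibrated fixture, so a partial configuration
#' that overrides a handful of constants is valid.  The merged configuration
#' is validated before it is returned.
#'
#' @param path path to a JSON configuration, or `NULL` for the shipped
#'   default.
#' @return a validated parameter list of class `circ_params`.
#' @seealso [write_config()], [validate_params()]
#' @export
load_config <- function(path = NULL) {
  defaults <- jsonlite::read_json(default_config_path(), simplifyVector = TRUE)
  if (is.null(path)) {
    p <- defaults
  } else {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- modifyList(defaults, user)
  }
  class(p) <- "circ_params"
  validate_params(p)
  p
}

#' Default calibrated parameter set
#'
#' The shipped fixture: published model constants where the literature
#' tabulates them (chamber and activation tables, vessel-law constants,
#' pulmonary resistances, scenario coefficient blocks, total blood volume
#' 4711 ml, cycle length 0.7845 s) and calibrated element values (per-edge
#' linear compliances, initial state) chosen so the normal run reproduces
#' the reference hemodynamics.
#'
#' @return a validated `circ_params` list.
#' @export
default_params <- function() load_config(NULL)

#' Write a configuration to JSON
#'
#' Serializes with full numeric precision, so
#' `load_config(write_config(p, f))` reproduces every value bit-identically.
#'
#' @param params a `circ_params` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  p <- unclass(params)
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the configuration: positivity of all
#' resistances, compliances and inductances; maximum volumes above their
#' minimum/unstressed counterparts; normalized frequencies in \[0, 1\];
#' initial compartment volumes summing to the configured total blood volume;
#' positive cycle length and step size.  All violations are collected and
#' reported together.
#'
#' @param params a parameter list as produced by [load_config()].
#' @return `params` invisibly if valid; otherwise an error listing every
#'   offending key.
#' @export
validate_params <- function(params) {
  bad <- character(0)
  chk <- function(cond, key) if (!isTRUE(all(cond))) bad <<- c(bad, key)

  sim <- params$simulation
  chk(sim$T > 0, "simulation.T")
  chk(sim$dt > 0, "simulation.dt")
  chk(sim$total_volume > 0, "simulation.total_volume")
  for (f in c("F_con", "F_Hrs", "F_vaso", "F_Hrv"))
    chk(sim[[f]] >= 0 && sim[[f]] <= 1, paste0("simulation.", f))

  for (ch in c("lv", "la", "rv", "ra")) {
    cp <- params$chambers[[ch]]
    chk(cp$E_es > 0, paste0("chambers.", ch, ".E_es"))
    chk(cp$M_0 >= 0, paste0("chambers.", ch, ".M_0"))
    chk(cp$lambda > 0, paste0("chambers.", ch, ".lambda"))
    chk(cp$V_0 >= 0 && cp$V_d >= 0, paste0("chambers.", ch, ".V_0/V_d"))
    chk(all(cp$B > 0), paste0("chambers.", ch, ".B"))
    chk(length(cp$A) == length(cp$B) && length(cp$B) == length(cp$C),
        paste0("chambers.", ch, ".activation"))
  }

  vs <- params$vessels
  for (nm in names(vs)) {
    v <- vs[[nm]]
    if (identical(v$law, "linear"))
      chk(v$C > 0, paste0("vessels.", nm, ".C"))
  }
  chk(vs$sv$K_v > 0 && vs$sv$V_sv_max > 0, "vessels.sv")
  chk(vs$vc$V_vc_max > vs$vc$V_vc_min, "vessels.vc.V_vc_max")
  chk(vs$vc$V_vc_0 > vs$vc$V_vc_min, "vessels.vc.V_vc_0")
  chk(vs$sap$V_sap_max > vs$sap$V_sap_min, "vessels.sap.V_sap_max")

  ed <- params$edges
  chk(is.data.frame(ed) || is.list(ed), "edges")
  ed <- as.data.frame(ed, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ed))) {
    if (identical(ed$R_law[i], "constant"))
      chk(ed$R[i] > 0, paste0("edges.", ed$name[i], ".R"))
    else
      chk(ed$R[i] >= 0, paste0("edges.", ed$name[i], ".R"))
    chk(ed$L[i] >= 0, paste0("edges.", ed$name[i], ".L"))
    chk(ed$from[i] %in% node_order && ed$to[i] %in% node_order,
        paste0("edges.", ed$name[i], ".from/to"))
  }

  vols <- unlist(params$initial$volumes)
  chk(setequal(names(vols), node_order), "initial.volumes (compartment set)")
  chk(all(vols >= 0), "initial.volumes (non-negative)")
  if (length(vols) && is.numeric(sim$total_volume))
    chk(abs(sum(vols) - sim$total_volume) <= 1e-6 * sim$total_volume,
        "initial.volumes (sum != simulation.total_volume)")

  if (length(bad))
    stop("invalid configuration; offending keys: ", paste(bad, collapse = ", "))
  invisible(params)
}

#' @export
print.circ_params <- function(x, ...) {
  cat("<circ_params>  lumped-parameter circulation configuration\n")
  cat(sprintf("  cycle length T = %g s, dt = %g s, total volume = %g ml\n",
              x$simulation$T, x$simulation$dt, x$simulation$total_volume))
  cat(sprintf("  %d compartments, %d edges, scenarios: %s\n",
              length(node_order), nrow(as.data.frame(x$edges)),
              paste(names(x$scenarios), collapse = ", ")))
  invisible(x)
}
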