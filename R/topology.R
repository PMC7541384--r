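# Network topology: the circuit wiring and its translation to solver arrays.
#
# Assumed wiring of the peripheral branches (the one place it is defined):
# the proximal aorta feeds a head-and-arm trunk (haa -> right internal
# carotid, right upper-limb artery), a left neck artery (-> left internal
# carotid) and a left clavicular artery (-> left upper-limb artery).  Each
# peripheral artery drains through a capillary-bed resistance with a diode
# (D51..D54) into its named vein (rijv, rsv, lijv, lsv), and the veins empty
# through diodes D1..D4 into the vena cava.  The main trunk runs aorta ->
# proximal systemic artery -> systemic veins -> vena cava.  Viscoelastic
# resistances are folded into the adjacent edge resistances of the
# calibrated fixture.

r_law_code <- c(constant = 0L, vc_volume = 1L, sap_volume = 2L)

#' Construct a circuit topology
#'
#' Low-level constructor turning a node/edge description into the array form
#' consumed by the compiled solver.  `simulate_circulation()` builds the full
#' 25-compartment circulation this way; tests and toy studies can assemble
#' arbitrary closed-loop circuits.
#'
#' @param node_laws named character vector mapping each compartment to its
#'   pressure law (`"linear"`, `"sv_log10"`, `"vc_piecewise"`, `"sap_blend"`,
#'   `"log_saturating"` or `"chamber"`).
#' @param node_params list (same names/order) of numeric law-parameter
#'   vectors; for `"chamber"` nodes the 7th entry indexes (1-based) into
#'   `act`.
#' @param edges data frame with columns `name`, `from`, `to`, `R`, `R_law`,
#'   `L`, `valve`; `from`/`to` are node names.
#' @param act list of activation descriptions
#'   `list(A, B, C, form, bscale, lin)` referenced by chamber nodes.
#' @param edge_R_params optional list (by edge name) of numeric parameter
#'   vectors for non-constant edge resistance laws.
#' @return an object of class `circ_topology`.
#' @export
new_topology <- function(node_laws, node_params, edges, act = list(),
                         edge_R_params = list()) {
  nodes <- names(node_laws)
  stopifnot(!is.null(nodes), setequal(nodes, names(node_params)))
  n <- length(nodes)
  npar <- matrix(0, n, 7)
  nlaw <- integer(n)
  for (i in seq_len(n)) {
    nlaw[i] <- law_code[[node_laws[[i]]]]
    p <- as.numeric(node_params[[nodes[i]]])
    if (node_laws[[i]] == "chamber") p[7] <- p[7] - 1 # 0-based slot for C++
    npar[i, seq_along(p)] <- p
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  m <- nrow(edges)
  efrom <- match(edges$from, nodes)
  eto <- match(edges$to, nodes)
  if (anyNA(efrom) || anyNA(eto)) stop("edge endpoint not in node list")
  erlaw <- r_law_code[edges$R_law]
  if (anyNA(erlaw)) stop("unknown edge resistance law")
  erpar <- matrix(0, m, 3)
  for (j in seq_len(m)) {
    ep <- edge_R_params[[edges$name[j]]]
    if (!is.null(ep)) erpar[j, seq_along(ep)] <- as.numeric(ep)
  }
  structure(list(nodes = nodes, nlaw = nlaw, npar = npar, act = act,
                 efrom = as.integer(efrom), eto = as.integer(eto),
                 eRbase = as.numeric(edges$R), eRlaw = as.integer(erlaw),
                 eRpar = erpar, eL = as.numeric(edges$L),
                 evalve = as.integer(as.logical(edges$valve)),
                 edge_names = edges$name,
                 q_edges = edges$name[edges$L > 0]),
            class = "circ_topology")
}

# activation slot for one chamber, optionally with a scheduled linear term
chamber_act <- function(ch, form, bscale, lin = 0) {
  A <- pmax(as.numeric(ch$A), 0) # scheduled amplitudes are clamped at zero
  list(A = A, B = as.numeric(ch$B), C = as.numeric(ch$C),
       form = if (identical(form, "ventricular")) 0L else 1L,
       bscale = bscale, lin = lin)
}

#' Build the full circulation topology from a parameter set
#'
#' Translates a (possibly schedule-modified) `circ_params` configuration into
#' a `circ_topology`.  Chamber contractility a(F_con) and clock b(F_con) are
#' evaluated here from the configured sympathetic frequency.
#'
#' @param params a `circ_params` list.
#' @return a `circ_topology` for the 25-compartment closed loop.
#' @export
build_topology <- function(params) {
  sim <- params$simulation
  a <- contractility_scale(sim$F_con, params$contractility$a_min,
                           params$contractility$K_a)
  b <- time_scale(sim$F_con, params$contractility$b_min,
                  params$contractility$K_b)

  node_laws <- character(0)
  node_params <- list()
  act <- list()
  slot <- 0
  for (ch in c("lv", "la", "rv", "ra")) {
    cp <- params$chambers[[ch]]
    vent <- identical(cp$form, "ventricular")
    slot <- slot + 1
    act[[slot]] <- chamber_act(cp, cp$form, if (vent) b else 1,
                               if (is.null(cp$linear_term)) 0 else cp$linear_term)
    node_laws[ch] <- "chamber"
    node_params[[ch]] <- c(if (vent) a else 1, cp$E_es, cp$V_d, cp$M_0,
                           cp$lambda, cp$V_0, slot)
  }

  vs <- params$vessels
  for (nm in setdiff(node_order, c("lv", "la", "rv", "ra"))) {
    v <- vs[[nm]]
    node_laws[nm] <- v$law
    node_params[[nm]] <- switch(v$law,
      linear = v$C,
      sv_log10 = c(v$K_v, v$V_sv_max),
      vc_piecewise = c(v$N_1, v$K_1, v$V_vc_0, v$N_2, v$K_2, v$V_vc_min),
      sap_blend = c(sim$F_vaso, v$K_c, v$N_0, v$V_sap_min, v$K_p1, v$tau_aop,
                    v$K_p2),
      log_saturating = c(v$K, v$V_m),
      stop("unknown vessel law for node ", nm))
  }

  edges <- as.data.frame(params$edges, stringsAsFactors = FALSE)
  edge_R_params <- list()
  for (j in seq_len(nrow(edges))) {
    edge_R_params[[edges$name[j]]] <- switch(edges$R_law[j],
      constant = NULL,
      vc_volume = c(vs$vc$K_R, vs$vc$V_vc_max, vs$vc$R_0),
      sap_volume = c(vs$sap$K_r, sim$F_vaso, vs$sap$V_sap_max))
  }

  new_topology(node_laws[node_order], node_params[node_order], edges, act,
               edge_R_params)
}

#' @export
print.circ_topology <- function(x, ...) {
  cat(sprintf("<circ_topology> %d compartments, %d edges (%d valves, %d inductors)\n",
              length(x$nodes), length(x$efrom), sum(x$evalve),
              sum(x$eL > 0)))
  invisible(x)
}
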