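#' Effective cell parameters for a population
#'
#' Resolves the configured cell parameters of one population into the values
#' the engine integrates: compartment areas from the dendrite/soma area
#' ratio, and — for the cortical types under the `capacitive` soma variant —
#' every axosomatic maximal conductance rescaled by 3/4 relative to its
#' legacy value (the legacy parameter set was tuned for an axosomatic
#' compartment integrated without capacitance; restoring the capacitance
#' requires the compensating rescale).
#'
#' @param cfg A config object.
#' @param type One of `"py"`, `"inh"`, `"tc"`, `"re"`.
#' @return A list of resolved parameters; for cortical types it contains
#'   `soma_legacy` and `soma_effective` conductance vectors and
#'   `soma_rescale` (the factor actually applied).
#' @export
effective_cell_params <- function(cfg, type) {
  type <- match.arg(type, pop_names)
  cp <- cfg$cells[[type]]
  out <- cp
  out$type <- type
  if (type %in% c("py", "inh")) {
    fac <- if (identical(cfg$soma_variant, "capacitive")) 0.75 else 1
    out$soma_rescale <- fac
    out$soma_legacy <- unlist(cp$soma)
    out$soma_effective <- out$soma_legacy * fac
    out$area_dend_cm2 <- cp$area_soma_cm2 * cp$rho
    out$n_compartments <- 2L
  } else {
    out$n_compartments <- 1L
  }
  out
}

#' Build one cell at rest
#'
#' Initializes a cell of the given type near its configured resting
#' potential with every gating variable at its voltage (or calcium) steady
#' state, so the gating derivatives vanish at t = 0. Uses the same
#' initialization path as the network engine.
#'
#' @param type One of `"py"`, `"inh"`, `"tc"`, `"re"`.
#' @param cfg A config object supplying the cell parameters.
#' @return A list with `type`, `params` (see [effective_cell_params()]) and
#'   `state`, a named numeric vector of compartment voltages and gating
#'   variables.
#' @export
build_cell <- function(type, cfg = default_config()) {
  type <- match.arg(type, pop_names)
  pars <- effective_cell_params(cfg, type)
  one <- cfg
  for (p in pop_names) one$populations[[p]] <- if (p == type) 1L else 0L
  one$integration$duration_ms <- 1
  one$schedule$stages <- list(list(stage = "wake", duration_ms = 1))
  one$schedule$ramp_ms <- 0
  one <- validate_config(normalize_config(one))
  net <- build_network(one)
  ep <- build_engine_params(one, net)
  st <- engine_init(ep)
  m <- st[[type]]
  state <- m[1, ]
  names(state) <- state_colnames(type)
  list(type = type, params = pars, state = state)
}

state_colnames <- function(type) {
  if (type %in% c("py", "inh"))
    c("v_soma", "v_dend", "m_na_soma", "h_na_soma", "n_k_soma", "m_na_dend",
      "h_na_dend", "m_km", "m_kca", "m_hva", "h_hva", "ca", "last_spike")
  else if (type == "tc")
    c("v", "m_na", "h_na", "n_k", "m_t", "h_t", "O_h", "OL_h", "P1_h", "ca",
      "last_spike")
  else
    c("v", "m_na", "h_na", "n_k", "m_t", "h_t", "ca", "last_spike")
}

#' Two-compartment membrane equation right-hand side
#'
#' Voltage derivatives of the reduced cortical cell: for each compartment
#' `C_m dV/dt = -sum(g_i (V - E_i)) - I_syn + axial`, with the axial current
#' `g_c (V_other - V)` divided by the compartment's own area so that the
#' axial charge transfer cancels exactly in the area-weighted sum (charge
#' bookkeeping). Conductance/reversal pairs are supplied explicitly, which
#' makes the identity testable without a full channel evaluation.
#'
#' @param v_soma,v_dend Compartment voltages (mV).
#' @param g_soma,g_dend Named numeric vectors of conductance densities
#'   (mS/cm^2).
#' @param e_soma,e_dend Reversal potentials (mV) matching the conductances.
#' @param cm Membrane capacitance (uF/cm^2).
#' @param g_axial Axial coupling conductance (uS).
#' @param area_soma,area_dend Compartment areas (cm^2).
#' @param i_syn_dend Synaptic current density on the dendrite (uA/cm^2,
#'   outward positive).
#' @return List with `dv_soma`, `dv_dend` (mV/ms) and the area-weighted
#'   membrane currents `i_mem_soma`, `i_mem_dend` (uA).
#' @export
membrane_derivatives <- function(v_soma, v_dend, g_soma, e_soma, g_dend,
                                 e_dend, cm, g_axial, area_soma, area_dend,
                                 i_syn_dend = 0) {
  stopifnot(length(g_soma) == length(e_soma),
            length(g_dend) == length(e_dend))
  i_ion_s <- sum(g_soma * (v_soma - e_soma)) # uA/cm2
  i_ion_d <- sum(g_dend * (v_dend - e_dend)) + i_syn_dend
  ax <- g_axial * 1e-3 * (v_soma - v_dend) # mS * mV = uA, soma -> dend
  dv_soma <- (-i_ion_s - ax / area_soma) / cm
  dv_dend <- (-i_ion_d + ax / area_dend) / cm
  list(dv_soma = dv_soma, dv_dend = dv_dend,
       i_mem_soma = i_ion_s * area_soma + ax,
       i_mem_dend = i_ion_d * area_dend - ax)
}

#' Threshold-crossing spike detector
#'
#' A spike is registered when the somatic voltage crosses the threshold from
#' below and the previous spike is older than the refractory window — the
#' event rule used to build the raster.
#'
#' @param v_prev,v_now Voltage at the previous and current step (mV).
#' @param t Current time (ms).
#' @param last_spike Time of the previous registered spike (ms; `-Inf` if
#'   none).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum inter-spike interval (ms).
#' @return List with `spike` (logical) and `time` (`t` or `NA`).
#' @export
detect_spike <- function(v_prev, v_now, t, last_spike = -Inf, threshold = 0,
                         refractory = 2) {
  sp <- (v_prev < threshold) && (v_now >= threshold) &&
    (t - last_spike > refractory)
  list(spike = sp, time = if (sp) t else NA_real_)
}
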