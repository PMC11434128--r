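pop_code <- function(p) match(p, pop_names) - 1L
comp_code <- function(x) ifelse(x == "dend", 1L, 0L)

# Flatten a config + network into the numeric parameter list the compiled
# engine consumes. Applies the axosomatic 3/4 rescale, splits mixed
# GABA-A/GABA-B projections into one engine projection per receptor, and
# precomputes the transfer-resistance coefficients of the biophysical LFP.
build_engine_params <- function(cfg, net) {
  ki <- cfg$synapse_kinetics
  pops <- lapply(pop_names, function(p) {
    cp <- effective_cell_params(cfg, p)
    cortical <- p %in% c("py", "inh")
    list(
      n = as.numeric(cfg$populations[[p]]),
      ncomp = if (cortical) 2 else 1,
      area_s = cp$area_soma_cm2,
      area_d = if (cortical) cp$area_dend_cm2 else cp$area_soma_cm2,
      cm = cp$cm_uf_cm2,
      gc = if (cortical) cp$g_axial_us else 0,
      gna_s = if (cortical) cp$soma_effective[["g_na"]] else 0,
      gk_s = if (cortical) cp$soma_effective[["g_k"]] else 0,
      gnap_s = if (cortical) cp$soma_effective[["g_nap"]] else 0,
      gna_d = if (cortical) cp$dend$g_na else 0,
      gnap_d = if (cortical) cp$dend$g_nap else 0,
      gkm = if (cortical) cp$dend$g_km else 0,
      gkca = if (cortical) cp$dend$g_kca else 0,
      ghva = if (cortical) cp$dend$g_hva else 0,
      gna = if (cortical) 0 else cp$g_na,
      gk = if (cortical) 0 else cp$g_k,
      gt = if (cortical) 0 else cp$g_t,
      gh = if (!cortical && p == "tc") cp$g_h else 0,
      gkl = if (cortical) cp$dend$g_kl else cp$g_kl,
      gl = if (cortical) cp$dend$g_leak else cp$g_leak,
      el = cp$e_leak, ek = cp$e_k, ena = cp$e_na, eh = cp$e_h,
      vtraub = cp$v_traub, vinit = cp$v_init,
      ca_rest = cp$ca$rest_mm, ca_tau = cp$ca$tau_ms,
      ca_k = cp$ca$k_influx, ca_out = cp$ca$out_mm, temp = cp$ca$temp_k,
      kf_kca = if (cortical) cp$kca$k_f else 0,
      b_kca = if (cortical) cp$kca$beta else 1,
      q = if (cortical) cp$q_rate else 1,
      phi_m = if (cortical) 1 else cp$it_phi$m,
      phi_h = if (cortical) 1 else cp$it_phi$h,
      k1 = if (p == "tc") cp$ih$k1 else 0,
      k2 = if (p == "tc") cp$ih$k2 else 1,
      k3 = if (p == "tc") cp$ih$k3 else 0,
      k4 = if (p == "tc") cp$ih$k4 else 1,
      ginc = if (p == "tc") cp$ih$g_inc else 0,
      kappa_ach = cfg$modulation[[p]]$kappa_ach,
      kappa_ha = cfg$modulation[[p]]$kappa_ha)
  })
  names(pops) <- pop_names

  projections <- list()
  stream_block <- 16777216
  qn <- 0
  add_proj <- function(pr, recep, w, wn, erev) {
    qn <<- qn + 1
    cn <- pr$spec
    ab <- switch(recep + 1, ki$ampa, ki$gabaa, list(alpha = 0, beta = 1))
    list(
      sp = pop_code(pr$source), tp = pop_code(pr$target),
      recep = recep,
      comp = if (pr$target %in% c("py", "inh")) 1 else 0,
      pre = as.integer(pr$edges$pre), post = as.integer(pr$edges$post),
      w = as.numeric(w), wn = as.numeric(wn),
      erev = erev,
      alpha = ab$alpha, beta = ab$beta,
      alpha_n = ki$nmda$alpha, beta_n = ki$nmda$beta,
      K1 = ki$gabab$K1, K2 = ki$gabab$K2, K3 = ki$gabab$K3,
      K4 = ki$gabab$K4, Kd = ki$gabab$Kd,
      tmax = ki$pulse$amplitude_mm, tdur = ki$pulse$duration_ms,
      delay = cn$delay_ms,
      U = cn$u_depression, tau_d = cn$tau_depression,
      dep = as.numeric(recep == 0 && cn$u_depression > 0),
      mod_ampa = as.numeric(recep == 0 &&
                              pr$source %in% c("py", "inh") &&
                              pr$target %in% c("py", "inh")),
      mod_gaba = as.numeric(recep == 1),
      minis = as.numeric(recep == 0 && cn$minis$rate_max > 0),
      mini_amp = cn$minis$amp_fraction,
      mini_rate = cn$minis$rate_max,
      mini_tau = cn$minis$tau_rise,
      stream0 = qn * stream_block)
  }
  for (pr in net$projections) {
    zero <- rep(0, nrow(pr$edges))
    if (any(pr$w_ampa > 0))
      projections[[length(projections) + 1]] <-
        add_proj(pr, 0L, pr$w_ampa, pr$w_nmda, pr$spec$e_rev)
    if (any(pr$w_gabaa > 0))
      projections[[length(projections) + 1]] <-
        add_proj(pr, 1L, pr$w_gabaa, zero, pr$spec$e_rev)
    if (any(pr$w_gabab > 0))
      projections[[length(projections) + 1]] <-
        add_proj(pr, 2L, pr$w_gabab, zero,
                 cfg$cells[[pr$target]]$e_k)
  }

  sk <- schedule_knots(cfg)
  stim <- lapply(cfg$stimulus, function(s) list(
    pop = pop_code(s$pop), comp = comp_code(s$comp %||% "soma"),
    lo = if (is.null(s$cells)) -1 else s$cells[1],
    hi = if (is.null(s$cells)) -1 else s$cells[2],
    amp = s$amp_ua_cm2, t_on = s$t_on_ms, t_off = s$t_off_ms))

  co <- net$coords
  el <- cfg$lfp$electrode_um %||% c(0, 2 * cfg$lfp$dend_offset_um, 0)
  coef <- function(soma, dend) {
    if (nrow(soma) == 0) return(numeric(0))
    transfer_resistance(el, dend, cfg$lfp$sigma_s_m,
                        cfg$lfp$min_distance_um) -
      transfer_resistance(el, soma, cfg$lfp$sigma_s_m,
                          cfg$lfp$min_distance_um)
  }

  rc <- cfg$record$cells
  record <- list(
    pop = vapply(rc, function(r) pop_code(r$pop), 0L),
    idx = vapply(rc, function(r) as.integer(r$idx), 0L),
    comp = vapply(rc, function(r) comp_code(r$comp %||% "soma"), 0L))

  list(
    dt = cfg$integration$dt_ms,
    seed = as.numeric(cfg$integration$seed),
    record_dt = cfg$integration$record_dt_ms,
    spike_threshold = cfg$integration$spike_threshold_mv,
    refractory = cfg$integration$refractory_ms,
    lambda_ampa = cfg$modulation$lambda_ampa,
    pops = pops,
    projections = projections,
    schedule = list(t = sk$knots$t, ach = sk$knots$ach, ha = sk$knots$ha,
                    gaba = sk$knots$gaba),
    stimulus = stim,
    lfp = list(coef_py = coef(co$py_soma, co$py_dend),
               coef_inh = coef(co$inh_soma, co$inh_dend)),
    record = record)
}

#' Run a simulation
#'
#' Builds the network from the config, initializes every cell at its gating
#' steady state (or restores a checkpoint), and advances the coupled system
#' with the fixed-step semi-implicit scheme: gating variables by exact
#' exponential relaxation toward their voltage-dependent steady states,
#' voltages by a linearized implicit update (exact 2x2 solve for the
#' two-compartment cortical cells), synapses by exact exponential kinetics
#' with rectangular transmitter pulses. The run is fully deterministic given
#' (config, seed): miniature-EPSP times come from counter-based
#' per-connection substreams.
#'
#' @param cfg A config object.
#' @param seed Optional seed override.
#' @param duration Optional duration override (ms); defaults to the
#'   schedule's remaining time.
#' @param resume Optional checkpoint blob from [checkpoint()] to continue
#'   from; the checkpointed config must match `cfg`.
#' @return A `somnotc_run`: `raster` (data.frame `gid`, `t_ms`, `pop`),
#'   `sample_t`, `lfp_vsum` (mean PY dendritic voltage, mV), `lfp_bio`
#'   (transfer-resistance LFP, uV), `traces` (selected voltages), `levels`
#'   (neuromodulator track), and the final `state`.
#' @export
run_simulation <- function(cfg, seed = NULL, duration = NULL, resume = NULL) {
  validate_config(cfg)
  if (!is.null(seed)) cfg$integration$seed <- as.integer(seed)
  net <- build_network(cfg)
  ep <- build_engine_params(cfg, net)
  if (is.null(resume)) {
    state <- engine_init(ep)
  } else {
    state <- restore(resume)
    blob_cfg <- attr(state, "config")
    if (!is.null(seed)) blob_cfg$integration$seed <- as.integer(seed)
    if (!identical(unclass(blob_cfg), unclass(cfg)))
      stop("checkpoint was created under a different configuration")
    attr(state, "config") <- NULL
  }
  duration <- duration %||% (cfg$integration$duration_ms - state$t)
  if (duration < 0) stop("duration must be >= 0")
  res <- engine_run(ep, state, duration)

  n <- cfg$populations
  pop_lab <- rep(pop_names, times = c(n$py, n$inh, n$tc, n$re))
  raster <- data.frame(gid = res$spike_gid + 1L, t_ms = res$spike_t)
  raster$pop <- pop_lab[raster$gid]
  tr <- res$traces
  if (length(ep$record$pop))
    colnames(tr) <- vapply(cfg$record$cells, function(r)
      paste0(r$pop, r$idx, "_", r$comp %||% "soma"), "")
  lv <- as.data.frame(res$levels)
  names(lv) <- c("ach", "ha", "gaba")

  structure(list(
    config = cfg, seed = cfg$integration$seed, t0 = state$t,
    duration = duration, raster = raster, sample_t = res$sample_t,
    lfp_vsum = res$lfp_vsum, lfp_bio = res$lfp_bio, traces = tr,
    levels = lv, state = res$state, network = net),
    class = "somnotc_run")
}

#' Advance a state without assembling a full run result
#'
#' Low-level stepping entry point used for convergence and contract tests:
#' advances `state` by `duration` ms under `cfg` and returns the new state.
#'
#' @param cfg A config object.
#' @param state An engine state (from `engine_init()` via [run_simulation()],
#'   a run's `$state`, or a restored checkpoint).
#' @param duration Time to advance (ms).
#' @return The advanced state.
#' @export
advance <- function(cfg, state, duration) {
  net <- build_network(cfg)
  ep <- build_engine_params(cfg, net)
  engine_run(ep, state, duration)$state
}

#' Checkpoint a run
#'
#' Captures the complete engine state plus the config it was produced under.
#' Restoring and resuming is bit-identical to an uninterrupted run.
#'
#' @param run A `somnotc_run`.
#' @return A `somnotc_checkpoint` blob (plain R list; serialize as desired).
#' @export
checkpoint <- function(run) {
  stopifnot(inherits(run, "somnotc_run"))
  structure(list(blob_version = 1L, state = run$state, config = run$config),
            class = "somnotc_checkpoint")
}

#' Restore a checkpoint
#'
#' @param blob A `somnotc_checkpoint`.
#' @return The engine state, with the originating config attached as an
#'   attribute (checked by [run_simulation()] on resume).
#' @export
restore <- function(blob) {
  if (!inherits(blob, "somnotc_checkpoint") ||
      !identical(blob$blob_version, 1L) ||
      !all(c("state", "config") %in% names(blob)) ||
      !all(c("t", "py", "inh", "tc", "re", "syn") %in% names(blob$state)))
    stop("not a valid somnotc checkpoint (corrupt or wrong version)")
  st <- blob$state
  attr(st, "config") <- blob$config
  st
}

#' @export
print.somnotc_run <- function(x, ...) {
  cat("somnotc run: ", x$duration, " ms from t0=", x$t0, " ms, seed ",
      x$seed, "\n", sep = "")
  cat("  spikes: ", nrow(x$raster), ", samples: ", length(x$sample_t),
      "\n", sep = "")
  invisible(x)
}

#' Write a raster as plain text
#'
#' Tab-separated `cell_id<TAB>time_ms`, one spike per line.
#'
#' @param run A `somnotc_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_raster <- function(run, path) {
  utils::write.table(run$raster[, c("gid", "t_ms")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
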