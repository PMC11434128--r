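#' Default simulation configuration
#'
#' Returns the complete parameter tree of the headline protocol: the full
#' 500/100/100/100 network run through five equal sleep stages (wake, N2, N3,
#' REM, N2) over 360,000 ms, with stage-specific neuromodulator levels and
#' linear ramps at stage boundaries. Every value is overridable either by
#' editing the returned list or through a YAML config file read with
#' [load_config()].
#'
#' Units: conductance densities mS/cm^2, absolute synaptic conductances uS,
#' areas cm^2, voltages mV, times ms, concentrations mM, distances um.
#' Cortical axosomatic densities are stored as legacy values; when
#' `soma_variant` is `"capacitive"` the builder rescales them by 3/4 (see
#' [effective_cell_params()]).
#'
#' @return A validated config object (class `somnotc_config`).
#' @export
default_config <- function() {
  validate_config(normalize_config(build_default_tree()))
}

# the raw default parameter tree; also serves as the known-key reference
build_default_tree <- function() {
  list(
    schema_version = 1L,
    soma_variant = "capacitive",
    populations = list(py = 500L, inh = 100L, tc = 100L, re = 100L),
    integration = list(
      dt_ms = 0.025, duration_ms = 360000, seed = 1L, record_dt_ms = 1,
      settle_ms = 500, spike_threshold_mv = 0, refractory_ms = 2),
    schedule = list(
      ramp_ms = 5000,
      stages = list(
        list(stage = "wake", duration_ms = 72000),
        list(stage = "n2", duration_ms = 72000),
        list(stage = "n3", duration_ms = 72000),
        list(stage = "rem", duration_ms = 72000),
        list(stage = "n2", duration_ms = 72000))),
    levels = list(
      wake = list(ach = 1, ha = 1, gaba = 1),
      n2 = list(ach = 0.5, ha = 0.5, gaba = 1.2),
      n3 = list(ach = 0.3, ha = 0.3, gaba = 1.3),
      rem = list(ach = 1.2, ha = 0.1, gaba = 0.9)),
    modulation = list(
      lambda_ampa = 0.3,
      py = list(kappa_ach = 2.0, kappa_ha = 0),
      inh = list(kappa_ach = 2.0, kappa_ha = 0),
      tc = list(kappa_ach = 11.0, kappa_ha = 3.0),
      re = list(kappa_ach = 0.8, kappa_ha = 0.3)),
    cells = list(
      py = list(
        area_soma_cm2 = 1e-6, rho = 165, cm_uf_cm2 = 0.75, g_axial_us = 0.1,
        soma = list(g_na = 3000, g_k = 400, g_nap = 0.3),
        dend = list(g_na = 0.8, g_nap = 0.04, g_km = 0.02, g_kca = 0.15,
                    g_hva = 0.012, g_kl = 0.001, g_leak = 0.033),
        e_na = 50, e_k = -90, e_leak = -68, e_h = -40, v_traub = -70,
        v_init = -68,
        ca = list(rest_mm = 2.4e-4, tau_ms = 250, k_influx = 5.18e-4,
                  out_mm = 2, temp_k = 309.15),
        kca = list(k_f = 2, beta = 0.02), q_rate = 2.95),
      inh = list(
        area_soma_cm2 = 1e-6, rho = 50, cm_uf_cm2 = 0.75, g_axial_us = 0.1,
        soma = list(g_na = 2500, g_k = 400, g_nap = 0),
        dend = list(g_na = 0.8, g_nap = 0, g_km = 0.02, g_kca = 0.15,
                    g_hva = 0.012, g_kl = 0.001, g_leak = 0.033),
        e_na = 50, e_k = -90, e_leak = -68, e_h = -40, v_traub = -70,
        v_init = -68,
        ca = list(rest_mm = 2.4e-4, tau_ms = 250, k_influx = 5.18e-4,
                  out_mm = 2, temp_k = 309.15),
        kca = list(k_f = 2, beta = 0.02), q_rate = 2.95),
      tc = list(
        area_soma_cm2 = 2.9e-4, cm_uf_cm2 = 1,
        g_na = 90, g_k = 10, g_t = 2.2, g_h = 0.017, g_kl = 0.0033,
        g_leak = 0.01,
        e_na = 50, e_k = -95, e_leak = -70, e_h = -40, v_traub = -63,
        v_init = -68,
        ca = list(rest_mm = 2.4e-4, tau_ms = 5, k_influx = 5.18e-4,
                  out_mm = 2, temp_k = 309.15),
        it_phi = list(m = 6.96, h = 3.74),
        ih = list(k1 = 2.5e7, k2 = 4e-4, k3 = 0.1, k4 = 1e-3, g_inc = 2)),
      re = list(
        area_soma_cm2 = 1.43e-4, cm_uf_cm2 = 1,
        g_na = 100, g_k = 10, g_t = 2.3, g_kl = 0.003, g_leak = 0.05,
        e_na = 50, e_k = -95, e_leak = -77, e_h = -40, v_traub = -63,
        v_init = -70,
        ca = list(rest_mm = 2.4e-4, tau_ms = 5, k_influx = 5.18e-4,
                  out_mm = 2, temp_k = 309.15),
        it_phi = list(m = 6.96, h = 3.74))),
    synapse_kinetics = list(
      ampa = list(alpha = 1.1, beta = 0.19),
      nmda = list(alpha = 0.072, beta = 0.0066),
      gabaa = list(alpha = 5, beta = 0.18),
      gabab = list(K1 = 0.52, K2 = 0.0013, K3 = 0.098, K4 = 0.033, Kd = 100),
      pulse = list(amplitude_mm = 0.5, duration_ms = 0.3)),
    connectivity = list(
      py_py = list(radius = 5, g_ampa = 0.22, g_nmda = 0.05, g_gabaa = 0,
                   g_gabab = 0, u_depression = 0.25, tau_depression = 4000,
                   e_rev = 0, delay_ms = 0, allow_self = FALSE,
                   minis = list(rate_max = 0.002, tau_rise = 100,
                                amp_fraction = 0.3)),
      py_inh = list(radius = 1, g_ampa = 0.05, g_nmda = 0.004, g_gabaa = 0,
                    g_gabab = 0, u_depression = 0, tau_depression = 700,
                    e_rev = 0, delay_ms = 0, allow_self = TRUE,
                    minis = list(rate_max = 0.002, tau_rise = 100,
                                 amp_fraction = 0.3)),
      inh_py = list(radius = 5, g_ampa = 0, g_nmda = 0, g_gabaa = 0.2,
                    g_gabab = 0, u_depression = 0, tau_depression = 700,
                    e_rev = -70, delay_ms = 0, allow_self = TRUE,
                    minis = list(rate_max = 0, tau_rise = 100,
                                 amp_fraction = 0.2)),
      py_tc = list(radius = 10, g_ampa = 0.005, g_nmda = 0, g_gabaa = 0,
                   g_gabab = 0, u_depression = 0, tau_depression = 700,
                   e_rev = 0, delay_ms = 0, allow_self = TRUE,
                   minis = list(rate_max = 0.001, tau_rise = 100,
                                amp_fraction = 0.3)),
      py_re = list(radius = 8, g_ampa = 0.01, g_nmda = 0, g_gabaa = 0,
                   g_gabab = 0, u_depression = 0, tau_depression = 700,
                   e_rev = 0, delay_ms = 0, allow_self = TRUE,
                   minis = list(rate_max = 0.001, tau_rise = 100,
                                amp_fraction = 0.3)),
      tc_py = list(radius = 10, g_ampa = 0.03, g_nmda = 0, g_gabaa = 0,
                   g_gabab = 0, u_depression = 0, tau_depression = 700,
                   e_rev = 0, delay_ms = 0, allow_self = TRUE,
                   minis = list(rate_max = 0, tau_rise = 100,
                                amp_fraction = 0.2)),
      tc_inh = list(radius = 2, g_ampa = 0.015, g_nmda = 0, g_gabaa = 0,
                    g_gabab = 0, u_depression = 0, tau_depression = 700,
                    e_rev = 0, delay_ms = 0, allow_self = TRUE,
                    minis = list(rate_max = 0, tau_rise = 100,
                                 amp_fraction = 0.2)),
      tc_re = list(radius = 8, g_ampa = 0.1, g_nmda = 0, g_gabaa = 0,
                   g_gabab = 0, u_depression = 0, tau_depression = 700,
                   e_rev = 0, delay_ms = 0, allow_self = TRUE,
                   minis = list(rate_max = 0, tau_rise = 100,
                                amp_fraction = 0.2)),
      re_tc = list(radius = 8, g_ampa = 0, g_nmda = 0, g_gabaa = 0.18,
                   g_gabab = 0.12, u_depression = 0, tau_depression = 700,
                   e_rev = -85, delay_ms = 0, allow_self = TRUE,
                   minis = list(rate_max = 0, tau_rise = 100,
                                amp_fraction = 0.2)),
      re_re = list(radius = 5, g_ampa = 0, g_nmda = 0, g_gabaa = 0.05,
                   g_gabab = 0, u_depression = 0, tau_depression = 700,
                   e_rev = -75, delay_ms = 0, allow_self = FALSE,
                   minis = list(rate_max = 0, tau_rise = 100,
                                amp_fraction = 0.2))),
    lfp = list(sigma_s_m = 0.3, pitch_um = 20, dend_offset_um = 500,
               electrode_um = NULL, min_distance_um = 10),
    stimulus = list(),
    record = list(cells = list())
  )
}

stage_names <- c("wake", "n2", "n3", "rem")
pop_names <- c("py", "inh", "tc", "re")
proj_names <- c("py_py", "py_inh", "inh_py", "py_tc", "py_re", "tc_py",
                "tc_inh", "tc_re", "re_tc", "re_re")

# coerce parsed config scalars to canonical storage types so that
# serialize -> reparse round-trips to an identical object
normalize_config <- function(cfg) {
  as_int <- function(x) as.integer(x)
  as_num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  walk <- function(x, path = "") {
    if (!is.list(x)) return(x)
    for (nm in names(x)) {
      p <- paste0(path, "/", nm)
      v <- x[[nm]]
      if (is.list(v)) {
        x[[nm]] <- walk(v, p)
      } else if (nm %in% c("schema_version", "seed") ||
                 path == "/populations") {
        x[[nm]] <- as_int(v)
      } else if (nm %in% c("soma_variant", "stage", "pop", "comp")) {
        x[[nm]] <- as.character(v)
      } else if (nm == "allow_self") {
        x[[nm]] <- as.logical(v)
      } else if (is.numeric(v) || is.null(v)) {
        x[[nm]] <- as_num(v)
      }
    }
    x
  }
  out <- walk(cfg)
  class(out) <- "somnotc_config"
  out
}

# recursively collect keys absent from the reference tree
unknown_keys <- function(x, ref, path = "") {
  if (!is.list(x) || !is.list(ref)) return(character())
  bad <- character()
  # unnamed list-of-entries (stages, stimulus, record$cells): check entries
  if (is.null(names(x)) || all(names(x) == "")) {
    for (i in seq_along(x))
      bad <- c(bad, unknown_keys(x[[i]], ref[[1]],
                                 paste0(path, "[", i, "]")))
    return(bad)
  }
  for (nm in names(x)) {
    p <- paste0(path, "/", nm)
    if (!nm %in% names(ref)) {
      bad <- c(bad, p)
    } else if (is.list(x[[nm]])) {
      bad <- c(bad, unknown_keys(x[[nm]], ref[[nm]], p))
    }
  }
  bad
}

config_templates <- function() {
  list(
    stage = list(stage = "wake", duration_ms = 1),
    stimulus = list(pop = "tc", comp = "soma", amp_ua_cm2 = 0, t_on_ms = 0,
                    t_off_ms = 0, cells = c(0, 0)),
    record_cell = list(pop = "py", idx = 0, comp = "soma")
  )
}

#' Validate a simulation configuration
#'
#' Checks the whole parameter tree: known keys only (typos are hard errors),
#' population counts, positive time step, stage labels and durations summing
#' to the configured total, neuromodulator bounds, non-negative conductances
#' and connection radii. All violations are reported together.
#'
#' @param cfg A config list as returned by [default_config()] or
#'   [load_config()].
#' @return The validated config, invisibly classed `somnotc_config`.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  ref <- build_default_tree()
  tpl <- config_templates()
  # unknown keys against the default tree (entry templates substituted)
  ref$schedule$stages <- list(tpl$stage)
  ref$stimulus <- list(tpl$stimulus)
  ref$record$cells <- list(tpl$record_cell)
  bad <- unknown_keys(unclass(cfg), ref)
  if (length(bad))
    errs <- c(errs, paste0("unknown config key: ", bad))

  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  for (p in pop_names)
    need(is.numeric(cfg$populations[[p]]) && cfg$populations[[p]] >= 0,
         paste0("populations$", p, " must be a count >= 0"))
  need(sum(unlist(cfg$populations)) >= 1, "network must contain >= 1 cell")
  need(cfg$integration$dt_ms > 0, "integration$dt_ms must be > 0")
  need(cfg$integration$duration_ms >= 0,
       "integration$duration_ms must be >= 0")
  need(cfg$integration$record_dt_ms >= cfg$integration$dt_ms,
       "integration$record_dt_ms must be >= dt_ms")
  need(cfg$soma_variant %in% c("capacitive", "legacy_algebraic"),
       "soma_variant must be 'capacitive' or 'legacy_algebraic'")

  st <- cfg$schedule$stages
  durs <- vapply(st, function(s) s$duration_ms %||% NA_real_, 0)
  labs <- vapply(st, function(s) s$stage %||% NA_character_, "")
  need(all(labs %in% stage_names),
       paste0("unknown stage label(s): ",
              paste(setdiff(labs, stage_names), collapse = ", ")))
  need(all(durs > 0), "all stage durations must be > 0")
  if (all(is.finite(durs)))
    need(abs(sum(durs) - cfg$integration$duration_ms) < 1e-6,
         sprintf("stage durations sum to %g ms but duration_ms is %g ms",
                 sum(durs), cfg$integration$duration_ms))
  need(cfg$schedule$ramp_ms >= 0, "schedule$ramp_ms must be >= 0")
  if (all(is.finite(durs)) && length(durs))
    need(cfg$schedule$ramp_ms < min(durs),
         "schedule$ramp_ms must be < the shortest stage duration")

  for (sn in stage_names) {
    lv <- cfg$levels[[sn]]
    need(lv$ach >= 0 && lv$ach <= 2,
         paste0("levels$", sn, "$ach out of [0, 2]"))
    need(lv$ha >= 0 && lv$ha <= 2, paste0("levels$", sn, "$ha out of [0, 2]"))
    need(lv$gaba >= 0, paste0("levels$", sn, "$gaba must be >= 0"))
  }
  for (p in pop_names) {
    m <- cfg$modulation[[p]]
    need(m$kappa_ach >= 0 && m$kappa_ha >= 0,
         paste0("modulation$", p, " gains must be >= 0"))
  }

  for (p in pop_names) {
    cp <- cfg$cells[[p]]
    need(cp$cm_uf_cm2 > 0, paste0("cells$", p, "$cm_uf_cm2 must be > 0"))
    need(cp$area_soma_cm2 > 0, paste0("cells$", p, "$area_soma_cm2 > 0"))
    if (p %in% c("py", "inh"))
      need(!is.null(cp$rho) && cp$rho > 0,
           paste0("cells$", p, "$rho (dendrite/soma area ratio) required"))
    gs <- unlist(cp[names(cp) %in%
                      c("g_na", "g_k", "g_t", "g_h", "g_kl", "g_leak")])
    gs <- c(gs, unlist(cp$soma), unlist(cp$dend))
    need(all(gs >= 0), paste0("cells$", p, " conductances must be >= 0"))
    need(cp$ca$rest_mm > 0 && cp$ca$tau_ms > 0,
         paste0("cells$", p, "$ca rest and tau must be > 0"))
  }

  for (pj in proj_names) {
    cn <- cfg$connectivity[[pj]]
    need(cn$radius >= 0, paste0("connectivity$", pj, "$radius must be >= 0"))
    need(all(c(cn$g_ampa, cn$g_nmda, cn$g_gabaa, cn$g_gabab) >= 0),
         paste0("connectivity$", pj, " conductances must be >= 0"))
    need(cn$u_depression >= 0 && cn$u_depression < 1,
         paste0("connectivity$", pj, "$u_depression out of [0, 1)"))
    need(cn$tau_depression > 0,
         paste0("connectivity$", pj, "$tau_depression must be > 0"))
  }
  need(cfg$synapse_kinetics$pulse$duration_ms > 0,
       "synapse_kinetics$pulse$duration_ms must be > 0")
  need(cfg$lfp$sigma_s_m > 0, "lfp$sigma_s_m must be > 0")

  for (i in seq_along(cfg$stimulus)) {
    s <- cfg$stimulus[[i]]
    need(s$pop %in% pop_names,
         sprintf("stimulus[%d]$pop must be one of py/inh/tc/re", i))
    need(s$t_off_ms >= s$t_on_ms,
         sprintf("stimulus[%d] window must have t_off >= t_on", i))
  }

  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a config file
#'
#' Parses a YAML configuration, fills omitted optional keys from
#' [default_config()], normalizes scalar types and validates the result.
#' Unknown keys anywhere in the tree are a hard error so typos cannot pass
#' silently. Parse failures report the offending line.
#'
#' @param path Path to a YAML config file.
#' @return A config object (class `somnotc_config`).
#' @seealso [write_config()] for the inverse operation.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("config parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("config file must contain a mapping at top level")
  if (!is.null(raw$schema_version) && raw$schema_version != 1L)
    stop("unsupported schema_version: ", raw$schema_version)
  cfg <- merge_config(build_default_tree(), raw)
  cfg <- fill_stage_durations(cfg)
  validate_config(normalize_config(cfg))
}

# defaults overlaid with user values; list-of-entry sections are replaced,
# named sections merged recursively
merge_config <- function(base, user) {
  replace_whole <- c("stages", "stimulus", "cells_record")
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && !is.null(names(user[[nm]])) &&
        nm %in% names(base) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# equal split of any stage durations left unspecified
fill_stage_durations <- function(cfg) {
  st <- cfg$schedule$stages
  durs <- vapply(st, function(s) s$duration_ms %||% NA_real_, 0)
  if (anyNA(durs)) {
    rem <- cfg$integration$duration_ms - sum(durs, na.rm = TRUE)
    share <- rem / sum(is.na(durs))
    for (i in which(is.na(durs))) st[[i]]$duration_ms <- share
    cfg$schedule$stages <- st
  }
  cfg
}

#' Serialize a config to YAML
#'
#' Writes the full parameter tree; [load_config()] of the written file
#' reproduces an identical config object.
#'
#' @param cfg A config object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(drop_null(unclass(cfg)), path, precision = 15)
  invisible(path)
}

drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, drop_null)
}

#' Stage boundaries and neuromodulator knots of a schedule
#'
#' Internal representation of the schedule as a piecewise-linear function of
#' time: plateau values inside stages, linear interpolation across a ramp
#' window centred on each boundary.
#'
#' @param cfg A config object.
#' @return A list with `knots` (data.frame `t`, `ach`, `ha`, `gaba`),
#'   `bounds` (stage start times), `labels` and `total_ms`.
#' @export
schedule_knots <- function(cfg) {
  st <- cfg$schedule$stages
  durs <- vapply(st, function(s) s$duration_ms, 0)
  labs <- vapply(st, function(s) s$stage, "")
  lv <- t(vapply(labs, function(l) unlist(cfg$levels[[l]]), numeric(3)))
  ends <- cumsum(durs)
  starts <- c(0, head(ends, -1))
  r <- cfg$schedule$ramp_ms
  kt <- 0; kl <- lv[1, , drop = FALSE]
  n <- length(durs)
  if (n > 1) {
    for (b in seq_len(n - 1)) {
      kt <- c(kt, ends[b] - r / 2, ends[b] + r / 2)
      kl <- rbind(kl, lv[b, ], lv[b + 1, ])
    }
  }
  kt <- c(kt, ends[n]); kl <- rbind(kl, lv[n, ])
  list(knots = data.frame(t = kt, ach = kl[, 1], ha = kl[, 2],
                          gaba = kl[, 3]),
       bounds = starts, labels = labs, total_ms = ends[n])
}

#' Neuromodulator levels at a time point
#'
#' Evaluates the stage schedule: piecewise-constant acetylcholine, histamine
#' and GABA levels inside stages with linear interpolation over the ramp
#' window centred on each stage boundary; continuous in `t`. At a boundary
#' with a positive ramp the value is the arithmetic mean of the adjacent
#' stages' levels.
#'
#' @param cfg A config object (its `schedule` and `levels` define the map).
#' @param t Time (ms), scalar or vector, within `[0, total duration]`.
#' @return A data.frame with columns `ach`, `ha`, `gaba`, one row per `t`.
#' @export
neuromod_at <- function(cfg, t) {
  sk <- schedule_knots(cfg)
  if (any(t < 0 | t > sk$total_ms))
    stop("t out of schedule range [0, ", sk$total_ms, "] ms")
  k <- sk$knots
  data.frame(
    ach = approx(k$t, k$ach, t, rule = 2, ties = "ordered")$y,
    ha = approx(k$t, k$ha, t, rule = 2, ties = "ordered")$y,
    gaba = approx(k$t, k$gaba, t, rule = 2, ties = "ordered")$y)
}

#' Stage label at a time point
#'
#' @param cfg A config object.
#' @param t Time (ms), scalar or vector.
#' @return Character vector of stage labels (`wake`, `n2`, `n3`, `rem`).
#' @export
stage_at <- function(cfg, t) {
  sk <- schedule_knots(cfg)
  if (any(t < 0 | t > sk$total_ms))
    stop("t out of schedule range [0, ", sk$total_ms, "] ms")
  idx <- findInterval(t, sk$bounds, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  sk$labels[idx]
}

#' @export
print.somnotc_config <- function(x, ...) {
  p <- x$populations
  cat("somnotc config: PY=", p$py, " INH=", p$inh, " TC=", p$tc,
      " RE=", p$re, "\n", sep = "")
  labs <- vapply(x$schedule$stages, function(s) s$stage, "")
  cat("  schedule: ", paste(labs, collapse = " -> "), " (",
      x$integration$duration_ms, " ms total, ramp ", x$schedule$ramp_ms,
      " ms)\n", sep = "")
  cat("  dt = ", x$integration$dt_ms, " ms, seed = ", x$integration$seed,
      ", soma variant = ", x$soma_variant, "\n", sep = "")
  invisible(x)
}
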