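fixture_names <- c("single_tc_rebound", "re_tc_spindle_pair",
                   "cortical_slab_n3", "full_reduced_cycle")

#' Reduced desk-scale fixture configurations
#'
#' Complete, validated configs for four small scenarios that exercise the
#' model's characteristic dynamics in minutes on one core:
#' \describe{
#'   \item{single_tc_rebound}{One isolated TC cell, hyperpolarized by an
#'     injected current step and then released — probes the low-threshold
#'     rebound burst that seeds spindles.}
#'   \item{re_tc_spindle_pair}{A small RE+TC circuit under N2 levels (GABA-A
#'     + GABA-B feedback from RE, AMPA drive to RE), kicked once — probes
#'     the 7-14 Hz spindle loop. `stage` can override the level set (e.g.
#'     `"wake"` for the non-spindling control).}
#'   \item{cortical_slab_n3}{A PY/INH slab under N3 levels with depressing
#'     recurrent AMPA and miniature EPSPs — probes the < 1 Hz Up/Down slow
#'     oscillation.}
#'   \item{full_reduced_cycle}{The whole four-population network scaled by
#'     `scale` (default 1/10: 50/10/10/10 cells) run through the five-stage
#'     wake, N2, N3, REM, N2 sequence at `scale` times the full 360,000 ms.}
#' }
#'
#' @param scenario One of the four names above.
#' @param scale Scale factor in (0, 1]; `full_reduced_cycle` at `scale = 1`
#'   reproduces the default population counts and duration.
#' @param seed RNG seed stored in the config.
#' @param stage Optional stage-label override for the single-stage
#'   scenarios.
#' @return A validated config object.
#' @export
make_fixture <- function(scenario = fixture_names, scale = NULL, seed = 1,
                         stage = NULL) {
  scenario <- match.arg(scenario)
  cfg <- unclass(default_config())
  cfg$integration$seed <- as.integer(seed)

  single_stage <- function(cfg, label, dur, settle = 500) {
    cfg$schedule$stages <- list(list(stage = label, duration_ms = dur))
    cfg$schedule$ramp_ms <- 0
    cfg$integration$duration_ms <- dur
    cfg$integration$settle_ms <- settle
    cfg
  }

  if (scenario == "single_tc_rebound") {
    scale <- scale %||% 1
    cfg$populations <- list(py = 0L, inh = 0L, tc = 1L, re = 0L)
    cfg <- single_stage(cfg, stage %||% "wake", 3000)
    cfg$stimulus <- list(list(pop = "tc", comp = "soma",
                              amp_ua_cm2 = -1.5, t_on_ms = 500,
                              t_off_ms = 1500, cells = NULL))
    cfg$record$cells <- list(list(pop = "tc", idx = 0, comp = "soma"))
  } else if (scenario == "re_tc_spindle_pair") {
    scale <- scale %||% 1
    ntc <- max(1L, as.integer(round(4 * scale)))
    cfg$populations <- list(py = 0L, inh = 0L, tc = ntc, re = ntc)
    cfg <- single_stage(cfg, stage %||% "n2", 11000, settle = 1000)
    # isolated circuit: no tonic corticothalamic drive, so the relay cells
    # sit slightly deeper; a lower leak baseline restores the operating
    # point the full network reaches under the same stage levels
    cfg$cells$tc$g_kl <- 0.0025
    cfg$connectivity$tc_re$radius <- 2
    cfg$connectivity$re_tc$radius <- 2
    cfg$connectivity$re_re$radius <- 1
    cfg$stimulus <- list(list(pop = "tc", comp = "soma",
                              amp_ua_cm2 = -1.5, t_on_ms = 400,
                              t_off_ms = 700, cells = NULL))
    cfg$record$cells <- c(
      lapply(seq_len(ntc) - 1L, function(i)
        list(pop = "tc", idx = i, comp = "soma")),
      lapply(seq_len(ntc) - 1L, function(i)
        list(pop = "re", idx = i, comp = "soma")))
  } else if (scenario == "cortical_slab_n3") {
    scale <- scale %||% 1
    npy <- max(2L, as.integer(round(50 * scale)))
    ninh <- max(1L, as.integer(round(10 * scale)))
    cfg$populations <- list(py = npy, inh = ninh, tc = 0L, re = 0L)
    cfg <- single_stage(cfg, stage %||% "n3", 20500)
    # the isolated slab recurs slightly faster than the full network;
    # deeper, slower depression keeps the Up-state recurrence below 1 Hz
    cfg$connectivity$py_py$u_depression <- 0.3
    cfg$connectivity$py_py$tau_depression <- 5000
    cfg$record$cells <- list(list(pop = "py", idx = 0, comp = "dend"),
                             list(pop = "py", idx = as.integer(npy %/% 2),
                                  comp = "dend"))
  } else { # full_reduced_cycle
    scale <- scale %||% 0.1
    cfg$populations <- lapply(cfg$populations,
                              function(m) max(1L, as.integer(round(m * scale))))
    dur <- 360000 * scale
    cfg$integration$duration_ms <- dur
    cfg$schedule$stages <- lapply(cfg$schedule$stages, function(s) {
      s$duration_ms <- dur / 5; s
    })
    cfg$schedule$ramp_ms <- min(5000 * scale, dur / 5 * 0.5)
    cfg$record$cells <- list(list(pop = "py", idx = 0, comp = "dend"))
  }
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  validate_config(normalize_config(cfg))
}
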