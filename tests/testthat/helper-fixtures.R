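# tiny configs used across tests; built in code, never stored on disk

quiet_single_cell_cfg <- function(type = "tc", dur = 1000, stage = "wake") {
  cfg <- unclass(default_config())
  for (p in c("py", "inh", "tc", "re"))
    cfg$populations[[p]] <- if (p == type) 1L else 0L
  cfg$integration$duration_ms <- dur
  cfg$schedule$stages <- list(list(stage = stage, duration_ms = dur))
  cfg$schedule$ramp_ms <- 0
  cfg$record$cells <- list(list(pop = type, idx = 0, comp = "soma"))
  validate_config(somnotc:::normalize_config(cfg))
}

two_stage_cfg <- function(ach1 = 1, ach2 = 0.3, ramp = 10000,
                          dur1 = 30000, dur2 = 30000) {
  cfg <- unclass(default_config())
  cfg$integration$duration_ms <- dur1 + dur2
  cfg$schedule$stages <- list(list(stage = "wake", duration_ms = dur1),
                              list(stage = "n3", duration_ms = dur2))
  cfg$schedule$ramp_ms <- ramp
  cfg$levels$wake$ach <- ach1
  cfg$levels$n3$ach <- ach2
  validate_config(somnotc:::normalize_config(cfg))
}
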