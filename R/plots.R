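#' Raster plot of a run
#'
#' Spike times of every cell, one row per cell, populations stacked in PY,
#' INH, TC, RE order.
#'
#' @param run A `somnotc_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_raster <- function(run, ...) {
  r <- run$raster
  n <- run$config$populations
  graphics::plot(r$t_ms / 1000, r$gid, pch = ".", cex = 1.5,
                 xlab = "time (s)", ylab = "cell",
                 col = c(py = "black", inh = "red", tc = "blue",
                         re = "darkgreen")[r$pop], ...)
  offs <- cumsum(c(0, n$py, n$inh, n$tc))
  graphics::abline(h = offs[-1] + 0.5, col = "grey70")
}

#' Spectrogram image
#'
#' Time-frequency power on a log10 colour scale.
#'
#' @param spec A `somnotc_spectrogram`.
#' @param fmax Upper frequency limit of the display (Hz).
#' @param ... Passed to [graphics::image()].
#' @export
plot_spectrogram <- function(spec, fmax = 20, ...) {
  sel <- spec$freq <= fmax
  z <- log10(t(spec$power[sel, , drop = FALSE]) + 1e-12)
  graphics::image(spec$time, spec$freq[sel], z,
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
}
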