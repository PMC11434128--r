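#' Point-source transfer resistance
#'
#' Transfer resistance between a recording electrode and compartments in a
#' homogeneous volume conductor: `R = 1/(4 pi sigma r)`. A compartment's
#' contribution to the extracellular potential is `R` times its
#' transmembrane current.
#'
#' @param electrode Electrode position, length-3 numeric (um).
#' @param positions Compartment positions: a matrix with columns x, y, z
#'   (um), or a length-3 vector for a single compartment.
#' @param sigma Extracellular conductivity (S/m).
#' @param min_distance_um Minimum admissible electrode-compartment distance;
#'   closer geometries are an error (the point-source form diverges).
#' @return Transfer resistances in MOhm (1 nA through 1 MOhm gives 1 mV;
#'   e.g. sigma 0.3 S/m at r = 100 um gives 2.65e-3 MOhm, i.e. 2.65 uV/nA).
#' @export
transfer_resistance <- function(electrode, positions, sigma = 0.3,
                                min_distance_um = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  d <- sweep(positions[, 1:3, drop = FALSE], 2, electrode)
  r_um <- sqrt(rowSums(d^2))
  if (any(r_um < min_distance_um))
    stop("electrode within ", min_distance_um,
         " um of a compartment (min distance ", round(min(r_um), 2), " um)")
  r_m <- r_um * 1e-6
  1 / (4 * pi * sigma * r_m) / 1e6
}

#' Summed-voltage LFP
#'
#' First-approximation LFP: weighted combination of intracellular voltage
#' traces; by default the arithmetic mean, so the amplitude does not scale
#' with population size.
#'
#' @param v_traces Matrix of voltages, time in rows, cells in columns.
#' @param weights Optional weights, one per column; default equal weights
#'   summing to 1 (the mean).
#' @return Numeric trace (mV).
#' @export
summed_voltage_lfp <- function(v_traces, weights = NULL) {
  v_traces <- as.matrix(v_traces)
  if (ncol(v_traces) == 0) stop("no voltage traces selected")
  if (is.null(weights)) weights <- rep(1 / ncol(v_traces), ncol(v_traces))
  if (length(weights) != ncol(v_traces))
    stop("weights length must match number of traces")
  drop(v_traces %*% weights)
}

#' Transfer-resistance (biophysical) LFP
#'
#' Extracellular potential as the superposition of all compartmental
#' transmembrane currents weighted by their transfer resistances:
#' `phi(t) = sum_k R_k I_k(t)`. Currents must include the capacitive
#' component so that each cell's compartment currents sum to zero (a point
#' cell then contributes nothing; dipoles dominate).
#'
#' @param currents_na Matrix of transmembrane currents, time in rows and
#'   compartments in columns (nA, outward positive).
#' @param r_mohm Transfer resistances, one per compartment (MOhm).
#' @return LFP trace in uV.
#' @export
biophysical_lfp <- function(currents_na, r_mohm) {
  currents_na <- as.matrix(currents_na)
  if (ncol(currents_na) != length(r_mohm))
    stop("one transfer resistance per compartment required (",
         ncol(currents_na), " columns vs ", length(r_mohm), " resistances)")
  drop(currents_na %*% r_mohm) * 1000 # MOhm * nA = mV -> uV
}

#' Short-time power spectral density
#'
#' Hann-tapered short-time periodogram of an LFP trace, scaled as one-sided
#' power spectral density so that summing `power * df` over frequency
#' recovers the windowed signal variance (energy identity of the taper).
#'
#' @param x Signal (the trace is mean-subtracted per window).
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s).
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @return A `somnotc_spectrogram`: `freq` (Hz), `time` (s, window centres),
#'   `power` (freq x window PSD matrix), `df`, `fs`.
#' @export
lfp_spectrogram <- function(x, fs, window_s = 2, overlap = 0.75) {
  n <- floor(window_s * fs)
  if (n < 4) stop("window too short for the sampling rate")
  if (n > length(x)) stop("window longer than the trace")
  hop <- max(1, floor(n * (1 - overlap)))
  starts <- seq(1, length(x) - n + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) # Hann
  wnorm <- sum(w^2)
  nf <- floor(n / 2) + 1
  pow <- matrix(0, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + n - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * wnorm)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] # one-sided
    pow[, j] <- p
  }
  structure(list(
    freq = (seq_len(nf) - 1) * fs / n,
    time = (starts - 1 + n / 2) / fs,
    power = pow, df = fs / n, fs = fs, window_s = window_s,
    overlap = overlap), class = "somnotc_spectrogram")
}

#' Band power per window
#'
#' Integrates a spectrogram's PSD over a frequency band, per window.
#' Default bands used throughout the package: slow oscillation 0.1-1 Hz,
#' spindle 7-14 Hz, alpha 8-13 Hz.
#'
#' @param spec A `somnotc_spectrogram`.
#' @param band Length-2 numeric, `c(low, high)` in Hz, within Nyquist.
#' @return Numeric vector of band power, one value per window.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "somnotc_spectrogram"), length(band) == 2)
  if (band[2] <= band[1]) stop("band must have high > low")
  if (band[1] > max(spec$freq)) stop("band beyond Nyquist frequency")
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel)) stop("band selects no frequency bins")
  colSums(spec$power[sel, , drop = FALSE]) * spec$df
}

default_bands <- function() {
  list(so = c(0.1, 1), spindle = c(7, 14), alpha = c(8, 13))
}

#' Dominant frequency of a trace
#'
#' Frequency of the maximum of the time-averaged short-time PSD above a
#' floor frequency.
#'
#' @param x Signal.
#' @param fs Sampling rate (Hz).
#' @param fmin Ignore frequencies below this floor (Hz).
#' @param window_s Spectrogram window (s).
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, fmin = 0.25, window_s = 2) {
  sp <- lfp_spectrogram(x, fs, window_s = window_s)
  m <- rowMeans(sp$power)
  sel <- sp$freq >= fmin
  sp$freq[sel][which.max(m[sel])]
}

#' Per-stage band power report
#'
#' Splits a run's LFP into its schedule's stage plateaus (ramp halves and
#' the initial settling window excluded), computes a spectrogram per
#' segment, and reports the median band power per stage occurrence and
#' band. This is the quantitative handle on the stage-specific rhythms:
#' spindle-band power peaks in N2, slow-oscillation power in N3.
#'
#' @param run A `somnotc_run`.
#' @param bands Named list of `c(low, high)` Hz bands.
#' @param which_lfp `"vsum"` (summed-voltage) or `"bio"`.
#' @param window_s Spectrogram window (s).
#' @return A data.frame: `stage`, `occurrence`, `t_start_ms`, `t_end_ms`,
#'   and one column of median band power per band.
#' @export
stage_band_report <- function(run, bands = default_bands(),
                              which_lfp = c("vsum", "bio"), window_s = 2) {
  which_lfp <- match.arg(which_lfp)
  cfg <- run$config
  sk <- schedule_knots(cfg)
  fs <- 1000 / cfg$integration$record_dt_ms
  x <- if (which_lfp == "vsum") run$lfp_vsum else run$lfp_bio
  tt <- run$sample_t
  r2 <- cfg$schedule$ramp_ms / 2
  settle <- cfg$integration$settle_ms
  ends <- c(sk$bounds[-1], sk$total_ms)
  rows <- list()
  for (i in seq_along(sk$labels)) {
    a <- sk$bounds[i] + if (i == 1) settle else r2
    b <- ends[i] - if (i == length(sk$labels)) 0 else r2
    sel <- tt >= a & tt < b
    if (sum(sel) < window_s * fs) next
    sp <- lfp_spectrogram(x[sel], fs, window_s = window_s)
    med <- vapply(bands, function(bd) median(band_power(sp, bd)), 0)
    rows[[i]] <- cbind(
      data.frame(stage = sk$labels[i], occurrence = i, t_start_ms = a,
                 t_end_ms = b),
      as.data.frame(as.list(med)))
  }
  do.call(rbind, rows)
}

#' Network silence statistics from a raster
#'
#' Bins network-wide spiking and reports the fraction of silent bins and
#' the number of active/silent alternations — the signature of the slow
#' oscillation's Up/Down states.
#'
#' @param raster A run's raster data.frame (`t_ms` column used).
#' @param t_start,t_end Analysis window (ms).
#' @param bin_ms Bin width (ms).
#' @return List with `silent_fraction`, `n_alternations`, `n_bins`.
#' @export
silence_stats <- function(raster, t_start, t_end, bin_ms = 10) {
  breaks <- seq(t_start, t_end, by = bin_ms)
  if (length(breaks) < 3) stop("analysis window shorter than two bins")
  ts <- raster$t_ms[raster$t_ms >= t_start & raster$t_ms < t_end]
  counts <- tabulate(findInterval(ts, breaks), nbins = length(breaks) - 1)
  silent <- counts == 0
  list(silent_fraction = mean(silent),
       n_alternations = sum(diff(silent) != 0),
       n_bins = length(silent))
}
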