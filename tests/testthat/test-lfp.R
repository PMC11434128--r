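test_that("transfer resistance follows the point-source 1/r law", {
  r1 <- transfer_resistance(c(0, 0, 0), c(100, 0, 0), sigma = 0.3)
  r2 <- transfer_resistance(c(0, 0, 0), c(200, 0, 0), sigma = 0.3)
  expect_equal(r1, 2 * r2)
  # closed form: 1/(4 pi sigma r) = 2653 Ohm = 2.653e-3 MOhm at 100 um
  expect_equal(r1, 1 / (4 * pi * 0.3 * 1e-4) / 1e6, tolerance = 1e-12)
  # equidistant compartments see equal resistance
  rr <- transfer_resistance(c(0, 0, 0), rbind(c(100, 0, 0), c(0, 100, 0)))
  expect_equal(rr[1], rr[2])
  expect_error(transfer_resistance(c(0, 0, 0), c(5, 0, 0)), "electrode")
  expect_error(transfer_resistance(c(0, 0, 0), c(100, 0, 0), sigma = 0),
               "sigma")
})

test_that("biophysical LFP matches the closed form and superposes exactly", {
  r <- transfer_resistance(c(0, 0, 0), c(100, 0, 0), sigma = 0.3)
  phi <- biophysical_lfp(matrix(1), r) # 1 nA
  expect_equal(phi, 2.653, tolerance = 1e-3)
  expect_equal(phi, 1000 / (4 * pi * 0.3 * 1e-4) / 1e6, tolerance = 1e-10)
  # zero currents give zero potential
  expect_equal(biophysical_lfp(matrix(0, 5, 1), r), rep(0, 5))
  # superposition: phi(A union B) = phi(A) + phi(B), exactly
  set.seed(7)
  pos <- cbind(runif(6, 50, 500), runif(6, 50, 500), 0)
  rr <- transfer_resistance(c(0, 0, 0), pos)
  I <- matrix(rnorm(60), 10, 6)
  whole <- biophysical_lfp(I, rr)
  parts <- biophysical_lfp(I[, 1:3], rr[1:3]) +
    biophysical_lfp(I[, 4:6], rr[4:6])
  expect_equal(whole, parts, tolerance = 1e-12)
  expect_error(biophysical_lfp(I, rr[1:3]), "resistance")
})

test_that("summed-voltage LFP is a weighted mean of traces", {
  v <- cbind(a = c(-70, -60), b = c(-50, -40))
  expect_equal(summed_voltage_lfp(v[, 1, drop = FALSE]), v[, 1],
               ignore_attr = TRUE)
  expect_equal(summed_voltage_lfp(v), c(-60, -50))
  expect_equal(summed_voltage_lfp(matrix(-65, 4, 3)), rep(-65, 4))
  expect_error(summed_voltage_lfp(v[, 0]), "traces")
  expect_error(summed_voltage_lfp(v, weights = 1), "length")
})

test_that("spectrogram localizes known tones and satisfies the energy \
identity", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  sp <- lfp_spectrogram(x, fs, window_s = 2, overlap = 0.5)
  peak <- sp$freq[apply(sp$power, 2, which.max)]
  expect_true(all(abs(peak - 10) <= sp$df))
  # energy identity: integrated PSD recovers the signal variance (0.5)
  expect_equal(median(colSums(sp$power) * sp$df), 0.5, tolerance = 0.02)
  # zero in, zero out
  expect_true(all(lfp_spectrogram(numeric(800), fs)$power == 0))
  # two tones give two distinct ridges
  x2 <- sin(2 * pi * 1 * t) + sin(2 * pi * 12 * t)
  sp2 <- lfp_spectrogram(x2, fs, window_s = 4, overlap = 0.5)
  pm <- rowMeans(sp2$power)
  p1 <- pm[which.min(abs(sp2$freq - 1))]
  p12 <- pm[which.min(abs(sp2$freq - 12))]
  expect_gt(p1, 50 * median(pm))
  expect_gt(p12, 50 * median(pm))
  expect_error(lfp_spectrogram(x[1:100], fs, window_s = 2), "longer")
})

test_that("band power integrates the PSD over the requested band", {
  fs <- 200
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  sp <- lfp_spectrogram(x, fs, window_s = 2, overlap = 0.5)
  inband <- band_power(sp, c(7, 14))
  total <- band_power(sp, c(0, 100))
  expect_gt(median(inband) / median(total), 0.95)
  expect_lt(median(band_power(sp, c(30, 60))) / median(total), 0.01)
  expect_error(band_power(sp, c(14, 7)), "band")
  expect_error(band_power(sp, c(150, 200)), "Nyquist")
})

test_that("white-noise band power scales with bandwidth", {
  fs <- 100
  set.seed(11)
  ratios <- replicate(50, {
    x <- rnorm(fs * 8)
    sp <- lfp_spectrogram(x, fs, window_s = 2, overlap = 0)
    median(band_power(sp, c(5, 25))) / median(band_power(sp, c(30, 40)))
  })
  # 20 Hz band vs 10 Hz band: ratio 2 within sampling error
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("silence statistics count silent bins and alternations", {
  ras <- data.frame(t_ms = c(5, 7, 9, 105, 107, 300, 301))
  s <- silence_stats(ras, 0, 400, bin_ms = 100)
  expect_equal(s$n_bins, 4)
  expect_equal(s$silent_fraction, 0.25)
  expect_equal(s$n_alternations, 2)
})
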