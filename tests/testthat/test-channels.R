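test_that("sigmoid_inf has midpoint, saturation and monotonicity", {
  expect_equal(sigmoid_inf(-59, -59, 6.2), 0.5)
  expect_equal(sigmoid_inf(500, -59, 6.2), 1, tolerance = 1e-12)
  expect_equal(sigmoid_inf(-40, -59, 6.2), 1 / (1 + exp(-19 / 6.2)))
  expect_equal(sigmoid_inf(-40, -59, 6.2), 0.955, tolerance = 1e-3)
  v <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(sigmoid_inf(v, -59, 6.2)) > 0))
  expect_true(all(diff(sigmoid_inf(v, -83, -4)) < 0))
  expect_error(sigmoid_inf(0, 0, 0), "slope")
})

test_that("T-current kinetics match their closed forms", {
  k <- it_tc_kinetics(-59)
  expect_equal(k$m_inf, 0.5)
  expect_equal(it_tc_kinetics(-83)$h_inf, 0.5)
  k70 <- it_tc_kinetics(-70)
  # independent evaluation of the stated closed forms
  expect_equal(k70$tau_m,
               (0.612 + 1 / (exp(-(-70 + 132) / 16.7) +
                               exp((-70 + 16.8) / 18.2))) / 6.96)
  expect_true(k70$tau_h > 0 && is.finite(k70$tau_h))
  expect_equal(it_re_kinetics(-52)$m_inf, 0.5)
  expect_equal(it_re_kinetics(-80)$h_inf, 0.5)
  expect_equal(it_re_kinetics(-60)$m_inf, 1 / (1 + exp(8 / 7.4)))
  expect_equal(it_re_kinetics(-60)$m_inf, 0.2533, tolerance = 1e-3)
})

test_that("steady states are monotone and time constants positive over the \
physiological range", {
  v <- seq(-120, 60, by = 1)
  for (fn in list(it_tc_kinetics, it_re_kinetics)) {
    k <- lapply(v, fn)
    m <- vapply(k, `[[`, 0, "m_inf"); h <- vapply(k, `[[`, 0, "h_inf")
    expect_true(all(diff(m) > 0))
    expect_true(all(diff(h) < 0))
    expect_true(all(vapply(k, `[[`, 0, "tau_m") > 0))
    expect_true(all(vapply(k, `[[`, 0, "tau_h") > 0))
  }
})

test_that("regulated h-current conserves probability and responds to calcium", {
  st <- list(O = 0.2, OL = 0.1, P1 = 0.05)
  # no calcium: P1 relaxes toward 0, never binds
  s2 <- ih_regulated_step(st, v = -75, ca = 1e-8, dt = 0.025)
  expect_lt(s2$P1, st$P1)
  # probability conservation under a random voltage trajectory
  set.seed(42)
  s <- list(O = 0.3, OL = 0, P1 = 0)
  ok <- TRUE
  for (i in 1:2000) {
    v <- runif(1, -100, -40)
    ca <- runif(1, 1e-4, 5e-3)
    s <- ih_regulated_step(s, v, ca, dt = 0.025)
    ok <- ok && s$O >= 0 && s$OL >= 0 && s$O + s$OL <= 1 &&
      s$P1 >= 0 && s$P1 <= 1
  }
  expect_true(ok)
  # voltage clamp at half-activation: O equilibrates near 0.5*(1-OL)
  s <- list(O = 0, OL = 0, P1 = 0)
  for (i in seq_len(20000)) # 10 s at dt 0.5 (rates are slow)
    s <- ih_regulated_step(s, -75, 2.4e-4, 0.5)
  expect_equal(s$O, 0.5 * (1 - s$OL), tolerance = 0.02)
  expect_error(ih_regulated_step(s, -75, 2.4e-4, 0), "dt")
})

test_that("Km rate has its removable singularity evaluated by limit", {
  k <- km_kca_nap_hva_kinetics(-30, 2.4e-4)
  expect_equal(k$km$alpha, 2.95 * 0.001 * 9, tolerance = 1e-4)
  near <- km_kca_nap_hva_kinetics(-30 + 1e-7, 2.4e-4)
  expect_equal(k$km$alpha, near$km$alpha, tolerance = 1e-6)
})

test_that("KCa activation vanishes with calcium and Nap is sigmoidal", {
  k <- km_kca_nap_hva_kinetics(-60, 1e-9)
  expect_lt(k$kca$alpha, 1e-7)
  expect_equal(km_kca_nap_hva_kinetics(-42, 1e-3)$nap$m_inf, 0.5)
})

test_that("calcium pool has the stated fixed points", {
  # at rest with no current: unchanged
  expect_equal(update_calcium(2.4e-4, 0, 0.025), 2.4e-4)
  # decay toward rest from above
  ca <- 1e-3
  for (i in 1:200) ca <- update_calcium(ca, 0, 1)
  expect_lt(ca, 1e-3)
  expect_gt(ca, 2.4e-4)
  # constant inward current: steady state rest + k*|I|*tau
  ca <- 2.4e-4
  for (i in 1:40000) ca <- update_calcium(ca, -10, 0.025)
  expect_equal(ca, 2.4e-4 + 5.1819e-5 * 10 * 5, tolerance = 1e-6)
})

test_that("calcium reversal follows the Nernst relation", {
  expect_equal(nernst_eca(1, 1, 309.15), 0)
  # RT/F = 26 mV at T = 26e-3 * 96485.332 / 8.3145 K; ln(e^2)/2 * 26 = 26
  t26 <- 0.026 * 96485.33212 / 8.31446261815324
  expect_equal(nernst_eca(1, exp(2), t26), 26, tolerance = 1e-6)
  expect_equal(nernst_eca(2.4e-4, 2, 309), 120, tolerance = 0.5)
  expect_error(nernst_eca(0, 2), "positive")
})

test_that("gating step halving shows second-order-consistent trajectories", {
  # Richardson-style comparison for the regulated h-current update
  run <- function(dt, n) {
    s <- list(O = 0.1, OL = 0.05, P1 = 0.2)
    for (i in seq_len(n)) s <- ih_regulated_step(s, -80, 1e-3, dt)
    s
  }
  coarse <- run(0.1, 100)
  fine <- run(0.05, 200)
  finer <- run(0.025, 400)
  err1 <- abs(coarse$O - fine$O)
  err2 <- abs(fine$O - finer$O)
  expect_lt(err2, err1) # halving dt shrinks the increment
})

test_that("shipped channel parameter table matches the in-code constants", {
  tab <- channel_param_table()
  shipped <- read.delim(system.file("extdata", "channel_params.tsv",
                                    package = "somnotc"))
  expect_equal(tab, shipped, tolerance = 1e-12)
})
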