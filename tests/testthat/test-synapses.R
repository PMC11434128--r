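test_that("depression update matches its closed form and recovers fully", {
  expect_equal(depression_update(0.5, 1e9, 0.07, 700), 1)
  # pure recovery when U = 0, never below the previous value
  e <- 0.4
  expect_equal(depression_update(e, 350, 0, 700),
               1 - (1 - 0.4) * exp(-0.5))
  expect_gte(depression_update(e, 350, 0, 700), e)
  expect_equal(depression_update(1, 700, 0.07, 700), 1 - 0.07 * exp(-1))
  expect_equal(depression_update(1, 700, 0.07, 700), 0.97425, tolerance = 1e-4)
})

test_that("periodic spiking drives the resource to the analytic fixed point", {
  u <- 0.2; tau <- 700; isi <- 150
  e <- 1
  for (i in 1:200) e <- depression_update(e, isi, u, tau)
  estar <- (1 - exp(-isi / tau)) / (1 - (1 - u) * exp(-isi / tau))
  expect_equal(e, estar, tolerance = 1e-10)
  expect_true(e > 0 && e <= 1)
})

test_that("kinetic open fraction relaxes to alpha*T/(alpha*T + beta)", {
  expect_equal(kinetic_open_step(0, 0, 1.1, 0.19, 1), 0)
  o <- 0
  for (i in 1:5000) o <- kinetic_open_step(o, 0.5, 1, 0.1, 1)
  expect_equal(o, 0.5 / 0.6, tolerance = 1e-9)
  expect_equal(o, 0.833, tolerance = 1e-3)
  # stays in [0, 1] from any admissible start
  expect_lte(kinetic_open_step(1, 10, 5, 0.18, 10), 1)
  expect_error(kinetic_open_step(0.5, -1, 1, 0.1, 1), "T")
})

test_that("NMDA magnesium block is monotone with the stated anchor", {
  expect_equal(nmda_mg_block(0), 1 / (1 + 1 / 3.57))
  expect_equal(nmda_mg_block(0), 0.781, tolerance = 1e-3)
  expect_equal(nmda_mg_block(200), 1, tolerance = 1e-4)
  expect_lt(nmda_mg_block(-200), 1e-4)
  v <- seq(-90, 40, 1)
  expect_true(all(diff(nmda_mg_block(v)) > 0))
})

test_that("GABA-B second-messenger cascade reaches its fixed points", {
  s <- list(R = 0, G = 0)
  s0 <- gabab_step(s, 0, 1)
  expect_equal(unlist(s0), c(R = 0, G = 0))
  for (i in 1:80000) s <- gabab_step(s, 0.5, 1)
  rinf <- 0.52 * 0.5 / (0.52 * 0.5 + 0.0013)
  expect_equal(s$R, rinf, tolerance = 1e-6)
  expect_equal(s$R, 0.995, tolerance = 1e-3)
  ginf <- 0.098 * rinf / 0.033
  expect_equal(s$G, ginf, tolerance = 1e-4)
  act <- s$G^4 / (s$G^4 + 100)
  expect_equal(act, ginf^4 / (ginf^4 + 100), tolerance = 1e-4)
  expect_equal(act, 0.43, tolerance = 0.01)
})

test_that("transmitter pulses are rectangular and do not stack", {
  expect_equal(transmitter_pulse(numeric(0), 5), 0)
  expect_equal(transmitter_pulse(c(4.9), 5), 0.5)
  expect_equal(transmitter_pulse(c(4.9, 5.0), 5.1, 0.5, 0.3), 0.5)
  expect_equal(transmitter_pulse(c(4.0), 5), 0)
})

test_that("mini scheduler is deterministic, disableable, and slower right \
after a spike", {
  expect_identical(mini_next_time(1, 7, 0, 0, 0, 100), Inf)
  a <- mini_next_time(1, 7, 3, 100, 0.01, 100)
  b <- mini_next_time(1, 7, 3, 100, 0.01, 100)
  expect_identical(a, b)
  expect_false(mini_next_time(1, 8, 3, 100, 0.01, 100) == a)
  # mean interval shortly after the reference exceeds the saturated mean
  n <- 10000
  iv <- vapply(seq_len(n), function(k)
    mini_next_time(1, 1, k, 0, 0.01, 100), 0)
  # saturated-regime mean is 1/rate; the rising hazard adds ~tau
  expect_gt(mean(iv), 1 / 0.01)
  expect_equal(mean(iv), 1 / 0.01 + 100, tolerance = 0.1 * 200)
})
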