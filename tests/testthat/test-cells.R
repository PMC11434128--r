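test_that("capacitive soma variant rescales every axosomatic conductance \
by exactly 3/4", {
  cfg <- default_config()
  for (type in c("py", "inh")) {
    p <- effective_cell_params(cfg, type)
    expect_equal(p$soma_rescale, 0.75)
    expect_equal(p$soma_effective, 0.75 * p$soma_legacy)
  }
  legacy <- cfg
  legacy$soma_variant <- "legacy_algebraic"
  p <- effective_cell_params(validate_config(legacy), "py")
  expect_equal(p$soma_effective, p$soma_legacy)
})

test_that("cells are built with the right compartment count and gates at \
steady state", {
  tc <- build_cell("tc")
  expect_identical(tc$params$n_compartments, 1L)
  expect_false("v_dend" %in% names(tc$state))
  py <- build_cell("py")
  expect_identical(py$params$n_compartments, 2L)
  expect_equal(unname(py$state["v_soma"]), -68)
  # gating derivative zero at init: m equals its steady state at v_init
  r <- na_k_rates(-68, py$params$v_traub)
  expect_equal(unname(py$state["m_na_soma"]), r$am / (r$am + r$bm))
  k <- it_tc_kinetics(-68)
  expect_equal(unname(tc$state["m_t"]), k$m_inf)
  expect_equal(unname(tc$state["ca"]), 2.4e-4)
})

test_that("membrane derivatives satisfy symmetry and charge bookkeeping", {
  g_s <- c(na = 0.5, k = 2); e_s <- c(50, -90)
  g_d <- c(leak = 0.033, kl = 0.002); e_d <- c(-68, -90)
  # equal compartment voltages: axial current vanishes
  d <- membrane_derivatives(-60, -60, g_s, e_s, g_d, e_d, cm = 0.75,
                            g_axial = 0.1, area_soma = 1e-6,
                            area_dend = 1.65e-4)
  d0 <- membrane_derivatives(-60, -60, g_s, e_s, g_d, e_d, cm = 0.75,
                             g_axial = 0, area_soma = 1e-6,
                             area_dend = 1.65e-4)
  expect_equal(d$dv_soma, d0$dv_soma)
  expect_equal(d$dv_dend, d0$dv_dend)
  # all conductances zero: resting derivative zero
  z <- membrane_derivatives(-60, -60, numeric(0), numeric(0), numeric(0),
                            numeric(0), 0.75, 0.1, 1e-6, 1.65e-4)
  expect_equal(z$dv_soma, 0)
  expect_equal(z$dv_dend, 0)
  # area-weighted capacitive currents equal total membrane current;
  # the axial term cancels between compartments
  set.seed(1)
  for (i in 1:20) {
    vs <- runif(1, -90, 0); vd <- runif(1, -90, 0)
    d <- membrane_derivatives(vs, vd, g_s, e_s, g_d, e_d, 0.75, 0.1,
                              1e-6, 1.65e-4, i_syn_dend = runif(1, -5, 5))
    lhs <- 1e-6 * 0.75 * d$dv_soma + 1.65e-4 * 0.75 * d$dv_dend
    rhs <- -(d$i_mem_soma + d$i_mem_dend)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("spike detector implements threshold crossing with refractoriness", {
  expect_false(detect_spike(-60, -55, 10)$spike)
  s <- detect_spike(-5, 10, 10, last_spike = -Inf)
  expect_true(s$spike)
  expect_equal(s$time, 10)
  # second crossing 1 ms later inside a 2 ms refractory window: one spike
  expect_false(detect_spike(-5, 10, 11, last_spike = 10,
                            refractory = 2)$spike)
  expect_true(detect_spike(-5, 10, 12.5, last_spike = 10,
                           refractory = 2)$spike)
  # downward crossing never counts
  expect_false(detect_spike(10, -5, 10)$spike)
})

test_that("an isolated wake PY cell settles to a stable resting potential", {
  cfg <- quiet_single_cell_cfg("py", dur = 3000)
  r <- run_simulation(cfg)
  v <- r$traces[, 1]
  late <- v[r$sample_t > 2000]
  expect_lt(max(late) - min(late), 0.01)
  expect_true(all(late > -90 & late < -50))
})

test_that("raising the K-leak hyperpolarizes an isolated TC cell \
monotonically", {
  rest <- vapply(c(0.001, 0.005, 0.01, 0.02), function(g) {
    cfg <- quiet_single_cell_cfg("tc", dur = 3000)
    cfg$cells$tc$g_kl <- g
    cfg <- validate_config(cfg)
    r <- run_simulation(cfg)
    median(r$traces[r$sample_t > 2500, 1])
  }, 0)
  expect_true(all(diff(rest) < 0))
})

test_that("a hyperpolarized-and-released TC cell fires a rebound burst", {
  cfg <- make_fixture("single_tc_rebound")
  r <- run_simulation(cfg)
  release <- cfg$stimulus[[1]]$t_off_ms
  burst <- r$raster$t_ms[r$raster$t_ms > release &
                           r$raster$t_ms <= release + 50]
  expect_gte(length(burst), 2)
})
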