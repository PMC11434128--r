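test_that("wake reference levels leave every parameter unchanged", {
  cfg <- default_config()
  eff <- effective_params(cfg, list(ach = 1, ha = 1, gaba = 1))
  expect_equal(eff$g_kl[["tc"]], cfg$cells$tc$g_kl)
  expect_equal(eff$g_kl[["py"]], cfg$cells$py$dend$g_kl)
  expect_equal(eff$ampa_scale, 1)
  expect_equal(eff$gaba_scale, 1)
})

test_that("leak modulation follows the linear gain law", {
  expect_equal(modulated_gkl(0.01, list(ach = 0, ha = 1), kappa_ach = 2), 0.03)
  # clamped at zero when acetylcholine exceeds the reference
  expect_equal(modulated_gkl(0.01, list(ach = 2, ha = 1), kappa_ach = 2), 0)
  cfg <- default_config()
  eff <- effective_params(cfg, list(ach = 1, ha = 1, gaba = 1.3))
  expect_equal(eff$gaba_scale, 1.3)
})

test_that("effective parameters are pure and monotone in the modulators", {
  cfg <- default_config()
  lv <- list(ach = 0.4, ha = 0.6, gaba = 1.1)
  expect_identical(effective_params(cfg, lv), effective_params(cfg, lv))
  achs <- seq(0, 1, 0.1)
  g <- vapply(achs, function(a)
    effective_params(cfg, list(ach = a, ha = 1, gaba = 1))$g_kl[["tc"]], 0)
  expect_true(all(diff(g) <= 0)) # non-increasing in ach
  has <- seq(0, 1, 0.1)
  g <- vapply(has, function(h)
    effective_params(cfg, list(ach = 1, ha = h, gaba = 1))$g_kl[["tc"]], 0)
  expect_true(all(diff(g) <= 0))
  # histamine does not touch cortical leak
  g <- vapply(has, function(h)
    effective_params(cfg, list(ach = 1, ha = h, gaba = 1))$g_kl[["py"]], 0)
  expect_true(all(diff(g) == 0))
})
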