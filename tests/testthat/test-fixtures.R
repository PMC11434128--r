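test_that("fixtures are structurally correct and validate", {
  f <- make_fixture("single_tc_rebound")
  expect_identical(sum(unlist(f$populations)), 1L)
  expect_identical(f$populations$tc, 1L)

  f <- make_fixture("re_tc_spindle_pair")
  expect_gt(f$populations$tc, 0)
  expect_gt(f$populations$re, 0)
  expect_identical(f$populations$py, 0L)

  f <- make_fixture("cortical_slab_n3")
  expect_identical(f$populations$tc, 0L)
  expect_identical(f$schedule$stages[[1]]$stage, "n3")
  expect_gt(f$connectivity$py_py$u_depression, 0)

  f <- make_fixture("full_reduced_cycle")
  labs <- vapply(f$schedule$stages, function(s) s$stage, "")
  expect_identical(labs, c("wake", "n2", "n3", "rem", "n2"))
  expect_identical(f$populations$py, 50L)

  f1 <- make_fixture("full_reduced_cycle", scale = 1)
  expect_identical(unlist(f1$populations),
                   unlist(default_config()$populations))
  expect_equal(f1$integration$duration_ms, 360000)

  expect_error(make_fixture("nope"), "arg")
  expect_error(make_fixture("cortical_slab_n3", scale = 2), "scale")
})

test_that("every fixture runs to completion at the default step", {
  for (sc in c("single_tc_rebound", "re_tc_spindle_pair",
               "cortical_slab_n3", "full_reduced_cycle")) {
    f <- make_fixture(sc)
    r <- run_simulation(f, duration = 300)
    expect_s3_class(r, "somnotc_run")
    expect_true(all(r$raster$t_ms >= 0 & r$raster$t_ms <= 300))
  }
})
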