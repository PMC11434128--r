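test_that("projection fan-out follows the index-mapping rule", {
  e <- build_projection(10, 10, 1, allow_self = FALSE)
  expect_identical(sort(e$post[e$pre == 5]), c(4L, 6L))
  e <- build_projection(10, 10, 0, allow_self = TRUE)
  expect_identical(e$pre, e$post) # identity mapping
  e <- build_projection(100, 500, 2)
  expect_identical(sort(e$post[e$pre == 10]), 48:52)
  # clipping at the boundary, no wraparound
  e <- build_projection(10, 10, 3, allow_self = TRUE)
  expect_identical(sort(e$post[e$pre == 0]), 0:3)
  expect_identical(sort(e$post[e$pre == 9]), 6:9)
})

test_that("edge counts match a brute-force enumeration oracle", {
  oracle <- function(n_pre, n_post, radius, allow_self) {
    cnt <- 0
    for (i in seq_len(n_pre) - 1)
      for (j in seq_len(n_post) - 1)
        if (abs(j - round(i * n_post / n_pre)) <= radius &&
            (allow_self || i != j)) cnt <- cnt + 1
    cnt
  }
  cases <- list(c(10, 10, 1), c(7, 20, 3), c(20, 7, 2), c(13, 13, 4))
  for (cs in cases) for (as_ in c(TRUE, FALSE)) {
    e <- build_projection(cs[1], cs[2], cs[3], allow_self = as_)
    expect_equal(nrow(e), oracle(cs[1], cs[2], cs[3], as_))
  }
})

test_that("default network instantiates the configured populations and \
projection set", {
  cfg <- default_config()
  net <- build_network(cfg)
  expect_identical(net$populations$py, 500L)
  expect_identical(net$populations$inh, 100L)
  expect_identical(net$populations$tc, 100L)
  expect_identical(net$populations$re, 100L)
  expect_setequal(names(net$projections),
                  c("py_py", "py_inh", "inh_py", "py_tc", "py_re", "tc_py",
                    "tc_inh", "tc_re", "re_tc", "re_re"))
  # no dangling indices; in-degree bounded by 2r + 1
  for (pr in net$projections) {
    n_pre <- net$populations[[pr$source]]
    n_post <- net$populations[[pr$target]]
    expect_true(all(pr$edges$pre >= 0 & pr$edges$pre < n_pre))
    expect_true(all(pr$edges$post >= 0 & pr$edges$post < n_post))
    indeg <- tabulate(pr$edges$post + 1L, n_post)
    # a target collects (2r+1) sources per mapped pre index; converging
    # projections (n_pre > n_post) map ceiling(n_pre/n_post) pres per index
    expect_lte(max(indeg),
               (2 * pr$spec$radius + 1) * ceiling(n_pre / n_post))
    # no duplicate edges
    expect_false(any(duplicated(pr$edges)))
  }
  # every population participates in at least one projection
  pops <- unique(unlist(lapply(net$projections, function(p)
    c(p$source, p$target))))
  expect_setequal(pops, c("py", "inh", "tc", "re"))
})

test_that("network construction is deterministic and weights are \
in-degree normalized", {
  cfg <- make_fixture("full_reduced_cycle")
  a <- build_network(cfg)
  b <- build_network(cfg)
  expect_identical(a, b)
  pr <- a$projections$py_py
  tot <- tapply(pr$w_ampa, pr$edges$post, sum)
  expect_true(all(abs(tot - cfg$connectivity$py_py$g_ampa) < 1e-12))
})

test_that("reduced config yields non-empty projections and an edge export", {
  cfg <- make_fixture("full_reduced_cycle")
  net <- build_network(cfg)
  expect_true(all(vapply(net$projections, function(p) nrow(p$edges), 0) > 0))
  tab <- export_edges(net)
  expect_true(all(c("projection", "pre", "post", "receptor", "weight")
                  %in% names(tab)))
  expect_true(all(tab$weight > 0))
})
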