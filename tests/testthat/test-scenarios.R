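test_that("baseline tables carry one summary per reference scenario", {
  tb <- baseline_table("biased")
  expect_s3_class(tb, "goldrush_table")
  expect_equal(nrow(tb), 4)
  expect_equal(tb$f_p, c(0.05, 0.05, 0.20, 0.20))
  expect_equal(tb$t_d, c(0, 1, 0, 2))
  expect_true(all(tb$regime == "self_correcting"))
  # rows are plain model summaries
  s <- summary(baseline_model(0.20, 2))
  expect_equal(tb$t_c[4], s$t_c)
  expect_equal(tb$waste_ratio[4], s$waste_ratio)

  t3 <- baseline_table("no_bias")
  expect_equal(t3$f_p, c(0.05, 0.05, 0.50, 0.50))
  expect_true(all(t3$regime == "self_correcting"))
})

test_that("sweeps reproduce the baseline cells at matching grid points", {
  sg <- sweep_grid("f_p", "t_d",
                   values1 = c(0.05, 0.20, 0.25), values2 = c(0, 1, 2))
  tb <- baseline_table("biased")
  expect_equal(sg$t_c[1, 1], tb$t_c[1])   # f_p = 0.05, t_d = 0
  expect_equal(sg$r_w[1, 2], tb$r_w[2])   # f_p = 0.05, t_d = 1
  expect_equal(sg$c_e[2, 1], tb$c_e[3])   # f_p = 0.20, t_d = 0
  expect_equal(sg$waste_ratio[2, 3], tb$waste_ratio[4])
  # a 25% false positive rate is never correctable at these constants
  expect_true(all(sg$mask[3, ]))
  expect_true(all(is.na(sg$t_c[3, ])))
})

test_that("masked area grows with the false positive rate", {
  sg <- sweep_grid("f_p", "t_d", c(0.01, 0.40), c(0, 3), n = c(25, 7))
  masked_per_fp <- rowSums(sg$mask)
  expect_true(all(diff(masked_per_fp) >= 0))
  expect_gt(sum(sg$mask), 0)
})

test_that("the s_r x k sweep is masked exactly where the discriminant is negative", {
  sg <- sweep_grid("s_r", "k", c(0.05, 1), c(0.05, 1), n = 11,
                   fixed = list(f_p = 0.10, t_d = 1))
  # discriminant computed from first principles for each cell
  g <- 3 * 0.95 * 0.10
  for (i in seq_along(sg$axis1$values)) {
    for (j in seq_along(sg$axis2$values)) {
      e <- 3 * (1 - 0.95) * (1 - 0.10) * sg$axis1$values[i]
      d <- sg$axis2$values[j] * 3
      expect_equal(sg$mask[i, j], 4 * d * e - g^2 <= 0)
    }
  }
  expect_gt(sum(sg$mask), 0)          # the white region exists
  expect_lt(sum(sg$mask), length(sg$mask))
})

test_that("sweep rejects bad axis specifications", {
  expect_error(sweep_grid("f_p", "f_p", c(0, 1), c(0, 1)), "distinct")
  expect_error(sweep_grid("foo", "t_d", c(0, 1), c(0, 1)), "unknown")
  expect_error(sweep_grid("f_p", "t_d", c(0, 1), c(0, 1),
                          fixed = list(f_p = 0.1)), "fixed")
})

test_that("sweep long format mirrors the grid", {
  sg <- sweep_grid("f_p", "t_d", c(0.01, 0.25), c(0, 2), n = c(6, 5))
  df <- as.data.frame(sg)
  expect_equal(nrow(df), 30)
  expect_named(df, c("axis1_name", "axis1_value", "axis2_name", "axis2_value",
                     "regime", "t_c", "r_w", "c_e", "waste_ratio",
                     "log10_r_w"))
  expect_equal(sum(df$regime == "non_correcting"), sum(sg$mask))
  expect_true(all(is.finite(df$log10_r_w[df$regime == "self_correcting"])))
})

test_that("trajectory panels cover the correction episode", {
  m <- goldrush(f_p = 0.05, t_d = 0)
  tr <- trajectory_panel(m)
  tc <- correction_time(m)
  expect_equal(max(tr$time), 1.2 * tc)
  expect_true(all(diff(tr$time) > 0))
  # x rises above its initial level, then is back to ~0 by t_c (~5 years)
  expect_gt(max(tr$x), 1)
  expect_lt(min(abs(tr$x[tr$time < tc + 0.1])), 0.05)
  expect_equal(tr$x[1], 1)

  md <- goldrush(f_p = 0.05, t_d = 1)
  trd <- trajectory_panel(md)
  expect_true(all(trd$y[trd$time <= 1] == 0))

  # non-correcting panel: default 50-year horizon, x strictly increasing
  bad <- trajectory_panel(goldrush(f_p = 0.25), n = 301)
  expect_equal(max(bad$time), 50)
  expect_true(all(diff(bad$x) > 0))
  expect_true(all(diff(bad$y[bad$time > 0]) > 0))
})

test_that("predict evaluates closed forms on arbitrary grids", {
  m <- goldrush(f_p = 0.05, t_d = 1)
  pr <- predict(m, times = c(0, 0.5, 2, 4))
  expect_equal(pr$x, spurious_level(m, c(0, 0.5, 2, 4)))
  expect_equal(pr$y[1:2], c(0, 0))
  expect_error(predict(m, times = c(1, 1)), "increasing")
})
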