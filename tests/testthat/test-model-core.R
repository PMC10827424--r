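test_that("rate constants follow the biased and no-bias mappings", {
  m <- goldrush(f_p = 0.05, p_r = 3, B = 0.95, s_r = 0.5, k = 0.6)
  expect_equal(coef(m), c(g = 0.1425, e = 0.07125, d = 1.8))

  nb <- goldrush(f_p = 0.05, p_r = 3, bias_mode = "no_bias")
  expect_equal(coef(nb), c(g = 0.15, e = 2.85, d = 3))
  # B plays no role in the no-bias mapping
  expect_equal(coef(goldrush(f_p = 0.05, B = 0.2, bias_mode = "no_bias")),
               coef(nb))

  expect_equal(unname(coef(goldrush(f_p = 0))["g"]), 0)

  r <- rate_constants(m)
  expect_equal(r$discriminant, 4 * r$d * r$e - r$g^2)
  expect_equal(r$h^2 + r$g^2, 4 * r$d * r$e)
})

test_that("parameter validation names the offending field", {
  expect_error(goldrush(f_p = 1.2), "f_p")
  expect_error(goldrush(f_p = 0.1, p_r = 0), "p_r")
  expect_error(goldrush(f_p = 0.1, t_d = -1), "t_d")
  expect_error(goldrush(f_p = 0.1, x_o = 0), "x_o")
  expect_error(goldrush(f_p = 0.1, s_r = 2), "s_r")
  expect_error(goldrush(f_p = 0.1, B = -0.1), "B")
  expect_error(goldrush(f_p = 0.1, k = -1), "k")
})

test_that("no-bias mode fixes the submitted fraction and corrective impact", {
  nb <- goldrush(f_p = 0.05, bias_mode = "no_bias")
  expect_equal(nb$params$s_r, 1)
  expect_equal(nb$params$k, 1)
  expect_error(goldrush(f_p = 0.05, k = 0.3, bias_mode = "no_bias"), "k")
  expect_error(goldrush(f_p = 0.05, s_r = 0.4, bias_mode = "no_bias"), "s_r")
  # explicitly passing the fixed value is not an error
  expect_silent(goldrush(f_p = 0.05, k = 1, s_r = 1, bias_mode = "no_bias"))
})

test_that("regime classification follows the sign of the discriminant", {
  expect_equal(regime(goldrush(f_p = 0.20)), "self_correcting")
  expect_true(rate_constants(goldrush(f_p = 0.20))$discriminant > 0)
  # at the baseline constants a 25% false positive rate is beyond repair
  expect_equal(regime(goldrush(f_p = 0.25)), "non_correcting")
  # no corrective emergence (everything in the file drawer) -> no correction
  expect_equal(regime(goldrush(f_p = 0.1, s_r = 0)), "non_correcting")
})

test_that("correction time: delay enters additively and g = 0 reduces to pi/h", {
  t0 <- correction_time(goldrush(f_p = 0.05, t_d = 0))
  t1 <- correction_time(goldrush(f_p = 0.05, t_d = 1))
  expect_equal(t1 - t0, 1)
  expect_true(is.na(correction_time(goldrush(f_p = 0.25))))

  m0 <- goldrush(f_p = 0)  # g = 0, still self-correcting
  expect_equal(regime(m0), "self_correcting")
  r <- rate_constants(m0)
  expect_equal(correction_time(m0), pi / (2 * sqrt(r$d * r$e)))
})

test_that("spurious level: initial condition, delay continuity, zero at t_c", {
  set.seed(42)
  for (m in random_ecosystems(20)) {
    r <- rate_constants(m)
    p <- m$params
    expect_equal(spurious_level(m, 0), p$x_o)
    # both branch formulas reduce to x_o exp(g t_d) at the switch
    expect_equal(spurious_level(m, p$t_d), p$x_o * exp(r$g * p$t_d),
                 tolerance = 1e-9)
    tc <- correction_time(m)
    expect_gt(tc, p$t_d)
    expect_lt(abs(spurious_level(m, tc)), 1e-8)
    # h identity to machine precision
    expect_equal(r$g^2 + r$h^2, 4 * r$d * r$e)
  }
  expect_error(spurious_level(goldrush(f_p = 0.05), -1), "t must be")
})

test_that("corrective level starts at zero, grows as e*x, and needs h real", {
  m <- goldrush(f_p = 0.20, t_d = 2)
  r <- rate_constants(m)
  expect_equal(corrective_level(m, c(0, 1, 2)), c(0, 0, 0))
  expect_gt(corrective_level(goldrush(f_p = 0.20), 1e-3), 0)

  # y' = e x along the trajectory (the corrective equation restated)
  tc <- correction_time(m)
  ts <- seq(m$params$t_d + 0.2, tc - 0.2, length.out = 9)
  eps <- 1e-6
  dy <- (corrective_level(m, ts + eps) - corrective_level(m, ts - eps)) /
    (2 * eps)
  expect_equal(dy, r$e * spurious_level(m, ts), tolerance = 1e-6)
  # strictly increasing before correction
  grid <- seq(m$params$t_d, tc, length.out = 200)
  expect_true(all(diff(corrective_level(m, grid)) > 0))

  expect_error(corrective_level(goldrush(f_p = 0.25), 1), "self-correcting")
})

test_that("closed-form trajectories satisfy the model equations", {
  for (f_p in c(0.05, 0.20)) {
    res <- residuals(goldrush(f_p = f_p, t_d = 1))
    expect_lt(max(abs(res$res_x)), 1e-5)
    expect_lt(max(abs(res$res_y)), 1e-5)
  }
  expect_error(residuals(goldrush(f_p = 0.25)), "self-correcting")
})

test_that("waste and effort integrals: limits, continuity and regime errors", {
  m <- goldrush(f_p = 0.20, t_d = 2)
  expect_equal(research_waste(m, 0), 0)
  expect_equal(corrective_effort(m, m$params$t_d), 0)
  # pre- and post-delay branches agree at the switch
  eps <- 1e-9
  expect_equal(research_waste(m, m$params$t_d - eps),
               research_waste(m, m$params$t_d + eps), tolerance = 1e-6)
  # g = 0 limit of the pre-delay integral is x_o * t
  m0 <- goldrush(f_p = 0, t_d = 2, x_o = 3)
  expect_equal(research_waste(m0, 1.5), 4.5)

  bad <- goldrush(f_p = 0.25, t_d = 2)
  expect_equal(research_waste(bad, 1), exp(bad$rates$g) / bad$rates$g -
                 1 / bad$rates$g)  # pre-delay still fine
  expect_error(research_waste(bad, 3), "self-correcting")
  expect_error(corrective_effort(bad, 1), "self-correcting")
})

test_that("summary composes the correction quantities", {
  s <- summary(goldrush(f_p = 0.05, t_d = 1))
  expect_equal(s$r_w, research_waste(goldrush(f_p = 0.05, t_d = 1), s$t_c))
  expect_equal(s$waste_ratio, s$r_w / (s$r_w + s$c_e))
  expect_true(s$waste_ratio > 0 && s$waste_ratio < 1)

  ns <- summary(goldrush(f_p = 0.1, s_r = 0))
  expect_equal(ns$regime, "non_correcting")
  expect_true(all(is.na(c(ns$t_c, ns$r_w, ns$c_e, ns$waste_ratio))))
})

test_that("the no-bias critical false positive rate is 2(sqrt(2) - 1)", {
  fc <- critical_fp_no_bias()
  expect_equal(round(fc, 3), 0.828)
  expect_equal(floor(100 * fc), 82)
  disc <- function(f) rate_constants(
    goldrush(f_p = f, bias_mode = "no_bias"))$discriminant
  expect_gt(disc(0.5), 0)
  expect_lt(disc(0.9), 0)
  # regime flips exactly across the root
  expect_gt(disc(fc - 1e-6), 0)
  expect_lt(disc(fc + 1e-6), 0)
})
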