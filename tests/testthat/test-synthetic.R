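test_that("saturation_at matches the Hill sigmoid", {
  expect_equal(saturation_at(10, 10, 2.8), 0.5)
  expect_equal(saturation_at(0, 13.8, 2.5), 0)
  expect_equal(saturation_at(20, 10, 2), 0.8)
  # strictly increasing in po2, strictly decreasing in p50
  po2 <- seq(0.5, 120, length.out = 60)
  for (n in c(1, 2.5, 3.8)) {
    expect_true(all(diff(saturation_at(po2, 20, n)) > 0))
    expect_true(all(diff(saturation_at(30, po2, n)) < 0))
  }
  expect_error(saturation_at(10, -1, 2))
})

test_that("forward model is the identity at the reference state", {
  for (p in list(eastern_blood_params(), coast_blood_params(), hb_params())) {
    expect_equal(p50_at_conditions(p, p$ref_conditions), 10^p$logp50_ref,
                 tolerance = 1e-12)
  }
})

test_that("temperature response follows the integrated van't Hoff form", {
  p <- eastern_blood_params() # dH_corr -8.3 => dH_app -20.8
  r <- p50_at_conditions(p, conditions(40, 7.36, pco2 = 38)) /
    p50_at_conditions(p, conditions(32, 7.36, pco2 = 38))
  expect_equal(r, exp((-20800 / 8.314) * (1 / 313.15 - 1 / 305.15)),
               tolerance = 1e-12)
  expect_equal(r, 1.233, tolerance = 1e-3)
})

test_that("pH response follows the Bohr slope", {
  p <- eastern_blood_params() # bohr_phi -0.78
  r <- p50_at_conditions(p, conditions(36, 7.76, pco2 = 38)) /
    p50_at_conditions(p, conditions(36, 7.36, pco2 = 38))
  expect_equal(r, 10^(-0.78 * 0.40), tolerance = 1e-12)
  expect_equal(round(r, 2), 0.49)
})

test_that("sign conventions: acid and heat both lower affinity", {
  p <- hb_params() # bohr_phi < 0, dH_app < 0
  ref <- p$ref_conditions
  lower_ph <- conditions(37, 6.9, chloride = 0.1)
  warmer <- conditions(40, 7.2, chloride = 0.1)
  expect_gt(p50_at_conditions(p, lower_ph), p50_at_conditions(p, ref))
  expect_gt(p50_at_conditions(p, warmer), p50_at_conditions(p, ref))
})

test_that("chloride term needs chloride on both sides or neither", {
  p <- hb_params() # ref has 0.1 M chloride
  expect_error(p50_at_conditions(p, conditions(37, 7.2, chloride = NA)),
               "chloride reference mismatch")
  expect_error(p50_at_conditions(p, conditions(37, 7.2, chloride = 0)),
               "chloride reference mismatch")
  # both stripped: term vanishes
  p0 <- allosteric_params(log10(14), 2.7, k_cl = 0.3,
                          ref_conditions = conditions(37, 7.2))
  expect_equal(p50_at_conditions(p0, conditions(37, 7.2)), 14)
  # log-log slope honoured
  p10x <- p50_at_conditions(p, conditions(37, 7.2, chloride = 1.0))
  expect_equal(log10(p10x) - log10(10), p$k_cl, tolerance = 1e-12)
})

test_that("DPG term is linear to the saturating ratio, flat beyond", {
  p <- hb_params(dpg_shift = 0.26)
  at_ratio <- function(r) {
    p50_at_conditions(p, conditions(37, 7.2, chloride = 0.1, dpg_ratio = r))
  }
  expect_equal(log10(at_ratio(25)) - log10(at_ratio(0)), 0.13,
               tolerance = 1e-12)
  expect_equal(at_ratio(50), at_ratio(200), tolerance = 1e-12)
  # identity also holds when the reference itself is DPG-loaded
  pref <- allosteric_params(
    log10(18.3), 2.8, dpg_shift = 0.26,
    ref_conditions = conditions(37, 7.2, chloride = 0.1, dpg_ratio = 60))
  expect_equal(p50_at_conditions(pref, pref$ref_conditions), 18.3,
               tolerance = 1e-12)
})

test_that("oec_simulate is deterministic given a seed and respects its contracts", {
  p <- coast_blood_params()
  c0 <- p$ref_conditions
  grid <- po2_grid_window(17.7, 2.84, 10)
  d1 <- oec_simulate(p, c0, grid, noise_sd = 0.01, seed = 11)
  d2 <- oec_simulate(p, c0, grid, noise_sd = 0.01, seed = 11)
  expect_identical(d1, d2)
  d3 <- oec_simulate(p, c0, grid, noise_sd = 0.01, seed = 12)
  expect_false(identical(d1$saturation, d3$saturation))
  # noise-free curve passes exactly through half saturation at p50
  d0 <- oec_simulate(p, c0, c(5, 17.7, 40))
  expect_equal(d0$saturation[2], 0.5)
  # saturations stay in [0, 1] even with clipping-level noise
  dn <- oec_simulate(p, c0, seq(1, 150, length.out = 30), noise_sd = 0.05,
                     seed = 3)
  expect_true(all(dn$saturation >= 0 & dn$saturation <= 1))
  # contracts
  expect_error(oec_simulate(p, c0, numeric(0)))
  expect_error(oec_simulate(p, c0, c(10, 10, 20)))
  expect_error(oec_simulate(p, c0, grid, noise_sd = 0.2, seed = 1))
  expect_error(oec_simulate(p, c0, grid, noise_sd = 0.01), "seed")
  # caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(oec_simulate(p, c0, grid, noise_sd = 0.01, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("blood_panel_simulate reproduces its specs and its seed", {
  specs <- data.frame(label = c("a", "b"), mean = c(0.45, 7.09),
                      sd = c(0, 0), n = c(4, 3))
  pan <- blood_panel_simulate(specs, seed = 1)
  expect_equal(pan$draws$value, rep(c(0.45, 7.09), c(4, 3)))
  expect_equal(pan$summary$mean, c(0.45, 7.09))
  specs$sd <- c(0.12, 0.35)
  expect_identical(blood_panel_simulate(specs, seed = 7),
                   blood_panel_simulate(specs, seed = 7))
  expect_error(blood_panel_simulate(specs), "seed")
  expect_error(blood_panel_simulate(transform(specs, sd = -1), seed = 1))
})

test_that("groups separated as in the reference DPG contrast are detected in nearly all seeds", {
  # Welch rejection across seeds for means 0.45 vs 7.09 with table-scale
  # spread (sd = se * sqrt(n))
  specs <- data.frame(label = c("eastern", "coast"), mean = c(0.45, 7.09),
                      sd = c(0.06 * 2, 0.20 * sqrt(3)), n = c(4, 3))
  reject <- vapply(1:200, function(s) {
    sm <- blood_panel_simulate(specs, seed = s)$summary
    welch_t(sm$mean[1], sm$se[1], sm$n[1],
            sm$mean[2], sm$se[2], sm$n[2])$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.99)
})

test_that("condition and parameter validation rejects out-of-range values", {
  expect_error(conditions(50, 7.4))
  expect_error(conditions(36, 5.0))
  expect_error(conditions(36, 7.4, chloride = -0.1))
  expect_error(conditions(36, 7.4, dpg_ratio = -1))
  expect_error(allosteric_params(Inf, 2.8, ref_conditions = conditions(36, 7.4)))
  expect_error(allosteric_params(1, 5, ref_conditions = conditions(36, 7.4)))
})
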