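test_that("hill_transform maps steps to Hill coordinates", {
  expect_equal(hill_transform(10, 0.5), tibble::tibble(x = 1, y = 0))
  h <- hill_transform(100, 0.8)
  expect_equal(h$x, 2)
  expect_equal(h$y, log10(4))
  expect_error(hill_transform(5, 1.0), "untransformable step")
  expect_error(hill_transform(5, 0), "untransformable step")
  expect_error(hill_transform(-1, 0.5), "untransformable step")
})

test_that("hill_fit recovers noise-free generator parameters to machine precision", {
  cases <- list(c(p50 = 13.8, n = 2.5), c(p50 = 28.8, n = 2.76),
                c(p50 = 5.1, n = 3.2), c(p50 = 17.7, n = 1))
  for (cs in cases) {
    for (steps in c(6, 10)) {
      grid <- po2_grid_window(cs[["p50"]], cs[["n"]], steps)
      y <- saturation_at(grid, cs[["p50"]], cs[["n"]])
      f <- hill_fit(tibble::tibble(po2_mmHg = grid, saturation = y))
      expect_equal(f$p50, cs[["p50"]], tolerance = 1e-9)
      expect_equal(f$n50, cs[["n"]], tolerance = 1e-9)
      expect_equal(f$r2, 1, tolerance = 1e-12)
    }
  }
})

test_that("hill_fit honours its window and minimum-point contracts", {
  grid <- po2_grid_window(10, 2.5, 3, span = c(0.35, 0.65))
  d <- tibble::tibble(po2_mmHg = grid, saturation = saturation_at(grid, 10, 2.5))
  expect_error(hill_fit(d), "insufficient steps in saturation window")
  # widening the window explicitly makes the same data fittable
  grid2 <- po2_grid_window(10, 2.5, 4, span = c(0.2, 0.8))
  d2 <- tibble::tibble(po2_mmHg = grid2,
                       saturation = saturation_at(grid2, 10, 2.5))
  expect_error(hill_fit(d2), "insufficient")
  f <- hill_fit(d2, window = c(0.15, 0.85))
  expect_equal(f$p50, 10, tolerance = 1e-9)
  # window bounds are inclusive: ties at exactly 0.30 / 0.70 count
  y <- seq(0.30, 0.70, length.out = 4)
  din <- tibble::tibble(po2_mmHg = 10 * (y / (1 - y))^(1 / 2), saturation = y)
  expect_equal(hill_fit(din)$n_points_used, 4L)
})

test_that("hill_fit is invariant to step order and consistent in its fields", {
  grid <- po2_grid_window(22.5, 2.76, 9)
  d <- tibble::tibble(po2_mmHg = grid,
                      saturation = saturation_at(grid, 22.5, 2.76))
  f1 <- hill_fit(d)
  f2 <- hill_fit(d[sample(nrow(d)), ])
  expect_equal(tidy(f1), tidy(f2))
  expect_equal(f1$slope, f1$n50)
  expect_equal(f1$p50, 10^(-f1$intercept / f1$slope))
})

test_that("p50 estimates are nearly unbiased at small saturation noise", {
  p <- eastern_blood_params()
  grid <- po2_grid_window(28.8, 2.76, 12)
  rel_err <- vapply(1:500, function(s) {
    f <- hill_fit(oec_simulate(p, p$ref_conditions, grid,
                               noise_sd = 0.005, seed = s))
    abs(f$p50 / 28.8 - 1)
  }, numeric(1))
  expect_lt(median(rel_err), 0.005)
})

test_that("window-dense noisy protocols recover both Hill parameters", {
  # 16 equilibration steps across the 30-70% window, saturation noise 0.01
  p <- eastern_blood_params()
  grid <- po2_grid_window(28.8, 2.76, 16, span = c(0.30, 0.70))
  res <- vapply(1:500, function(s) {
    f <- hill_fit(oec_simulate(p, p$ref_conditions, grid,
                               noise_sd = 0.01, seed = s))
    c(abs(f$p50 / 28.8 - 1), abs(f$n50 / 2.76 - 1))
  }, numeric(2))
  expect_gte(mean(res[1, ] <= 0.03), 0.95)
  expect_gte(mean(res[2, ] <= 0.05), 0.95)
})

test_that("construct_oec evaluates a fitted Hill model on a grid", {
  f <- structure(list(p50 = 17.7, n50 = 2.84), class = "hill_fit")
  out <- construct_oec(f, c(5, 17.7, 60))
  expect_equal(out$saturation[2], 0.5)
  expect_equal(out$saturation, saturation_at(c(5, 17.7, 60), 17.7, 2.84))
})

test_that("construct_oec interpolates exactly through measured points", {
  po2 <- c(5, 10, 20)
  pts <- tibble::tibble(po2_mmHg = po2,
                        saturation = saturation_at(po2, 10, 2))
  out <- construct_oec(pts, po2)
  expect_equal(out$saturation, pts$saturation, tolerance = 1e-12)
  expect_error(
    construct_oec(tibble::tibble(po2_mmHg = po2,
                                 saturation = c(0.5, 0.3, 0.8)), po2),
    "non-decreasing")
})

test_that("constructed curves are monotone and bounded for arbitrary inputs", {
  grid <- c(seq(0.5, 50, length.out = 80), seq(55, 190, by = 5))
  for (s in 1:20) {
    n_pts <- withr::with_seed(s, sample(3:9, 1))
    p50 <- withr::with_seed(s + 100, stats::runif(1, 5, 40))
    n <- withr::with_seed(s + 200, stats::runif(1, 1, 3.5))
    po2 <- po2_grid_window(p50, n, n_pts, span = c(0.05, 0.95))
    pts <- tibble::tibble(po2_mmHg = po2,
                          saturation = saturation_at(po2, p50, n))
    out <- construct_oec(pts, grid)
    expect_true(all(diff(out$saturation) >= -1e-12))
    expect_true(all(out$saturation >= 0 & out$saturation <= 1))
  }
})

test_that("whole-blood curves order by affinity across the full PO2 range", {
  # coast blood (higher affinity) lies above/left of eastern blood everywhere
  grid <- seq(1, 190, by = 1)
  coast <- construct_oec(
    hill_fit(noise_free_oec(coast_blood_params(),
                            coast_blood_params()$ref_conditions, 10)), grid)
  eastern <- construct_oec(
    hill_fit(noise_free_oec(eastern_blood_params(),
                            eastern_blood_params()$ref_conditions, 10)), grid)
  expect_true(all(coast$saturation > eastern$saturation))
})

test_that("hill_fit_all fits each labelled dataset independently", {
  d <- dplyr::bind_rows(
    noise_free_oec(coast_blood_params(),
                   coast_blood_params()$ref_conditions, 8) |>
      dplyr::mutate(label = "coast"),
    noise_free_oec(eastern_blood_params(),
                   eastern_blood_params()$ref_conditions, 8) |>
      dplyr::mutate(label = "eastern"))
  fits <- hill_fit_all(d)
  expect_equal(nrow(fits), 2L)
  expect_equal(fits$p50_mmHg[fits$label == "coast"], 17.7, tolerance = 1e-9)
  expect_equal(fits$p50_mmHg[fits$label == "eastern"], 28.8, tolerance = 1e-9)
})

test_that("plot methods return ggplot objects", {
  f <- hill_fit(noise_free_oec(coast_blood_params(),
                               coast_blood_params()$ref_conditions, 8))
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(plot_oec(construct_oec(f, 1:100)), "ggplot")
})
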