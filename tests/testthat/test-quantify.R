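test_that("the gate is vacuous when every pixel-block holds Ca", {
  stack <- generate_stack(tiny_truth(seed = 51, planes = 40, side = 12L,
                                     fov = 1.8, ca_rate = 10, radius = 2.6),
                          bin_planes = 5)
  roi <- full_roi(12L)
  g1 <- gated_ratio(stack, roi, 1, "23Na", gate_min_ca = 1)
  g0 <- gated_ratio(stack, roi, 1, "23Na", gate_min_ca = 0)
  # at ca_rate 10 every 5-plane pixel-block holds Ca (P(0) ~ e^-50), so
  # the gate admits everything and the gated ratio equals the plain ratio
  expect_identical(g1$gated_fraction, 1)
  expect_identical(g1$ratio, g0$ratio)
})

test_that("gated sums exclude exactly the listed Ca-free pixel-block", {
  # 3 pixels x 2 blocks (1 plane each); pixel 2 in block 1 has Ca = 0 and
  # Na = 7, which the gate must discard
  na <- array(c(4L, 7L, 1L,   2L, 3L, 5L), dim = c(1, 3, 2))
  ca <- array(c(9L, 0L, 6L,   8L, 4L, 7L), dim = c(1, 3, 2))
  stack <- ion_image_stack(list("23Na" = na, "44Ca" = ca), fov_um = 1)
  g <- gated_ratio(stack, full_roi(1L, 3L), 1, "23Na",
                   block_size_planes = 1, gate_min_ca = 1)
  expect_equal(g$n_el, (4 + 1) + (2 + 3 + 5))
  expect_equal(g$n_ca, (9 + 6) + (8 + 4 + 7))
  expect_equal(g$ratio, 15 / 34)
  expect_equal(g$gated_fraction, 5 / 6)
  # without the gate the stray 7 biases the ratio upwards
  u <- gated_ratio(stack, full_roi(1L, 3L), 1, "23Na",
                   block_size_planes = 1, gate_min_ca = 0)
  expect_equal(u$ratio, 22 / 34)
})

test_that("gated_ratio errors when nothing passes the gate", {
  stack <- ion_image_stack(list("23Na" = array(5L, c(2, 2, 4)),
                                "44Ca" = array(0L, c(2, 2, 4))), fov_um = 1)
  expect_error(gated_ratio(stack, full_roi(2L), 1, "23Na",
                           block_size_planes = 1), "Ca gate")
})

test_that("dimer correction follows its closed form and floors at zero", {
  expect_identical(dimer_correct(90, 1000, 0), 90)
  expect_equal(dimer_correct(90, 1000, 0.005), 85)
  # on ratios: R_corr = R_raw - delta
  expect_equal(dimer_correct(0.090 * 5e4, 5e4, 0.005) / 5e4, 0.085)
  expect_warning(out <- dimer_correct(5, 1000, 0.01), "floored")
  expect_identical(out, 0)
  expect_error(dimer_correct(5, 10, -0.1), "delta")
})

test_that("the dimer yield is recoverable from an Sr-free region", {
  truth <- tiny_truth(seed = 53, planes = 300, side = 24L, fov = 3.6,
                      masses = c("44Ca", "88Sr"), ratios = c("88Sr" = 0),
                      dimer_delta = 0.01)
  stack <- generate_stack(truth, bin_planes = 5)
  mask <- phantom_mask(truth, "liths", 1)
  est <- estimate_delta(stack, mask)
  n_ca <- sum(accumulate(stack)[["44Ca"]][mask])
  expect_lt(abs(est - 0.01), 3 * sqrt(0.01 / n_ca))
})

test_that("calibration is proportional, invertible, and absent for K", {
  cal <- default_calibration()
  expect_setequal(cal$element, c("23Na", "24Mg", "88Sr", "138Ba"))
  expect_identical(calibrate(0, 0.05, cal, "23Na")$molar_ratio, 0)
  # round trip
  r <- 0.4321
  m <- calibrate(r, 0.05, cal, "24Mg")$molar_ratio
  expect_equal(m / cal$slope[cal$element == "24Mg"], r, tolerance = 1e-12)
  # no potassium slope -> no molar output
  k <- calibrate(0.3, 0.05, cal, "39K")
  expect_true(is.na(k$molar_ratio) && is.na(k$molar_uncertainty))
  # uncertainty combines precision and calibration accuracy in quadrature
  out <- calibrate(1, 0.1, cal, "23Na")
  expect_equal(out$molar_uncertainty,
               out$molar_ratio * sqrt(0.1^2 + 0.20^2), tolerance = 1e-12)
})

test_that("the fitted Na slope reproduces the printed reference conversion", {
  cal <- default_calibration()
  m <- calibrate(0.437, 0, cal, "23Na")$molar_ratio
  expect_lt(abs(m - 11.14) / 11.14, 0.01)
})

test_that("calibration JSON round-trips through files", {
  cal <- default_calibration()
  path <- file.path(withr::local_tempdir(), "calib.json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cal$slope, tolerance = 1e-12)
  expect_equal(back$rel_uncertainty, cal$rel_uncertainty)
  expect_error(read_calibration("no/such/file.json"), "does not exist")
})

test_that("ratio estimates are scale-consistent in rates and planes", {
  # halving rates while doubling planes leaves expected R unchanged
  est <- function(ca_rate, planes, seeds) {
    vapply(seeds, function(s) {
      truth <- tiny_truth(seed = s, planes = planes, side = 24L, fov = 3.6,
                          ca_rate = ca_rate, masses = c("23Na", "44Ca"),
                          ratios = c("23Na" = 0.4))
      stack <- generate_stack(truth, bin_planes = planes %/% 20)
      roi <- roi_map(matrix(as.integer(phantom_mask(truth, "liths", 1)),
                            24, 24), c("1" = "coccolith"))
      gated_ratio(stack, roi, 1, "23Na",
                  block_size_planes = planes %/% 4)$ratio
    }, 1)
  }
  r1 <- est(4, 100, 1:6)
  r2 <- est(2, 200, 7:12)
  pooled_se <- sqrt(var(r1) / 6 + var(r2) / 6)
  expect_lt(abs(mean(r1) - mean(r2)), 4 * pooled_se + 1e-4)
})

test_that("quantify_lith assembles ratios, precision and flags per element", {
  run <- clean_run()
  cfg <- pipeline_config(delta = run$truth$dimer_delta)
  lab <- roi_labels(run$roi)[1]
  res <- quantify_lith(run$stack, run$roi, lab, cfg)
  expect_setequal(res$element, c("23Na", "24Mg", "39K", "88Sr", "138Ba"))
  expect_true(all(res$ion_ratio > 0))
  expect_true(all(res$precision_cv >= 0))
  expect_true(all(res$gated_fraction > 0.99))       # high-rate clean lith
  expect_false(any(res$flag_low_precision))
  # molar output present iff a slope exists (K has none)
  expect_true(is.na(res$molar_ratio[res$element == "39K"]))
  expect_true(all(!is.na(res$molar_ratio[res$element != "39K"])))
})

test_that("a weak Ba signal trips the low-precision flag", {
  truth <- tiny_truth(seed = 54, planes = 50, side = 16L, fov = 2.4,
                      masses = c("44Ca", "138Ba"),
                      ratios = c("138Ba" = 5e-4))
  stack <- generate_stack(truth, bin_planes = 5)
  roi <- roi_map(matrix(as.integer(phantom_mask(truth, "liths", 1)), 16, 16),
                 c("1" = "coccolith"))
  res <- quantify_lith(stack, roi, 1, pipeline_config(delta = 0))
  ba <- res[res$element == "138Ba", ]
  expect_gt(ba$poisson_cv, 0.25)
  expect_true(ba$flag_low_precision)
})
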