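test_that("a constant-rate phantom yields the arithmetic block count", {
  stack <- generate_stack(tiny_truth(seed = 41, planes = 1000, side = 16L,
                                     fov = 2.4, masses = c("23Na", "44Ca"),
                                     ratios = c("23Na" = 0.4)),
                          bin_planes = 5)
  roi <- full_roi(16L)
  prof <- build_profile(stack, roi, 1, "23Na", block_size_planes = 5)
  expect_identical(nrow(prof) + attr(prof, "dropped_blocks"), 200L)
  expect_identical(prof$plane_end - prof$plane_start + 1L,
                   rep(5L, nrow(prof)))
})

test_that("profile ratios of a hand-built two-block fixture equal hand division", {
  # 2 pixels x 2 blocks of 1 plane each; counts listed literally
  na <- array(c(3L, 7L, 2L, 0L), dim = c(1, 2, 2))
  ca <- array(c(10L, 5L, 4L, 6L), dim = c(1, 2, 2))
  stack <- ion_image_stack(list("23Na" = na, "44Ca" = ca), fov_um = 1)
  prof <- build_profile(stack, full_roi(1L, 2L), 1, "23Na",
                        block_size_planes = 1, gate_min_ca = 0)
  expect_equal(prof$n_el, c(3 + 7, 2 + 0))
  expect_equal(prof$n_ca, c(10 + 5, 4 + 6))
  expect_equal(prof$ratio, c(10 / 15, 2 / 10))
})

test_that("profiles reject the reference mass and empty ROIs", {
  stack <- generate_stack(tiny_truth(seed = 42, planes = 20, side = 8L))
  expect_error(build_profile(stack, full_roi(8L), 1, "44Ca"),
               "trace element")
  zca <- ion_image_stack(list("23Na" = array(1L, c(4, 4, 10)),
                              "44Ca" = array(0L, c(4, 4, 10))), fov_um = 1)
  expect_error(build_profile(zca, full_roi(4L), 1, "23Na", gate_min_ca = 0),
               "no 44Ca counts")
})

test_that("poisson_cv matches its closed form and scaling law", {
  prof <- make_profile(rep(100, 50), rep(10000, 50))
  expect_equal(poisson_cv(prof), sqrt(0.01 + 1e-4), tolerance = 1e-12)
  doubled <- make_profile(rep(200, 50), rep(20000, 50))
  expect_equal(poisson_cv(doubled), poisson_cv(prof) / sqrt(2),
               tolerance = 1e-12)
  expect_error(poisson_cv(make_profile(5, 50)), "2 retained blocks")
})

test_that("mean observed CV of stationary Poisson profiles matches CV_P", {
  set.seed(4242)
  B <- 200
  cvp <- sqrt(1 / 50 + 1 / 500)
  cvs <- replicate(400, {
    r <- rpois(B, 50) / rpois(B, 500)
    sd(r) / mean(r)
  })
  expect_lt(abs(mean(cvs) / cvp - 1), 0.02)
})

test_that("the Poisson correction floors at zero and is unbiased in quadrature", {
  # identical ratios: cv_obs = 0 < CV_P -> corrected exactly 0
  flat <- make_profile(rep(80, 30), rep(1000, 30))
  qc <- corrected_cv(flat)
  expect_identical(qc$cv_corrected, 0)
  expect_false(qc$flag_unstable)

  # stationary counts at clean-coccolith scale: corrected CV stays < 3%
  # in >= 95% of seeds, and cv_obs^2 - CV_P^2 is centred on zero
  set.seed(77)
  res <- t(replicate(500, {
    prof <- make_profile(rpois(200, 3700), rpois(200, 9200))
    qc <- corrected_cv(prof)
    c(qc$cv_corrected, qc$cv_obs^2 - qc$cv_poisson^2)
  }))
  expect_gte(mean(res[, 1] < 0.03), 0.95)
  excess <- res[, 2]
  expect_lt(abs(mean(excess)), 3 * sd(excess) / sqrt(length(excess)))
})

test_that("yield drift is detected as residual CV above 5%", {
  # profile-level emulation of the drifty scenario: element yield decays by
  # a 0.3 amplitude with 150-plane half-life over 500 planes, Ca stable
  set.seed(88)
  p_mid <- (seq_len(100) - 0.5) * 5
  drift <- 1 + 0.3 * 2^(-p_mid / 150)
  hits <- replicate(200, {
    prof <- make_profile(rpois(100, 3700 * drift), rpois(100, 9200))
    corrected_cv(prof)$cv_corrected > 0.05
  })
  expect_gte(mean(hits), 0.95)

  # stack-level spot check on the registered scenario
  truth <- default_scenario("drifty", seed = 99)
  stack <- generate_stack(truth, bin_planes = 5)
  roi <- segment(accumulate(stack))
  prof <- build_profile(stack, roi, roi_labels(roi)[1], "23Na")
  expect_gt(corrected_cv(prof)$cv_corrected, 0.05)
})

test_that("the corrected CV is order-free though window selection is not", {
  set.seed(5)
  prof <- make_profile(rpois(60, 500), rpois(60, 5000))
  shuffled <- prof[sample(nrow(prof)), ]
  class(shuffled) <- class(prof)
  attr(shuffled, "roi_label") <- 1L; attr(shuffled, "element") <- "23Na"
  expect_equal(corrected_cv(shuffled)$cv_corrected,
               corrected_cv(prof)$cv_corrected, tolerance = 1e-12)
})

test_that("a stationary profile keeps all blocks in the stable window", {
  set.seed(6)
  prof <- make_profile(rpois(100, 4000), rpois(100, 10000))
  sw <- select_stable_window(prof)
  expect_identical(c(sw$qc$window_start, sw$qc$window_end), c(1L, 100L))
  expect_identical(sw$qc$excluded_fraction, 0)
})

test_that("equal-CV candidate windows break ties towards higher Ca counts", {
  # blocks 1-4 and 7-10 are perfectly flat with identical ratios; blocks
  # 5-6 spike; the first window carries twice the Ca counts
  n_ca <- c(rep(20000, 4), 1000, 1000, rep(10000, 4))
  n_el <- c(rep(8000, 4), 3000, 3000, rep(4000, 4))
  prof <- make_profile(n_el, n_ca)
  sw <- select_stable_window(prof, cv_target = 0.02, min_fraction = 0.4)
  expect_identical(c(sw$qc$window_start, sw$qc$window_end), c(1L, 4L))
})

test_that("surface-contaminated early planes are excluded by the window rule", {
  truth <- default_scenario("salt_speckled", seed = 1)
  film_blocks <- unique(ceiling(contaminated_planes(truth, "23Na",
                                                    contaminants = 3) / 5))
  hits <- vapply(1:12, function(s) {
    tr <- default_scenario("salt_speckled", seed = 3000 + s)
    stack <- generate_stack(tr, bin_planes = 5)
    roi <- segment(accumulate(stack))
    prof <- build_profile(stack, roi, roi_labels(roi)[1], "23Na")
    sw <- select_stable_window(prof)
    excluded <- setdiff(prof$block, sw$qc$window_start:sw$qc$window_end)
    mean(film_blocks %in% excluded)
  }, 1)
  expect_true(all(hits >= 0.8))
})
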