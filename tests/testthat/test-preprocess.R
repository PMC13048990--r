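test_that("an unshifted stack aligns with all-zero offsets and no crop", {
  stack <- generate_stack(tiny_truth(seed = 31, planes = 50), bin_planes = 5)
  al <- align_stack(stack, max_shift_px = 2, block_size_planes = 25)
  expect_true(all(al$trace$dy == 0) && all(al$trace$dx == 0))
  expect_identical(stack_dim(al$stack), stack_dim(stack))
  expect_identical(al$stack$counts, stack$counts)
})

test_that("known injected per-block integer shifts are recovered exactly", {
  truth <- tiny_truth(seed = 32, planes = 60, side = 40L, fov = 6,
                      ca_rate = 4)
  stack <- generate_stack(truth, bin_planes = 5)      # 12 pages
  injected <- rbind(c(0, 0), c(2, -1), c(-2, 2), c(1, 1))  # 4 blocks x 3 pages
  shifted <- stack$counts
  for (m in names(shifted)) {
    for (b in 1:4) for (g in ((b - 1) * 3 + 1):(b * 3)) {
      shifted[[m]][, , g] <-
        coccosims:::shift_image(shifted[[m]][, , g],
                                injected[b, 1], injected[b, 2])
    }
  }
  sstack <- ion_image_stack(shifted, fov_um = truth$fov_um,
                            planes_per_page = 5)
  al <- align_stack(sstack, max_shift_px = 2, block_size_planes = 15)
  expect_equal(cbind(al$trace$dy, al$trace$dx),
               cbind(-injected[, 1], -injected[, 2]), ignore_attr = TRUE)
  # undoing the shifts restores the original stack inside the common crop,
  # so in particular the 44Ca counts there are conserved exactly
  applied <- -injected
  d <- stack_dim(stack)
  r <- (1 + max(0, max(applied[, 1]))):(d[1] + min(0, min(applied[, 1])))
  cc <- (1 + max(0, max(applied[, 2]))):(d[2] + min(0, min(applied[, 2])))
  for (m in names(shifted)) {
    expect_identical(al$stack$counts[[m]],
                     stack$counts[[m]][r, cc, , drop = FALSE])
  }
})

test_that("alignment refuses an all-zero Ca channel and hints the bypass", {
  z <- array(0L, dim = c(8, 8, 10))
  stack <- ion_image_stack(list("23Na" = z + 1L, "44Ca" = z), fov_um = 1)
  expect_error(align_stack(stack), "max_shift_px = 0")
})

test_that("accumulation is additive over disjoint plane ranges", {
  stack <- generate_stack(tiny_truth(seed = 33, planes = 40), bin_planes = 5)
  full <- accumulate(stack)
  first <- accumulate(stack, c(1, 20))
  second <- accumulate(stack, c(21, 40))
  for (m in names(full)) {
    expect_identical(first[[m]] + second[[m]], full[[m]])
  }
  # single-page range reproduces that page
  one <- accumulate(stack, c(6, 10))
  expect_identical(one[["44Ca"]], stack$counts[["44Ca"]][, , 2])
  expect_error(accumulate(stack, c(2, 11)), "page boundaries")
})

test_that("a background-only field yields no coccolith ROI", {
  set.seed(99)
  imgs <- list("44Ca" = matrix(rpois(64 * 64, 5), 64),
               "23Na" = matrix(rpois(64 * 64, 1), 64),
               "24Mg" = matrix(rpois(64 * 64, 0.1), 64))
  expect_warning(roi <- segment(imgs), "No coccolith")
  expect_length(roi_labels(roi, "coccolith"), 0)
  expect_true(isTRUE(attr(roi, "empty")))
})

test_that("clean-scenario coccoliths are recovered with IoU >= 0.8", {
  run <- clean_run()
  ids <- roi_labels(run$roi, "coccolith")
  expect_length(ids, 3)
  expect_length(roi_labels(run$roi, "contaminant"), 0)
  for (k in seq_along(run$truth$liths)) {
    tm <- phantom_mask(run$truth, "liths", k)
    best <- max(vapply(ids, function(id) iou(tm, roi_pixels(run$roi, id)), 1))
    expect_gte(best, 0.8)
  }
})

test_that("salt particles are flagged contaminant with high core recall", {
  run <- salt_run()
  contam_px <- matrix(FALSE, nrow(run$roi$labels), ncol(run$roi$labels))
  for (id in roi_labels(run$roi, "contaminant")) {
    contam_px <- contam_px | run$roi$labels == id
  }
  # particles 1 (on the lith) and 2 (on the filter); particle cores are the
  # unblurred discs, comfortably above 50% of the blurred peak rate
  for (k in 1:2) {
    core <- phantom_mask(run$truth, "contaminants", k)
    expect_gte(sum(core & contam_px) / sum(core), 0.7)
  }
  # the particle atop the lith was carved out of the coccolith ROI but its
  # provenance is retained
  lith_id <- roi_labels(run$roi, "coccolith")[1]
  expect_gt(sum(run$roi$labels_raw == lith_id), 0)
})

test_that("segmentation is invariant to global count rescaling", {
  run <- salt_run()
  acc <- accumulate(run$stack)
  scaled <- lapply(unclass(acc)[names(run$stack$counts)], function(m) m * 3L)
  expect_identical(segment(acc)$labels, segment(scaled)$labels)
})

test_that("Sr enrichment alone never creates a contaminant ROI", {
  set.seed(100)
  ca <- matrix(rpois(64 * 64, 5), 64)
  ca[20:40, 20:40] <- rpois(21 * 21, 600)
  sr <- round(ca * 0.08)
  sr[45:55, 45:55] <- 900               # massive Sr-only hot spot
  na <- round(ca * 0.4)
  roi <- segment(list("44Ca" = ca, "23Na" = na, "88Sr" = sr))
  expect_length(roi_labels(roi, "contaminant"), 0)
})
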