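test_that("among-lith CV matches hand calculations", {
  tbl <- sim_results_table(c(g = 0), 6)
  tbl$ion_ratio <- c(84.2, 78.1, 81.1, 79.8, 76.4, 78.4)
  cd <- cv_decomposition(tbl, "23Na", group = "sample_id")
  expect_equal(cd$among$among_lith_cv, sd(tbl$ion_ratio) / mean(tbl$ion_ratio),
               tolerance = 1e-12)
  expect_equal(round(100 * cd$among$among_lith_cv, 1), 3.4)
  expect_false(cd$among$exceeds_one)

  tbl$ion_ratio <- rep(2.5, 6)
  expect_identical(cv_decomposition(tbl, "23Na")$among$among_lith_cv, 0)
})

test_that("among-lith CV is invariant to row order and achieves the sampling-oracle coverage", {
  set.seed(61)
  tbl <- sim_results_table(c(a = 0, b = 1), c(a = 12, b = 9))
  cd1 <- cv_decomposition(tbl, "23Na")
  cd2 <- cv_decomposition(tbl[sample(nrow(tbl)), ], "23Na")
  expect_equal(cd1$among, cd2$among)

  # sampling-distribution oracle for the n-1 CV estimator at true CV 0.3,
  # n = 30: its 90% coverage radius, simulated directly and independently
  cv_true <- 0.3
  sdlog <- sqrt(log(1 + cv_true^2))
  oracle_err <- replicate(1500, {
    x <- stats::rlnorm(30, 0, sdlog)
    abs(sd(x) / mean(x) - cv_true) / cv_true
  })
  radius <- quantile(oracle_err, 0.90)
  est_err <- replicate(300, {
    tbl <- sim_results_table(c(g = 2), 30, sdlog = sdlog)
    abs(cv_decomposition(tbl, "23Na")$among$among_lith_cv - cv_true) / cv_true
  })
  # binomial slack: 300 draws at nominal 90%
  expect_gte(mean(est_err <= radius), 0.90 - 3 * sqrt(0.9 * 0.1 / 300))
  expect_lt(abs(mean(est_err <= radius) - 0.90), 0.06)
})

test_that("identical groups share a letter and exact agreement is degenerate-safe", {
  tbl <- sim_results_table(c(a = 0, b = 0), 8)
  tbl$ion_ratio <- rep(c(1, 2, 3, 4), 4)          # same values in both groups
  tg <- anova_tukey(tbl, "23Na")
  expect_identical(tg$groups$letters[1], tg$groups$letters[2])

  tbl$ion_ratio <- rep(c(1, 8), each = 8)         # zero within-group variance
  expect_warning(tg2 <- anova_tukey(tbl, "23Na"), "exact separation")
  expect_false(tg2$groups$letters[1] == tg2$groups$letters[2])
})

test_that("adjusted p-values agree with an independent studentized-range oracle", {
  set.seed(62)
  for (rep in 1:5) {
    tbl <- sim_results_table(c(a = 0, b = 0.4, c = 0.1), c(a = 9, b = 6, c = 12))
    tg <- anova_tukey(tbl, "23Na")
    oracle <- tukey_oracle_p(log(tbl$ion_ratio), tbl$sample_id)
    got <- setNames(tg$pairs$p_adj, paste(tg$pairs$group1, tg$pairs$group2,
                                          sep = "-"))
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-6)
  }
})

test_that("letters are consistent with pairwise significance and multcomp", {
  set.seed(63)
  tbl <- sim_results_table(c(a = 0, b = 0.25, c = 1.2, d = 1.25), 10)
  tg <- anova_tukey(tbl, "23Na")
  lt <- setNames(tg$groups$letters, as.character(tg$groups$group))
  share <- function(g1, g2) {
    any(strsplit(lt[[g1]], "")[[1]] %in% strsplit(lt[[g2]], "")[[1]])
  }
  for (k in seq_len(nrow(tg$pairs))) {
    expect_identical(share(tg$pairs$group1[k], tg$pairs$group2[k]),
                     tg$pairs$p_adj[k] >= tg$alpha)
  }
  # cross-check the letter partition against multcomp's display
  fit <- stats::aov(log(ion_ratio) ~ sample_id,
                    data = transform(tbl, sample_id = factor(sample_id)))
  mc <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(
    sample_id = "Tukey")))$mcletters$Letters
  canon <- function(x) {
    key <- lapply(names(x), function(g) {
      which(vapply(names(x), function(h)
        any(strsplit(x[[g]], "")[[1]] %in% strsplit(x[[h]], "")[[1]]), TRUE))
    })
    key
  }
  expect_identical(canon(lt[names(mc)]), canon(mc))
})

test_that("global rescaling leaves F, letters and correlations unchanged", {
  set.seed(64)
  tbl <- sim_results_table(c(a = 0, b = 0.5, c = 0.9), 8)
  cov <- tibble::tibble(sample_id = c("a", "b", "c"),
                        salinity = c(31, 35, 38),
                        alkalinity = c(2300, 2500, 2650))
  tg1 <- anova_tukey(tbl, "23Na")
  cm1 <- correlation_matrix(tbl, cov)
  tbl2 <- dplyr::mutate(tbl, ion_ratio = ion_ratio * 137.2)
  tg2 <- anova_tukey(tbl2, "23Na")
  cm2 <- correlation_matrix(tbl2, cov)
  expect_equal(tg1$anova$statistic, tg2$anova$statistic, tolerance = 1e-9)
  expect_equal(tg1$pairs$p_adj, tg2$pairs$p_adj, tolerance = 1e-9)
  expect_identical(tg1$groups$letters, tg2$groups$letters)
  expect_equal(cm1$r, cm2$r, tolerance = 1e-9)
})

test_that("correlations match hand computation and detect exact linearity", {
  # 5-point hand fixture
  tbl <- sim_results_table(c(a = 0, b = 0, c = 0, d = 0, e = 0), 1)
  tbl$ion_ratio <- c(1.0, 1.6, 2.1, 3.0, 4.2)
  cov <- tibble::tibble(sample_id = letters[1:5],
                        temperature = c(14.2, 15.1, 17.3, 16.0, 19.5))
  cm <- correlation_matrix(tbl, cov)
  x <- log(tbl$ion_ratio); y <- cov$temperature
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r, r_hand, tolerance = 1e-12)

  # covariate an exact linear function of the log-ratio -> r = 1
  cov2 <- tibble::tibble(sample_id = letters[1:5],
                         lin = 3 + 2 * log(tbl$ion_ratio))
  expect_equal(correlation_matrix(tbl, cov2)$r, 1, tolerance = 1e-12)
  expect_error(correlation_matrix(tbl[1:2, ], cov),
               "Fewer than 3 complete pairs")
})

test_that("permuting the covariate recovers the nominal false-positive rate", {
  # lith-level permutation null: every coccolith carries its own covariate
  # value, permuted against the ratios, so p-values must be calibrated
  set.seed(65)
  ids <- sprintf("s%02d", 1:40)
  tbl <- sim_results_table(setNames(rep(0, 40), ids), 1)
  x <- rnorm(40)
  hits <- replicate(600, {
    cov <- tibble::tibble(sample_id = ids, x = sample(x))
    correlation_matrix(tbl, cov)$significant
  })
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / 600) + 0.01)
})

test_that("growth rates recover exact and noisy exponential growth", {
  t <- 0:6
  fit <- growth_rate(t, 500 * exp(0.45 * t))
  expect_equal(fit$mu_per_day, 0.45, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(66)
  noisy <- 500 * exp(0.45 * t) * exp(rnorm(7, 0, 0.05))
  nf <- growth_rate(t, noisy)
  ci <- stats::confint(nf$fit, level = 0.999)["times_days", ]
  expect_true(ci[1] <= 0.45 && 0.45 <= ci[2])
  expect_gt(nf$r_squared, 0.95)

  expect_error(growth_rate(c(0, 1), c(10, 20)), "3 time points")
  expect_error(growth_rate(t, c(-1, 2, 3, 4, 5, 6, 7)), "positive")
  g <- glance(nf)
  expect_identical(names(g), c("mu_per_day", "r_squared", "n"))
})
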