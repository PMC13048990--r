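#' Reference per-sample El/Ca means for *E. huxleyi* coccoliths
#'
#' Published per-sample averages (mean of N individual coccoliths, +/- 1 SE)
#' of NanoSIMS El/Ca ion-count ratios and the corresponding calibrated molar
#' ratios for thirteen *E. huxleyi* samples: six laboratory cultures
#' (C1--C6) grown at controlled salinity/alkalinity and seven field stations
#' from the Black Sea (BS) and the eastern/western Mediterranean (EM/WM).
#' The table is the package's reference input for fitting calibration
#' slopes ([default_calibration()]) and for the among-culture variability
#' worked examples.
#'
#' All values are stored in natural units: ion-count ratios are
#' dimensionless (the source table prints Sr/Ca and Ba/Ca ion ratios
#' multiplied by 1000), molar ratios are mmol/mol (Ba/Ca printed x1000).
#' `ion_letter` is the published Tukey compact letter (cultures a--e and
#' field samples m--r were compared separately). `molar_unit` records the
#' unit of the last printed digit of the molar mean, i.e. its rounding
#' granularity in stored units. K/Ca has no molar values (no K calibration
#' standard exists) and was not determined in the field samples.
#'
#' @return Tibble, one row per sample and element: `sample_id`,
#'   `sample_type`, `n_liths`, `element`, `ion_ratio`, `ion_se`,
#'   `ion_letter`, `molar_ratio`, `molar_se`, `molar_unit`.
#' @export
ehux_sample_means <- function() {
  row <- function(sample_id, sample_type, n, element, ion, ion_se, letter,
                  molar, molar_se, molar_unit) {
    tibble::tibble(sample_id = sample_id, sample_type = sample_type,
                   n_liths = n, element = element, ion_ratio = ion,
                   ion_se = ion_se, ion_letter = letter, molar_ratio = molar,
                   molar_se = molar_se, molar_unit = molar_unit)
  }
  k <- 1e-3   # printed x1000 scaling for Sr/Ba ion ratios and Ba molar
  dplyr::bind_rows(
    ## cultures -------------------------------------------------------------
    row("C1", "culture", 43L, "23Na", 0.437, 0.003, "c", 11.14, 0.09, 0.01),
    row("C1", "culture", 43L, "24Mg", 0.0295, 4e-04, "c", 4.29, 0.05, 0.01),
    row("C1", "culture", 43L, "39K", 0.307, 0.005, "a", NA, NA, NA),
    row("C1", "culture", 43L, "88Sr", 84.2 * k, 0.2 * k, "a", 2.658, 0.005, 0.001),
    row("C1", "culture", 43L, "138Ba", 1.68 * k, 0.01 * k, "b", 24.5 * k, 0.2 * k, 0.1 * k),
    row("C2", "culture", 32L, "23Na", 0.61, 0.006, "b", 15.6, 0.1, 0.1),
    row("C2", "culture", 32L, "24Mg", 0.059, 0.003, "a", 8.6, 0.4, 0.1),
    row("C2", "culture", 32L, "39K", 0.102, 0.006, "c", NA, NA, NA),
    row("C2", "culture", 32L, "88Sr", 78.1 * k, 0.2 * k, "b", 2.464, 0.005, 0.001),
    row("C2", "culture", 32L, "138Ba", 0.423 * k, 0.009 * k, "e", 6.2 * k, 0.1 * k, 0.1 * k),
    row("C3", "culture", 18L, "23Na", 0.8, 0.02, "b", 20.5, 0.6, 0.1),
    row("C3", "culture", 18L, "24Mg", 0.0321, 7e-04, "abc", 4.7, 0.1, 0.1),
    row("C3", "culture", 18L, "39K", 0.42, 0.04, "ab", NA, NA, NA),
    row("C3", "culture", 18L, "88Sr", 81.1 * k, 0.3 * k, "ab", 2.56, 0.01, 0.01),
    row("C3", "culture", 18L, "138Ba", 0.96 * k, 0.02 * k, "c", 14 * k, 0.2 * k, 1 * k),
    row("C4", "culture", 36L, "23Na", 0.629, 0.005, "b", 16, 0.1, 0.1),
    row("C4", "culture", 36L, "24Mg", 0.0298, 5e-04, "c", 4.34, 0.008, 0.01),
    row("C4", "culture", 36L, "39K", 0.164, 0.005, "b", NA, NA, NA),
    row("C4", "culture", 36L, "88Sr", 79.8 * k, 0.1 * k, "b", 2.52, 0.003, 0.01),
    row("C4", "culture", 36L, "138Ba", 2.86 * k, 0.02 * k, "a", 41.6 * k, 0.3 * k, 0.1 * k),
    row("C5", "culture", 22L, "23Na", 0.676, 0.005, "b", 17.2, 0.1, 0.1),
    row("C5", "culture", 22L, "24Mg", 0.0295, 3e-04, "bc", 4.3, 0.04, 0.1),
    row("C5", "culture", 22L, "39K", 0.117, 0.003, "bc", NA, NA, NA),
    row("C5", "culture", 22L, "88Sr", 76.4 * k, 0.2 * k, "b", 2.411, 0.007, 0.001),
    row("C5", "culture", 22L, "138Ba", 0.594 * k, 0.005 * k, "d", 8.65 * k, 0.08 * k, 0.01 * k),
    row("C6", "culture", 27L, "23Na", 1.34, 0.02, "a", 34.2, 0.5, 0.1),
    row("C6", "culture", 27L, "24Mg", 0.045, 0.001, "ab", 6.5, 0.1, 0.1),
    row("C6", "culture", 27L, "39K", 0.344, 0.009, "a", NA, NA, NA),
    row("C6", "culture", 27L, "88Sr", 78.4 * k, 0.2 * k, "b", 2.474, 0.006, 0.001),
    row("C6", "culture", 27L, "138Ba", 0.73 * k, 0.01 * k, "d", 10.7 * k, 0.2 * k, 0.1 * k),
    ## field stations -------------------------------------------------------
    row("BS-2", "field", 28L, "23Na", 0.129, 0.002, "q", 3.28, 0.05, 0.01),
    row("BS-2", "field", 28L, "24Mg", 0.0068, 2e-04, "qr", 0.99, 0.03, 0.01),
    row("BS-2", "field", 28L, "88Sr", 93.6 * k, 0.5 * k, "n", 2.95, 0.02, 0.01),
    row("EM-2", "field", 9L, "23Na", 1.35, 0.04, "o", 35, 1, 1),
    row("EM-2", "field", 9L, "24Mg", 0.0252, 8e-04, "op", 3.7, 0.1, 0.1),
    row("EM-2", "field", 9L, "88Sr", 112.6 * k, 0.4 * k, "m", 3.55, 0.01, 0.01),
    row("EM-6", "field", 11L, "23Na", 0.306, 0.008, "p", 7.8, 0.2, 0.1),
    row("EM-6", "field", 11L, "24Mg", 0.026, 0.003, "pq", 3.8, 0.5, 0.1),
    row("EM-6", "field", 11L, "88Sr", 109.4 * k, 0.5 * k, "m", 3.45, 0.02, 0.01),
    row("WM-1", "field", 9L, "23Na", 0.34, 0.01, "p", 8.6, 0.3, 0.1),
    row("WM-1", "field", 9L, "24Mg", 0.0044, 7e-04, "r", 0.6, 0.1, 0.1),
    row("WM-1", "field", 9L, "88Sr", 107 * k, 1 * k, "m", 3.37, 0.03, 0.01),
    row("WM-7", "field", 7L, "23Na", 2.7, 0.2, "n", 69, 5, 1),
    row("WM-7", "field", 7L, "24Mg", 0.049, 0.004, "no", 7.2, 0.6, 0.1),
    row("WM-7", "field", 7L, "88Sr", 94.9 * k, 0.6 * k, "mn", 3, 0.02, 0.01),
    row("WM-9", "field", 9L, "23Na", 2.9, 0.2, "n", 74, 6, 1),
    row("WM-9", "field", 9L, "24Mg", 0.24, 0.02, "m", 34, 3, 1),
    row("WM-9", "field", 9L, "88Sr", 91 * k, 2 * k, "n", 2.88, 0.06, 0.01),
    row("WM-10", "field", 9L, "23Na", 4.4, 0.1, "m", 113, 3, 1),
    row("WM-10", "field", 9L, "24Mg", 0.132, 0.009, "mn", 19, 1, 1),
    row("WM-10", "field", 9L, "88Sr", 91.8 * k, 0.9 * k, "n", 2.9, 0.03, 0.1)
  )
}

#' Among-sample CV of per-sample mean ratios
#'
#' Coefficient of variation (n-1 SD over mean, in percent) of a set of
#' per-sample mean El/Ca ratios -- e.g. the variability among culture means
#' for one element. Scale-free, so it can be computed on printed
#' (rescaled) or natural-unit values alike.
#'
#' @param means Numeric vector of per-sample means.
#' @return CV in percent.
#' @export
among_sample_cv <- function(means) {
  stopifnot(length(means) >= 2, all(is.finite(means)))
  100 * sd(means) / mean(means)
}
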