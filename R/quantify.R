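#' Ca-gated El/Ca ion-count ratio of one coccolith ROI
#'
#' Accumulates element and 44Ca counts over the ROI's pixels and the stable
#' block window, including a (pixel, block) cell only when at least
#' `gate_min_ca` 44Ca ions were detected in it. Gating on 5-plane blocks
#' rather than single planes avoids bias from the high probability of
#' detecting zero 44Ca ions in any single pixel and plane, while still
#' excluding material (particulate contamination) that carries no calcium.
#' Pixels re-classed as contaminant are excluded by default even where they
#' overlap the coccolith.
#'
#' @inheritParams build_profile
#' @param window `c(first, last)` block positions (as returned by
#'   [select_stable_window()]); default all blocks.
#' @param gate_min_ca Minimum 44Ca counts per pixel-block (default 1;
#'   0 bypasses the gate, making the gated ratio equal the plain ratio).
#' @return A list: `ratio`, `n_el`, `n_ca` (gated sums), `pixel_blocks_used`,
#'   `pixel_blocks_total`, `gated_fraction`, `n_pixels`, `planes_used`.
#' @export
gated_ratio <- function(stack, roi, roi_label, element, window = NULL,
                        block_size_planes = 5, gate_min_ca = 1,
                        exclude_contaminants = TRUE) {
  check_mass(element)
  if (element == "44Ca") abort("`element` must be a trace element, not 44Ca.")
  if (gate_min_ca < 0) abort("`gate_min_ca` must be >= 0.")
  bc <- roi_block_counts(stack, roi, roi_label, element, block_size_planes,
                         exclude_contaminants)
  window <- window %||% c(1L, bc$n_blocks)
  stopifnot(length(window) == 2, window[1] >= 1, window[2] >= window[1],
            window[2] <= bc$n_blocks)
  cols <- window[1]:window[2]
  el <- bc$el[, cols, drop = FALSE]
  ca <- bc$ca[, cols, drop = FALSE]
  gate <- if (gate_min_ca > 0) ca >= gate_min_ca else ca >= 0
  used <- sum(gate)
  if (used == 0 || sum(ca[gate]) == 0) {
    abort(sprintf("ROI %s: no pixel-blocks pass the Ca gate.", roi_label))
  }
  n_el <- sum(el[gate]); n_ca <- sum(ca[gate])
  list(ratio = n_el / n_ca, n_el = n_el, n_ca = n_ca,
       pixel_blocks_used = used, pixel_blocks_total = length(gate),
       gated_fraction = used / length(gate),
       n_pixels = bc$n_pixels,
       planes_used = length(cols) * block_size_planes)
}

#' Correct mass-88 counts for the 44Ca2+ dimer interference
#'
#' The 88Sr+ peak overlaps the non-resolvable 44Ca2+ dimer, whose expected
#' contribution is `delta` counts per detected 44Ca ion. Subtracting
#' `delta * ca_counts` from the gated mass-88 sums before ratio formation is
#' algebraically the same as subtracting `delta` from the raw Sr/Ca ratio.
#' The result is floored at zero (with a warning when the floor binds).
#'
#' @param raw_sr_counts Raw mass-88 counts (scalar or vector).
#' @param ca_counts Matching 44Ca counts.
#' @param delta Dimer yield ratio (instrument/session constant, >= 0). See
#'   [estimate_delta()] for estimating it from an Sr-free region.
#' @return Corrected counts, same shape as `raw_sr_counts`.
#' @export
dimer_correct <- function(raw_sr_counts, ca_counts, delta) {
  if (delta < 0) abort("`delta` must be >= 0.")
  corrected <- raw_sr_counts - delta * ca_counts
  if (any(corrected < 0)) {
    warn("Dimer correction floored at zero counts for some entries.")
  }
  pmax(corrected, 0)
}

#' Estimate the dimer yield ratio from an Sr-free region
#'
#' Mean mass-88 to mass-44 count ratio over the given pixels; on an
#' Sr-free reference this estimates the 44Ca2+ dimer yield `delta`. The
#' estimate is provided for instrument characterisation and is never
#' applied automatically.
#'
#' @param stack An [ion_image_stack()] recording `"88Sr"` and `"44Ca"`.
#' @param mask Logical matrix selecting the Sr-free pixels.
#' @return Numeric scalar.
#' @export
estimate_delta <- function(stack, mask) {
  stopifnot(inherits(stack, "ion_stack"), is.matrix(mask))
  d <- stack_dim(stack)
  idx <- which(mask)
  if (length(idx) == 0) abort("`mask` selects no pixels.")
  per_pixel <- function(m) {
    arr <- stack$counts[[m]]
    dim(arr) <- c(d[1] * d[2], d[3])
    sum(arr[idx, ])
  }
  ca <- per_pixel("44Ca")
  if (ca == 0) abort("No 44Ca counts in the reference region.")
  per_pixel("88Sr") / ca
}

#' Calibration relations from ion-count to molar ratios
#'
#' Each element's proportional (through-origin) slope maps its El/Ca
#' ion-count ratio to a molar ratio in mmol/mol; `rel_uncertainty` is the
#' relative accuracy of the calibration itself, which bounds the accuracy of
#' any calibrated value. K has no relation (the K content of the synthetic
#' calcite standards is unknown) and stays in ion-count units.
#'
#' `fit_calibration()` fits the slopes by through-origin least squares with
#' relative-error (1/x^2) weights, i.e. the mean of the per-sample
#' molar/ion ratios. Ion ratios span orders of magnitude across samples and
#' calibration scatter is multiplicative, so absolute-error weighting would
#' let the largest samples dominate.
#'
#' @param data Tibble with columns `element`, `ion_ratio`, `molar_ratio`
#'   (one row per sample and element; `NA` rows are dropped).
#' @param rel_uncertainty Named numeric of relative calibration
#'   uncertainties per element.
#' @return A tibble of class `calibration_relation`: `element`, `slope`,
#'   `rel_uncertainty`.
#' @export
fit_calibration <- function(data,
                            rel_uncertainty = c("23Na" = 0.20, "24Mg" = 0.21,
                                                "88Sr" = 0.05, "138Ba" = 0.04)) {
  stopifnot(all(c("element", "ion_ratio", "molar_ratio") %in% names(data)))
  out <- data |>
    dplyr::filter(!is.na(.data$ion_ratio), !is.na(.data$molar_ratio),
                  .data$ion_ratio > 0) |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(slope = mean(.data$molar_ratio / .data$ion_ratio),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rel_uncertainty =
                    unname(rel_uncertainty[.data$element]) %|NA|% 0)
  if (any(out$slope <= 0)) abort("Calibration slopes must be positive.")
  tibble::new_tibble(out, class = "calibration_relation")
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' @rdname fit_calibration
#' @param slopes Named numeric of slopes (mmol/mol per unit ion ratio).
#' @export
calibration_relation <- function(slopes, rel_uncertainty) {
  stopifnot(!is.null(names(slopes)), all(slopes > 0))
  check_mass(names(slopes), several = TRUE)
  tibble::new_tibble(tibble::tibble(
    element = names(slopes), slope = unname(slopes),
    rel_uncertainty = unname(rel_uncertainty[names(slopes)]) %|NA|% 0,
    n = NA_integer_), class = "calibration_relation")
}

#' Default calibration fitted to the bundled reference sample means
#'
#' Through-origin slopes fitted with [fit_calibration()] to the paired
#' ion-count and molar ratio columns of [ehux_sample_means()], with the
#' documented relative accuracies (20% Na, 21% Mg, 5% Sr, 4% Ba).
#'
#' @return A `calibration_relation` tibble (Na, Mg, Sr, Ba; no K).
#' @export
default_calibration <- function() {
  fit_calibration(ehux_sample_means())
}

#' Convert an ion-count ratio to a molar ratio
#'
#' Proportional calibration `M = slope * R` (no intercept). The reported
#' uncertainty combines the measurement precision (residual depth CV) and
#' the calibration's relative uncertainty in quadrature; overall accuracy is
#' never better than the calibration uncertainty itself.
#'
#' @param ion_ratio El/Ca ion-count ratio.
#' @param precision_cv Relative measurement precision of `ion_ratio`.
#' @param calibration A `calibration_relation` tibble.
#' @param element Element mass label.
#' @return A one-row tibble `molar_ratio` (mmol/mol), `molar_uncertainty`;
#'   both `NA` when the element has no calibration slope (e.g. K).
#' @export
calibrate <- function(ion_ratio, precision_cv, calibration, element) {
  stopifnot(inherits(calibration, "calibration_relation"))
  row <- calibration[calibration$element == element, ]
  if (nrow(row) == 0) {
    return(tibble::tibble(molar_ratio = NA_real_,
                          molar_uncertainty = NA_real_))
  }
  m <- row$slope * ion_ratio
  tibble::tibble(
    molar_ratio = m,
    molar_uncertainty = abs(m) * sqrt(precision_cv^2 + row$rel_uncertainty^2))
}

#' Quantify one coccolith: the full per-ROI pipeline
#'
#' Per trace element: build the depth profile, select the stable plane
#' window, form the Ca-gated ratio over that window, correct mass 88 for
#' the 44Ca2+ dimer, and calibrate to a molar ratio where a slope exists.
#' The residual (Poisson-corrected) CV of the selected window is reported
#' as the measurement precision; the counting-statistics CV of the gated
#' sums is reported as `poisson_cv`, and results whose Poisson error
#' exceeds `ba_precision_threshold` (default 0.25; in practice only Ba)
#' are flagged low-precision. A result is flagged surface-contaminated when
#' the stable window excluded more than 10% of the blocks.
#'
#' @param stack Aligned [ion_image_stack()].
#' @param roi A [roi_map()].
#' @param roi_label Coccolith ROI label.
#' @param config A [pipeline_config()].
#' @param calibration A `calibration_relation`; default fitted from the
#'   bundled reference table.
#' @param sample_id Identifier copied into the result rows.
#' @return Tibble, one row per element, in the [write_results()] schema.
#' @export
quantify_lith <- function(stack, roi, roi_label, config = pipeline_config(),
                          calibration = default_calibration(),
                          sample_id = stack$meta$sample_id) {
  elements <- setdiff(names(stack$counts), "44Ca")
  rows <- lapply(elements, function(el) {
    res <- tryCatch({
      prof <- build_profile(stack, roi, roi_label, el,
                            block_size_planes = config$block_size_planes,
                            gate_min_ca = config$gate_min_ca)
      sw <- select_stable_window(prof, cv_target = config$cv_target,
                                 min_fraction = config$min_fraction)
      gr <- gated_ratio(stack, roi, roi_label, el,
                        window = c(sw$qc$window_start, sw$qc$window_end),
                        block_size_planes = config$block_size_planes,
                        gate_min_ca = config$gate_min_ca)
      n_el <- gr$n_el
      var_el <- gr$n_el                    # Poisson variance of the raw sum
      if (el == "88Sr" && config$delta > 0) {
        n_el <- unname(dimer_correct(gr$n_el, gr$n_ca, config$delta))
        var_el <- gr$n_el + config$delta^2 * gr$n_ca
      }
      ratio <- n_el / gr$n_ca
      pois_cv <- sqrt(var_el / max(n_el, 1)^2 + 1 / gr$n_ca)
      cal <- calibrate(ratio, sw$qc$cv_corrected, calibration, el)
      tibble::tibble(
        sample_id = sample_id, roi_label = as.integer(roi_label),
        element = el, ion_ratio = ratio,
        precision_cv = sw$qc$cv_corrected, poisson_cv = pois_cv,
        molar_ratio = cal$molar_ratio,
        molar_uncertainty = cal$molar_uncertainty,
        planes_used = as.integer(gr$planes_used),
        pixels_used = as.integer(gr$n_pixels),
        gated_fraction = gr$gated_fraction,
        flag_unstable = sw$qc$flag_unstable,
        flag_surface_contaminated = sw$qc$excluded_fraction > 0.10,
        flag_low_precision = pois_cv > config$ba_precision_threshold)
    }, error = function(e) {
      abort(sprintf("ROI %s, element %s: %s", roi_label, el,
                    conditionMessage(e)))
    })
    res
  })
  dplyr::bind_rows(rows)
}

#' Quantify every coccolith ROI of a stack
#'
#' @inheritParams quantify_lith
#' @return Tibble with one row per coccolith and element (the
#'   [write_results()] schema); zero rows when the map holds no coccolith.
#' @export
quantify_stack <- function(stack, roi, config = pipeline_config(),
                           calibration = default_calibration(),
                           sample_id = stack$meta$sample_id) {
  labs <- roi_labels(roi, "coccolith")
  if (length(labs) == 0) return(empty_results())
  purrr::map_dfr(labs, function(l) {
    quantify_lith(stack, roi, l, config, calibration, sample_id)
  })
}
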