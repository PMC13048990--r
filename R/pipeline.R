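#' Pipeline configuration
#'
#' Collects every tunable threshold of the processing chain with its
#' documented default. Unknown keys are rejected so configuration typos
#' fail loudly; every run writes the resolved configuration next to its
#' outputs.
#'
#' @param block_size_planes Planes per depth/gating block (default 5).
#' @param gate_min_ca Minimum 44Ca counts per pixel-block (default 1).
#' @param cv_target Residual-CV acceptance level for the stable window
#'   (default 0.10).
#' @param min_fraction Minimum fraction of blocks the stable window must
#'   cover (default 0.5).
#' @param ca_quantile Ca threshold quantile for segmentation (default 0.90).
#' @param enrichment_factor Contaminant ratio-enrichment factor (default 3).
#' @param min_area_px Minimum ROI area (default 20 px).
#' @param min_signal_frac Noise guard of the contaminant screen (default
#'   0.25; see [segment()]).
#' @param alpha Significance level for the statistics stage (default 0.05).
#' @param delta 44Ca2+ dimer yield ratio; `NA` (default) means "use the
#'   generator's true value for synthetic scenarios, 0 otherwise".
#' @param ba_precision_threshold Poisson-error level above which a result
#'   is flagged low-precision (default 0.25).
#' @param max_shift_px Alignment search radius (default 2 px).
#' @param align_block_planes Planes per alignment block (default 50).
#' @param bin_planes Acquisition planes per generated page for synthetic
#'   scenarios (default 5; see [generate_stack()]).
#' @param calibration `NULL` (fit from the bundled reference table), a path
#'   to a calibration JSON, or a `calibration_relation`.
#' @param seed Integer seed for scenario generation.
#' @param ... Rejected; guards against misspelled keys.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(block_size_planes = 5, gate_min_ca = 1,
                            cv_target = 0.10, min_fraction = 0.5,
                            ca_quantile = 0.90, enrichment_factor = 3,
                            min_area_px = 20, min_signal_frac = 0.25,
                            alpha = 0.05, delta = NA_real_,
                            ba_precision_threshold = 0.25, max_shift_px = 2,
                            align_block_planes = 50, bin_planes = 5,
                            calibration = NULL, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(names(extra), collapse = ", ")))
  }
  cfg <- list(block_size_planes = block_size_planes, gate_min_ca = gate_min_ca,
              cv_target = cv_target, min_fraction = min_fraction,
              ca_quantile = ca_quantile, enrichment_factor = enrichment_factor,
              min_area_px = min_area_px,
              min_signal_frac = min_signal_frac,
              alpha = alpha, delta = delta,
              ba_precision_threshold = ba_precision_threshold,
              max_shift_px = max_shift_px,
              align_block_planes = align_block_planes,
              bin_planes = bin_planes, calibration = calibration,
              seed = as.integer(seed))
  stopifnot(cfg$block_size_planes >= 1, cfg$gate_min_ca >= 0,
            cfg$cv_target > 0, cfg$min_fraction > 0, cfg$min_fraction <= 1,
            cfg$ca_quantile > 0, cfg$ca_quantile < 1,
            cfg$enrichment_factor > 1, cfg$min_area_px >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$max_shift_px >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Read / write calibration relations as JSON
#'
#' Schema: `{"<element>": {"slope": <number>, "rel_uncertainty": <number>}}`.
#'
#' @param path JSON file path.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Calibration file '%s' does not exist.", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_relation(
    slopes = vapply(raw, function(x) x$slope, 1),
    rel_uncertainty = vapply(raw, function(x) x$rel_uncertainty %||% 0, 1))
}

#' @rdname read_calibration
#' @param calibration A `calibration_relation`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "calibration_relation"))
  obj <- setNames(
    lapply(seq_len(nrow(calibration)), function(i) {
      list(slope = calibration$slope[i],
           rel_uncertainty = calibration$rel_uncertainty[i])
    }), calibration$element)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Depth-variability QC table for every coccolith ROI
#'
#' One row per (coccolith ROI, element): observed, Poisson and residual CV
#' of the depth profile, the selected stable window and its flags.
#'
#' @inheritParams quantify_stack
#' @return Tibble of `depth_qc` rows with window columns.
#' @export
qc_stack <- function(stack, roi, config = pipeline_config()) {
  labs <- roi_labels(roi, "coccolith")
  elements <- setdiff(names(stack$counts), "44Ca")
  purrr::map_dfr(labs, function(l) {
    purrr::map_dfr(elements, function(el) {
      prof <- build_profile(stack, roi, l, el,
                            block_size_planes = config$block_size_planes,
                            gate_min_ca = config$gate_min_ca)
      select_stable_window(prof, cv_target = config$cv_target,
                           min_fraction = config$min_fraction)$qc
    })
  })
}

#' Run the full processing pipeline
#'
#' Wires generation/ingest, alignment, segmentation, depth QC,
#' quantification and the per-sample statistics into one deterministic run:
#' `input` is either a scenario name (see [default_scenario()]), a
#' [stack_truth()], an [ion_image_stack()], or a directory written by
#' [write_stack()]. Outputs in `out_dir`: `roi.tif`/`roi.json`, `qc.csv`,
#' `liths.csv`, `sample_summary.csv`, `cv_decomposition.csv`,
#' `config.yaml` and `run.log`. All results are written only after every
#' stage succeeded, so a failed run leaves no partial `liths.csv`.
#'
#' @param input Scenario name, truth, stack, or stack directory.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param roi_in Optional path (without extension) of an externally
#'   supplied ROI map ([write_roi_map()]) replacing automated segmentation,
#'   mimicking manually drawn ROIs.
#' @return Invisibly, a list with `results`, `roi`, `qc` and `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         roi_in = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ## Resolve the calibration up front: a broken configuration must fail
  ## before any expensive stage runs or any output is written.
  calibration <- config$calibration
  if (is.null(calibration)) {
    calibration <- default_calibration()
  } else if (is.character(calibration)) {
    calibration <- read_calibration(calibration)
  }
  stopifnot(inherits(calibration, "calibration_relation"))

  truth <- NULL
  if (inherits(input, "stack_truth")) {
    truth <- input
  } else if (is.character(input) && input %in% scenario_names()) {
    truth <- default_scenario(input, seed = config$seed)
  }
  if (!is.null(truth)) {
    say("stage generate: scenario stack %d planes, seed %d",
        truth$shape[1], truth$seed)
    stack <- generate_stack(truth, bin_planes = config$bin_planes)
    if (is.na(config$delta)) config$delta <- truth$dimer_delta
  } else if (inherits(input, "ion_stack")) {
    stack <- input
  } else if (is.character(input) && dir.exists(input)) {
    say("stage ingest: reading stack from %s", input)
    stack <- read_stack(input)
  } else {
    abort(sprintf("`input` '%s' is neither a scenario, truth, stack nor directory.",
                  input))
  }
  if (is.na(config$delta)) config$delta <- 0

  say("stage align: max shift %d px, block %d planes",
      config$max_shift_px, config$align_block_planes)
  al <- align_stack(stack, max_shift_px = config$max_shift_px,
                    block_size_planes = config$align_block_planes)
  acc <- accumulate(al$stack)

  if (!is.null(roi_in)) {
    say("stage segment: external ROI map %s", roi_in)
    roi <- read_roi_map(roi_in)
  } else {
    roi <- segment(acc, ca_quantile = config$ca_quantile,
                   enrichment_factor = config$enrichment_factor,
                   min_area_px = config$min_area_px,
                   min_signal_frac = config$min_signal_frac)
  }
  for (cl in c("coccolith", "contaminant")) {
    ids <- roi_labels(roi, cl)
    areas <- vapply(ids, function(l) sum(roi$labels == l), 1L)
    say("stage segment: %d %s ROI(s)%s", length(ids), cl,
        if (length(ids)) sprintf(" (area px: %s)", paste(areas, collapse = ", "))
        else "")
  }

  qc <- qc_stack(al$stack, roi, config)
  results <- quantify_stack(al$stack, roi, config, calibration)
  say("stage quantify: %d coccolith(s) x %d element(s)",
      length(unique(results$roi_label)), length(unique(results$element)))

  ## Statistics stage: per-sample summaries; letters only when comparable.
  summary_tbl <- NULL
  cvdec_tbl <- NULL
  if (nrow(results) > 0) {
    counts <- results |>
      dplyr::distinct(.data$sample_id, .data$roi_label) |>
      dplyr::count(.data$sample_id)
    summary_tbl <- results |>
      dplyr::group_by(.data$sample_id, .data$element) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_ion_ratio = mean(.data$ion_ratio),
                       se_ion_ratio = sd(.data$ion_ratio) / sqrt(dplyr::n()),
                       mean_molar_ratio = mean(.data$molar_ratio),
                       se_molar_ratio = sd(.data$molar_ratio) / sqrt(dplyr::n()),
                       .groups = "drop") |>
      dplyr::mutate(letters = NA_character_)
    if (nrow(counts) >= 2 && sum(counts$n >= 2) >= 2) {
      for (el in unique(results$element)) {
        tg <- anova_tukey(results, el, alpha = config$alpha)
        idx <- summary_tbl$element == el
        summary_tbl$letters[idx] <-
          tg$groups$letters[match(summary_tbl$sample_id[idx],
                                  as.character(tg$groups$group))]
      }
    }
    if (any(counts$n >= 2)) {
      cvdec_tbl <- purrr::map_dfr(unique(results$element), function(el) {
        cd <- cv_decomposition(results, el)
        dplyr::mutate(cd$among, element = el, .before = 1)
      })
    }
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_roi_map(roi, file.path(out_dir, "roi"))
  readr::write_csv(qc, file.path(out_dir, "qc.csv"))
  write_results(results, file.path(out_dir, "liths.csv"))
  if (!is.null(summary_tbl)) {
    readr::write_csv(summary_tbl, file.path(out_dir, "sample_summary.csv"))
  }
  if (!is.null(cvdec_tbl)) {
    readr::write_csv(cvdec_tbl, file.path(out_dir, "cv_decomposition.csv"))
  }
  cfg_out <- unclass(config)
  cfg_out$calibration <- NULL
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  write_calibration(calibration, file.path(out_dir, "calibration.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  say("done: outputs in %s", out_dir)
  invisible(list(results = results, roi = roi, qc = qc, out_dir = out_dir))
}
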