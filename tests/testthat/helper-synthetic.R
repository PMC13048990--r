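# Shared fixtures, all built in code at test time.

# Small single-lith truth for fast unit tests.
tiny_truth <- function(seed = 1, planes = 50, side = 32L, fov = 5,
                       ca_rate = 2, ratios = c("23Na" = 0.4, "24Mg" = 0.03,
                                               "39K" = 0.3, "88Sr" = 0.08,
                                               "138Ba" = 0.0017),
                       masses = c("23Na", "24Mg", "39K", "44Ca",
                                  "88Sr", "138Ba"),
                       dimer_delta = 0, contaminants = list(),
                       drift_amplitude = NULL, radius = 0.35 * fov, ...) {
  ratios <- ratios[intersect(names(ratios), masses)]
  stack_truth(
    fov_um = fov, shape = c(planes, side, side), masses = masses,
    liths = list(lith_phantom(c(fov / 2, fov / 2), radius, 0,
                              ca_rate = ca_rate, true_ratios = ratios)),
    contaminants = contaminants,
    background_rates = setNames(
      c("23Na" = 0.002, "24Mg" = 2e-4, "39K" = 0.002, "44Ca" = 0.01,
        "88Sr" = 5e-5, "138Ba" = 2e-5)[masses], masses),
    drift_amplitude = drift_amplitude,
    psf_fwhm_um = 0.35, dimer_delta = dimer_delta, seed = seed, ...)
}

# Whole-image ROI map marking every pixel as one coccolith: lets count-level
# fixtures be quantified without segmentation.
full_roi <- function(side_r, side_c = side_r) {
  roi_map(matrix(1L, side_r, side_c), classes = c("1" = "coccolith"))
}

# Depth profile assembled from explicit block counts (for closed-form CV
# checks on exact numbers).
make_profile <- function(n_el, n_ca, element = "23Na", roi_label = 1L,
                         block_size = 5L) {
  keep <- n_ca > 0
  out <- tibble::tibble(
    block = which(keep),
    plane_start = (which(keep) - 1L) * block_size + 1L,
    plane_end = which(keep) * block_size,
    n_el = n_el[keep], n_ca = n_ca[keep],
    ratio = n_el[keep] / n_ca[keep])
  structure(out, class = c("depth_profile", class(out)),
            roi_label = roi_label, element = element,
            block_size_planes = block_size, gate_min_ca = 1L,
            n_pixels = NA_integer_, dropped_blocks = sum(!keep))
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Cache expensive scenario stacks once per test run.
.fixture_env <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

clean_run <- function() cached("clean_run", {
  truth <- default_scenario("clean", seed = 20260901)
  stack <- generate_stack(truth, bin_planes = 5)
  al <- align_stack(stack, max_shift_px = 2)
  roi <- segment(accumulate(al$stack))
  list(truth = truth, stack = al$stack, roi = roi)
})

salt_run <- function() cached("salt_run", {
  truth <- default_scenario("salt_speckled", seed = 20260902)
  stack <- generate_stack(truth, bin_planes = 5)
  al <- align_stack(stack, max_shift_px = 2)
  roi <- segment(accumulate(al$stack))
  list(truth = truth, stack = al$stack, roi = roi)
})

# Long results table with lognormal per-lith ratios for the statistics
# stage: `meanlog` is a named vector of per-group log-means.
sim_results_table <- function(meanlog, n_per_group, sdlog = 0.3,
                              element = "23Na") {
  purrr::map_dfr(names(meanlog), function(g) {
    n <- if (length(n_per_group) == 1) n_per_group else n_per_group[[g]]
    tibble::tibble(
      sample_id = g, roi_label = seq_len(n), element = element,
      ion_ratio = stats::rlnorm(n, meanlog[[g]], sdlog),
      precision_cv = 0.05, poisson_cv = 0.01,
      molar_ratio = NA_real_, molar_uncertainty = NA_real_,
      planes_used = 500L, pixels_used = 400L, gated_fraction = 1,
      flag_unstable = FALSE, flag_surface_contaminated = FALSE,
      flag_low_precision = FALSE)
  })
}

# Independent Tukey--Kramer oracle: adjusted p for every group pair straight
# from the studentized-range CDF, using only group means and sizes.
tukey_oracle_p <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  df <- length(values) - k
  s2 <- sum((values - ms[groups])^2) / df
  out <- list()
  lev <- levels(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(s2 / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(ms[[i]] - ms[[j]]) / se
    out[[paste(lev[j], lev[i], sep = "-")]] <-
      stats::ptukey(q, k, df, lower.tail = FALSE)
  }
  unlist(out)
}
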