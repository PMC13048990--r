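#' Registry of documented synthetic acquisition scenarios
#'
#' Fully parameterised [stack_truth()] objects emulating typical fields of
#' view of coccoliths deposited on a polycarbonate filter:
#'
#' * `"clean"` -- three uncontaminated coccoliths (solid discs, outer radii
#'   2.1--2.3 um) on a low-count filter background; 500 planes over a
#'   20 x 20 um, 128 x 128 px raster; no yield drift; dimer yield 0.005.
#'   True El/Ca ratios differ between the three liths and span the ranges
#'   observed in cultured *E. huxleyi*.
#' * `"salt_speckled"` -- one coccolith (12 x 12 um FOV) carrying three
#'   kinds of contamination: a compact salt particle sitting on the lith rim,
#'   a second particle on the bare filter, and a thin surface film covering
#'   the whole lith that sputters away within the first ~100 planes. The
#'   particles are strongly Na/Mg/K/Ba-enriched (no Sr) and detectable in the
#'   accumulated ratio images; the film is too dilute to segment laterally
#'   and must be caught by the depth-profile screen.
#' * `"drifty"` -- the clean geometry with incomplete yield stabilisation:
#'   drift amplitudes of 0.3 (Na), 0.2 (Mg), 0.15 (K) and 0.05 (Sr) with a
#'   150-plane half-life, while the 44Ca yield is stable, so El/Ca depth
#'   profiles decay measurably.
#'
#' @param name Scenario id: `"clean"`, `"salt_speckled"` or `"drifty"`.
#' @param seed Integer seed stored in the returned truth.
#' @return A [stack_truth()].
#' @export
default_scenario <- function(name, seed = 1L) {
  builder <- scenario_registry[[name]]
  if (is.null(builder)) {
    abort(sprintf("Unknown scenario '%s'. Available: %s.", name,
                  paste(names(scenario_registry), collapse = ", ")))
  }
  builder(as.integer(seed))
}

#' @rdname default_scenario
#' @export
scenario_names <- function() names(scenario_registry)

## Filter background rates (counts px^-1 plane^-1): low-count polycarbonate
## with traces of Na/K, essentially Sr- and Ba-free.
.bg_filter <- c("23Na" = 0.002, "24Mg" = 2e-4, "39K" = 0.002,
                "44Ca" = 0.01, "88Sr" = 5e-5, "138Ba" = 2e-5)

.clean_liths <- function() list(
  lith_phantom(c(5.2, 5.2), 2.1, 0, ca_rate = 2.0,
               true_ratios = c("23Na" = 0.35, "24Mg" = 0.025, "39K" = 0.25,
                               "88Sr" = 0.075, "138Ba" = 0.0015)),
  lith_phantom(c(14.6, 6.0), 2.2, 0, ca_rate = 2.0,
               true_ratios = c("23Na" = 0.45, "24Mg" = 0.032, "39K" = 0.32,
                               "88Sr" = 0.082, "138Ba" = 0.0018)),
  lith_phantom(c(8.8, 14.4), 2.3, 0, ca_rate = 2.0,
               true_ratios = c("23Na" = 0.55, "24Mg" = 0.040, "39K" = 0.38,
                               "88Sr" = 0.088, "138Ba" = 0.0022)))

scenario_registry <- list(

  clean = function(seed) {
    stack_truth(
      fov_um = 20, shape = c(500L, 128L, 128L), masses = COCCO_MASSES,
      liths = .clean_liths(), contaminants = list(),
      background_rates = .bg_filter,
      drift_amplitude = NULL, drift_halflife_planes = 150,
      psf_fwhm_um = 0.4, dimer_delta = 0.005, seed = seed)
  },

  salt_speckled = function(seed) {
    lith <- lith_phantom(c(5.5, 5.5), 2.2, 0, ca_rate = 2.0,
                         true_ratios = c("23Na" = 0.40, "24Mg" = 0.030,
                                         "39K" = 0.30, "88Sr" = 0.080,
                                         "138Ba" = 0.0017))
    particle_rates <- c("23Na" = 12, "24Mg" = 3, "39K" = 5,
                        "138Ba" = 0.05, "88Sr" = 0)
    contaminants <- list(
      ## Compact salt particle on the coccolith rim (lateral detection case).
      contaminant_phantom(c(7.0, 5.5), 0.6, particle_rates,
                          depletion_halflife_planes = 60),
      ## Particle on the bare filter.
      contaminant_phantom(c(2.0, 9.5), 0.5, particle_rates,
                          depletion_halflife_planes = 60),
      ## Thin surface film over the whole lith: strong at the surface,
      ## gone within ~100 planes; invisible in accumulated ratio images.
      contaminant_phantom(c(5.5, 5.5), 2.35,
                          c("23Na" = 4.0, "24Mg" = 0.4, "39K" = 2.0,
                            "138Ba" = 0.01, "88Sr" = 0),
                          depletion_halflife_planes = 25))
    stack_truth(
      fov_um = 12, shape = c(500L, 128L, 128L), masses = COCCO_MASSES,
      liths = list(lith), contaminants = contaminants,
      background_rates = .bg_filter,
      drift_amplitude = NULL, drift_halflife_planes = 150,
      psf_fwhm_um = 0.4, dimer_delta = 0.005, seed = seed)
  },

  drifty = function(seed) {
    stack_truth(
      fov_um = 20, shape = c(500L, 128L, 128L), masses = COCCO_MASSES,
      liths = .clean_liths(), contaminants = list(),
      background_rates = .bg_filter,
      drift_amplitude = c("23Na" = 0.3, "24Mg" = 0.2, "39K" = 0.15,
                          "88Sr" = 0.05),
      drift_halflife_planes = 150,
      psf_fwhm_um = 0.4, dimer_delta = 0.005, seed = seed)
  }
)
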