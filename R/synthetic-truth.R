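#' Coccolith phantom for synthetic stacks
#'
#' Describes one simulated coccolith as a disc or annulus of calcite with a
#' mean \eqn{^{44}}Ca detection rate and fixed true element-to-calcium
#' ion-count ratios. Coccoliths of *E. huxleyi* are 3--5 um across, so the
#' default-sized phantoms use outer radii of 1.5--2.5 um.
#'
#' @param center_um Numeric length-2, (x, y) centre in micrometres. x runs
#'   along columns, y along rows (downwards).
#' @param outer_radius_um Outer radius in micrometres.
#' @param inner_radius_um Inner radius in micrometres; 0 gives a solid disc.
#' @param ca_rate Mean \eqn{^{44}}Ca counts per pixel per plane inside the
#'   phantom.
#' @param true_ratios Named numeric vector of true El/Ca ion-count ratios
#'   (dimensionless), names from [cocco_masses()] other than `"44Ca"`.
#' @return An object of class `lith_phantom`.
#' @export
lith_phantom <- function(center_um, outer_radius_um, inner_radius_um = 0,
                         ca_rate, true_ratios) {
  stopifnot(length(center_um) == 2, is.finite(center_um))
  if (!is.finite(outer_radius_um) || outer_radius_um <= 0) {
    abort("`outer_radius_um` must be positive.")
  }
  if (inner_radius_um < 0 || inner_radius_um >= outer_radius_um) {
    abort("`inner_radius_um` must lie in [0, outer_radius_um).")
  }
  if (!is.finite(ca_rate) || ca_rate < 0) abort("`ca_rate` must be >= 0.")
  check_mass(names(true_ratios), several = TRUE)
  if ("44Ca" %in% names(true_ratios)) {
    abort("`true_ratios` are relative to 44Ca; do not include 44Ca itself.")
  }
  if (any(!is.finite(true_ratios)) || any(true_ratios < 0)) {
    abort("All `true_ratios` must be finite and >= 0.")
  }
  structure(
    list(center_um = as.numeric(center_um),
         outer_radius_um = outer_radius_um,
         inner_radius_um = inner_radius_um,
         ca_rate = ca_rate,
         true_ratios = true_ratios),
    class = "lith_phantom")
}

#' Contaminant phantom for synthetic stacks
#'
#' A surface particle (salt precipitate or organic remnant) enriched in
#' Na/Mg/K/Ba but carrying no Sr, which sputters away exponentially with
#' depth. Contaminants observed next to or atop coccoliths show elevated
#' counts of 24Mg, and often 23Na, 39K and 138Ba, but never 88Sr; the
#' constructor enforces a zero Sr rate.
#'
#' @param center_um Numeric length-2 (x, y) centre in micrometres.
#' @param radius_um Particle radius in micrometres.
#' @param rates Named numeric vector: surface counts per pixel per plane at
#'   plane 1 for each mass. Any `"88Sr"` entry must be 0 (and is implied 0
#'   when absent).
#' @param depletion_halflife_planes E-folding (half-life) depth in planes
#'   over which the particle sputters away.
#' @return An object of class `contaminant_phantom`.
#' @export
contaminant_phantom <- function(center_um, radius_um, rates,
                                depletion_halflife_planes) {
  stopifnot(length(center_um) == 2, is.finite(center_um))
  if (!is.finite(radius_um) || radius_um <= 0) abort("`radius_um` must be > 0.")
  check_mass(names(rates), several = TRUE)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("All contaminant `rates` must be finite and >= 0.")
  }
  if (!is.na(rates["88Sr"]) && rates[["88Sr"]] != 0) {
    abort("Contaminants carry no Sr: `rates[\"88Sr\"]` must be 0.")
  }
  if (depletion_halflife_planes <= 0) {
    abort("`depletion_halflife_planes` must be > 0.")
  }
  structure(
    list(center_um = as.numeric(center_um),
         radius_um = radius_um,
         rates = rates,
         depletion_halflife_planes = depletion_halflife_planes),
    class = "contaminant_phantom")
}

#' Ground truth for a synthetic NanoSIMS acquisition
#'
#' Collects everything [generate_stack()] needs: raster geometry, the masses
#' recorded, coccolith and contaminant phantoms, filter background rates, a
#' per-mass secondary-ion yield-drift term, the beam point-spread function,
#' the mass-88 dimer yield and the RNG seed.
#'
#' The yield drift multiplies every rate by
#' \eqn{1 + a_m 2^{-p/\tau}} for plane \eqn{p} (0-based), modelling
#' incomplete stabilisation after pre-sputtering; contaminants decay as
#' \eqn{2^{-p/h}} with their own half-life \eqn{h}. Mass 88 additionally
#' receives an independent Poisson dimer contribution with expectation
#' `dimer_delta` times the local \eqn{^{44}}Ca rate.
#'
#' @param fov_um Physical raster width in micrometres (square pixels; the
#'   raster height is `rows / cols * fov_um`).
#' @param shape Integer length-3: planes P (>= 10), rows H, cols W.
#' @param masses Character vector of recorded masses; must contain `"44Ca"`.
#' @param liths List of [lith_phantom()] objects.
#' @param contaminants List of [contaminant_phantom()] objects.
#' @param background_rates Named numeric: mean counts per pixel per plane on
#'   the bare filter, one entry per mass.
#' @param drift_amplitude Named numeric per mass (missing masses get 0):
#'   the amplitude \eqn{a_m} of the yield-drift term.
#' @param drift_halflife_planes E-folding depth of the drift term, in planes.
#' @param psf_fwhm_um Beam full width at half maximum in micrometres
#'   (0.35--0.5 um on the instrument; accepted range 0.1--1).
#' @param dimer_delta Expected mass-88 dimer counts per detected 44Ca count
#'   (dimensionless, in `[0, 1)`).
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   truth object.
#' @return An object of class `stack_truth`.
#' @export
stack_truth <- function(fov_um, shape, masses, liths,
                        contaminants = list(),
                        background_rates,
                        drift_amplitude = NULL,
                        drift_halflife_planes = 100,
                        psf_fwhm_um = 0.4,
                        dimer_delta = 0,
                        seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (shape[1] < 10) abort("At least 10 acquisition planes are required.")
  check_mass(masses, several = TRUE)
  if (!"44Ca" %in% masses) abort("`masses` must include the reference 44Ca.")
  if (anyDuplicated(masses)) abort("`masses` must be unique.")
  stopifnot(is.list(liths), is.list(contaminants))
  for (l in liths) stopifnot(inherits(l, "lith_phantom"))
  for (cc in contaminants) {
    stopifnot(inherits(cc, "contaminant_phantom"))
    if (cc$depletion_halflife_planes >= shape[1]) {
      abort("Contaminant depletion half-life must be < the number of planes.")
    }
  }
  bg <- setNames(rep(0, length(masses)), masses)
  check_mass(names(background_rates), several = TRUE)
  bg[names(background_rates)] <- background_rates
  if (any(!is.finite(bg)) || any(bg < 0)) {
    abort("`background_rates` must be finite and >= 0.")
  }
  a <- setNames(rep(0, length(masses)), masses)
  if (!is.null(drift_amplitude)) {
    check_mass(names(drift_amplitude), several = TRUE)
    a[names(drift_amplitude)] <- drift_amplitude
  }
  if (any(!is.finite(a)) || any(a < -1)) {
    abort("`drift_amplitude` must be finite and > -1.")
  }
  if (psf_fwhm_um < 0.1 || psf_fwhm_um > 1.0) {
    abort("`psf_fwhm_um` outside the supported 0.1--1.0 um range.")
  }
  if (dimer_delta < 0 || dimer_delta >= 1) {
    abort("`dimer_delta` must lie in [0, 1).")
  }
  structure(
    list(fov_um = fov_um, shape = shape, masses = masses,
         liths = liths, contaminants = contaminants,
         background_rates = bg[masses],
         drift_amplitude = a[masses],
         drift_halflife_planes = drift_halflife_planes,
         psf_fwhm_um = psf_fwhm_um,
         dimer_delta = dimer_delta,
         seed = as.integer(seed)),
    class = "stack_truth")
}

#' @export
print.stack_truth <- function(x, ...) {
  cat(sprintf(
    "<stack_truth> %d x %d px, %d planes, FOV %.3g um, %d lith(s), %d contaminant(s)\n",
    x$shape[2], x$shape[3], x$shape[1], x$fov_um,
    length(x$liths), length(x$contaminants)))
  cat("  masses:", paste(x$masses, collapse = ", "),
      sprintf("| psf %.2f um | dimer delta %.4g | seed %d\n",
              x$psf_fwhm_um, x$dimer_delta, x$seed))
  invisible(x)
}

## Pixel-centre coordinate grids in um. Pixel (row 1, col 1) is centred at
## (0.5*pitch, 0.5*pitch); rows increase downwards.
pixel_grid <- function(truth) {
  rows <- truth$shape[2]; cols <- truth$shape[3]
  pitch <- truth$fov_um / cols
  list(pitch = pitch,
       x = matrix((seq_len(cols) - 0.5) * pitch, rows, cols, byrow = TRUE),
       y = matrix((seq_len(rows) - 0.5) * pitch, rows, cols))
}

disc_mask <- function(grid, center_um, outer_um, inner_um = 0) {
  d2 <- (grid$x - center_um[1])^2 + (grid$y - center_um[2])^2
  d2 <= outer_um^2 & d2 >= inner_um^2
}

#' Ground-truth masks of the simulated phantoms
#'
#' @param truth A [stack_truth()].
#' @param what `"liths"` or `"contaminants"`.
#' @return Integer label matrix (rows x cols); pixel value k marks the k-th
#'   phantom of the requested kind, 0 elsewhere. Later phantoms overwrite
#'   earlier ones where they overlap.
#' @export
phantom_masks <- function(truth, what = c("liths", "contaminants")) {
  what <- match.arg(what)
  grid <- pixel_grid(truth)
  lab <- matrix(0L, truth$shape[2], truth$shape[3])
  objs <- truth[[what]]
  for (k in seq_along(objs)) {
    o <- objs[[k]]
    m <- if (what == "liths") {
      disc_mask(grid, o$center_um, o$outer_radius_um, o$inner_radius_um)
    } else {
      disc_mask(grid, o$center_um, o$radius_um)
    }
    lab[m] <- k
  }
  lab
}

#' @rdname phantom_masks
#' @param index Phantom index within its kind.
#' @return `phantom_mask()`: logical matrix for a single phantom,
#'   unaffected by overlaps.
#' @export
phantom_mask <- function(truth, what = c("liths", "contaminants"), index) {
  what <- match.arg(what)
  grid <- pixel_grid(truth)
  o <- truth[[what]][[index]]
  if (what == "liths") {
    disc_mask(grid, o$center_um, o$outer_radius_um, o$inner_radius_um)
  } else {
    disc_mask(grid, o$center_um, o$radius_um)
  }
}

#' Planes dominated by contaminant flux in the generator truth
#'
#' Marks acquisition planes on which the ROI-integrated flux of `element`
#' contributed by the selected contaminants still exceeds `rel_threshold`
#' times the intrinsic coccolith flux of that element -- i.e. planes a
#' depth-profile screen ought to discard.
#'
#' @param truth A [stack_truth()].
#' @param element Trace-element mass label (not `"44Ca"`).
#' @param contaminants Indices of the contaminants to consider
#'   (default: all).
#' @param rel_threshold Contaminant-to-coccolith flux ratio above which a
#'   plane counts as contaminated (default 0.5).
#' @return Integer vector of 1-based plane indices.
#' @export
contaminated_planes <- function(truth, element, contaminants = NULL,
                                rel_threshold = 0.5) {
  check_mass(element)
  if (element == "44Ca") abort("`element` must be a trace element.")
  idx <- contaminants %||% seq_along(truth$contaminants)
  grid <- pixel_grid(truth)
  lith_lab <- phantom_masks(truth, "liths")
  lith_flux <- 0
  for (l in truth$liths) {
    m <- disc_mask(grid, l$center_um, l$outer_radius_um, l$inner_radius_um)
    r <- l$true_ratios[element]
    if (!is.na(r)) lith_flux <- lith_flux + sum(m) * l$ca_rate * r
  }
  if (lith_flux <= 0) abort("No coccolith flux for this element in the truth.")
  p <- seq_len(truth$shape[1])
  cont_flux0 <- 0
  decay <- rep(0, length(p))
  for (k in idx) {
    cc <- truth$contaminants[[k]]
    rate <- cc$rates[element]
    if (is.na(rate) || rate == 0) next
    m <- disc_mask(grid, cc$center_um, cc$radius_um) & lith_lab > 0
    decay <- decay + sum(m) * rate * 2^(-(p - 1) / cc$depletion_halflife_planes)
  }
  which(decay / lith_flux > rel_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
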