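#' Generate a synthetic NanoSIMS ion-count image stack
#'
#' Draws independent Poisson counts per pixel, plane and mass from the rate
#' model described by a [stack_truth()]. The per-plane expectation is
#' \deqn{\lambda_m(x,p) = \big[(1-\omega(x))\,b_m + L_m(x) +
#'   \sum_c C_{c,m}(x)\,2^{-p/h_c}\big]\,(1 + a_m 2^{-p/\tau}),}
#' where \eqn{b_m} is the filter background, \eqn{L_m} the coccolith rate
#' field, \eqn{C_{c,m}} the contaminant surface fields with sputtering
#' half-lives \eqn{h_c}, and \eqn{1 + a_m 2^{-p/\tau}} the yield-drift term.
#' \eqn{\omega(x)} is the beam fraction occluded by coccolith calcite: where
#' a coccolith covers the filter the beam samples the lith surface, not the
#' substrate beneath it, so the background is suppressed there rather than
#' added through the lith. All spatial fields are blurred by a Gaussian beam
#' point-spread function of FWHM `psf_fwhm_um`. Mass 88 additionally
#' receives an independent Poisson dimer contribution with expectation
#' `dimer_delta` times the local (drifted) \eqn{^{44}}Ca rate; dimer
#' detections do not remove monomer detections.
#'
#' `bin_planes > 1` stores each group of `bin_planes` consecutive planes as
#' one page. Because sums of independent Poisson variables are Poisson with
#' the summed rate, the pages are drawn from the exact distribution of the
#' corresponding plane sums -- every statistic computed on plane blocks that
#' are multiples of `bin_planes` (accumulation, 5-plane gating, depth
#' profiles) is distributionally identical to per-plane generation, at a
#' fraction of the cost.
#'
#' @param truth A [stack_truth()].
#' @param bin_planes Acquisition planes per stored page; must divide the
#'   number of planes. Default 1 (one page per plane).
#' @return An [ion_image_stack()]. Bit-identical for a fixed `truth`
#'   (including its `seed`).
#' @export
generate_stack <- function(truth, bin_planes = 1L) {
  stopifnot(inherits(truth, "stack_truth"))
  P <- truth$shape[1]
  bin_planes <- as.integer(bin_planes)
  if (bin_planes < 1 || P %% bin_planes != 0) {
    abort("`bin_planes` must be a positive divisor of the plane count.")
  }
  G <- P %/% bin_planes
  rows <- truth$shape[2]; cols <- truth$shape[3]
  grid <- pixel_grid(truth)
  sigma_px <- truth$psf_fwhm_um / (2 * sqrt(2 * log(2))) / grid$pitch

  ## Static spatial fields (counts px^-1 plane^-1), then PSF blur.
  occ <- matrix(0, rows, cols)
  lith_fields <- lapply(truth$masses, function(m) matrix(0, rows, cols))
  names(lith_fields) <- truth$masses
  for (l in truth$liths) {
    ind <- disc_mask(grid, l$center_um, l$outer_radius_um, l$inner_radius_um)
    occ <- pmin(occ + ind, 1)
    for (m in truth$masses) {
      r <- if (m == "44Ca") 1 else unname(l$true_ratios[m])
      if (!is.na(r) && r > 0) {
        lith_fields[[m]] <- lith_fields[[m]] + ind * (l$ca_rate * r)
      }
    }
  }
  cont_fields <- lapply(truth$contaminants, function(cc) {
    ind <- disc_mask(grid, cc$center_um, cc$radius_um)
    f <- lapply(truth$masses, function(m) {
      r <- cc$rates[m]
      if (is.na(r) || r == 0) NULL else ind * unname(r)
    })
    names(f) <- truth$masses
    f
  })

  occ_b <- pmin(psf_blur(occ, sigma_px), 1)
  lith_fields <- lapply(lith_fields, psf_blur, sigma_px = sigma_px)
  cont_fields <- lapply(cont_fields, function(f) {
    lapply(f, function(x) if (is.null(x)) NULL else psf_blur(x, sigma_px))
  })

  ## Per-page sums of the depth-dependence terms (planes are 0-based).
  p0 <- 0:(P - 1)
  page_of <- rep(seq_len(G), each = bin_planes)
  d <- 2^(-p0 / truth$drift_halflife_planes)
  sum_by_page <- function(v) as.numeric(rowsum(v, page_of))
  sd_g <- sum_by_page(d)
  cont_sums <- lapply(truth$contaminants, function(cc) {
    e <- 2^(-p0 / cc$depletion_halflife_planes)
    list(se = sum_by_page(e), sed = sum_by_page(e * d))
  })

  page_lambda <- function(m) {
    a <- truth$drift_amplitude[[m]]
    A <- (1 - occ_b) * truth$background_rates[[m]] + lith_fields[[m]]
    lam <- outer(A, bin_planes + a * sd_g)
    for (k in seq_along(cont_fields)) {
      Ck <- cont_fields[[k]][[m]]
      if (!is.null(Ck)) {
        lam <- lam + outer(Ck, cont_sums[[k]]$se + a * cont_sums[[k]]$sed)
      }
    }
    if (any(!is.finite(lam))) abort("Non-finite expected rates encountered.")
    lam
  }

  counts <- withr::with_seed(truth$seed, {
    lam_ca <- page_lambda("44Ca")
    out <- lapply(truth$masses, function(m) {
      lam <- if (m == "44Ca") lam_ca else page_lambda(m)
      array(rpois(length(lam), lam), dim = dim(lam))
    })
    names(out) <- truth$masses
    if ("88Sr" %in% truth$masses && truth$dimer_delta > 0) {
      dimer <- array(rpois(length(lam_ca), truth$dimer_delta * lam_ca),
                     dim = dim(lam_ca))
      out[["88Sr"]] <- out[["88Sr"]] + dimer
    }
    out
  })

  ion_image_stack(counts, fov_um = truth$fov_um, planes_per_page = bin_planes,
                  sample_id = "synthetic", session_id = "simulated")
}

## Gaussian PSF blur with zero padding: ions sputtered towards positions
## outside the raster are lost, so total rate is conserved up to edge
## truncation only.
psf_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  half <- ceiling(4 * sigma_px)
  size <- min(2 * half + 1, 2 * (min(dim(mat)) %/% 2) - 1)
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  k <- k / sum(k)
  EBImage::filter2(mat, k, boundary = 0)
}
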