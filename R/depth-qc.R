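## Per-pixel, per-block count matrices for one ROI: the shared machinery of
## depth profiles and gated accumulation. Blocks are consecutive,
## non-overlapping groups of `block_size_planes` planes; a short trailing
## block is dropped.
roi_block_counts <- function(stack, roi, roi_label, element,
                             block_size_planes = 5,
                             exclude_contaminants = TRUE) {
  stopifnot(inherits(stack, "ion_stack"), inherits(roi, "roi_map"))
  check_mass(element)
  if (!element %in% names(stack$counts)) {
    abort(sprintf("Mass %s was not recorded in this stack.", element))
  }
  d <- stack_dim(stack); ppp <- stack$meta$planes_per_page
  if (block_size_planes %% ppp != 0) {
    abort("`block_size_planes` must be a multiple of planes_per_page.")
  }
  ppb <- block_size_planes %/% ppp
  n_blocks <- d[3] %/% ppb
  if (n_blocks < 1) abort("Stack shorter than one block.")
  mask <- roi_pixels(roi, roi_label, exclude_contaminants)
  if (!any(mask)) abort(sprintf("ROI %s has no pixels.", roi_label))
  idx <- which(mask)

  as_blocks <- function(arr) {
    dim(arr) <- c(d[1] * d[2], d[3])
    m <- arr[idx, seq_len(n_blocks * ppb), drop = FALSE]
    if (ppb > 1) {
      dim(m) <- c(length(idx), ppb, n_blocks)
      m <- colSums(aperm(m, c(2, 1, 3)))       # (pix, blocks)
      dim(m) <- c(length(idx), n_blocks)
    }
    m
  }
  list(el = as_blocks(stack$counts[[element]]),
       ca = as_blocks(stack$counts[["44Ca"]]),
       n_blocks = n_blocks, n_pixels = length(idx),
       block_size_planes = block_size_planes)
}

#' Depth profile of an El/Ca ion-count ratio in one ROI
#'
#' Sums element and 44Ca counts over the ROI's pixels in consecutive blocks
#' of `block_size_planes` planes (default 5) and forms the per-block ratio
#' series used by the depth-variability QC. With `gate_min_ca >= 1`, a
#' pixel's counts enter a block only if at least that many 44Ca ions were
#' detected there within the block (Ca-gated accumulation); `gate_min_ca =
#' 0` disables the gate. Blocks whose gated Ca sum is zero are dropped (the
#' count of dropped blocks is kept as an attribute).
#'
#' @param stack Aligned [ion_image_stack()].
#' @param roi A [roi_map()].
#' @param roi_label Coccolith ROI label.
#' @param element Trace-element mass label (not `"44Ca"`).
#' @param block_size_planes Planes per depth block (default 5).
#' @param gate_min_ca Minimum 44Ca counts per pixel-block for inclusion
#'   (default 1).
#' @param exclude_contaminants Drop pixels re-classed as contaminant
#'   (default `TRUE`).
#' @return A tibble of class `depth_profile`: `block`, `plane_start`,
#'   `plane_end`, `n_el`, `n_ca`, `ratio`.
#' @export
build_profile <- function(stack, roi, roi_label, element,
                          block_size_planes = 5, gate_min_ca = 1,
                          exclude_contaminants = TRUE) {
  block_size_planes <- as.integer(block_size_planes)
  check_mass(element)
  if (element == "44Ca") abort("`element` must be a trace element, not 44Ca.")
  bc <- roi_block_counts(stack, roi, roi_label, element, block_size_planes,
                         exclude_contaminants)
  if (sum(bc$ca) == 0) {
    abort(sprintf("ROI %s holds no 44Ca counts; no profile can be formed.",
                  roi_label))
  }
  gate <- if (gate_min_ca > 0) bc$ca >= gate_min_ca else bc$ca >= 0
  n_el <- colSums(bc$el * gate)
  n_ca <- colSums(bc$ca * gate)
  keep <- n_ca > 0
  out <- tibble::tibble(
    block = which(keep),
    plane_start = (which(keep) - 1L) * block_size_planes + 1L,
    plane_end = which(keep) * block_size_planes,
    n_el = n_el[keep], n_ca = n_ca[keep],
    ratio = n_el[keep] / n_ca[keep])
  structure(out,
            class = c("depth_profile", class(out)),
            roi_label = roi_label, element = element,
            block_size_planes = block_size_planes,
            gate_min_ca = gate_min_ca,
            n_pixels = bc$n_pixels,
            dropped_blocks = sum(!keep))
}

#' Poisson-expected CV of a depth-profile ratio series
#'
#' First-order relative standard deviation of a ratio of independent
#' Poisson sums, averaged over blocks:
#' \deqn{CV_P = \sqrt{\mathrm{mean}_b\,(1/n_{el}(b) + 1/n_{Ca}(b))}.}
#' Blocks with zero element counts contribute `1/max(n_el, 1)` so the
#' expectation stays finite.
#'
#' @param profile A [build_profile()] result with at least 2 blocks.
#' @return Numeric scalar, the counting-statistics CV.
#' @export
poisson_cv <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) < 2) abort("At least 2 retained blocks are required.")
  sqrt(mean(1 / pmax(profile$n_el, 1) + 1 / profile$n_ca))
}

#' Depth-variability QC: observed, Poisson and residual CV
#'
#' The observed CV of the per-block ratios (n-1 denominator, blocks weighted
#' equally) has two contributions: true variation with depth and the random
#' nature of ion detection. The residual (Poisson-corrected) CV removes the
#' latter in quadrature,
#' \eqn{CV_{corr} = \sqrt{\max(CV_{obs}^2 - CV_P^2,\,0)}}, and is the
#' measurement-precision figure reported for quantification.
#'
#' @param profile A [build_profile()] result.
#' @param cv_unstable Residual CV above which the profile is flagged
#'   unstable (default 0.10).
#' @return A one-row tibble of class `depth_qc`: `roi_label`, `element`,
#'   `n_blocks`, `cv_obs`, `cv_poisson`, `cv_corrected`, `flag_unstable`.
#' @export
corrected_cv <- function(profile, cv_unstable = 0.10) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) < 2) abort("At least 2 retained blocks are required.")
  cv_obs <- sd(profile$ratio) / mean(profile$ratio)
  cv_p <- poisson_cv(profile)
  cv_corr <- sqrt(max(cv_obs^2 - cv_p^2, 0))
  tibble::new_tibble(tibble::tibble(
    roi_label = attr(profile, "roi_label") %||% NA_integer_,
    element = attr(profile, "element") %||% NA_character_,
    n_blocks = nrow(profile),
    cv_obs = cv_obs, cv_poisson = cv_p, cv_corrected = cv_corr,
    flag_unstable = cv_corr > cv_unstable), class = "depth_qc")
}

#' Select the stable depth window of a profile
#'
#' Searches all contiguous block windows covering at least `min_fraction`
#' of the retained blocks and returns the longest whose residual CV is at
#' most `cv_target`. Ties prefer (a) the window with the larger total Ca
#' counts, then (b) the deeper start, since surface contamination and yield
#' drift concentrate in the early planes. If no window qualifies, the
#' minimum-residual-CV window is returned and flagged unstable. Planes
#' outside the window are excluded from quantification, not corrected.
#'
#' @param profile A [build_profile()] result.
#' @param cv_target Residual-CV acceptance level (default 0.10).
#' @param min_fraction Minimum fraction of blocks a window must cover
#'   (default 0.5).
#' @return List with `window` (`c(first, last)` positions in the retained
#'   block series) and `qc` (a `depth_qc` row for the selected window, with
#'   `window_start`/`window_end`/`excluded_fraction` columns added).
#' @export
select_stable_window <- function(profile, cv_target = 0.10,
                                 min_fraction = 0.5) {
  stopifnot(inherits(profile, "depth_profile"))
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must lie in (0, 1].")
  }
  B <- nrow(profile)
  if (B < 2) abort("At least 2 retained blocks are required.")
  min_len <- max(2L, ceiling(min_fraction * B))
  r <- profile$ratio
  s1 <- cumsum(c(0, r)); s2 <- cumsum(c(0, r^2))
  sp <- cumsum(c(0, 1 / pmax(profile$n_el, 1) + 1 / profile$n_ca))
  sc <- cumsum(c(0, profile$n_ca))

  best <- NULL
  fallback <- NULL
  for (i in seq_len(B - min_len + 1)) {
    j <- (i + min_len - 1):B
    n <- j - i + 1
    m <- (s1[j + 1] - s1[i]) / n
    v <- (s2[j + 1] - s2[i] - n * m^2) / (n - 1)
    cv_obs2 <- pmax(v, 0) / m^2
    cv_p2 <- (sp[j + 1] - sp[i]) / n
    cv_corr <- sqrt(pmax(cv_obs2 - cv_p2, 0))
    ca_tot <- sc[j + 1] - sc[i]
    cand <- tibble::tibble(i = i, j = j, len = n, cv_corr = cv_corr,
                           ca_tot = ca_tot)
    ok <- cand[cand$cv_corr <= cv_target, ]
    if (nrow(ok) > 0) {
      best <- dplyr::bind_rows(best, ok)
    }
    fallback <- dplyr::bind_rows(fallback, cand[which.min(cand$cv_corr), ])
  }

  unstable <- is.null(best)
  pick <- if (!unstable) {
    best |>
      dplyr::arrange(dplyr::desc(.data$len), dplyr::desc(.data$ca_tot),
                     dplyr::desc(.data$i)) |>
      dplyr::slice(1)
  } else {
    fallback |>
      dplyr::arrange(.data$cv_corr, dplyr::desc(.data$ca_tot),
                     dplyr::desc(.data$i)) |>
      dplyr::slice(1)
  }
  window <- c(pick$i, pick$j)
  sub <- profile[window[1]:window[2], ]
  attr(sub, "roi_label") <- attr(profile, "roi_label")
  attr(sub, "element") <- attr(profile, "element")
  class(sub) <- unique(c("depth_profile", class(sub)))
  qc <- corrected_cv(sub)
  qc$flag_unstable <- unstable | qc$flag_unstable
  qc$window_start <- profile$block[window[1]]
  qc$window_end <- profile$block[window[2]]
  qc$excluded_fraction <- 1 - (window[2] - window[1] + 1) / B
  list(window = window, qc = qc)
}
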