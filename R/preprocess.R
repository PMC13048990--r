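#' Align stack planes on the 44Ca channel
#'
#' Estimates one integer (dy, dx) shift per block of consecutive planes by
#' maximising the cross-correlation of the block's accumulated 44Ca image
#' against a running accumulated reference, applies the block's shift to all
#' masses, and crops every mass to the common valid window. Per-block
#' integer shifts are used rather than per-plane subpixel shifts: single
#' planes carry too few Ca counts for reliable registration, and integer
#' shifts keep the counts integral.
#'
#' @param stack An [ion_image_stack()].
#' @param max_shift_px Maximum absolute shift searched per axis; 0 bypasses
#'   estimation (all offsets zero).
#' @param block_size_planes Acquisition planes per alignment block
#'   (default 50); must be a multiple of the stack's `planes_per_page`.
#' @return A list with `stack` (aligned, cropped `ion_stack`) and `trace`
#'   (tibble: block, plane_start, plane_end, dy, dx).
#' @export
align_stack <- function(stack, max_shift_px = 2L, block_size_planes = 50L) {
  stopifnot(inherits(stack, "ion_stack"), max_shift_px >= 0,
            block_size_planes >= 1)
  d <- stack_dim(stack)
  ppp <- stack$meta$planes_per_page
  if (block_size_planes %% ppp != 0) {
    abort("`block_size_planes` must be a multiple of planes_per_page.")
  }
  ppb <- max(1L, block_size_planes %/% ppp)        # pages per block
  n_blocks <- ceiling(d[3] / ppb)
  block_of <- rep(seq_len(n_blocks), each = ppb)[seq_len(d[3])]
  ca <- stack$counts[["44Ca"]]
  if (is.null(ca)) abort("Alignment requires the 44Ca channel.")
  if (sum(ca) == 0) {
    abort(paste("All-zero 44Ca image: alignment is undefined.",
                "Re-run with max_shift_px = 0 to bypass alignment."))
  }

  block_img <- function(arr, b) {
    pages <- which(block_of == b)
    if (length(pages) == 1) arr[, , pages] else rowSums(arr[, , pages, drop = FALSE], dims = 2)
  }

  shifts <- matrix(0L, n_blocks, 2)
  if (max_shift_px > 0 && n_blocks > 1) {
    cand <- expand.grid(dy = -max_shift_px:max_shift_px,
                        dx = -max_shift_px:max_shift_px)
    cand <- cand[order(cand$dy^2 + cand$dx^2), ]   # prefer small shifts on ties
    ref <- block_img(ca, 1)
    for (b in 2:n_blocks) {
      img <- block_img(ca, b)
      best <- c(0L, 0L); best_score <- -Inf
      for (k in seq_len(nrow(cand))) {
        sh <- shift_image(img, cand$dy[k], cand$dx[k])
        score <- sum(ref * sh)
        if (score > best_score) { best_score <- score; best <- c(cand$dy[k], cand$dx[k]) }
      }
      shifts[b, ] <- best
      ref <- ref + shift_image(img, best[1], best[2])
    }
  }

  aligned <- stack$counts
  if (any(shifts != 0)) {
    for (m in names(aligned)) {
      arr <- aligned[[m]]
      for (b in which(shifts[, 1] != 0 | shifts[, 2] != 0)) {
        for (g in which(block_of == b)) {
          arr[, , g] <- shift_image(arr[, , g], shifts[b, 1], shifts[b, 2])
        }
      }
      aligned[[m]] <- arr
    }
  }

  ## Common valid window across all applied shifts.
  r1 <- 1 + max(0, max(shifts[, 1])); r2 <- d[1] + min(0, min(shifts[, 1]))
  c1 <- 1 + max(0, max(shifts[, 2])); c2 <- d[2] + min(0, min(shifts[, 2]))
  if (r1 > r2 || c1 > c2) abort("Empty crop window: shifts exceed the frame.")
  if (r1 > 1 || r2 < d[1] || c1 > 1 || c2 < d[2]) {
    aligned <- lapply(aligned, function(a) a[r1:r2, c1:c2, , drop = FALSE])
  }

  out <- ion_image_stack(aligned, fov_um = stack$meta$fov_um * (c2 - c1 + 1) / d[2],
                         planes_per_page = ppp,
                         dwell_time_us = stack$meta$dwell_time_us,
                         session_id = stack$meta$session_id,
                         sample_id = stack$meta$sample_id)
  trace <- tibble::tibble(
    block = seq_len(n_blocks),
    plane_start = (vapply(seq_len(n_blocks), function(b) min(which(block_of == b)), 1L) - 1L) * ppp + 1L,
    plane_end = vapply(seq_len(n_blocks), function(b) max(which(block_of == b)), 1L) * ppp,
    dy = shifts[, 1], dx = shifts[, 2])
  list(stack = out, trace = trace)
}

## Integer translation with zero padding: out[y, x] = in[y - dy, x - dx].
shift_image <- function(mat, dy, dx) {
  if (dy == 0 && dx == 0) return(mat)
  out <- matrix(0L, nrow(mat), ncol(mat))
  ys <- seq_len(nrow(mat)); xs <- seq_len(ncol(mat))
  yd <- ys + dy; xd <- xs + dx
  ok_y <- yd >= 1 & yd <= nrow(mat); ok_x <- xd >= 1 & xd <= ncol(mat)
  out[yd[ok_y], xd[ok_x]] <- mat[ys[ok_y], xs[ok_x]]
  out
}

#' Accumulate a stack over a plane range
#'
#' Element-wise sum of each mass over the requested acquisition-plane range.
#'
#' @param stack An [ion_image_stack()].
#' @param planes `c(first, last)` acquisition planes (1-based, inclusive);
#'   default the full stack. Must fall on page boundaries when the stack is
#'   plane-binned.
#' @return Named list of integer matrices (class `accumulated_images`) with
#'   attributes `fov_um` and `planes`.
#' @export
accumulate <- function(stack, planes = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  d <- stack_dim(stack); ppp <- stack$meta$planes_per_page
  planes <- planes %||% c(1L, d[3] * ppp)
  stopifnot(length(planes) == 2, planes[1] >= 1, planes[2] >= planes[1],
            planes[2] <= d[3] * ppp)
  if ((planes[1] - 1) %% ppp != 0 || planes[2] %% ppp != 0) {
    abort("Plane range must align with the stack's page boundaries.")
  }
  g1 <- (planes[1] - 1) %/% ppp + 1; g2 <- planes[2] %/% ppp
  out <- lapply(stack$counts, function(a) {
    m <- rowSums(a[, , g1:g2, drop = FALSE], dims = 2)
    storage.mode(m) <- "integer"
    m
  })
  structure(out, class = "accumulated_images",
            fov_um = stack$meta$fov_um, planes = planes)
}

#' Segment accumulated images into coccolith, contaminant and background
#'
#' Coccolith ROIs are connected components of pixels whose accumulated 44Ca
#' count reaches the `ca_quantile` quantile of all nonzero-Ca pixels, kept
#' when at least `min_area_px` large. Potential contaminants are connected
#' components where any smoothed El/Ca accumulated-count ratio (El among
#' Na, Mg, K, Ba -- never Sr, which contaminant particles lack) exceeds
#' `enrichment_factor` times the median of that ratio over coccolith pixels.
#' Pixels satisfying both criteria are classed contaminant (conservative);
#' the pre-override coccolith label is retained in `labels_raw`.
#'
#' @param images An `accumulated_images` list (see [accumulate()]) or a
#'   named list of count matrices including `"44Ca"`.
#' @param ca_quantile Quantile of nonzero-Ca pixels defining the coccolith
#'   threshold (default 0.90).
#' @param enrichment_factor Ratio enrichment relative to the coccolith
#'   median flagging contamination (default 3; must exceed 1).
#' @param min_area_px Minimum ROI area in pixels (default 20).
#' @param min_signal_frac Noise guard of the ratio screen: a pixel counts as
#'   enriched only if its smoothed element signal is at least this fraction
#'   of the median smoothed element signal over coccolith pixels (default
#'   0.25). Guards the plug-in ratio against Poisson noise -- a single stray
#'   ion on the near-zero filter background exceeds any ratio threshold,
#'   whereas genuine salt/organic particles carry element counts comparable
#'   to the coccoliths' own. Being a fraction, it preserves invariance of
#'   the segmentation under global count rescaling.
#' @return A [roi_map()]. When no coccolith is found, an empty map with
#'   attribute `empty = TRUE` and a warning, not an error.
#' @export
segment <- function(images, ca_quantile = 0.90, enrichment_factor = 3,
                    min_area_px = 20, min_signal_frac = 0.25) {
  stopifnot(is.list(images), "44Ca" %in% names(images))
  stopifnot(ca_quantile > 0, ca_quantile < 1, enrichment_factor > 1)
  ca <- images[["44Ca"]]
  nz <- ca[ca > 0]
  empty_map <- function() {
    warn("No coccolith ROI found; returning an empty ROI map.")
    structure(roi_map(matrix(0L, nrow(ca), ncol(ca)), classes = character()),
              empty = TRUE)
  }
  if (length(nz) == 0) return(empty_map())
  thr <- as.numeric(quantile(nz, ca_quantile))
  lab <- EBImage::bwlabel(ca >= thr)
  areas <- tabulate(lab)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) return(empty_map())
  cocco <- matrix(0L, nrow(ca), ncol(ca))
  for (k in seq_along(keep)) cocco[lab == keep[k]] <- k
  n_cocco <- length(keep)

  ## Contaminant screen on smoothed accumulated ratio images. Sr is
  ## excluded by construction: contaminant particles show no Sr enrichment.
  mean3 <- function(x) EBImage::filter2(x, matrix(1 / 9, 3, 3),
                                        boundary = "replicate")
  ca_s <- mean3(ca)
  contam <- matrix(FALSE, nrow(ca), ncol(ca))
  for (el in intersect(c("23Na", "24Mg", "39K", "138Ba"), names(images))) {
    el_s <- mean3(images[[el]])
    ratio <- ifelse(ca_s > 0, el_s / ca_s, NA_real_)
    med <- median(ratio[cocco > 0], na.rm = TRUE)
    if (!is.finite(med) || med <= 0) next
    med_signal <- median(el_s[cocco > 0])
    contam <- contam | (!is.na(ratio) & ratio > enrichment_factor * med &
                          el_s >= min_signal_frac * med_signal)
  }
  clab <- EBImage::bwlabel(contam)
  careas <- tabulate(clab)
  ckeep <- which(careas >= min_area_px)

  labels <- cocco
  labels_raw <- matrix(0L, nrow(ca), ncol(ca))
  classes <- setNames(rep("coccolith", n_cocco), as.character(seq_len(n_cocco)))
  for (k in seq_along(ckeep)) {
    id <- n_cocco + k
    px <- clab == ckeep[k]
    labels_raw[px] <- cocco[px]        # remember any coccolith underneath
    labels[px] <- id
    classes[as.character(id)] <- "contaminant"
  }
  ## Coccolith components may have lost pixels to the contaminant override;
  ## drop those that fell below the minimum area.
  for (k in seq_len(n_cocco)) {
    if (sum(labels == k) < min_area_px) {
      labels_raw[labels == k] <- 0L
      labels[labels == k] <- 0L
      classes <- classes[names(classes) != as.character(k)]
    }
  }
  if (!any(classes == "coccolith")) return(empty_map())
  structure(roi_map(labels, classes, labels_raw), ca_threshold = thr)
}

#' Pixel mask of one ROI
#'
#' @param roi A [roi_map()].
#' @param label ROI label id.
#' @param exclude_contaminants When `FALSE`, pixels of this coccolith that
#'   were re-classed as contaminant are included again (the uncorrected
#'   region).
#' @return Logical matrix.
#' @export
roi_pixels <- function(roi, label, exclude_contaminants = TRUE) {
  m <- roi$labels == label
  if (!exclude_contaminants && !is.null(roi$labels_raw)) {
    m <- m | roi$labels_raw == label
  }
  m
}
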