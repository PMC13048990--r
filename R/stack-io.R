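#' Multi-mass ion-count image stack
#'
#' The raw object every stage consumes: one 3-D array of non-negative
#' integer counts per recorded mass, all sharing the same
#' rows x cols x pages shape, plus acquisition metadata. Pages normally hold
#' one acquisition plane each; `planes_per_page > 1` marks stacks whose
#' pages are sums over consecutive planes (see [generate_stack()]).
#'
#' @param counts Named list of integer arrays, `dim = c(rows, cols, pages)`,
#'   one per mass label (see [cocco_masses()]).
#' @param fov_um Physical raster width in micrometres.
#' @param planes_per_page Acquisition planes accumulated into each stored
#'   page (default 1).
#' @param dwell_time_us Dwell time per pixel in microseconds (default 1000).
#' @param session_id,sample_id Free-text identifiers.
#' @return An object of class `ion_stack`.
#' @export
ion_image_stack <- function(counts, fov_um, planes_per_page = 1L,
                            dwell_time_us = 1000, session_id = "",
                            sample_id = "") {
  if (!is.list(counts) || is.null(names(counts))) {
    abort("`counts` must be a named list of 3-D arrays.")
  }
  check_mass(names(counts), several = TRUE)
  dims <- lapply(counts, dim)
  if (any(vapply(dims, length, 1L) != 3)) {
    abort("Each counts entry must be a rows x cols x pages array.")
  }
  if (length(unique(dims)) != 1) {
    abort("All masses must share an identical rows x cols x pages shape.")
  }
  for (m in names(counts)) {
    x <- counts[[m]]
    if (any(x < 0) || any(x != round(x))) {
      abort(sprintf("Counts for mass %s must be non-negative integers.", m))
    }
    storage.mode(counts[[m]]) <- "integer"
  }
  d <- dims[[1]]
  structure(
    list(counts = counts,
         meta = list(fov_um = fov_um,
                     planes_per_page = as.integer(planes_per_page),
                     dwell_time_us = dwell_time_us,
                     session_id = session_id, sample_id = sample_id)),
    class = "ion_stack")
}

#' @export
print.ion_stack <- function(x, ...) {
  d <- dim(x$counts[[1]])
  cat(sprintf(
    "<ion_stack> %d x %d px, %d page(s) x %d plane(s), FOV %.3g um\n",
    d[1], d[2], d[3], x$meta$planes_per_page, x$meta$fov_um))
  cat("  masses:", paste(names(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ion_image_stack
#' @param stack An `ion_stack`.
#' @export
stack_dim <- function(stack) dim(stack$counts[[1]])

#' Total acquisition planes represented by a stack
#' @param stack An `ion_stack`.
#' @return Integer: pages times planes per page.
#' @export
n_planes <- function(stack) stack_dim(stack)[3] * stack$meta$planes_per_page

#' Write / read an ion-count stack directory
#'
#' One 16-bit multi-page TIFF per mass (page k = stored plane k; file
#' `<mass>.tif`) plus a JSON sidecar `stack.json` naming the masses and
#' carrying the acquisition metadata. The representation is lossless for
#' integer counts up to 65535 per pixel and page (NanoSIMS per-plane counts
#' are orders of magnitude smaller).
#'
#' @param stack An [ion_image_stack()].
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns a
#'   validated `ion_stack`.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "ion_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in names(stack$counts)) {
    x <- stack$counts[[m]]
    if (max(x) > 65535) {
      abort(sprintf("Counts for mass %s exceed the 16-bit TIFF limit.", m))
    }
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(m, ".tif")),
                    bits.per.sample = 16, compression = "deflate")
  }
  sidecar <- c(list(masses = names(stack$counts),
                    shape = dim(stack$counts[[1]])),
               stack$meta)
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  sidecar_path <- file.path(dir, "stack.json")
  if (!file.exists(sidecar_path)) {
    abort(sprintf("No stack.json sidecar found in '%s'.", dir))
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  counts <- list()
  for (m in side$masses) {
    f <- file.path(dir, paste0(m, ".tif"))
    if (!file.exists(f)) {
      abort(sprintf("Sidecar declares mass %s but '%s' is missing.", m, f))
    }
    pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    if (any(arr < 0)) abort(sprintf("Negative pixel values in mass %s.", m))
    counts[[m]] <- arr
  }
  shapes <- unique(lapply(counts, dim))
  if (length(shapes) != 1) abort("Shape mismatch across mass files.")
  ion_image_stack(counts,
                  fov_um = side$fov_um,
                  planes_per_page = side$planes_per_page %||% 1L,
                  dwell_time_us = side$dwell_time_us %||% 1000,
                  session_id = side$session_id %||% "",
                  sample_id = side$sample_id %||% "")
}

#' ROI label map with per-ROI classes
#'
#' Partitions the field of view into coccolith, contaminant and background
#' regions. `labels` is an integer image (0 = unassigned/background pixel);
#' `classes` maps each nonzero label to its class. Coccolith and contaminant
#' labels are disjoint pixel sets; where a contaminant overlaps a coccolith
#' the pixel is classed contaminant and `labels_raw` retains the coccolith
#' label it was carved out of (0 elsewhere), so the uncorrected region can
#' be reconstructed.
#'
#' @param labels Integer matrix of ROI labels.
#' @param classes Named character vector, names = label ids, values in
#'   `c("coccolith", "contaminant", "background")`.
#' @param labels_raw Optional integer matrix: for contaminant-classed pixels
#'   the coccolith label they overlapped, else 0.
#' @return An object of class `roi_map`.
#' @export
roi_map <- function(labels, classes, labels_raw = NULL) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 0) {
    missing <- setdiff(as.character(ids), names(classes))
    if (length(missing) > 0) {
      abort(sprintf("Labels without a class: %s.",
                    paste(missing, collapse = ", ")))
    }
  }
  bad <- setdiff(classes, c("coccolith", "contaminant", "background"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown ROI class(es): %s.", paste(bad, collapse = ", ")))
  }
  if (!is.null(labels_raw)) {
    stopifnot(all(dim(labels_raw) == dim(labels)))
    storage.mode(labels_raw) <- "integer"
  }
  structure(list(labels = labels, classes = classes, labels_raw = labels_raw),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  tab <- table(factor(x$classes, c("coccolith", "contaminant", "background")))
  cat(sprintf("<roi_map> %d x %d px: %d coccolith, %d contaminant, %d background ROI(s)\n",
              nrow(x$labels), ncol(x$labels),
              tab[["coccolith"]], tab[["contaminant"]], tab[["background"]]))
  invisible(x)
}

#' Labels of a given ROI class
#' @param roi A [roi_map()].
#' @param class ROI class to select.
#' @return Integer vector of label ids.
#' @export
roi_labels <- function(roi, class = "coccolith") {
  as.integer(names(roi$classes)[roi$classes == class])
}

#' Write / read an ROI map
#'
#' Stored as a single- or two-page 16-bit integer TIFF (`<path>.tif`: page 1
#' labels, page 2 the pre-override coccolith labels when present) plus a
#' JSON class map (`<path>.json`).
#'
#' @param roi A [roi_map()].
#' @param path File path without extension.
#' @export
write_roi_map <- function(roi, path) {
  stopifnot(inherits(roi, "roi_map"))
  pages <- list(roi$labels / 65535)
  if (!is.null(roi$labels_raw)) pages <- c(pages, list(roi$labels_raw / 65535))
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 16,
                  compression = "deflate")
  jsonlite::write_json(list(classes = as.list(roi$classes),
                            has_raw = !is.null(roi$labels_raw)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_map
#' @export
read_roi_map <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  roi_map(pages[[1]],
          classes = unlist(side$classes),
          labels_raw = if (isTRUE(side$has_raw)) pages[[2]] else NULL)
}

## Stable schema of the per-coccolith results table (long format: one row
## per coccolith x element).
results_schema <- c(
  "sample_id", "roi_label", "element", "ion_ratio", "precision_cv",
  "poisson_cv", "molar_ratio", "molar_uncertainty", "planes_used",
  "pixels_used", "gated_fraction", "flag_unstable",
  "flag_surface_contaminated", "flag_low_precision")

#' Write / read per-coccolith results tables
#'
#' Comma-separated, UTF-8, `"."` decimal; one row per coccolith and element.
#' Numeric fields are written at full precision so a write/read round trip
#' is the identity. `read_results()` checks the documented schema and fails
#' on malformed files.
#'
#' @param results A tibble of per-coccolith results ([quantify_stack()]).
#' @param path CSV file path.
#' @return `read_results()` returns a tibble.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  missing <- setdiff(results_schema, names(results))
  if (length(missing) > 0) {
    abort(sprintf("Results table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(results, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such results file: '%s'.", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(results_schema, names(out))
  if (length(missing) > 0) {
    abort(sprintf("Malformed results CSV, missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out
}

#' Empty results table with the documented schema
#' @return A zero-row tibble with the stable column set.
#' @export
empty_results <- function() {
  tibble::tibble(
    sample_id = character(), roi_label = integer(), element = character(),
    ion_ratio = double(), precision_cv = double(), poisson_cv = double(),
    molar_ratio = double(), molar_uncertainty = double(),
    planes_used = integer(), pixels_used = integer(),
    gated_fraction = double(), flag_unstable = logical(),
    flag_surface_contaminated = logical(), flag_low_precision = logical())
}
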