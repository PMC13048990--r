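#' Within- versus among-coccolith variability of one element
#'
#' Decomposes the variability of an El/Ca ion-count ratio into the
#' within-coccolith component (the per-lith residual depth CVs passed
#' through from the QC stage) and the among-coccolith component (the
#' n-1 CV of the per-lith ratios within each sample). Samples whose
#' among-lith CV exceeds 1 are flagged.
#'
#' @param table Results tibble (the [write_results()] schema), one row per
#'   coccolith and element, with a `sample_id` grouping column.
#' @param element Element mass label to decompose.
#' @param group Name of the grouping column (default `"sample_id"`).
#' @return List of class `cv_decomposition`: `$within` (one row per lith:
#'   group, roi_label, cv) and `$among` (one row per group: n, among CV,
#'   `exceeds_one` flag).
#' @export
cv_decomposition <- function(table, element, group = "sample_id") {
  stopifnot(is.data.frame(table), group %in% names(table))
  sub <- table[table$element == element, , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("No rows for element %s.", element))
  sub$group <- sub[[group]]
  within <- sub |>
    dplyr::select(group = "group", roi_label = "roi_label",
                  cv = "precision_cv") |>
    tibble::as_tibble()
  among <- sub |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      among_lith_cv = sd(.data$ion_ratio) / mean(.data$ion_ratio),
      .groups = "drop") |>
    dplyr::mutate(exceeds_one = .data$among_lith_cv > 1)
  if (any(among$n < 2)) {
    warn("Groups with fewer than 2 coccoliths yield an undefined among-lith CV.")
  }
  structure(list(within = within, among = among, element = element),
            class = "cv_decomposition")
}

#' @export
print.cv_decomposition <- function(x, ...) {
  cat(sprintf("<cv_decomposition> %s: %d group(s)\n", x$element,
              nrow(x$among)))
  print(x$among)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Ion-count ratios are skewed towards high values, so group comparisons
#' run on natural-log-transformed ratios: one-way ANOVA across groups
#' followed by Tukey's honest-significant-difference test on all pairs
#' (studentized-range distribution; Tukey--Kramer for unequal group sizes).
#' Groups are then labelled with a compact letter display built by
#' insert-and-absorb: two groups share a letter iff their pairwise adjusted
#' p-value is at least `alpha`.
#'
#' Rows with non-positive ratios cannot be log-transformed and are dropped
#' with a warning reporting the count.
#'
#' @param table Results tibble with `element`, `ion_ratio` and a grouping
#'   column.
#' @param element Element mass label to test.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param group Name of the grouping column (default `"sample_id"`).
#' @return Object of class `tukey_grouping`: `$groups` (group, n, mean of
#'   log ratios, raw-scale mean and SE, letters), `$pairs` (pairwise
#'   differences of log means with Tukey-adjusted p), `$anova` (F statistic,
#'   degrees of freedom, p), `$alpha`.
#' @export
anova_tukey <- function(table, element, alpha = 0.05, group = "sample_id") {
  stopifnot(is.data.frame(table), group %in% names(table))
  sub <- table[table$element == element, , drop = FALSE]
  n_bad <- sum(!(sub$ion_ratio > 0) | !is.finite(sub$ion_ratio))
  if (n_bad > 0) {
    warn(sprintf("%d row(s) with non-positive ratios excluded from the log-scale ANOVA.",
                 n_bad))
    sub <- sub[sub$ion_ratio > 0 & is.finite(sub$ion_ratio), , drop = FALSE]
  }
  sub$group <- factor(sub[[group]])
  counts <- table(sub$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("At least 2 groups with at least 2 coccoliths each are required.")
  }
  sub$log_ratio <- log(sub$ion_ratio)

  fit <- aov(log_ratio ~ group, data = sub)
  an <- suppressWarnings(anova(fit))   # perfect fits warn; handled below
  ## residual mean square at floating-point noise level => exact separation
  degenerate <- an[["Mean Sq"]][2] <= sqrt(.Machine$double.eps) *
    an[["Mean Sq"]][1] || !is.finite(an[["F value"]][1])
  if (degenerate) {
    warn("Zero within-group variance: groups separated exactly; letters reflect exact separation.")
    pmat <- outer(tapply(sub$log_ratio, sub$group, mean),
                  tapply(sub$log_ratio, sub$group, mean),
                  function(a, b) ifelse(a == b, 1, 0))
    pairs <- NULL
  } else {
    tk <- TukeyHSD(fit, "group")$group
    nm <- rownames(tk)
    parts <- strsplit(nm, "-", fixed = TRUE)
    pairs <- tibble::tibble(
      group1 = vapply(parts, `[`, "", 1),
      group2 = vapply(parts, `[`, "", 2),
      diff_log = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"]))
    lev <- levels(sub$group)
    pmat <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
    for (k in seq_len(nrow(pairs))) {
      pmat[pairs$group1[k], pairs$group2[k]] <- pairs$p_adj[k]
      pmat[pairs$group2[k], pairs$group1[k]] <- pairs$p_adj[k]
    }
  }

  letters_by_group <- cld_insert_absorb(pmat, alpha)
  groups <- sub |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_log = mean(.data$log_ratio),
                     mean = mean(.data$ion_ratio),
                     se = sd(.data$ion_ratio) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(letters = unname(letters_by_group[as.character(.data$group)]))

  structure(
    list(element = element, groups = groups, pairs = pairs,
         anova = tibble::tibble(
           statistic = an[["F value"]][1],
           df_between = an[["Df"]][1], df_within = an[["Df"]][2],
           p_value = an[["Pr(>F)"]][1]),
         alpha = alpha, degenerate = degenerate),
    class = "tukey_grouping")
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat(sprintf("<tukey_grouping> %s: F(%d, %d) = %.3g, p = %.3g, alpha = %g\n",
              x$element, x$anova$df_between, x$anova$df_within,
              x$anova$statistic, x$anova$p_value, x$alpha))
  print(x$groups)
  invisible(x)
}

## Compact letter display by insert-and-absorb: start from one class holding
## all groups; for every significant pair split each class containing both;
## absorb classes that became subsets of others; assign letters in order of
## first appearance. Two groups share a letter iff not significantly
## different.
cld_insert_absorb <- function(pmat, alpha) {
  groups <- rownames(pmat)
  classes <- list(groups)
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig) > 0) {
    for (k in seq_len(nrow(sig))) {
      g1 <- groups[sig[k, 1]]; g2 <- groups[sig[k, 2]]
      new_classes <- list()
      for (cl in classes) {
        if (g1 %in% cl && g2 %in% cl) {
          new_classes <- c(new_classes, list(setdiff(cl, g1)),
                           list(setdiff(cl, g2)))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      ## absorb: drop classes that are subsets of another class
      keep <- rep(TRUE, length(new_classes))
      for (i in seq_along(new_classes)) {
        for (j in seq_along(new_classes)) {
          if (i != j && keep[j] &&
              all(new_classes[[i]] %in% new_classes[[j]]) &&
              (length(new_classes[[i]]) < length(new_classes[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      classes <- new_classes[keep]
    }
  }
  ## order classes by the position of their best-ranked member for stable,
  ## readable letters, then assign
  ord <- order(vapply(classes, function(cl) min(match(cl, groups)), 1))
  classes <- classes[ord]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(classes)) {
    for (g in classes[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Correlation screen of log-ratios against covariates
#'
#' Pearson correlations between natural-log-transformed per-coccolith El/Ca
#' ion-count ratios and environmental covariates, with two-sided t-test
#' p-values and a significance flag at p < 0.05. Covariates are defined per
#' group (station or culture) and mapped onto the individual coccoliths, so
#' the effective replication is at the coccolith level; no multiple-testing
#' adjustment is applied.
#'
#' @param table Results tibble with `element`, `ion_ratio` and a grouping
#'   column.
#' @param covariates Tibble with the grouping column plus one numeric
#'   column per covariate.
#' @param elements Elements to test (default: all present).
#' @param group Name of the grouping column (default `"sample_id"`).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Tibble: element, covariate, n, r, p_value, significant.
#' @export
correlation_matrix <- function(table, covariates, elements = NULL,
                               group = "sample_id", alpha = 0.05) {
  stopifnot(is.data.frame(table), is.data.frame(covariates),
            group %in% names(table), group %in% names(covariates))
  elements <- elements %||% unique(table$element)
  covar_names <- setdiff(names(covariates), group)
  merged <- dplyr::inner_join(
    table[table$element %in% elements,
          c(group, "element", "ion_ratio")],
    covariates, by = group)
  merged <- merged[merged$ion_ratio > 0 & is.finite(merged$ion_ratio), ]
  grid <- tidyr::expand_grid(element = elements, covariate = covar_names)
  purrr::pmap_dfr(grid, function(element, covariate) {
    sub <- merged[merged$element == element, ]
    x <- log(sub$ion_ratio); y <- sub[[covariate]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      abort(sprintf("Fewer than 3 complete pairs for %s vs %s.",
                    element, covariate))
    }
    if (sd(y[ok]) == 0 || sd(x[ok]) == 0) {
      return(tibble::tibble(element = element, covariate = covariate,
                            n = sum(ok), r = NA_real_, p_value = NA_real_,
                            significant = NA))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(element = element, covariate = covariate, n = sum(ok),
                   r = unname(ct$estimate), p_value = ct$p.value,
                   significant = ct$p.value < alpha)
  })
}

#' Specific growth rate from a cell-density time series
#'
#' Ordinary least-squares slope of the natural log of cell density against
#' time: the specific growth rate of an exponentially growing batch culture,
#' in per-day units when `times_days` is in days.
#'
#' @param times_days Numeric vector of sampling times (days), length >= 3.
#' @param cell_densities Positive cell densities at those times.
#' @return Object of class `growth_fit`: `mu_per_day`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
growth_rate <- function(times_days, cell_densities) {
  if (length(times_days) < 3) {
    abort("At least 3 time points are required for a growth-rate regression.")
  }
  stopifnot(length(times_days) == length(cell_densities))
  if (any(!is.finite(cell_densities)) || any(cell_densities <= 0)) {
    abort("All cell densities must be positive.")
  }
  fit <- lm(log(cell_densities) ~ times_days)
  structure(
    list(mu_per_day = unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         n = length(times_days), fit = fit),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu = %.4g d^-1, R^2 = %.4f, n = %d\n",
              x$mu_per_day, x$r_squared, x$n))
  invisible(x)
}
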