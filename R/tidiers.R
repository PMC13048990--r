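#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the pairwise comparisons of a Tukey grouping
#'
#' @param x A [anova_tukey()] result.
#' @param ... Unused.
#' @return Tibble of pairwise contrasts: `group1`, `group2`, `diff_log`
#'   (difference of log-ratio means), `p_adj` (Tukey-adjusted p).
#' @export
tidy.tukey_grouping <- function(x, ...) {
  if (is.null(x$pairs)) {
    return(tibble::tibble(group1 = character(), group2 = character(),
                          diff_log = double(), p_adj = double()))
  }
  tibble::as_tibble(x$pairs)
}

#' @rdname tidy.tukey_grouping
#' @export
glance.tukey_grouping <- function(x, ...) x$anova

#' Tidy a growth-rate fit
#'
#' @param x A [growth_rate()] result.
#' @param ... Unused.
#' @return `tidy()`: the term-level coefficients of the log-linear fit;
#'   `glance()`: one row with `mu_per_day`, `r_squared`, `n`.
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(mu_per_day = x$mu_per_day, r_squared = x$r_squared, n = x$n)
}

#' @export
tidy.cv_decomposition <- function(x, ...) x$among
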