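# Automated-vs-manual comparison and contrasting-phenotype screening.

#' Pair automated and manual measurements of one trait
#'
#' @param x Manual / reference values.
#' @param y Automated values (same length, same units).
#' @param ids Unit identifiers (image or stoma ids).
#' @param trait Trait name.
#' @param units Measurement units label.
#' @return Object of class `paired_measurements`.
#' @export
paired_measurements <- function(x, y, ids = seq_along(x),
                                trait = "trait", units = "") {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_stomapipe("paired measurements need equal lengths >= 2",
                   "stomapipe_config_error")
  }
  keep <- is.finite(x) & is.finite(y)
  structure(
    list(ids = ids[keep], x = x[keep], y = y[keep],
         trait = trait, units = units),
    class = "paired_measurements"
  )
}

#' Ordinary least-squares regression of automated on manual values
#'
#' Fits `y ~ x` with intercept and reports slope, intercept, the coefficient
#' of determination `R^2 = 1 - SS_res / SS_tot`, and n. The regression
#' direction (automated on manual) keeps calibration bias visible in the
#' slope and intercept even when R^2 is high.
#'
#' @param pairs A [paired_measurements()] object, or manual values when `y`
#'   is given.
#' @param y Automated values (when `pairs` is a numeric vector).
#' @return List of class `regression_result`: `slope, intercept, r2, n`.
#' @export
fit_regression <- function(pairs, y = NULL) {
  if (!inherits(pairs, "paired_measurements")) {
    pairs <- paired_measurements(pairs, y)
  }
  x <- pairs$x
  yy <- pairs$y
  if (length(x) < 3L) {
    stop_stomapipe("regression needs at least 3 finite pairs",
                   "stomapipe_fit_error")
  }
  if (stats::var(x) == 0) {
    stop_stomapipe("manual values are constant; regression undefined",
                   "stomapipe_fit_error")
  }
  fit <- lm(yy ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((yy - mean(yy))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n = length(x), trait = pairs$trait, units = pairs$units),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result %s: y = %.4f x + %.4f, R^2 = %.4f, n = %d>\n",
    x$trait, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Regression comparison of two trait tables
#'
#' Joins automated and manual per-image trait tables on `image_id` and fits
#' [fit_regression()] for each requested trait column.
#'
#' @param automated,manual Data frames with `image_id` and trait columns.
#' @param traits Character vector of trait column names present in both.
#' @return Data frame `trait, n, slope, intercept, r2`.
#' @export
compare_traits <- function(automated, manual, traits) {
  rows <- lapply(traits, function(tr) {
    stopifnot(tr %in% names(automated), tr %in% names(manual))
    m <- merge(manual[, c("image_id", tr)], automated[, c("image_id", tr)],
               by = "image_id", suffixes = c("_manual", "_auto"))
    pr <- paired_measurements(m[[paste0(tr, "_manual")]],
                              m[[paste0(tr, "_auto")]],
                              ids = m$image_id, trait = tr)
    fit <- fit_regression(pr)
    data.frame(trait = tr, n = fit$n, slope = fit$slope,
               intercept = fit$intercept, r2 = fit$r2)
  })
  do.call(rbind, rows)
}

# Spearman-type rank correlation via explicit rank transform.
rank_correlation <- function(a, b) {
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  ra <- rank(a)
  rb <- rank(b)
  stats::cor(ra, rb)
}

#' Screen an image cohort for contrasting density / size phenotypes
#'
#' Ranks per-image summaries by stomatal density and reports the top and
#' bottom quantile groups with their density and mean-size statistics, plus
#' the rank correlation between density and mean complex area across all
#' units - surfacing the density-size trade-off (many small stomata vs few
#' large ones).
#'
#' @param summaries Data frame of per-image summaries ([summarize_image()]):
#'   needs `image_id`, `density_mm2`, `mean_complex_area_um2`.
#' @param quantile Tail fraction in (0, 0.5); default 0.2.
#' @return List of class `contrast_report`: `high`, `low` (data frames),
#'   `rank_correlation`, `group_size`, plus per-group mean density and size.
#' @export
screen_contrasts <- function(summaries, quantile = 0.2) {
  if (quantile <= 0 || quantile >= 0.5) {
    stop_stomapipe("quantile must lie in (0, 0.5)", "stomapipe_config_error")
  }
  n <- nrow(summaries)
  total <- ceiling(2 * quantile * n)
  n_high <- ceiling(total / 2)
  n_low <- total - n_high
  if (n < 2L || n_high < 1L || n_low < 1L || total > n) {
    stop_stomapipe("need at least 2 units per tail group",
                   "stomapipe_config_error")
  }
  ord <- order(-summaries$density_mm2, summaries$image_id)
  high <- summaries[ord[seq_len(n_high)], , drop = FALSE]
  low <- summaries[rev(ord)[seq_len(n_low)], , drop = FALSE]
  rc <- rank_correlation(summaries$density_mm2,
                         summaries$mean_complex_area_um2)
  structure(
    list(high = high, low = low,
         rank_correlation = rc,
         group_size = c(high = n_high, low = n_low),
         high_mean_density = mean(high$density_mm2),
         low_mean_density = mean(low$density_mm2),
         high_mean_area = mean(high$mean_complex_area_um2),
         low_mean_area = mean(low$mean_complex_area_um2)),
    class = "contrast_report"
  )
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf(
    "<contrast_report: high group n=%d (%.1f per mm^2), low group n=%d (%.1f per mm^2), density-size rank correlation %.3f>\n",
    x$group_size["high"], x$high_mean_density,
    x$group_size["low"], x$low_mean_density,
    if (is.na(x$rank_correlation)) NA else x$rank_correlation))
  invisible(x)
}
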