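#' Build a table of paired predicted and manual counts
#'
#' @param sample_id sample barcodes.
#' @param predicted_count,manual_count non-negative counts.
#' @param method method label (e.g. `"edge"`), recycled.
#' @return data frame of class `count_records`.
#' @export
count_records <- function(sample_id, predicted_count, manual_count,
                          method = "edge") {
  stopifnot(length(predicted_count) == length(sample_id),
            length(manual_count) == length(sample_id),
            all(predicted_count >= 0), all(manual_count >= 0))
  structure(data.frame(sample_id = as.character(sample_id),
                       predicted_count = as.numeric(predicted_count),
                       manual_count = as.numeric(manual_count),
                       method = rep_len(as.character(method), length(sample_id))),
            class = c("count_records", "data.frame"))
}

#' Normalized RMSE as a percentage
#'
#' `100 * rmse / truth_range`, the scale-adjusted error used throughout
#' the evaluation: the normalizer is the ground-truth count range of the
#' sample set (or density stratum) being evaluated.
#'
#' @param rmse root mean squared error.
#' @param truth_range max minus min of the manual counts.
#' @return NRMSE in percent.
#' @examples
#' round(nrmse_pct(8.45, 128), 2)   # 6.60
#' round(nrmse_pct(83.33, 553), 2)  # 15.07
#' @export
nrmse_pct <- function(rmse, truth_range) {
  stopifnot(rmse >= 0)
  if (any(truth_range <= 0)) stop("truth_range must be positive")
  100 * rmse / truth_range
}

#' Counting-accuracy regression report
#'
#' Ordinary least squares of predicted on manual counts, with the error
#' metrics used to compare counting methods: R-squared (the OLS fit's
#' coefficient of determination), RMSE, NRMSE (percent of the manual-count
#' range), MAPE (percent, over records with manual > 0), MAE and bias
#' (mean signed error; negative = undercounting). An identity-line
#' R-squared (`1 - SS(pred - manual) / SS_tot`) is also reported for
#' reference against the y = x line.
#'
#' @param records a [count_records()] data frame (n >= 3, manual counts
#'   not all equal).
#' @return object of class `count_regression`: list with `n`, `slope`,
#'   `intercept`, `r2`, `r2_identity`, `rmse`, `nrmse_pct`, `mape_pct`,
#'   `mae`, `bias`, `truth_range`, `method`.
#' @examples
#' r <- count_records(1:5, c(11, 19, 32, 38, 52), c(10, 20, 30, 40, 50))
#' regress(r)
#' @export
regress <- function(records) {
  p <- records$predicted_count; m <- records$manual_count
  n <- length(m)
  if (n < 3) stop("regression needs at least 3 records")
  if (max(m) == min(m)) stop("degenerate ground truth: all manual counts equal")
  fit <- stats::lm(p ~ m)
  err <- p - m
  rmse <- sqrt(mean(err^2))
  truth_range <- max(m) - min(m)
  pos <- m > 0
  if (any(!pos))
    warning(sum(!pos), " record(s) with manual count 0 excluded from MAPE")
  mape <- if (any(pos)) 100 * mean(abs(err[pos]) / m[pos]) else NA_real_
  sst <- sum((p - mean(p))^2)
  structure(list(
    n = n,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    r2_identity = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
    rmse = rmse,
    nrmse_pct = nrmse_pct(rmse, truth_range),
    mape_pct = mape,
    mae = mean(abs(err)),
    bias = mean(err),
    truth_range = truth_range,
    method = if (!is.null(records$method)) records$method[1] else NA_character_,
    records = records),
    class = "count_regression")
}

#' @export
print.count_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Counting accuracy (%s), n = %d, manual-count range = %g\n",
              x$method, x$n, x$truth_range))
  cat(sprintf("  fit: predicted = %.*f + %.*f * manual,  R^2 = %.*f\n",
              digits, x$intercept, digits, x$slope, digits, x$r2))
  cat(sprintf("  RMSE %.*f  NRMSE %.*f%%  MAPE %.*f%%  MAE %.*f  bias %+.*f\n",
              digits, x$rmse, digits, x$nrmse_pct, digits, x$mape_pct,
              digits, x$mae, digits, x$bias))
  invisible(x)
}

#' @export
plot.count_regression <- function(x, ...) {
  r <- x$records
  lim <- range(0, r$manual_count, r$predicted_count)
  graphics::plot(r$manual_count, r$predicted_count, xlim = lim, ylim = lim,
                 xlab = "Manual count", ylab = "Predicted count",
                 pch = 19, col = grDevices::adjustcolor("darkgreen", 0.6), ...)
  graphics::abline(0, 1, lty = 3, col = "gray40")
  graphics::abline(x$intercept, x$slope, col = "darkgreen")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("R² = %.2f, n = %d", x$r2, x$n))
  invisible(x)
}

#' Density-stratified regression reports
#'
#' Groups records by the density regime of their manual counts
#' ([regime_of()]: low < 150, medium 150-400, high > 400) and fits a
#' [regress()] report per occupied stratum. Strata with fewer than `min_n`
#' records are reported with `NA` metrics and flagged.
#'
#' @param records a [count_records()] data frame.
#' @param min_n minimum records per stratum for a fit (default 3).
#' @return named list (subset of `low`, `medium`, `high`) of
#'   `count_regression` objects or low-n placeholders.
#' @export
stratified_report <- function(records, min_n = 3) {
  reg <- regime_of(records$manual_count)
  out <- list()
  for (lev in levels(reg)) {
    sel <- reg == lev
    k <- sum(sel)
    if (k == 0) {
      warning("no records in the ", lev, "-density stratum; omitted")
      next
    }
    sub <- records[sel, , drop = FALSE]
    if (k < min_n || max(sub$manual_count) == min(sub$manual_count)) {
      warning(lev, "-density stratum has too few records for a fit (n = ",
              k, "); metrics set NA")
      out[[lev]] <- structure(list(n = k, slope = NA, intercept = NA, r2 = NA,
                                   r2_identity = NA, rmse = NA, nrmse_pct = NA,
                                   mape_pct = NA, mae = NA, bias = NA,
                                   truth_range = NA, low_n = TRUE,
                                   method = sub$method[1], records = sub),
                              class = "count_regression")
    } else {
      out[[lev]] <- regress(sub)
    }
  }
  out
}

#' Population distribution summary
#'
#' Quantiles (linear-interpolation convention), extremes, Fisher-Pearson
#' moment skewness g1 = m3 / m2^(3/2), and kurtosis in both conventions:
#' Pearson (m4 / m2^2; normal = 3, the headline value) and excess
#' (Pearson - 3). A histogram with a configurable number of bins is
#' included for plotting.
#'
#' @param counts numeric vector of per-plant counts, n >= 4.
#' @param bins number of histogram bins.
#' @return object of class `population_summary`: list with `n`, `min`,
#'   `q25`, `median`, `q75`, `max`, `skewness`, `kurtosis` (Pearson),
#'   `kurtosis_excess`, `histogram` (list `breaks`, `counts`).
#' @examples
#' population_summary(c(1, 2, 3, 4, 5))$skewness  # 0 by symmetry
#' @export
population_summary <- function(counts, bins = 20) {
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 4) stop("need at least 4 observations for fourth-moment statistics")
  m <- mean(counts)
  m2 <- mean((counts - m)^2)
  m3 <- mean((counts - m)^3)
  m4 <- mean((counts - m)^4)
  if (m2 == 0) stop("zero variance: distribution summary undefined")
  q <- unname(stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7))
  h <- graphics::hist(counts, breaks = seq(min(counts), max(counts),
                                           length.out = bins + 1),
                      plot = FALSE, include.lowest = TRUE)
  structure(list(n = n, min = min(counts), q25 = q[1], median = q[2],
                 q75 = q[3], max = max(counts),
                 skewness = m3 / m2^1.5,
                 kurtosis = m4 / m2^2,
                 kurtosis_excess = m4 / m2^2 - 3,
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Population counts: n = %d, range %g-%g\n", x$n, x$min, x$max))
  cat(sprintf("  quartiles %g / %g / %g (25th / median / 75th)\n",
              round(x$q25, digits), round(x$median, digits), round(x$q75, digits)))
  cat(sprintf("  skewness %.*f, kurtosis %.*f (excess %+.*f)\n",
              digits, x$skewness, digits, x$kurtosis, digits, x$kurtosis_excess))
  invisible(x)
}

#' @export
plot.population_summary <- function(x, ...) {
  graphics::plot(NULL, xlim = range(x$histogram$breaks),
                 ylim = c(0, max(x$histogram$counts)),
                 xlab = "Tiller count", ylab = "Frequency", ...)
  graphics::rect(utils::head(x$histogram$breaks, -1), 0,
                 x$histogram$breaks[-1], x$histogram$counts,
                 col = "darkseagreen3", border = "white")
  invisible(x)
}
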