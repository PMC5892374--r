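#' Restrict a time stack to a seasonal calendar window
#'
#' Keeps only observations whose month-day falls inside the window
#' (inclusive on both ends; the default is the July 1 - August 30 peak
#' growing season). An empty result is allowed; downstream trend mapping
#' handles low observation counts via its `min_obs` rule.
#'
#' @param stack an `ndvi_stack`.
#' @param start,end window bounds as `"MM-DD"` strings.
#' @return the filtered `ndvi_stack`.
#' @export
seasonal_filter <- function(stack, start = "07-01", end = "08-30") {
  md <- format(stack$dates, "%m-%d")
  keep <- md >= start & md <= end
  stack$dates <- stack$dates[keep]
  stack$dec_years <- stack$dec_years[keep]
  stack$sensors <- stack$sensors[keep]
  stack$ndvi <- stack$ndvi[, , keep, drop = FALSE]
  stack$valid <- stack$valid[, , keep, drop = FALSE]
  stack
}

#' Theil-Sen robust trend of a single series
#'
#' The slope is the median of all pairwise slopes `(y_j - y_i)/(t_j - t_i)`
#' over pairs with distinct times; the intercept is the median of
#' `y_i - slope * (t_i - ref_year)`, i.e. the fitted NDVI level at the
#' reference year. The two-sided `1 - alpha` confidence interval of the
#' slope is rank-based (Sen/Kendall): with `N` pairwise slopes and Kendall's
#' `var(S) = n(n-1)(2n+5)/18` (corrected for tied times), the bounds are the
#' slopes of rank `(N - C)/2` and `(N + C)/2 + 1` in the sorted slope list,
#' where `C = z[1-alpha/2] * sqrt(var(S))`.
#'
#' @param times numeric times (decimal years) or `Date`s.
#' @param values numeric observations.
#' @param ref_year reference year for the intercept (default 2014).
#' @param alpha two-sided CI level is `1 - alpha`.
#' @return named list `slope`, `intercept`, `ci_low`, `ci_high`, `n_pairs`;
#'   all-`NA` when fewer than two distinct times are available.
#' @export
#' @examples
#' theil_sen(0:2, c(0, 1, 10), ref_year = 0)$slope  # median of {1, 5, 9} = 5
theil_sen <- function(times, values, ref_year = 2014, alpha = 0.05) {
  if (inherits(times, "Date")) times <- decimal_year(times)
  if (length(times) != length(values)) stop("times and values lengths differ")
  ok <- is.finite(times) & is.finite(values)
  res <- cpp_theil_sen(times[ok], values[ok], ref_year, alpha)
  as.list(res)
}

#' Per-pixel Theil-Sen trend map
#'
#' Applies [theil_sen()] to the valid observations of every pixel of a
#' masked NDVI time stack. Pixels with fewer than `min_obs` valid
#' observations get nodata. Output layers follow the published band order:
#' slope (NDVI per year; multiply by `per_decade = TRUE` to report per
#' decade), intercept (NDVI at the reference year), then upper and lower
#' 95% confidence bounds of the slope.
#'
#' @param stack an `ndvi_stack` (already seasonally filtered if desired).
#' @param min_obs minimum valid observations per pixel (default 10).
#' @param ref_year intercept reference year; defaults to the stack's.
#' @param alpha CI level.
#' @param per_decade report slopes (and their CIs) per decade instead of per
#'   year.
#' @return A `trend_raster`: list of matrices `slope`, `intercept`,
#'   `ci_upper`, `ci_lower`, `n_valid`.
#' @export
trend_map <- function(stack, min_obs = 10, ref_year = stack$ref_year,
                      alpha = 0.05, per_decade = FALSE) {
  if (min_obs < 2) stop("min_obs must be >= 2")
  d <- dim(stack$ndvi)
  vals <- matrix(stack$ndvi, d[1] * d[2], d[3])
  ok <- matrix(stack$valid, d[1] * d[2], d[3])
  res <- cpp_trend_stack(vals, ok, stack$dec_years, ref_year, alpha,
                         as.integer(min_obs))
  shape <- function(k) matrix(res[, k], d[1], d[2])
  scl <- if (per_decade) 10 else 1
  structure(list(slope = shape(1) * scl, intercept = shape(2),
                 ci_upper = shape(3) * scl, ci_lower = shape(4) * scl,
                 n_valid = shape(5), ref_year = ref_year,
                 units = if (per_decade) "NDVI/decade" else "NDVI/yr"),
            class = "trend_raster")
}

#' @export
print.trend_raster <- function(x, ...) {
  cat(sprintf("trend_raster: %d x %d pixels, %d with trend (%s)\n",
              nrow(x$slope), ncol(x$slope), sum(!is.na(x$slope)), x$units))
  invisible(x)
}

#' Inter-sensor NDVI bias diagnostics
#'
#' For every year observed by both the reference sensor and another sensor,
#' computes the regional mean (and sd) NDVI per sensor over all valid
#' observations, then fits a least-squares line of the non-reference yearly
#' means against the reference means. Deviation of the fit from the 1:1
#' line summarizes the bias. Because the fitted line is ill-conditioned when
#' yearly means barely vary, two direct summaries are reported alongside it:
#' `mean_bias`, the average difference of paired yearly means (estimates an
#' additive offset), and `gain`, the ratio of mean levels (estimates a
#' multiplicative bias).
#'
#' @param stack an `ndvi_stack`.
#' @param reference reference sensor tag (default `"ETM+"`).
#' @return list with `yearly` (year x sensor means/sds) and `bias` (one row
#'   per non-reference sensor: `slope`, `intercept`, `mean_bias`,
#'   `n_years`).
#' @export
sensor_bias <- function(stack, reference = "ETM+") {
  sensors <- unique(stack$sensors)
  if (!(reference %in% sensors)) stop("reference sensor not present in stack")
  if (length(sensors) < 2) stop("need at least two sensors for bias analysis")
  years <- as.integer(format(stack$dates, "%Y"))
  d <- dim(stack$ndvi)
  yearly <- list()
  for (y in unique(years)) {
    for (s in unique(stack$sensors[years == y])) {
      k <- which(years == y & stack$sensors == s)
      v <- stack$ndvi[, , k, drop = FALSE]
      m <- stack$valid[, , k, drop = FALSE]
      vals <- v[m]
      yearly[[length(yearly) + 1]] <-
        data.frame(year = y, sensor = s, mean_ndvi = mean(vals),
                   sd_ndvi = stats::sd(vals), n_obs = length(vals))
    }
  }
  yearly <- do.call(rbind, yearly)
  bias <- list()
  for (s in setdiff(sensors, reference)) {
    a <- yearly[yearly$sensor == s, ]
    b <- yearly[yearly$sensor == reference, ]
    common <- intersect(a$year, b$year)
    if (!length(common))
      stop("no overlapping years between ", s, " and ", reference)
    x <- b$mean_ndvi[match(common, b$year)]
    y <- a$mean_ndvi[match(common, a$year)]
    fit <- if (length(common) >= 2) stats::coef(stats::lm(y ~ x))
           else c(`(Intercept)` = NA_real_, x = NA_real_)
    bias[[s]] <- data.frame(sensor = s, reference = reference,
                            slope = unname(fit[2]),
                            intercept = unname(fit[1]),
                            mean_bias = mean(y - x),
                            gain = mean(y) / mean(x),
                            n_years = length(common))
  }
  bias <- do.call(rbind, bias)
  rownames(bias) <- NULL
  list(yearly = yearly, bias = bias)
}
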