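# Covariate construction: survey date, size-scaled conspecific density, and
# 3-day mean temperature.  Covariates are z-standardized against the fitted
# dataset before entering linear predictors; the mean/sd pair is stored so
# estimates can be back-transformed to natural units.

#' Conspecific density on one host plant at one occasion
#'
#' Density is computed from the caterpillars *observed* together on a plant
#' (what a field worker could record).  The size-scaled metric sums their
#' body lengths in mm, a biomass proxy; the count metric simply counts
#' them.
#'
#' @param lengths numeric vector of body lengths (mm) of the caterpillars
#'   observed concurrently on the plant; may be empty.
#' @param metric `"size"` (sum of lengths, default) or `"count"`.
#' @return A single nonnegative number.
#' @examples
#' size_scaled_density(c(4.1, 19.9))        # 24
#' size_scaled_density(c(4.1, 19.9), "count")  # 2
#' @export
size_scaled_density <- function(lengths, metric = c("size", "count")) {
  metric <- match.arg(metric)
  lengths <- lengths[!is.na(lengths)]
  if (any(lengths < 0)) stop("caterpillar lengths must be nonnegative")
  if (metric == "size") sum(lengths) else length(lengths)
}

#' Mean temperature over a survey interval
#'
#' Arithmetic mean of hourly temperatures over the half-open interval
#' `[start, end)` (days since season start).  Up to 10% of the interval's
#' hours may be missing; the mean is then taken over the available hours.
#' More missingness is a hard error, since a 3-day mean from a sparse
#' record would silently alias the diurnal cycle.
#'
#' @param hourly data frame with columns `hour` (integer hours since season
#'   start) and `temp`.
#' @param start,end interval bounds in days since season start.
#' @param max_missing maximum tolerated fraction of missing hours (0.1).
#' @return Mean temperature (same units as the input series).
#' @examples
#' h <- data.frame(hour = 0:71, temp = 70)
#' interval_mean_temperature(h, 0, 3)
#' @export
interval_mean_temperature <- function(hourly, start, end, max_missing = 0.1) {
  stopifnot(is.data.frame(hourly), all(c("hour", "temp") %in% names(hourly)))
  if (end <= start) stop("interval end must exceed start")
  hrs <- seq(floor(start * 24), ceiling(end * 24) - 1L)
  temp <- hourly$temp[match(hrs, hourly$hour)]
  n_missing <- sum(is.na(temp))
  if (n_missing > max_missing * length(hrs))
    stop(sprintf("interval [%g, %g) days has %d/%d missing hourly records",
                 start, end, n_missing, length(hrs)))
  mean(temp, na.rm = TRUE)
}

#' Plot-by-occasion mean temperatures from an hourly series
#'
#' Computes the 3-day mean temperature for every transition interval of
#' every plot: the covariate attached to the transition leaving occasion
#' `t` is the mean over `[day_t, day_t + step)`.
#'
#' @param hourly hourly temperature data frame (`hour`, `temp`).
#' @param schedule data frame with columns `plot_id`, `occasion`, `day`
#'   (the plot's survey days), e.g. the `schedule` element of a simulated
#'   cohort.
#' @param step_days interval length in days (default 3).
#' @return Data frame `plot_id`, `occasion`, `mean_temp`.
#' @export
temperature_covariate <- function(hourly, schedule, step_days = 3) {
  out <- schedule[, c("plot_id", "occasion", "day")]
  out$mean_temp <- vapply(out$day, function(d)
    interval_mean_temperature(hourly, d, d + step_days), numeric(1))
  out$day <- NULL
  out
}

# z-standardization with stored scale, invertible
standardize <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1 # constant covariate: center only
  list(z = (x - m) / s, center = m, scale = s)
}
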