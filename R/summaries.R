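# Descriptive cohort summaries: stage abundance and density series, stage
# mean lengths, and the per-capita corpse-encounter trend.

#' Per-day abundance, corpse counts, and size-scaled density
#'
#' Aggregates encounter histories by survey day (plots are surveyed on a
#' staggered 3-day rotation, so the day index, not the occasion number, is
#' the common time axis): counts of detected live individuals per stage,
#' total live count, corpse recoveries, and total size-scaled density
#' (summed observed instar lengths).
#'
#' @param enc encounter-history data frame.
#' @return Data frame with one row per survey day: `day`, one column per
#'   live stage (`egg`, `I1`..`I5`, `pupa`), `live` (total), `corpses`,
#'   and `density`.
#' @export
abundance_series <- function(enc) {
  enc <- as_encounter_data(enc)
  days <- sort(unique(enc$day))
  out <- data.frame(day = days)
  idx <- category_index(enc$category)
  for (s in seq_along(STAGES)) {
    cnt <- tapply(idx == s + 1L, enc$day, sum)
    out[[STAGES[s]]] <- as.integer(cnt[as.character(days)])
  }
  live <- idx >= 2L & idx <= 8L
  instar <- idx >= 3L & idx <= 7L
  dead <- idx >= 9L & idx <= 15L
  out$live <- as.integer(tapply(live, enc$day, sum)[as.character(days)])
  out$corpses <- as.integer(tapply(dead, enc$day, sum)[as.character(days)])
  len <- ifelse(instar & !is.na(enc$length_mm), enc$length_mm, 0)
  out$density <- as.numeric(tapply(len, enc$day, sum)[as.character(days)])
  out
}

#' Mean recorded length per stage
#'
#' Arithmetic mean of the recorded body lengths by observed live stage;
#' stages with no recorded lengths are omitted with a warning.
#'
#' @param enc encounter-history data frame.
#' @return Named numeric vector of mean lengths (mm) by stage.
#' @export
stage_mean_lengths <- function(enc) {
  enc <- as_encounter_data(enc)
  idx <- category_index(enc$category)
  live <- idx >= 2L & idx <= 8L & !is.na(enc$length_mm)
  if (!any(live)) stop("no recorded lengths for any stage")
  stg <- STAGES[idx[live] - 1L]
  m <- tapply(enc$length_mm[live], stg, mean)
  missing_st <- setdiff(c("I1", "I2", "I3", "I4", "I5"), names(m))
  if (length(missing_st))
    warning("no lengths recorded for stage(s): ",
            paste(missing_st, collapse = ", "))
  m[order(match(names(m), STAGES))]
}

#' Per-capita corpse-encounter trend by Poisson regression
#'
#' Fits a log-linear Poisson model of per-day corpse counts against the
#' day index with the log of live abundance as an offset, i.e. a trend in
#' the per-capita corpse-encounter rate.  Reported as the daily percent
#' change `100 * (exp(slope) - 1)`.  The model is fit by iteratively
#' reweighted least squares (via [stats::glm()]) to convergence.
#' Alternatively (`method = "rate"`), the precomputed per-capita rates can
#' be modeled directly with quasi-likelihood weights; the offset form is
#' the default and standard equivalent.
#'
#' @param corpses integer vector of corpse counts per survey day; or a
#'   `cohort` from [simulate_cohort()], in which case the full corpse
#'   survey (every corpse encountered, marked or not) is regressed against
#'   the detected live-instar count at the same plot's previous survey
#'   (the population at risk), one observation per plot-survey; or an
#'   encounter data frame, in which case [abundance_series()] supplies
#'   marked-corpse counts and same-day abundance (a biased version of the
#'   field statistic when early stages are hard to detect — prefer the
#'   cohort form for simulated data).
#' @param live positive live-abundance values entering the offset.
#' @param day integer day index aligned with `corpses`.
#' @param method `"offset"` (counts with log-abundance offset, default) or
#'   `"rate"` (Poisson fit to counts with abundance folded into the
#'   response via weights).
#' @return An object of class `corpse_trend`: list with `intercept`,
#'   `slope` (per-day log-rate change), `percent_per_day`, `fit` (the glm
#'   object), and `data`.
#' @examples
#' day <- 0:26
#' counts <- rpois(27, 50 * exp(0.1 * day) * 1e-3 * 50)
#' # fit_corpse_trend(counts, live = rep(50, 27), day = day)
#' @export
fit_corpse_trend <- function(corpses, live = NULL, day = NULL,
                             method = c("offset", "rate")) {
  method <- match.arg(method)
  if (inherits(corpses, "cohort")) {
    cs <- corpses$corpse_survey
    wide_c <- cs[cs$what == "corpses", ]
    wide_l <- cs[cs$what == "live_instars", ]
    key <- function(p, o) paste(p, o)
    prev_live <- wide_l$count[match(key(wide_c$plot_id, wide_c$occasion - 1L),
                                    key(wide_l$plot_id, wide_l$occasion))]
    keep <- !is.na(prev_live) & prev_live > 0
    corpses <- wide_c$count[keep]
    live <- prev_live[keep]
    day <- wide_c$day[keep]
  } else if (is.data.frame(corpses)) {
    ab <- abundance_series(corpses)
    keep <- ab$live > 0
    corpses <- ab$corpses[keep]
    live <- ab$live[keep]
    day <- ab$day[keep]
  }
  if (length(corpses) != length(live) || length(corpses) != length(day))
    stop("corpses, live, and day must have equal length")
  if (any(corpses < 0) || any(corpses != round(corpses)))
    stop("corpse counts must be nonnegative integers")
  if (any(live <= 0)) stop("live abundance must be positive (it enters ",
                           "as an offset)")
  if (all(corpses == 0)) {
    warning("all corpse counts are zero; trend slope is undefined")
    out <- list(intercept = NA_real_, slope = NA_real_,
                percent_per_day = NA_real_, fit = NULL,
                data = data.frame(day = day, corpses = corpses, live = live))
    class(out) <- "corpse_trend"
    return(out)
  }
  df <- data.frame(corpses = corpses, day = day, live = live)
  fit <- if (method == "offset") {
    glm(corpses ~ day + offset(log(live)), family = poisson(), data = df,
        control = list(epsilon = 1e-12, maxit = 100))
  } else {
    glm(I(corpses / live) ~ day, family = poisson(), data = df,
        weights = live, control = list(epsilon = 1e-12, maxit = 100))
  }
  sl <- unname(coef(fit)["day"])
  out <- list(intercept = unname(coef(fit)[1]), slope = sl,
              percent_per_day = 100 * (exp(sl) - 1), fit = fit, data = df)
  class(out) <- "corpse_trend"
  out
}

#' @export
print.corpse_trend <- function(x, ...) {
  cat("Per-capita corpse-encounter trend (Poisson, log-abundance offset)\n")
  cat(sprintf("  log-rate slope: %.5f per day  (%+.2f%% per day)\n",
              x$slope, x$percent_per_day))
  invisible(x)
}
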