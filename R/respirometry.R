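# Respirometry: raw intermittent-flow O2 traces -> quality-filtered,
# background-corrected MO2 series -> per-trial metabolic summaries
# (MMR, RMR, AAS, FAS).

#' Fit the O2 decline of one measurement cycle
#'
#' Ordinary least-squares line of dissolved O2 (mg/L) against time (minutes)
#' over the cycle's measure phase, after discarding the first `trim_start`
#' seconds (chamber mixing/wait period). Cycles whose trimmed span is shorter
#' than `min_duration` are flagged rejected (`"too_short"`) rather than
#' raising an error; cycles with zero O2 variance have an undefined
#' coefficient of determination and are flagged `"degenerate"`.
#'
#' @param trace An `"o2_trace"` object.
#' @param cycle_index Which cycle to fit.
#' @param trim_start Seconds discarded from the start of the measure phase.
#' @param min_duration Minimum trimmed span (s) for a usable regression.
#' @return A list of class `"slope_fit"`: `cycle_index`, `slope`
#'   (mg L^-1 min^-1), `intercept`, `r_squared`, `duration` (s), `n_points`,
#'   `t_mid` (s, midpoint of the fitted window) and `reason`
#'   (`NA` when usable).
#' @export
fit_cycle_slope <- function(trace, cycle_index, trim_start = 60,
                            min_duration = 180) {
  stopifnot(inherits(trace, "o2_trace"))
  s <- trace$samples
  rows <- s$phase == "measure" & s$cycle_index == cycle_index
  if (!any(rows))
    stopf("cycle %s has no measure phase in trace %s", cycle_index,
          trace$fish_id %||% "?")
  tt <- s$time_s[rows]
  o2 <- s$o2_mg_per_l[rows]
  keep <- (tt - min(tt)) >= trim_start
  tt <- tt[keep]; o2 <- o2[keep]
  out <- list(cycle_index = cycle_index, slope = NA_real_,
              intercept = NA_real_, r_squared = NA_real_,
              duration = if (length(tt)) diff(range(tt)) else 0,
              n_points = length(tt),
              t_mid = if (length(tt)) mean(range(tt)) else NA_real_,
              reason = NA_character_)
  class(out) <- "slope_fit"
  if (out$duration < min_duration || out$n_points < 3) {
    out$reason <- "too_short"
    return(out)
  }
  if (stats::var(o2) == 0) {
    out$slope <- 0
    out$reason <- "degenerate"
    return(out)
  }
  t_min <- tt / 60
  fit <- stats::lm.fit(cbind(1, t_min), o2)
  out$slope <- unname(fit$coefficients[2])
  out$intercept <- unname(fit$coefficients[1])
  out$r_squared <- 1 - sum(fit$residuals^2) / sum((o2 - mean(o2))^2)
  out
}

#' Extract a background-corrected MO2 series from a trace
#'
#' Fits every measurement cycle, applies the quality rules (coefficient of
#' determination above `r2_threshold`, trimmed duration at least
#' `min_duration`), and converts accepted slopes to oxygen-uptake rates:
#' `MO2 = (|m_fish| - |m_background|) * V_net` in mg O2 min^-1, with the
#' background slope interpolated linearly in time between its pre- and
#' post-trial measurements and `V_net` the chamber volume minus the fish's
#' volume (density 1 kg/L). Rejected cycles are retained with
#' `accepted = FALSE` and a reason.
#'
#' @param trace An `"o2_trace"` object.
#' @param background_pre,background_post Background slopes (mg L^-1 min^-1,
#'   <= 0 expected) measured in the empty chamber before/after the trial;
#'   default to the trace's recorded values, else 0.
#' @param r2_threshold Minimum R^2 for acceptance.
#' @param trim_start,min_duration Passed to [fit_cycle_slope()].
#' @return An object of class `"mo2_series"`: per-cycle data.frame `cycles`
#'   (`cycle_index`, `t_mid_s`, `slope`, `r_squared`, `duration_s`,
#'   `n_points`, `accepted`, `reason`, `mo2`), plus `fish_id`,
#'   `temperature`, `net_volume` and the background slopes.
#' @export
extract_mo2_series <- function(trace, background_pre = NULL,
                               background_post = NULL, r2_threshold = 0.96,
                               trim_start = 60, min_duration = 180) {
  stopifnot(inherits(trace, "o2_trace"))
  background_pre <- background_pre %||%
    (if (is.finite(trace$background_slope_pre)) trace$background_slope_pre else 0)
  background_post <- background_post %||%
    (if (is.finite(trace$background_slope_post)) trace$background_slope_post else 0)
  v_net <- trace$chamber_volume - trace$fish_mass / 1
  if (!is.finite(v_net) || v_net <= 0)
    stopf("configuration error: net volume %.3f L is not positive", v_net)
  cyc_ids <- sort(unique(trace$samples$cycle_index[
    trace$samples$phase == "measure"]))
  t0 <- min(trace$samples$time_s)
  t1 <- max(trace$samples$time_s)
  fits <- lapply(cyc_ids, fit_cycle_slope, trace = trace,
                 trim_start = trim_start, min_duration = min_duration)
  cycles <- do.call(rbind, lapply(fits, function(f) {
    reason <- f$reason
    if (is.na(reason) && f$r_squared <= r2_threshold)
      reason <- "r2_below_threshold"
    accepted <- is.na(reason)
    mo2 <- NA_real_
    if (accepted) {
      frac <- if (t1 > t0) (f$t_mid - t0) / (t1 - t0) else 0
      bg <- background_pre + frac * (background_post - background_pre)
      mo2 <- (abs(f$slope) - abs(bg)) * v_net
    }
    data.frame(cycle_index = f$cycle_index, t_mid_s = f$t_mid,
               slope = f$slope, r_squared = f$r_squared,
               duration_s = f$duration, n_points = f$n_points,
               accepted = accepted, reason = reason, mo2 = mo2,
               stringsAsFactors = FALSE)
  }))
  if (!any(cycles$accepted))
    stopf("empty series: no cycle in trace %s passed the quality filters",
          trace$fish_id %||% "?")
  structure(list(fish_id = trace$fish_id, temperature = trace$temperature,
                 cycles = cycles, net_volume = v_net,
                 background_slope_pre = background_pre,
                 background_slope_post = background_post),
            class = "mo2_series")
}

#' Summarize a trial's metabolism (MMR, RMR, AAS, FAS)
#'
#' MMR is the highest accepted MO2 whose cycle lasted at least
#' `mmr_min_duration` seconds (candidates include every cycle, post-chase and
#' overnight alike). RMR is an order-statistic estimator: the mean of the
#' `rmr_keep` lowest accepted MO2 values after excluding the
#' `rmr_drop_lowest` lowest. AAS = MMR - RMR and FAS = MMR / RMR exactly.
#'
#' @param series An `"mo2_series"` object.
#' @param mmr_min_duration Minimum cycle duration (s) for MMR candidacy.
#' @param rmr_drop_lowest Number of lowest values excluded before averaging.
#' @param rmr_keep Number of values averaged for RMR.
#' @return A list of class `"metabolic_summary"`: `fish_id`, `temperature`,
#'   `mmr`, `rmr`, `aas`, `fas`, `n_accepted_cycles` and `warning_flag`
#'   (TRUE when RMR >= MMR; values are reported unclamped).
#' @export
summarize_metabolism <- function(series, mmr_min_duration = 180,
                                 rmr_drop_lowest = 5, rmr_keep = 10) {
  stopifnot(inherits(series, "mo2_series"))
  acc <- series$cycles[series$cycles$accepted, ]
  need <- rmr_drop_lowest + rmr_keep
  if (nrow(acc) < need)
    stopf("insufficient data: %d accepted cycles, need at least %d",
          nrow(acc), need)
  mmr_pool <- acc$mo2[acc$duration_s >= mmr_min_duration]
  if (!length(mmr_pool))
    stopf("insufficient data: no accepted cycle of >= %d s for MMR",
          mmr_min_duration)
  mmr <- max(mmr_pool)
  ranked <- sort(acc$mo2)
  rmr <- mean(ranked[(rmr_drop_lowest + 1):(rmr_drop_lowest + rmr_keep)])
  out <- list(fish_id = series$fish_id, temperature = series$temperature,
              mmr = mmr, rmr = rmr, aas = mmr - rmr, fas = mmr / rmr,
              n_accepted_cycles = nrow(acc),
              warning_flag = rmr >= mmr)
  if (out$warning_flag)
    warning(sprintf("RMR >= MMR for fish %s at %s degC; summary not clamped",
                    series$fish_id %||% "?", series$temperature),
            call. = FALSE)
  class(out) <- "metabolic_summary"
  out
}

#' @export
print.metabolic_summary <- function(x, ...) {
  cat(sprintf(
    "Metabolic summary %s @ %s degC: MMR %.4f, RMR %.4f, AAS %.4f, FAS %.3f (%d cycles)\n",
    x$fish_id %||% "?", x$temperature, x$mmr, x$rmr, x$aas, x$fas,
    x$n_accepted_cycles))
  invisible(x)
}

#' @export
print.mo2_series <- function(x, ...) {
  cat(sprintf("MO2 series %s @ %s degC: %d cycles (%d accepted), V_net %.3f L\n",
              x$fish_id %||% "?", x$temperature, nrow(x$cycles),
              sum(x$cycles$accepted), x$net_volume))
  invisible(x)
}
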