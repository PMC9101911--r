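# Dose schedules: oral ingestion as short constant-rate boluses into the gut
# lumen, dermal penetration and inhalation as continuous infusions into skin
# and lung tissue. Events are half-open intervals [start, start + duration).

DOSE_ROUTES <- c("oral", "dermal", "inhalation")

new_dose_schedule <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(route = character(), start_h = numeric(),
                         duration_h = numeric(), rate_mg_h = numeric(),
                         amount_mg = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(events$route %in% DOSE_ROUTES),
            all(events$duration_h > 0),
            all(events$rate_mg_h >= 0))
  events <- events[order(events$start_h, events$route), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events), class = "dose_schedule")
}

#' Build a daily oral ingestion schedule
#'
#' Splits a daily oral DEHP intake across meals in the given ratios, each
#' delivered at constant rate over a short duration (a 30-minute meal by
#' default), repeated daily. The default reproduces a 1.95 mg/day intake as
#' 0.5, 0.8 and 0.65 mg at 08:00, 12:00 and 18:00.
#'
#' @param total_mg_per_day total oral DEHP per day (mg).
#' @param ratios relative meal sizes (same length as `meal_times`); they are
#'   normalised to sum to 1.
#' @param meal_times start times within the day, hours in `[0, 24)`.
#' @param duration_h duration of each intake (h), default 0.5.
#' @param days number of repeated days (0 gives an empty schedule).
#' @return a `dose_schedule` object.
#' @examples
#' sched <- oral_schedule(days = 2)
#' sched$events[, c("start_h", "amount_mg")]
#' @export
oral_schedule <- function(total_mg_per_day = 1.95,
                          ratios = c(0.5, 0.8, 0.65),
                          meal_times = c(8, 12, 18),
                          duration_h = 0.5,
                          days = 1) {
  stopifnot(total_mg_per_day > 0, duration_h > 0, days >= 0,
            length(ratios) == length(meal_times))
  if (any(meal_times < 0 | meal_times >= 24)) {
    stop("meal_times must lie in [0, 24)", call. = FALSE)
  }
  amounts <- total_mg_per_day * ratios / sum(ratios)
  if (days == 0) return(new_dose_schedule(NULL))
  starts <- rep(meal_times, times = days) + 24 * rep(seq_len(days) - 1,
                                                     each = length(meal_times))
  ev <- data.frame(
    route = "oral",
    start_h = starts,
    duration_h = duration_h,
    rate_mg_h = rep(amounts, times = days) / duration_h,
    amount_mg = rep(amounts, times = days),
    stringsAsFactors = FALSE
  )
  new_dose_schedule(ev)
}

#' Build a continuous-exposure schedule
#'
#' One constant-rate infusion covering `[0, t_end_h)`, representing all-day
#' exposure: dermal penetration into skin tissue or inhalation into lung
#' tissue. Reference rates are 0.68 mg/h (dermal) and 0.53 mg/h
#' (inhalation).
#'
#' @param route one of `"dermal"`, `"inhalation"` (or `"oral"` for a
#'   constant oral infusion).
#' @param rate_mg_h input rate, mg/h, `>= 0`.
#' @param t_end_h end of the infusion (h).
#' @return a `dose_schedule` object.
#' @export
continuous_dose <- function(route, rate_mg_h, t_end_h) {
  route <- match.arg(route, DOSE_ROUTES)
  if (!is.numeric(rate_mg_h) || rate_mg_h < 0) {
    stop("rate must be non-negative", call. = FALSE)
  }
  stopifnot(t_end_h > 0)
  ev <- data.frame(route = route, start_h = 0, duration_h = t_end_h,
                   rate_mg_h = rate_mg_h, amount_mg = rate_mg_h * t_end_h,
                   stringsAsFactors = FALSE)
  new_dose_schedule(ev)
}

#' Combine dose schedules
#'
#' @param ... `dose_schedule` objects.
#' @return a single merged `dose_schedule`.
#' @export
combine_schedules <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "dose_schedule")))
  new_dose_schedule(do.call(rbind, lapply(parts, `[[`, "events")))
}

#' Instantaneous dose input rate by route
#'
#' Evaluates the piecewise-constant input rate of a schedule at time `t`.
#' Bolus events contribute `amount / duration` while active; intervals are
#' half-open, so a rate drops to zero exactly at `start + duration`.
#'
#' @param schedule a `dose_schedule`.
#' @param t time (h), scalar, `>= 0`.
#' @return named numeric vector `c(oral = , dermal = , inhalation = )`, mg/h.
#' @export
input_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"), t >= 0)
  ev <- schedule$events
  out <- c(oral = 0, dermal = 0, inhalation = 0)
  if (nrow(ev) == 0L) return(out)
  active <- ev$start_h <= t & t < ev$start_h + ev$duration_h
  if (any(active)) {
    agg <- tapply(ev$rate_mg_h[active], ev$route[active], sum)
    out[names(agg)] <- agg
  }
  out
}

#' Cumulative dosed amount by route
#'
#' Exact integral of the piecewise-constant input rates over `[0, t]`.
#'
#' @param schedule a `dose_schedule`.
#' @param t time (h), scalar or vector.
#' @return if `t` is scalar, a named vector (mg) per route; otherwise a
#'   matrix with one row per time.
#' @export
cumulative_input <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"), all(t >= 0))
  ev <- schedule$events
  one <- function(ti) {
    out <- c(oral = 0, dermal = 0, inhalation = 0)
    if (nrow(ev) == 0L) return(out)
    overlap <- pmax(0, pmin(ti, ev$start_h + ev$duration_h) - ev$start_h)
    agg <- tapply(ev$rate_mg_h * overlap, ev$route, sum)
    out[names(agg)] <- agg
    out
  }
  if (length(t) == 1L) one(t) else t(vapply(t, one, numeric(3)))
}

# Total dosed amount per route over the whole schedule (mg).
schedule_totals <- function(schedule) {
  ev <- schedule$events
  out <- c(oral = 0, dermal = 0, inhalation = 0)
  if (nrow(ev) == 0L) return(out)
  agg <- tapply(ev$amount_mg, ev$route, sum)
  out[names(agg)] <- agg
  out
}

# Times at which the input-rate function is discontinuous (event on/off),
# clipped to [0, t_end]. The integrator restarts at these points.
schedule_breakpoints <- function(schedule, t_end) {
  ev <- schedule$events
  b <- sort(unique(c(0, t_end, ev$start_h, ev$start_h + ev$duration_h)))
  b[b >= 0 & b <= t_end]
}

#' @export
print.dose_schedule <- function(x, ...) {
  ev <- x$events
  totals <- schedule_totals(x)
  cat(sprintf("Dose schedule: %d event(s)\n", nrow(ev)))
  for (r in DOSE_ROUTES) {
    if (totals[[r]] > 0) {
      cat(sprintf("  %-10s total %g mg over %d event(s)\n",
                  r, totals[[r]], sum(ev$route == r)))
    }
  }
  invisible(x)
}
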