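# Acoustics: interval Leq logs -> period levels -> day-evening-night level Lden.
#
# All levels are equivalent continuous sound pressure levels in dB. Aggregation
# across intervals is energetic (on the 10^(L/10) energy scale), the standard
# rule for Leq; the arithmetic mean of dB values underestimates the energy mean
# whenever levels differ.

# Fixed analysis periods (hours on a 24 h clock): day 07-19, evening 19-23,
# night 23-07, contributing 12, 4 and 8 hours respectively.
.period_hours <- c(day = 12, evening = 4, night = 8)

parse_clock <- function(x) {
  if (!is.character(x)) stop_input("clock times must be strings in HH:MM format")
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop_input("invalid clock time(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  h <- as.numeric(vapply(m, `[`, character(1), 2L))
  mi <- as.numeric(vapply(m, `[`, character(1), 3L))
  if (any(h > 23) || any(mi > 59)) {
    stop_input("clock time out of range: ", paste(unique(x[h > 23 | mi > 59]), collapse = ", "))
  }
  h + mi / 60
}

# overlap (in hours) of [s, e) with window [w1, w2), both on the real line
.overlap <- function(s, e, w1, w2) pmax(0, pmin(e, w2) - pmax(s, w1))

#' Assign a measurement interval to analysis periods
#'
#' Splits a clock interval over the three analysis periods -- day
#' (07:00-19:00), evening (19:00-23:00) and night (23:00-07:00) -- returning
#' the overlap with each in hours. Intervals crossing midnight are handled by
#' clock arithmetic modulo 24 h, so an interval such as 22:00-01:00
#' contributes 1 h to the evening and 2 h to the night period.
#'
#' @param start,end Clock times as "HH:MM" strings (24-hour clock).
#' @return Named numeric vector with components `day`, `evening`, `night`
#'   giving overlap hours; they sum to the interval duration.
#' @export
#' @examples
#' assign_period("07:00", "10:00")  # day, 3 h
#' assign_period("22:00", "01:00")  # evening 1 h + night 2 h
assign_period <- function(start, end) {
  s <- parse_clock(start)
  e <- parse_clock(end)
  if (length(s) != 1 || length(e) != 1) stop_input("assign_period takes a single interval")
  if (e == s) stop_input("zero-duration interval: ", start, "-", end)
  if (e < s) e <- e + 24
  # windows replicated one day forward so intervals starting late still overlap
  day <- .overlap(s, e, 7, 19) + .overlap(s, e, 31, 43)
  evening <- .overlap(s, e, 19, 23) + .overlap(s, e, 43, 47)
  night <- .overlap(s, e, 23, 31) + .overlap(s, e, 47, 55) + .overlap(s, e, -1, 7)
  c(day = day, evening = evening, night = night)
}

#' Energetic mean of sound levels
#'
#' Averages dB levels on the energy scale: `10 * log10(weighted mean of
#' 10^(L/10))`. This is the correct way to pool Leq values and is always at
#' least the arithmetic mean of the dB inputs (with equality only when all
#' inputs are equal).
#'
#' @param levels Numeric vector of levels in dB; must be non-empty and finite.
#' @param weights Optional non-negative weights (e.g. overlap hours); default
#'   equal weighting.
#' @return The energetic mean level in dB.
#' @export
#' @examples
#' energetic_mean(c(50, 60))  # 57.4 dB, not 55
energetic_mean <- function(levels, weights = NULL) {
  if (length(levels) == 0) stop_input("no measurements in period")
  if (!is_finite_num(levels)) stop_input("levels must be finite numbers")
  if (is.null(weights)) weights <- rep(1, length(levels))
  if (length(weights) != length(levels) || !is_finite_num(weights) || any(weights < 0)) {
    stop_input("weights must be non-negative, finite, and match levels in length")
  }
  if (sum(weights) <= 0) stop_input("no measurements in period")
  10 * log10(sum(weights * 10^(levels / 10)) / sum(weights))
}

#' Period levels from an interval Leq log
#'
#' Aggregates interval Leq measurements into the three analysis-period levels.
#' Each measurement is split over the periods it overlaps (see
#' [assign_period()]) and each period level is the energetic mean of the
#' contributing measurements weighted by overlap hours. Every period must be
#' covered by at least one measurement.
#'
#' @param log A data frame with columns `start`, `end` ("HH:MM" strings) and
#'   `leq_db` (numeric); typically one location's rows of [read_noise_log()].
#' @return Named numeric vector `c(l_day, l_evening, l_night)` in dB.
#' @export
#' @examples
#' log <- data.frame(start = c("07:00", "19:00", "23:00"),
#'                   end = c("19:00", "23:00", "07:00"),
#'                   leq_db = c(60, 55, 50))
#' period_levels_from_log(log)
period_levels_from_log <- function(log) {
  if (!is.data.frame(log) || nrow(log) == 0) stop_input("noise log is empty")
  need <- c("start", "end", "leq_db")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop_input("noise log lacks column(s): ", paste(miss, collapse = ", "))
  if (!is_finite_num(log$leq_db)) stop_input("leq_db must be finite")
  w <- t(vapply(seq_len(nrow(log)),
                function(i) assign_period(log$start[i], log$end[i]),
                numeric(3)))
  out <- numeric(3)
  for (k in 1:3) {
    if (sum(w[, k]) <= 0) {
      stop_input("no measurements in period: ", c("day", "evening", "night")[k])
    }
    out[k] <- energetic_mean(log$leq_db, w[, k])
  }
  names(out) <- c("l_day", "l_evening", "l_night")
  out
}

#' Day-evening-night weighted level (Lden)
#'
#' Combines period levels into the 24-hour Lden indicator with the standard
#' penalties for non-daytime noise:
#' `Lden = 10*log10( (12*10^(Ld/10) + 4*10^((Le+5)/10) + 8*10^((Ln+10)/10)) / 24 )`.
#' The +5 dB evening and +10 dB night weighting factors reflect the greater
#' human sensitivity to noise in those periods; the 12/4/8 hour weights sum to
#' the full 24 h day.
#'
#' @param l_day,l_evening,l_night Period levels in dB, or pass the named
#'   vector returned by [period_levels_from_log()] as `l_day`.
#' @return The Lden level in dB, with the contributing hours attached as
#'   attribute `"hours"`.
#' @export
#' @examples
#' compute_lden(60, 55, 50)     # exactly 60: penalties cancel the weights
#' compute_lden(50, 50, 50)     # 56.4
compute_lden <- function(l_day, l_evening = NULL, l_night = NULL) {
  if (is.null(l_evening) && is.null(l_night) && length(l_day) == 3) {
    l_evening <- l_day[[2]]
    l_night <- l_day[[3]]
    l_day <- l_day[[1]]
  }
  lv <- c(l_day, l_evening, l_night)
  if (length(lv) != 3 || !is_finite_num(lv)) {
    stop_input("compute_lden needs three finite period levels")
  }
  e <- 12 * 10^(lv[1] / 10) + 4 * 10^((lv[2] + 5) / 10) + 8 * 10^((lv[3] + 10) / 10)
  structure(10 * log10(e / 24), hours = .period_hours)
}

#' Per-location Lden table from a noise log
#'
#' Computes period levels and Lden for every location in an interval Leq log.
#'
#' @param log A noise-log data frame (see [read_noise_log()]) with a
#'   `location_id` column.
#' @param digits Decimal places for the reported levels (full precision is
#'   used internally); `NULL` to leave unrounded.
#' @return A data frame with one row per location: `location_id`, `l_day`,
#'   `l_evening`, `l_night`, `lden_db`.
#' @export
lden_by_location <- function(log, digits = 2) {
  if (!is.data.frame(log) || !"location_id" %in% names(log)) {
    stop_input("noise log lacks column(s): location_id")
  }
  locs <- unique(log$location_id)
  rows <- lapply(locs, function(id) {
    pl <- period_levels_from_log(log[log$location_id == id, , drop = FALSE])
    data.frame(location_id = id, l_day = pl[["l_day"]], l_evening = pl[["l_evening"]],
               l_night = pl[["l_night"]], lden_db = as.numeric(compute_lden(pl)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- c("l_day", "l_evening", "l_night", "lden_db")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  rownames(out) <- NULL
  out
}
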