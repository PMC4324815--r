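#' Standard gravitational acceleration (m s^-2)
#'
#' Used by [training_work()] unless overridden; exposed so sensitivity
#' analyses can vary it.
#' @export
STANDARD_GRAVITY <- 9.81

#' Construct and validate a table of climb sessions
#'
#' A climb-session table holds one row per rat per training session of a
#' ladder-climbing resistance-exercise program: the animal's body mass, the
#' additional load carried in the tail bag, the climb height, the number of
#' repetitions, and the summed climbing time (rests excluded).
#'
#' @param rat_id character or factor; animal identifier.
#' @param day integer day index, 1-based; day 1 is the first training day.
#' @param body_mass body mass in kg.
#' @param load_mass additional load in kg (>= 0).
#' @param climb_height climbed height per repetition in m.
#' @param repetitions number of climbs in the session.
#' @param total_time summed climbing time in s (excludes inter-climb rest).
#' @return A `data.frame` of class `climb_sessions`.
#' @examples
#' climb_sessions(rat_id = "r1", day = 1, body_mass = 0.28,
#'                load_mass = 0.14, climb_height = 1, repetitions = 10,
#'                total_time = 90)
#' @export
climb_sessions <- function(rat_id, day, body_mass, load_mass,
                           climb_height = 1, repetitions = 10L,
                           total_time) {
  x <- data.frame(rat_id = as.character(rat_id),
                  day = as.integer(day),
                  body_mass = as.numeric(body_mass),
                  load_mass = as.numeric(load_mass),
                  climb_height = as.numeric(climb_height),
                  repetitions = as.integer(repetitions),
                  total_time = as.numeric(total_time),
                  stringsAsFactors = FALSE)
  validate_climb_sessions(x)
}

#' @rdname climb_sessions
#' @param x a data.frame with the climb-session columns.
#' @export
validate_climb_sessions <- function(x) {
  required <- c("rat_id", "day", "body_mass", "load_mass", "climb_height",
                "repetitions", "total_time")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("climb session table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  check_field <- function(field, ok, what) {
    bad <- !ok(x[[field]])
    if (any(bad))
      stop(sprintf("invalid %s: %s must be %s (rows %s)", field, field, what,
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
  }
  check_field("body_mass", function(v) is.finite(v) & v > 0, "> 0")
  check_field("load_mass", function(v) is.finite(v) & v >= 0, ">= 0")
  check_field("climb_height", function(v) is.finite(v) & v > 0, "> 0")
  check_field("repetitions", function(v) is.finite(v) & v >= 1, ">= 1")
  check_field("total_time", function(v) is.finite(v) & v > 0, "> 0")
  check_field("day", function(v) is.finite(v) & v >= 1, ">= 1")
  if (anyDuplicated(x[c("rat_id", "day")]))
    stop("duplicate (rat_id, day) in climb session table", call. = FALSE)
  class(x) <- unique(c("climb_sessions", class(x)))
  x
}

#' Training work of a climb session
#'
#' Potential mechanical work of the combined centre of mass over all
#' repetitions of a session: `(load_mass + body_mass) * g * climb_height *
#' repetitions`, in joules. This is the daily training impulse driving the
#' systems models.
#'
#' @param session a `climb_sessions` table (or any data.frame with the same
#'   columns); vectorised over rows.
#' @param g gravitational acceleration in m s^-2.
#' @return numeric vector of work in J, one value per session row.
#' @seealso [session_performance()]
#' @export
training_work <- function(session, g = STANDARD_GRAVITY) {
  (session$load_mass + session$body_mass) * g * session$climb_height *
    session$repetitions
}

#' Mean power output of a climb session
#'
#' Session performance: training work divided by total climbing time, in
#' watts. This is the system output the models are fitted to.
#'
#' @inheritParams training_work
#' @return numeric vector of power in W, one value per session row.
#' @export
session_performance <- function(session, g = STANDARD_GRAVITY) {
  if (any(!is.finite(session$total_time) | session$total_time <= 0))
    stop("total_time must be > 0", call. = FALSE)
  training_work(session, g = g) / session$total_time
}

#' Session days of a 5-on/2-off training calendar
#'
#' Maps session numbers to calendar day indices for a program of
#' `days_per_week` consecutive training days followed by rest days making up
#' a 7-day week. Day 1 is the first training day. The returned `n_days`
#' spans all weeks touched by the sessions through the last scheduled
#' training day of the final week, so trailing rest days of that week are
#' not counted.
#'
#' @param n_sessions number of training sessions.
#' @param days_per_week consecutive training days per week (default 5).
#' @return list with `session_day` (integer vector, one per session) and
#'   `n_days` (span of the program in days).
#' @examples
#' training_calendar(19)$session_day   # days 1-5, 8-12, 15-19, 22-25
#' training_calendar(19)$n_days        # 26
#' @export
training_calendar <- function(n_sessions, days_per_week = 5L) {
  stopifnot(n_sessions >= 1, days_per_week >= 1, days_per_week <= 7)
  s <- seq_len(n_sessions) - 1L
  day <- (s %/% days_per_week) * 7L + (s %% days_per_week) + 1L
  n_weeks <- ceiling(n_sessions / days_per_week)
  list(session_day = day,
       n_days = (n_weeks - 1L) * 7L + days_per_week)
}

#' Construct a daily training series for one rat
#'
#' @param rat_id animal identifier.
#' @param w numeric vector of daily training amounts in J, length `n_days`;
#'   zero on rest days.
#' @param measured_days integer days on which performance was observed.
#' @param p_obs observed performance in W on each measured day.
#' @param n_days span of the series in days (default `length(w)`).
#' @return object of class `training_series`.
#' @export
training_series <- function(rat_id, w, measured_days = integer(),
                            p_obs = numeric(), n_days = length(w)) {
  w <- as.numeric(w)
  measured_days <- as.integer(measured_days)
  if (length(w) != n_days)
    stop("length(w) must equal n_days", call. = FALSE)
  if (any(!is.finite(w) | w < 0))
    stop("daily training amounts w must be finite and >= 0", call. = FALSE)
  if (length(measured_days) != length(p_obs))
    stop("measured_days and p_obs must have equal length", call. = FALSE)
  if (length(measured_days)) {
    if (any(measured_days < 1 | measured_days > n_days))
      stop("measured days must lie within 1..n_days", call. = FALSE)
    if (anyDuplicated(measured_days))
      stop("duplicate measured days", call. = FALSE)
    if (any(!is.finite(p_obs) | p_obs <= 0))
      stop("observed performances must be finite and > 0", call. = FALSE)
  }
  structure(list(rat_id = as.character(rat_id), n_days = as.integer(n_days),
                 w = w, measured_days = measured_days,
                 p_obs = as.numeric(p_obs)),
            class = "training_series")
}

#' @export
print.training_series <- function(x, ...) {
  cat(sprintf("<training_series> rat %s: %d days, %d sessions (total %.1f J), %d measured performances\n",
              x$rat_id, x$n_days, sum(x$w > 0), sum(x$w), length(x$measured_days)))
  invisible(x)
}

#' Build daily training series from climb-session logs
#'
#' Places each session's training work on its calendar day (zero elsewhere)
#' and attaches the session's measured power output to the same day, giving
#' one `training_series` per rat.
#'
#' @param sessions a `climb_sessions` table (rows for one or several rats).
#' @param n_days span of the series; default is the latest session day
#'   across the table (a common span keeps cohort series aligned).
#' @inheritParams training_work
#' @return a list of `training_series`, one per rat, named by `rat_id`.
#' @export
build_training_series <- function(sessions, n_days = NULL,
                                  g = STANDARD_GRAVITY) {
  if (nrow(sessions) == 0)
    stop("empty session table", call. = FALSE)
  sessions <- validate_climb_sessions(as.data.frame(sessions))
  if (is.null(n_days)) n_days <- max(sessions$day)
  if (max(sessions$day) > n_days)
    stop("session day exceeds n_days", call. = FALSE)
  out <- lapply(split(sessions, sessions$rat_id), function(s) {
    s <- s[order(s$day), , drop = FALSE]
    w <- numeric(n_days)
    w[s$day] <- training_work(s, g = g)
    training_series(rat_id = s$rat_id[1], w = w, measured_days = s$day,
                    p_obs = session_performance(s, g = g), n_days = n_days)
  })
  out[order(names(out))]
}

#' Read / write climb-session logs and training series as CSV
#'
#' Session logs are comma-separated with header
#' `rat_id, day, body_mass_g, load_mass_g, height_m, reps, total_time_s`;
#' masses are in grams in files and converted to kg internally. Training
#' series are written tidy as `rat_id, day, w_joules, p_obs_watts` with
#' `p_obs_watts` empty on unmeasured days.
#'
#' @param path file path.
#' @return `read_session_log` returns a validated `climb_sessions` table.
#' @export
read_session_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("rat_id", "day", "body_mass_g", "load_mass_g", "height_m",
                "reps", "total_time_s")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("session log lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  climb_sessions(rat_id = raw$rat_id, day = raw$day,
                 body_mass = raw$body_mass_g / 1000,
                 load_mass = raw$load_mass_g / 1000,
                 climb_height = raw$height_m, repetitions = raw$reps,
                 total_time = raw$total_time_s)
}

#' @rdname read_session_log
#' @param sessions a `climb_sessions` table.
#' @export
write_session_log <- function(sessions, path) {
  out <- data.frame(rat_id = sessions$rat_id, day = sessions$day,
                    body_mass_g = sessions$body_mass * 1000,
                    load_mass_g = sessions$load_mass * 1000,
                    height_m = sessions$climb_height,
                    reps = sessions$repetitions,
                    total_time_s = sessions$total_time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_session_log
#' @param series a `training_series` or list of them.
#' @export
write_training_series <- function(series, path) {
  if (inherits(series, "training_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    p <- rep(NA_real_, s$n_days)
    p[s$measured_days] <- s$p_obs
    data.frame(rat_id = s$rat_id, day = seq_len(s$n_days),
               w_joules = s$w, p_obs_watts = p)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_session_log
#' @export
read_training_series <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(raw, raw$rat_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    meas <- which(!is.na(d$p_obs_watts))
    training_series(rat_id = d$rat_id[1], w = d$w_joules,
                    measured_days = d$day[meas],
                    p_obs = d$p_obs_watts[meas], n_days = max(d$day))
  })
  out[order(names(out))]
}
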