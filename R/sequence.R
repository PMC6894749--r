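#' Bout-level feeding event sequence
#'
#' The central data container: an ordered, typed event log for one subject
#' over an observation window. Events are feeding bouts (with an amount
#' consumed) and pauses, the latter classed as short within-meal pauses
#' (`"S"`), intermeal intervals (`"L"`), or `"unknown"` when read from raw
#' monitor files before [label_meals()] has been applied.
#'
#' @param events A data frame with columns `kind` (`"bout"`/`"pause"`),
#'   `start` (s), `duration` (s), `amount` (g, `NA` for pauses),
#'   `pause_class` (`"S"`, `"L"`, `"unknown"`, `NA` for bouts),
#'   `fullness_start` (g, optional), and `censored` (logical, optional).
#' @param subject Subject identifier.
#' @param condition Condition label (drug, dose, photoperiod, ...).
#' @param window Numeric length-2 observation window in seconds; defaults to
#'   the span of the events.
#' @param x_init Fullness at the window start (grams).
#' @return An object of class `"feeding_seq"` (a data frame with metadata
#'   attributes).
#' @export
feeding_seq <- function(events, subject = "subject1", condition = "none",
                        window = NULL, x_init = 0) {
  events <- as.data.frame(events)
  needed <- c("kind", "start", "duration")
  miss <- setdiff(needed, names(events))
  if (length(miss)) stop("events missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(events)
  if (!"amount" %in% names(events)) events$amount <- rep(NA_real_, n)
  if (!"pause_class" %in% names(events))
    events$pause_class <- rep(NA_character_, n)
  if (!"fullness_start" %in% names(events))
    events$fullness_start <- rep(NA_real_, n)
  if (!"censored" %in% names(events)) events$censored <- rep(FALSE, n)
  events <- events[order(events$start),
                   c("kind", "start", "duration", "amount", "pause_class",
                     "fullness_start", "censored")]
  rownames(events) <- NULL
  if (nrow(events)) {
    if (any(!events$kind %in% c("bout", "pause")))
      stop("event 'kind' must be 'bout' or 'pause'")
    if (any(events$duration <= 0)) stop("event durations must be > 0")
    ends <- events$start + events$duration
    if (any(events$start[-1] < ends[-nrow(events)] - 1e-9))
      stop("overlapping events")
    isb <- events$kind == "bout"
    if (any(isb & (is.na(events$amount) | events$amount < 0)))
      stop("bout events need a nonnegative 'amount'")
    events$pause_class[isb] <- NA_character_
    events$pause_class[!isb & is.na(events$pause_class)] <- "unknown"
  }
  if (is.null(window)) {
    window <- if (nrow(events)) c(min(events$start),
                                  max(events$start + events$duration))
              else c(0, 0)
  }
  if (length(window) == 1L) window <- c(0, window)
  structure(events, subject = subject, condition = condition,
            window = as.numeric(window), x_init = x_init,
            class = c("feeding_seq", "data.frame"))
}

#' @export
print.feeding_seq <- function(x, ...) {
  w <- attr(x, "window")
  nb <- sum(x$kind == "bout")
  cat(sprintf("Feeding sequence '%s' (%s): %d events (%d bouts) over %.2f h\n",
              attr(x, "subject"), attr(x, "condition"), nrow(x), nb,
              diff(w) / 3600))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...", nrow(x) - 4, "more events\n")
  invisible(x)
}

#' Plot a feeding sequence with its implied fullness
#'
#' Draws the bout raster (top) and the model-derived fullness curve (bottom)
#' for one subject's observation window.
#'
#' @param x A [feeding_seq()].
#' @param gut A [gut_model()] used to reconstruct fullness.
#' @param ... Passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.feeding_seq <- function(x, gut = gut_model(), ...) {
  w <- attr(x, "window")
  tr <- fullness_trajectory(x, gut, attr(x, "x_init"))
  tt <- seq(w[1], w[2], length.out = 600)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  b <- as.data.frame(x)[x$kind == "bout", ]
  graphics::plot(NA, xlim = w / 3600, ylim = c(0, 1), yaxt = "n",
                 xlab = "", ylab = "bouts", ...)
  if (nrow(b))
    graphics::rect(b$start / 3600, 0, (b$start + b$duration) / 3600, 1,
                   col = "steelblue", border = NA)
  graphics::par(mar = c(4, 4, 0.5, 1))
  graphics::plot(tt / 3600, eval_fullness(tr, tt), type = "l",
                 xlab = "time (h)", ylab = "fullness (g)", col = "firebrick")
  invisible(x)
}

#' Append one sequence after another
#'
#' Shifts the events of `b` so that its window starts where `a`'s ends, and
#' returns the combined sequence. Useful for concatenating recording blocks
#' from the same subject.
#'
#' @param a,b [feeding_seq()] objects.
#' @return A [feeding_seq()] spanning both windows.
#' @export
bind_sequences <- function(a, b) {
  wa <- attr(a, "window"); wb <- attr(b, "window")
  eb <- as.data.frame(b)
  eb$start <- eb$start - wb[1] + wa[2]
  feeding_seq(rbind(as.data.frame(a), eb), subject = attr(a, "subject"),
              condition = attr(a, "condition"),
              window = c(wa[1], wa[2] + diff(wb)), x_init = attr(a, "x_init"))
}

# Split a sequence into meals: returns an integer meal index per event
# (NA for L pauses and pauses of unknown class), requiring resolved classes.
meal_index <- function(seq) {
  ev <- as.data.frame(seq)
  if (nrow(ev) == 0L) return(integer(0))
  pauses <- ev$kind == "pause"
  if (any(pauses & ev$pause_class == "unknown"))
    stop("sequence has unresolved pause classes; run label_meals() first")
  idx <- rep(NA_integer_, nrow(ev))
  m <- 0L
  in_meal <- FALSE
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "bout") {
      if (!in_meal) { m <- m + 1L; in_meal <- TRUE }
      idx[i] <- m
    } else if (ev$pause_class[i] == "S") {
      if (in_meal) idx[i] <- m
    } else {
      in_meal <- FALSE
    }
  }
  idx
}

#' Summarise a feeding sequence
#'
#' Meal-pattern summary of an event log: total and normalised intake, meal
#' sizes and durations, intermeal intervals, and ingestive statistics.
#' Censored terminal events are included in intake totals but excluded from
#' duration-based summaries.
#'
#' @param object A [feeding_seq()] with pause classes resolved (see
#'   [label_meals()]).
#' @param normalise_hours Window length in hours used to normalise intake;
#'   defaults to the observation window.
#' @param ... Unused.
#' @return A list of class `"feeding_summary"` with elements `total_intake`,
#'   `hourly_intake`, `meal_sizes`, `meal_durations`, `imis`, `meal_count`,
#'   `bout_count`, `mean_bout_duration`, `mean_bout_rate`.
#' @export
summary.feeding_seq <- function(object, normalise_hours = NULL, ...) {
  ev <- as.data.frame(object)
  w <- attr(object, "window")
  if (is.null(normalise_hours)) normalise_hours <- diff(w) / 3600
  idx <- meal_index(object)
  isb <- ev$kind == "bout"
  total <- sum(ev$amount[isb], na.rm = TRUE)
  complete <- !ev$censored
  # meals
  meal_ids <- sort(unique(idx[isb & !is.na(idx)]))
  meal_sizes <- vapply(meal_ids, function(m)
    sum(ev$amount[isb & !is.na(idx) & idx == m]), numeric(1))
  meal_durations <- vapply(meal_ids, function(m) {
    rows <- which(!is.na(idx) & idx == m)
    if (any(ev$censored[rows])) return(NA_real_)
    brows <- rows[ev$kind[rows] == "bout"]
    max(ev$start[brows] + ev$duration[brows]) - min(ev$start[brows])
  }, numeric(1))
  # intermeal intervals: complete L pauses that follow a meal
  isL <- ev$kind == "pause" & !is.na(ev$pause_class) & ev$pause_class == "L"
  follows_meal <- rep(FALSE, nrow(ev))
  if (nrow(ev) > 1) {
    seen_bout <- cumsum(isb) > 0
    follows_meal <- isL & seen_bout
  }
  imis <- ev$duration[follows_meal & complete]
  bd <- ev$duration[isb & complete]
  br <- (ev$amount / ev$duration)[isb]
  out <- list(total_intake = total,
              hourly_intake = total / normalise_hours,
              meal_sizes = meal_sizes,
              meal_durations = meal_durations[!is.na(meal_durations)],
              imis = imis,
              meal_count = length(meal_ids),
              bout_count = sum(isb),
              mean_bout_duration = if (length(bd)) mean(bd) else NA_real_,
              mean_bout_rate = if (any(isb)) mean(br, na.rm = TRUE) else NA_real_,
              window_hours = diff(w) / 3600)
  class(out) <- "feeding_summary"
  out
}

#' @export
print.feeding_summary <- function(x, ...) {
  cat(sprintf("Feeding summary over %.2f h:\n", x$window_hours))
  cat(sprintf("  total intake %.3f g (%.3f g/h); %d meals, %d bouts\n",
              x$total_intake, x$hourly_intake, x$meal_count, x$bout_count))
  if (length(x$meal_sizes))
    cat(sprintf("  mean meal size %.3f g; mean meal duration %.1f s\n",
                mean(x$meal_sizes), mean(x$meal_durations)))
  if (length(x$imis))
    cat(sprintf("  mean intermeal interval %.1f s (n = %d)\n",
                mean(x$imis), length(x$imis)))
  invisible(x)
}
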