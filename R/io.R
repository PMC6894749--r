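# Readers, writers, cleaning and meal labelling for bout-level event logs
# (CLAMS/BioDAQ-style monitors export per-bout timestamp/duration/amount
# tables), plus JSON round-tripping of model configuration.

#' Bout-file dialect
#'
#' Describes the column layout of a delimited bout-level file.
#'
#' @param subject_col,time_col,duration_col,amount_col Column names for the
#'   subject id, bout start time, duration (s), and amount (g).
#' @param sep Field separator.
#' @param time_format `NULL` for numeric seconds, otherwise a
#'   [strptime()] format used to parse timestamps.
#' @param lights_on,lights_off Clock times ("HH:MM") of the light cycle used
#'   to annotate photoperiod (defaults 06:00 / 18:00).
#' @return An object of class `"bout_dialect"`.
#' @export
bout_dialect <- function(subject_col = "subject", time_col = "time_s",
                         duration_col = "duration_s", amount_col = "amount_g",
                         sep = ",", time_format = NULL,
                         lights_on = "06:00", lights_off = "18:00") {
  structure(list(subject_col = subject_col, time_col = time_col,
                 duration_col = duration_col, amount_col = amount_col,
                 sep = sep, time_format = time_format,
                 lights_on = lights_on, lights_off = lights_off),
            class = "bout_dialect")
}

#' Cleaning rules for raw bout tables
#'
#' Rules applied by [clean_events()], in order: adjacent equal-magnitude
#' opposite-sign ("cancelling") pairs within a subject are dropped first,
#' then remaining non-positive amounts, then amount and implied-rate
#' outliers. The default bounds (amount in (0, `max_amount`] g, implied rate
#' at most `max_rate` g/s) are configurable approximations of typical
#' monitor-artefact screens.
#'
#' @param max_amount Upper bound on a single bout's amount (g).
#' @param max_rate Upper bound on the implied feeding rate (g/s).
#' @param min_amount Lower bound; amounts `<= min_amount` are dropped.
#' @param cancel_tol Absolute tolerance for the cancelling-pair match (g).
#' @return An object of class `"clean_rules"`.
#' @export
clean_rules <- function(max_amount = 10, max_rate = 0.2, min_amount = 0,
                        cancel_tol = 1e-9) {
  structure(list(max_amount = max_amount, max_rate = max_rate,
                 min_amount = min_amount, cancel_tol = cancel_tol),
            class = "clean_rules")
}

#' Read a bout-level event file into feeding sequences
#'
#' Parses a delimited bout table, optionally cleans it, and assembles one
#' [feeding_seq()] per subject in which the gaps between bouts become pause
#' events of class `"unknown"` (resolve them with [label_meals()]).
#' Unparseable rows are collected on the result as attribute `"bad_rows"`
#' and reported with a warning, never silently dropped.
#'
#' @param path File path.
#' @param dialect A [bout_dialect()].
#' @param window Optional `c(start, end)` observation window in seconds;
#'   defaults to the span of each subject's events.
#' @param clean `FALSE`, `TRUE` (default rules), or a [clean_rules()].
#' @param x_init Initial fullness attached to each sequence (g).
#' @return A named list of [feeding_seq()], one per subject, with the
#'   [clean_events()] report attached as attribute `"cleaning"` when
#'   cleaning was requested and a provenance record as attribute
#'   `"provenance"`.
#' @export
read_bout_events <- function(path, dialect = bout_dialect(), window = NULL,
                             clean = FALSE, x_init = 0) {
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE)
  need <- c(dialect$subject_col, dialect$time_col, dialect$duration_col,
            dialect$amount_col)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("bout file missing column(s): ", paste(miss, collapse = ", "))
  tm <- raw[[dialect$time_col]]
  if (!is.null(dialect$time_format)) {
    tt <- as.POSIXct(strptime(tm, dialect$time_format, tz = "UTC"))
    tsec <- as.numeric(tt) - min(as.numeric(tt), na.rm = TRUE)
  } else {
    tsec <- suppressWarnings(as.numeric(tm))
  }
  dur <- suppressWarnings(as.numeric(raw[[dialect$duration_col]]))
  amt <- suppressWarnings(as.numeric(raw[[dialect$amount_col]]))
  bad <- !is.finite(tsec) | !is.finite(dur) | dur <= 0 | !is.finite(amt)
  bad_rows <- raw[bad, , drop = FALSE]
  if (nrow(bad_rows))
    warning(nrow(bad_rows), " unparseable row(s) excluded; see attr(x, 'bad_rows')")
  tab <- data.frame(subject = as.character(raw[[dialect$subject_col]]),
                    time = tsec, duration = dur, amount = amt,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  report <- NULL
  if (!isFALSE(clean)) {
    rules <- if (isTRUE(clean)) clean_rules() else clean
    cl <- clean_events(tab, rules)
    tab <- cl$events
    report <- cl$report
  }
  out <- bout_table_to_sequences(tab, window = window, x_init = x_init)
  attr(out, "bad_rows") <- bad_rows
  attr(out, "cleaning") <- report
  attr(out, "provenance") <- list(
    path = path, md5 = unname(tools::md5sum(path)), read_at = Sys.time(),
    cleaned = !isFALSE(clean))
  out
}

# assemble per-subject sequences, bouts separated by unknown-class pauses
bout_table_to_sequences <- function(tab, window = NULL, x_init = 0) {
  split_tab <- split(tab, tab$subject)
  out <- lapply(split_tab, function(st) {
    st <- st[order(st$time), , drop = FALSE]
    ev <- data.frame(kind = "bout", start = st$time, duration = st$duration,
                     amount = st$amount, pause_class = NA_character_)
    if (nrow(st) > 1) {
      gap_start <- st$time[-nrow(st)] + st$duration[-nrow(st)]
      gap_len <- st$time[-1] - gap_start
      keep <- gap_len > 1e-9
      if (any(keep))
        ev <- rbind(ev, data.frame(kind = "pause", start = gap_start[keep],
                                   duration = gap_len[keep],
                                   amount = NA_real_,
                                   pause_class = "unknown"))
    }
    feeding_seq(ev, subject = st$subject[1], window = window,
                x_init = x_init)
  })
  names(out) <- names(split_tab)
  out
}

#' Write feeding sequences as a bout-level file
#'
#' Writes the bout events (pauses are implied by the gaps) in the given
#' dialect; the inverse of [read_bout_events()].
#'
#' @param seqs A [feeding_seq()] or named list of them.
#' @param path Output path.
#' @param dialect A [bout_dialect()].
#' @return `path`, invisibly.
#' @export
write_bout_events <- function(seqs, path, dialect = bout_dialect()) {
  if (inherits(seqs, "feeding_seq")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    b <- as.data.frame(s)
    b <- b[b$kind == "bout", , drop = FALSE]
    stats::setNames(
      data.frame(attr(s, "subject"), b$start, b$duration, b$amount),
      c(dialect$subject_col, dialect$time_col, dialect$duration_col,
        dialect$amount_col))
  })
  utils::write.table(do.call(rbind, rows), path, sep = dialect$sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clean a raw bout table
#'
#' Applies the [clean_rules()] to a raw bout table (columns `subject`,
#' `time`, `duration`, `amount`): cancelling adjacent pairs, non-positive
#' amounts, then amount/rate outliers. Cleaning never raises on content and
#' is idempotent.
#'
#' @param tab Data frame with columns `subject`, `time`, `duration`,
#'   `amount`.
#' @param rules A [clean_rules()].
#' @return List with `events` (the retained rows) and `report` (class
#'   `"cleaning_report"`: per-rule drop counts and the retained fraction).
#' @export
clean_events <- function(tab, rules = clean_rules()) {
  stopifnot(all(c("subject", "time", "duration", "amount") %in% names(tab)))
  n_in <- nrow(tab)
  drop <- rep(FALSE, n_in)
  reason <- rep(NA_character_, n_in)
  ord <- order(tab$subject, tab$time)
  tab <- tab[ord, , drop = FALSE]
  # cancelling pairs: adjacent rows of one subject, amounts a and -a
  if (n_in > 1) {
    for (i in seq_len(n_in - 1)) {
      if (drop[i] || drop[i + 1]) next
      if (tab$subject[i] == tab$subject[i + 1] &&
          abs(tab$amount[i] + tab$amount[i + 1]) <= rules$cancel_tol &&
          abs(tab$amount[i]) > rules$cancel_tol) {
        drop[c(i, i + 1)] <- TRUE
        reason[c(i, i + 1)] <- "cancelling"
      }
    }
  }
  sel <- !drop & tab$amount <= rules$min_amount
  drop[sel] <- TRUE; reason[sel] <- "nonpositive"
  sel <- !drop & tab$amount > rules$max_amount
  drop[sel] <- TRUE; reason[sel] <- "high_outlier"
  sel <- !drop & tab$amount / tab$duration > rules$max_rate
  drop[sel] <- TRUE; reason[sel] <- "rate_outlier"
  report <- structure(list(
    n_input = n_in,
    dropped = c(cancelling = sum(reason == "cancelling", na.rm = TRUE),
                nonpositive = sum(reason == "nonpositive", na.rm = TRUE),
                high_outlier = sum(reason == "high_outlier", na.rm = TRUE),
                rate_outlier = sum(reason == "rate_outlier", na.rm = TRUE)),
    retained = sum(!drop),
    retained_fraction = if (n_in) sum(!drop) / n_in else 1,
    rules = rules), class = "cleaning_report")
  list(events = tab[!drop, , drop = FALSE], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report: %d rows in, %d retained (%.1f%%)\n",
              x$n_input, x$retained, 100 * x$retained_fraction))
  for (nm in names(x$dropped))
    if (x$dropped[[nm]] > 0) cat(sprintf("  %-12s %d\n", nm, x$dropped[[nm]]))
  invisible(x)
}

#' Label pauses as within-meal or intermeal
#'
#' Resolves pause classes: either a fixed duration threshold (pauses of at
#' least `threshold` seconds become intermeal intervals `"L"`, shorter ones
#' within-meal pauses `"S"`), or a two-component Gaussian mixture on
#' log-duration whose crossover point becomes the split. The 300 s default
#' is a common meal-definition convention, not a property of the model;
#' downstream parameter estimates depend on it, so the labelling criterion
#' is recorded in the sequence metadata.
#'
#' @param seq A [feeding_seq()].
#' @param criterion `"threshold"` or `"mixture"`.
#' @param threshold Meal-definition threshold in seconds.
#' @return The sequence with `pause_class` set for every pause and the
#'   labelling recorded in attribute `"labelling"`. Bout events are never
#'   altered.
#' @export
label_meals <- function(seq, criterion = c("threshold", "mixture"),
                        threshold = 300) {
  criterion <- match.arg(criterion)
  ev <- as.data.frame(seq)
  isp <- ev$kind == "pause"
  info <- list(criterion = criterion)
  if (criterion == "mixture") {
    d <- log(ev$duration[isp])
    if (sum(isp) < 10) stop("mixture labelling needs at least 10 pauses")
    fit <- Mclust(d, G = 2, modelNames = "V", verbose = FALSE)
    mu <- fit$parameters$mean
    lo <- which.min(mu); hi <- which.max(mu)
    cl <- ifelse(fit$classification == hi, "L", "S")
    # crossover: smallest duration classified long
    threshold <- exp(min(d[cl == "L"]))
    info$component_means <- exp(mu)
    ev$pause_class[isp] <- cl
  } else {
    ev$pause_class[isp] <- ifelse(ev$duration[isp] >= threshold, "L", "S")
  }
  info$threshold <- threshold
  out <- feeding_seq(ev, subject = attr(seq, "subject"),
                     condition = attr(seq, "condition"),
                     window = attr(seq, "window"),
                     x_init = attr(seq, "x_init"))
  attr(out, "sham") <- attr(seq, "sham")
  attr(out, "labelling") <- info
  out
}

# --- JSON configuration round-trip -----------------------------------------

#' Read and write model configuration as JSON
#'
#' Serialises any combination of [feed_params()] (or a named list of them),
#' a [gut_model()], a [hyper_prior()], and an administration schedule to a
#' versioned JSON file, and reads it back with schema validation. A missing
#' gut `k` is filled with the default 0.00055 and flagged in the returned
#' provenance.
#'
#' @param path File path.
#' @param params A [feed_params()] or named list of them.
#' @param gut A [gut_model()].
#' @param hyper A [hyper_prior()].
#' @param schedule A data frame with columns `time`, `label`.
#' @return `write_feed_config()` returns `path` invisibly;
#'   `read_feed_config()` returns a list with elements `params`, `gut`,
#'   `hyper`, `schedule` (those present) and a `provenance` element.
#' @export
write_feed_config <- function(path, params = NULL, gut = NULL, hyper = NULL,
                              schedule = NULL) {
  obj <- list(format = "feedPDMP-config", version = 1L)
  if (!is.null(params)) {
    obj$params <- if (inherits(params, "feed_params"))
      as.list(unclass(params)) else lapply(params, function(p)
        as.list(unclass(as_feed_params(p))))
  }
  if (!is.null(gut))
    obj$gut <- list(law = gut$law, k = gut$k, gamma = gut$gamma,
                    epsilon_empty = gut$epsilon_empty)
  if (!is.null(hyper))
    obj$hyper <- list(mu_star = as.numeric(hyper$mu_star),
                      mu_prior_sd = hyper$mu_prior_sd,
                      tau_scale = hyper$tau_scale, lkj_eta = hyper$lkj_eta)
  if (!is.null(schedule)) obj$schedule <- as.data.frame(schedule)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feed_config
#' @export
read_feed_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "feedPDMP-config")
    stop("not a feedPDMP configuration file (missing format marker)")
  out <- list()
  prov <- list(path = path, md5 = unname(tools::md5sum(path)),
               version = obj$version, defaults_injected = character(0))
  if (!is.null(obj$params)) {
    out$params <- if (!is.null(obj$params$lambda_F)) {
      as_feed_params(unlist(obj$params))
    } else {
      lapply(obj$params, function(p) as_feed_params(unlist(p)))
    }
  }
  if (!is.null(obj$gut)) {
    g <- obj$gut
    if (is.null(g$law)) stop("config field 'gut$law' is required")
    if (is.null(g$k)) {
      g$k <- 0.00055
      prov$defaults_injected <- c(prov$defaults_injected, "gut$k = 0.00055")
    }
    out$gut <- gut_model(law = g$law, k = g$k,
                         gamma = if (identical(g$law, "power")) g$gamma,
                         epsilon_empty = g$epsilon_empty %||% 1e-9)
  }
  if (!is.null(obj$hyper)) {
    h <- obj$hyper
    for (f in c("mu_star", "mu_prior_sd", "tau_scale", "lkj_eta"))
      if (is.null(h[[f]])) stop("config field 'hyper$", f, "' is required")
    out$hyper <- hyper_prior(h$mu_star, h$mu_prior_sd, h$tau_scale, h$lkj_eta)
  }
  if (!is.null(obj$schedule)) {
    sc <- as.data.frame(obj$schedule)
    if (!all(c("time", "label") %in% names(sc)))
      stop("config field 'schedule' needs columns 'time' and 'label'")
    out$schedule <- sc
  }
  out$provenance <- prov
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
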