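#' Meal-termination probability
#'
#' Probability that the meal terminates (the process enters an intermeal
#' interval rather than a short pause) after a bout ending at fullness `x`:
#' \deqn{p(x) = \frac{1}{1 + e^{-T_1 (x - T_2)}}.}
#' `T1` sets the sharpness of the decision and `T2` the fullness at which
#' termination is a coin flip; `T1 = 0` gives a fullness-independent 1/2.
#'
#' @param x Fullness (grams), vectorised.
#' @param T1 Sharpness (1/g, >= 0).
#' @param T2 Threshold (g).
#' @return Termination probability in (0, 1).
#' @export
termination_probability <- function(x, T1, T2) {
  stats::plogis(T1 * (x - T2))
}

#' Draw feeding bouts
#'
#' Samples bout durations (Exponential with rate `lambda_F`) and per-bout
#' feeding rates (Normal with mean `mu_F` and sd `sigma_F`, truncated below
#' at zero); the amount consumed is rate times duration. Truncation keeps
#' negative feeding rates out of the generative model while leaving the
#' density in closed form for the likelihood.
#'
#' @param params A [feed_params()].
#' @param n Number of bouts to draw.
#' @return A data frame with columns `duration` (s), `rate` (g/s),
#'   `amount` (g).
#' @export
sample_bout <- function(params, n = 1) {
  params <- as_feed_params(params)
  dur <- stats::rexp(n, params[["lambda_F"]])
  rate <- rtruncnorm0(n, params[["mu_F"]], params[["sigma_F"]])
  data.frame(duration = dur, rate = rate, amount = rate * dur)
}

# truncated-below-zero normal by inverse CDF (one uniform per draw)
rtruncnorm0 <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Draw an intermeal interval by exact hazard inversion
#'
#' Samples the intermeal-interval duration given fullness `x0` at meal
#' termination: the hazard is \eqn{\lambda_L(x(t)) = 1/(L_1 + L_2 x(t))}
#' along the emptying trajectory, so a unit-exponential deviate \eqn{E} is
#' mapped through the inverse of the cumulative hazard
#' [integrated_imi_hazard()]. For the sqrt emptying law the inversion is
#' closed-form; other laws use bracketed root finding (the hazard is bounded
#' between \eqn{1/(L_1 + L_2 x_0)} and \eqn{1/L_1}, which gives exact
#' brackets).
#'
#' @param x0 Fullness at interval onset (grams).
#' @param params A [feed_params()].
#' @param gut A [gut_model()].
#' @param n Number of draws.
#' @param min_t Optional left truncation (seconds): draws are conditioned on
#'   the interval exceeding `min_t` (used by the conditional-survival
#'   refractory semantics).
#' @return Interval durations in seconds.
#' @export
sample_imi_duration <- function(x0, params, gut = gut_model(), n = 1,
                                min_t = 0) {
  params <- as_feed_params(params)
  L1 <- params[["L1"]]; L2 <- params[["L2"]]
  E <- stats::rexp(n)
  base <- if (min_t > 0) integrated_imi_hazard(x0, min_t, L1, L2, gut) else 0
  target <- base + E
  if (L2 == 0 || x0 == 0) return(target * L1)
  if (gut$law == "sqrt") {
    k <- gut$k
    s0 <- sqrt(x0)
    te <- 2 * s0 / k
    b <- sqrt(L2 / L1)
    c0 <- 2 / (k * L1 * b)
    lam_te <- c0 * atan(b * s0)
    out <- numeric(n)
    post <- target >= lam_te
    out[post] <- te + (target[post] - lam_te) * L1
    if (any(!post)) {
      u <- tan(atan(b * s0) - target[!post] / c0) / b
      out[!post] <- 2 * (s0 - u) / k
    }
    out
  } else {
    vapply(target, function(tg) {
      lo <- L1 * tg
      hi <- (L1 + L2 * x0) * tg
      stats::uniroot(function(t)
        integrated_imi_hazard(x0, t, L1, L2, gut) - tg,
        lower = lo, upper = hi, tol = 1e-6)$root
    }, numeric(1))
  }
}

#' Intervention specification for in-silico experiments
#'
#' Bundles the behavioural interventions the simulator understands: a
#' post-meal refractory period, sham feeding (gut filling disabled while
#' intake is still recorded), and timed parameter-set switches modelling drug
#' administration.
#'
#' @param refractory Minimum intermeal interval in seconds (>= 0).
#' @param refractory_mode `"extend"` lengthens each sampled interval to at
#'   least the refractory period (interval := max(interval, R));
#'   `"condition"` instead draws the interval conditioned on surviving past
#'   R (hazard suppressed during the refractory period, then resumed). The
#'   two semantics differ: `"extend"` piles probability mass at exactly R.
#' @param sham If `TRUE`, feeding does not increase fullness; consumption is
#'   still recorded, so meal termination is evaluated at the un-filled
#'   fullness.
#' @param schedule Optional data frame with columns `time` (s) and `label`
#'   naming which parameter set applies to draws initiated from that time
#'   onward; labels index the named list of parameter sets passed to
#'   [simulate_feeding()]. An in-progress interval is not resampled at a
#'   switch.
#' @return An object of class `"intervention_spec"`.
#' @export
intervention_spec <- function(refractory = 0,
                              refractory_mode = c("extend", "condition"),
                              sham = FALSE, schedule = NULL) {
  refractory_mode <- match.arg(refractory_mode)
  if (refractory < 0) stop("'refractory' must be >= 0")
  if (!is.null(schedule)) {
    schedule <- as.data.frame(schedule)
    if (!all(c("time", "label") %in% names(schedule)))
      stop("'schedule' needs columns 'time' and 'label'")
    schedule <- schedule[order(schedule$time), ]
  }
  structure(list(refractory = refractory, refractory_mode = refractory_mode,
                 sham = isTRUE(sham), schedule = schedule),
            class = "intervention_spec")
}

#' Simulate bout-level feeding behaviour
#'
#' Exact simulation of the feeding process: starting in the intermeal state
#' at fullness `x_init`, the process alternates intermeal intervals (drawn by
#' hazard inversion at the current fullness), feeding bouts, and, after each
#' bout, a meal-termination decision at the bout-end fullness that routes to
#' either a short within-meal pause or the next intermeal interval. Fullness
#' fills linearly during bouts and empties under the gut model otherwise.
#' Events truncated by the window end are emitted with `censored = TRUE`.
#'
#' @param params A [feed_params()], or a named list of them when `intervention`
#'   carries a parameter-switch schedule (the label active at a draw's
#'   initiation time governs that draw).
#' @param gut A [gut_model()].
#' @param window Observation window: a length in seconds or a `c(start, end)`
#'   pair.
#' @param x_init Fullness at the window start (grams). Fasted protocols start
#'   at 0.
#' @param intervention An [intervention_spec()] (default: none).
#' @param subject,condition Metadata labels stored on the result.
#' @param seed Optional integer seed (`set.seed` is called if given).
#' @return A [feeding_seq()]; the number of meal terminations (F to L
#'   transitions) is stored in attribute `n_terminations`, and the realised
#'   termination probabilities in attribute `termination_draws`.
#' @examples
#' seq <- simulate_feeding(feed_params(), window = 6 * 3600, seed = 1)
#' summary(seq)
#' @export
simulate_feeding <- function(params, gut = gut_model(), window = 12 * 3600,
                             x_init = 0, intervention = intervention_spec(),
                             subject = "sim", condition = "simulated",
                             seed = NULL) {
  check_gut(gut)
  if (!inherits(intervention, "intervention_spec"))
    stop("'intervention' must be an intervention_spec()")
  if (!is.null(seed)) set.seed(seed)
  if (length(window) == 1L) window <- c(0, window)
  W0 <- window[1]; W <- window[2]
  if (W < W0) stop("window end before start")
  sched <- intervention$schedule
  if (inherits(params, "feed_params")) {
    if (!is.null(sched)) stop("a schedule requires a named list of parameter sets")
    params_at <- function(t) params
  } else {
    if (is.null(sched)) stop("multiple parameter sets require a schedule")
    params <- lapply(params, as_feed_params)
    if (!all(sched$label %in% names(params)))
      stop("schedule labels missing from 'params': ",
           paste(setdiff(sched$label, names(params)), collapse = ", "))
    if (any(sched$time < W0 | sched$time > W))
      stop("schedule switch times must lie within the window")
    params_at <- function(t) {
      i <- findInterval(t, sched$time)
      if (i == 0L) stop("no parameter set active before the first switch; ",
                        "add a switch at the window start")
      params[[sched$label[i]]]
    }
  }

  # preallocated growing event store
  cap <- 256L
  kind <- character(cap); start <- numeric(cap); duration <- numeric(cap)
  amount <- rep(NA_real_, cap); pclass <- rep(NA_character_, cap)
  fstart <- numeric(cap); cens <- logical(cap)
  ne <- 0L
  push <- function(k, s, d, a, pc, fs, cn) {
    ne <<- ne + 1L
    if (ne > cap) {
      cap <<- cap * 2L
      length(kind) <<- cap; length(start) <<- cap; length(duration) <<- cap
      length(amount) <<- cap; length(pclass) <<- cap; length(fstart) <<- cap
      length(cens) <<- cap
    }
    kind[ne] <<- k; start[ne] <<- s; duration[ne] <<- d; amount[ne] <<- a
    pclass[ne] <<- pc; fstart[ne] <<- fs; cens[ne] <<- cn
  }

  sqrt_law <- gut$law == "sqrt"
  k_gut <- gut$k
  eps <- gut$epsilon_empty
  decay <- function(x0, dt) {            # inlined sqrt-law emptying
    if (sqrt_law) {
      s <- sqrt(x0) - k_gut * dt / 2
      x1 <- if (s > 0) s * s else 0
      if (x1 <= eps) 0 else x1
    } else empty_fullness(x0, dt, gut)
  }
  draw_imi <- function(x0, pm) {          # one exact inversion draw
    L1 <- pm[["L1"]]; L2 <- pm[["L2"]]
    E <- stats::rexp(1)
    if (L2 == 0 || x0 == 0) return(E * L1)
    if (sqrt_law) {
      s0 <- sqrt(x0)
      b <- sqrt(L2 / L1)
      c0 <- 2 / (k_gut * L1 * b)
      a0 <- atan(b * s0)
      if (E >= c0 * a0) {
        2 * s0 / k_gut + (E - c0 * a0) * L1
      } else {
        2 * (s0 - tan(a0 - E / c0) / b) / k_gut
      }
    } else sample_imi_duration(x0, pm, gut)
  }

  t <- W0; x <- x_init
  n_term <- 0L
  term_probs <- numeric(cap); npr <- 0L
  refr <- intervention$refractory
  cond_refr <- refr > 0 && intervention$refractory_mode == "condition"
  sham <- intervention$sham
  state <- "L"
  while (t < W) {
    pm <- params_at(t)
    if (state == "L") {
      imi <- if (cond_refr) {
        sample_imi_duration(x, pm, gut, min_t = refr)
      } else {
        max(draw_imi(x, pm), refr)
      }
      if (t + imi >= W) {
        push("pause", t, W - t, NA_real_, "L", x, TRUE)
        break
      }
      push("pause", t, imi, NA_real_, "L", x, FALSE)
      x <- decay(x, imi)
      t <- t + imi
      state <- "F"
    } else if (state == "F") {
      dur <- stats::rexp(1, pm[["lambda_F"]])
      rho <- rtruncnorm0(1, pm[["mu_F"]], pm[["sigma_F"]])
      if (t + dur >= W) {
        d <- W - t
        push("bout", t, d, rho * d, NA_character_, x, TRUE)
        break
      }
      push("bout", t, dur, rho * dur, NA_character_, x, FALSE)
      if (!sham) x <- x + rho * dur
      t <- t + dur
      p <- stats::plogis(pm[["T1"]] * (x - pm[["T2"]]))
      npr <- npr + 1L
      if (npr > length(term_probs)) length(term_probs) <- 2L * npr
      term_probs[npr] <- p
      if (stats::runif(1) < p) {
        n_term <- n_term + 1L
        state <- "L"
      } else {
        state <- "S"
      }
    } else { # short within-meal pause
      d <- stats::rexp(1, pm[["lambda_S"]])
      if (t + d >= W) {
        push("pause", t, W - t, NA_real_, "S", x, TRUE)
        break
      }
      push("pause", t, d, NA_real_, "S", x, FALSE)
      x <- decay(x, d)
      t <- t + d
      state <- "F"
    }
  }
  term_probs <- term_probs[seq_len(npr)]
  ev <- data.frame(kind = kind[seq_len(ne)], start = start[seq_len(ne)],
                   duration = duration[seq_len(ne)],
                   amount = amount[seq_len(ne)],
                   pause_class = pclass[seq_len(ne)],
                   fullness_start = fstart[seq_len(ne)],
                   censored = cens[seq_len(ne)])
  out <- feeding_seq(ev, subject = subject, condition = condition,
                     window = c(W0, W), x_init = x_init)
  attr(out, "n_terminations") <- n_term
  attr(out, "termination_draws") <- term_probs
  attr(out, "sham") <- intervention$sham
  out
}

#' Simulate method for feeding-model parameters
#'
#' Draws `nsim` independent event logs from the model at these parameters.
#'
#' @param object A [feed_params()].
#' @param nsim Number of sequences.
#' @param seed Optional seed.
#' @param ... Passed to [simulate_feeding()] (`gut`, `window`, `x_init`,
#'   `intervention`, ...).
#' @return A list of [feeding_seq()] objects (length `nsim`), or a single
#'   sequence if `nsim = 1`.
#' @export
simulate.feed_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_feeding(object, ..., subject = paste0("sim", i)))
  if (nsim == 1L) out[[1]] else out
}
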