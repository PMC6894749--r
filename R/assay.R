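#' Simplified, regression-based feeding-behaviour assay
#'
#' An MCMC-free estimate of every behavioural component from pooled
#' bout-level data: a logistic regression of meal termination on fullness at
#' bout end (whose slope and intercept map exactly onto the sigmoid
#' termination kernel via `T1 = slope`, `T2 = -intercept/slope`), a linear
#' regression of intermeal interval on fullness at meal termination,
#' exponential fits for bout and short-pause durations, and a truncated
#' normal fit for pooled feeding rates. Individuals within a group are
#' pooled, so interindividual variation is deliberately discarded.
#'
#' @param seqs A [feeding_seq()] or list of them (pooled; pause classes must
#'   be resolved).
#' @param gut A [gut_model()] used to reconstruct fullness at event
#'   boundaries.
#' @param x_init Initial fullness passed to the trajectory reconstruction.
#' @return An object of class `"feed_assay"`: list with `termination`
#'   (glm fit summary and implied `T1`, `T2`), `imi` (lm fit: intercept s,
#'   slope s/g, standard errors), `bout` (exponential rate `lambda_F` and
#'   mean), `short_pause` (rate `lambda_S`), `rate` (truncated-normal `mu_F`,
#'   `sigma_F`), `implied_params` (a partial parameter vector), and pooled
#'   record counts.
#' @export
feed_assay <- function(seqs, gut = gut_model(), x_init = NULL) {
  if (inherits(seqs, "feeding_seq")) seqs <- list(seqs)
  dats <- lapply(seqs, seq_lik_data, gut = gut, x_init = x_init)
  rx <- unlist(lapply(dats, `[[`, "route_x"))
  rl <- unlist(lapply(dats, `[[`, "route_L"))
  term <- fit_termination_logistic(rx, rl)
  # pooled records: complete intervals that follow a meal termination (the
  # leading interval of a window starts at x_init, not at a termination)
  imi_t <- unlist(lapply(dats, function(d)
    d$imi_dur[!d$imi_cens & d$imi_after_meal]))
  imi_x <- unlist(lapply(dats, function(d)
    d$imi_x0[!d$imi_cens & d$imi_after_meal]))
  imi <- fit_imi_linear(imi_x, imi_t)
  bd <- unlist(lapply(dats, function(d) d$bout_dur[!d$bout_cens]))
  sp <- unlist(lapply(dats, function(d) d$s_dur[!d$s_cens]))
  rt <- unlist(lapply(dats, `[[`, "rate"))
  rate_fit <- fit_rate_truncnorm(rt)
  out <- list(
    termination = term,
    imi = imi,
    bout = list(lambda_F = 1 / mean(bd), mean_duration = mean(bd), n = length(bd)),
    short_pause = list(lambda_S = 1 / mean(sp), mean_duration = mean(sp),
                       n = length(sp)),
    rate = rate_fit,
    implied_params = c(lambda_F = 1 / mean(bd), mu_F = rate_fit$mu_F,
                       sigma_F = rate_fit$sigma_F, lambda_S = 1 / mean(sp),
                       T1 = term$T1, T2 = term$T2,
                       L1 = unname(imi$intercept), L2 = unname(imi$slope)),
    n_pooled = c(bouts = length(bd), routings = length(rx),
                 imis = length(imi_t)))
  class(out) <- "feed_assay"
  out
}

#' @export
print.feed_assay <- function(x, ...) {
  cat("Simplified feeding-behaviour assay (pooled fits)\n")
  cat(sprintf("  termination: T1 = %.3f 1/g, T2 = %.3f g%s\n", x$termination$T1,
              x$termination$T2,
              if (x$termination$separation) " [complete separation flagged]" else ""))
  cat(sprintf("  intermeal interval: %.1f s + %.1f s/g x fullness\n",
              x$imi$intercept, x$imi$slope))
  cat(sprintf("  bouts: lambda_F = %.4f 1/s; rates: mu_F = %.4g, sigma_F = %.4g g/s\n",
              x$bout$lambda_F, x$rate$mu_F, x$rate$sigma_F))
  cat(sprintf("  short pauses: lambda_S = %.4f 1/s\n", x$short_pause$lambda_S))
  invisible(x)
}

#' Logistic regression of meal termination on fullness
#'
#' Pooled bout-end records (fullness, terminated flag) are fitted by
#' maximum-likelihood logistic regression. The fitted linear predictor
#' `intercept + slope * x` equals the termination kernel
#' \eqn{T_1 (x - T_2)}, so `T1 = slope` and `T2 = -intercept/slope`.
#' Complete separation is detected and flagged; a ridge-penalised refit is
#' used in that case.
#'
#' @param fullness Fullness at bout termination (g).
#' @param terminated Logical: did the meal terminate (enter an intermeal
#'   interval)?
#' @return List with `intercept`, `slope`, their standard errors, implied
#'   `T1`, `T2`, the `glm` object, and a `separation` flag.
#' @export
fit_termination_logistic <- function(fullness, terminated) {
  if (length(unique(terminated)) < 2L)
    stop("both outcome classes (terminated and continued) must be present")
  df <- data.frame(x = fullness, y = as.logical(terminated))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     data = df))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 1e3) ||
    max(stats::fitted(fit)) > 1 - 1e-8 && min(stats::fitted(fit)) < 1e-8
  if (sep) {
    # mild ridge penalty via data augmentation keeps the fit finite
    aug <- data.frame(x = c(df$x, mean(df$x), mean(df$x)),
                      y = c(df$y, TRUE, FALSE))
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                       data = aug))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  list(intercept = intercept, slope = slope,
       se = stats::setNames(se, c("intercept", "slope")),
       T1 = slope, T2 = if (abs(slope) > 1e-12) -intercept / slope else NA_real_,
       separation = sep, fit = fit)
}

#' Linear regression of intermeal interval on fullness
#'
#' Least-squares fit of pooled (fullness at meal termination, following
#' intermeal interval) records. Under the constant-hazard limit (`L2 = 0`)
#' the expected interval is `L1` regardless of fullness, so the slope tests
#' fullness dependence directly.
#'
#' @param fullness Fullness at meal termination (g).
#' @param imi Following intermeal interval (s).
#' @return List with `intercept` (s), `slope` (s/g), standard errors,
#'   confidence intervals, and the `lm` object.
#' @export
fit_imi_linear <- function(fullness, imi) {
  if (length(imi) < 3L) stop("need at least 3 complete intermeal intervals")
  fit <- stats::lm(imi ~ fullness)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- stats::confint(fit)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       se = stats::setNames(unname(se), c("intercept", "slope")),
       ci = ci, fit = fit)
}

# truncated-at-zero normal fit of pooled feeding rates by ML
fit_rate_truncnorm <- function(rates) {
  stopifnot(length(rates) >= 2L)
  nll <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    -sum(stats::dnorm(rates, mu, sig, log = TRUE) -
         stats::pnorm(0, mu, sig, lower.tail = FALSE, log.p = TRUE))
  }
  st <- c(mean(rates), log(stats::sd(rates) + 1e-12))
  opt <- stats::optim(st, nll, method = "BFGS")
  list(mu_F = opt$par[1], sigma_F = exp(opt$par[2]), n = length(rates),
       convergence = opt$convergence)
}

#' Satiety ratio and its intermeal-interval predictions
#'
#' The classical satiety-ratio baseline: the ratio of the intermeal interval
#' following the first meal to the size of that first meal (s/g; larger =
#' more satiating). The predicted interval after any later meal is
#' `ratio * meal size`. Only the first meal informs the ratio — precisely
#' the weakness this baseline is criticised for, since it ignores residual
#' fullness carried over from earlier meals.
#'
#' @param seq A [feeding_seq()] with pause classes resolved.
#' @return List with `ratio` (s/g), `first_meal_size` (g), `first_imi` (s),
#'   and a data frame `predictions` pairing each later meal's size, the
#'   predicted interval, and the observed interval (where complete).
#' @export
satiety_ratio <- function(seq) {
  ev <- as.data.frame(seq)
  idx <- meal_index(seq)
  if (!any(!is.na(idx))) stop("no meals in sequence")
  meal_ids <- sort(unique(idx[!is.na(idx)]))
  sizes <- vapply(meal_ids, function(m)
    sum(ev$amount[!is.na(idx) & idx == m & ev$kind == "bout"]), numeric(1))
  # interval following each meal: first complete L pause after its last event
  follow_imi <- vapply(meal_ids, function(m) {
    last_row <- max(which(!is.na(idx) & idx == m))
    nxt <- which(seq_len(nrow(ev)) > last_row & ev$kind == "pause" &
                 ev$pause_class == "L")
    if (length(nxt) && !ev$censored[nxt[1]] && nxt[1] == last_row + 1L)
      ev$duration[nxt[1]] else NA_real_
  }, numeric(1))
  if (is.na(follow_imi[1]))
    stop("first meal has no complete following intermeal interval")
  ratio <- follow_imi[1] / sizes[1]
  later <- seq_along(meal_ids)[-1]
  preds <- data.frame(meal = meal_ids[later], size = sizes[later],
                      predicted_imi = ratio * sizes[later],
                      observed_imi = follow_imi[later])
  list(ratio = ratio, first_meal_size = sizes[1], first_imi = follow_imi[1],
       predictions = preds)
}

#' Model-free moving-window average of intermeal interval against fullness
#'
#' Orders pooled (fullness at meal termination, intermeal interval) records
#' by fullness and averages the interval within a sliding fullness window —
#' the model-free check that fullness is informative of the interval.
#'
#' @param fullness Fullness at meal termination (g).
#' @param imi Following intermeal interval (s).
#' @param width Window width in grams; default 10 percent of the pooled
#'   fullness range.
#' @param min_count Minimum records per window; emptier windows are skipped
#'   with a warning.
#' @param n_centres Number of evaluation points across the fullness range.
#' @return Data frame with `fullness` (window centre), `mean_imi`, and `n`
#'   (records in window).
#' @export
moving_window_imi <- function(fullness, imi, width = NULL, min_count = 20,
                              n_centres = 50) {
  stopifnot(length(fullness) == length(imi), length(imi) >= 1)
  if (length(unique(fullness)) == 1L)
    return(data.frame(fullness = fullness[1], mean_imi = mean(imi),
                      n = length(imi)))
  rng <- range(fullness)
  if (is.null(width)) width <- 0.1 * diff(rng)
  centres <- seq(rng[1], rng[2], length.out = n_centres)
  rows <- lapply(centres, function(cc) {
    inw <- abs(fullness - cc) <= width / 2
    if (sum(inw) < min_count) return(NULL)
    data.frame(fullness = cc, mean_imi = mean(imi[inw]), n = sum(inw))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    warning("all windows below 'min_count'; returning the global mean")
    return(data.frame(fullness = mean(rng), mean_imi = mean(imi),
                      n = length(imi)))
  }
  if (any(!keep)) warning(sum(!keep), " window(s) skipped (too few records)")
  do.call(rbind, rows[keep])
}
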