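#' Log-density of an intermeal interval
#'
#' Exact density of the fullness-dependent intermeal interval: with hazard
#' \eqn{\lambda_L(x) = 1/(L_1 + L_2 x)} evaluated along the emptying
#' trajectory from `x0`, the interval duration has density
#' \deqn{p(t \mid x_0) = \lambda_L(x(t))\, e^{-\Lambda(t)},}
#' where \eqn{\Lambda} is [integrated_imi_hazard()]. With `L2 = 0` (or
#' `x0 = 0`) this reduces to an Exponential with mean `L1`.
#'
#' @param t Interval duration(s), seconds (> 0), vectorised.
#' @param x0 Fullness at interval onset (grams, scalar).
#' @param params A [feed_params()] (only `L1`, `L2` are used).
#' @param gut A [gut_model()].
#' @return Log-density values.
#' @export
imi_logpdf <- function(t, x0, params, gut = gut_model()) {
  params <- as_feed_params(params)
  if (any(t <= 0)) stop("'t' must be > 0")
  L1 <- params[["L1"]]; L2 <- params[["L2"]]
  xt <- empty_fullness(rep(x0, length(t)), t, gut)
  -log(L1 + L2 * xt) - integrated_imi_hazard(x0, t, L1, L2, gut)
}

#' Log survival of an intermeal interval
#'
#' \eqn{\log P(T > t) = -\Lambda(t)}; used for intervals right-censored by
#' the observation window.
#'
#' @inheritParams imi_logpdf
#' @param t Elapsed time(s), seconds (>= 0).
#' @return Log survival probabilities (<= 0).
#' @export
imi_logsurvival <- function(t, x0, params, gut = gut_model()) {
  params <- as_feed_params(params)
  -integrated_imi_hazard(x0, t, params[["L1"]], params[["L2"]], gut)
}

# --- sequence decomposition -------------------------------------------------

# Decompose a feeding sequence into the sufficient event-level terms for the
# likelihood. Fullness at each boundary is recomputed from the observed
# events via the gut model, never trusted from file metadata.
seq_lik_data <- function(seq, gut = gut_model(), x_init = NULL) {
  ev <- as.data.frame(seq)
  if (is.null(x_init)) {
    x_init <- attr(seq, "x_init")
    if (is.null(x_init)) x_init <- 0
  }
  if (nrow(ev) == 0L)
    return(list(bout_dur = numeric(0), bout_cens = logical(0),
                rate = numeric(0), route_x = numeric(0), route_L = logical(0),
                s_dur = numeric(0), s_cens = logical(0),
                imi_dur = numeric(0), imi_x0 = numeric(0),
                imi_cens = logical(0), sham = isTRUE(attr(seq, "sham"))))
  if (any(ev$kind == "pause" & ev$pause_class == "unknown"))
    stop("sequence has unresolved pause classes; run label_meals() first")
  sham <- isTRUE(attr(seq, "sham"))
  w <- attr(seq, "window")
  # fullness at each event start, recomputed from events
  x <- x_init
  t_cur <- w[1]
  n <- nrow(ev)
  x_start <- numeric(n)
  x_end <- numeric(n)
  for (i in seq_len(n)) {
    if (ev$start[i] > t_cur) x <- empty_fullness(x, ev$start[i] - t_cur, gut)
    x_start[i] <- x
    if (ev$kind[i] == "bout") {
      if (!sham) x <- x + ev$amount[i]
    } else {
      x <- empty_fullness(x, ev$duration[i], gut)
    }
    x_end[i] <- x
    t_cur <- ev$start[i] + ev$duration[i]
  }
  isb <- ev$kind == "bout"
  cens <- ev$censored
  # routing: complete bouts followed by a classed pause
  route_x <- numeric(0); route_L <- logical(0)
  bi <- which(isb & !cens)
  for (i in bi) {
    if (i < n && ev$kind[i + 1L] == "pause") {
      route_x <- c(route_x, x_end[i])
      route_L <- c(route_L, ev$pause_class[i + 1L] == "L")
    }
  }
  isS <- !isb & ev$pause_class == "S"
  isL <- !isb & ev$pause_class == "L"
  after_meal <- c(FALSE, isb[-n])  # previous event is a bout
  list(bout_dur = ev$duration[isb], bout_cens = cens[isb],
       rate = (ev$amount / ev$duration)[isb],
       route_x = route_x, route_L = route_L,
       s_dur = ev$duration[isS], s_cens = cens[isS],
       imi_dur = ev$duration[isL], imi_x0 = x_start[isL],
       imi_cens = cens[isL], imi_after_meal = after_meal[isL], sham = sham)
}

# log(1/(1+exp(-a))) stably
log_sigmoid <- function(a) ifelse(a > 0, -log1p(exp(-a)), a - log1p(exp(a)))

# pure-R likelihood over decomposed terms; works under any gut law
seq_loglik_terms <- function(d, p, gut) {
  lamF <- p[["lambda_F"]]; muF <- p[["mu_F"]]; sigF <- p[["sigma_F"]]
  lamS <- p[["lambda_S"]]; T1 <- p[["T1"]]; T2 <- p[["T2"]]
  L1 <- p[["L1"]]; L2 <- p[["L2"]]
  ll <- 0
  if (length(d$bout_dur)) {
    ll <- ll + sum(ifelse(d$bout_cens, -lamF * d$bout_dur,
                          log(lamF) - lamF * d$bout_dur))
    ll <- ll + sum(stats::dnorm(d$rate, muF, sigF, log = TRUE) -
                   stats::pnorm(0, muF, sigF, lower.tail = FALSE, log.p = TRUE))
  }
  if (length(d$route_x)) {
    a <- T1 * (d$route_x - T2)
    ll <- ll + sum(ifelse(d$route_L, log_sigmoid(a), log_sigmoid(-a)))
  }
  if (length(d$s_dur))
    ll <- ll + sum(ifelse(d$s_cens, -lamS * d$s_dur,
                          log(lamS) - lamS * d$s_dur))
  for (j in seq_along(d$imi_dur)) {
    x0 <- d$imi_x0[j]; t <- d$imi_dur[j]
    lam <- integrated_imi_hazard(x0, t, L1, L2, gut)
    ll <- ll - lam
    if (!d$imi_cens[j]) {
      xt <- empty_fullness(x0, t, gut)
      ll <- ll - log(L1 + L2 * xt)
    }
  }
  ll
}

#' Exact log-likelihood of a feeding sequence
#'
#' Sums the event-level log terms of the process: Exponential bout and
#' short-pause durations, zero-truncated Normal per-bout feeding rates, the
#' sigmoid meal-termination decision at each bout-end fullness, and the
#' time-varying-hazard intermeal-interval density at the fullness at meal
#' termination. Events right-censored by the window contribute the matching
#' log-survival instead of a log-density. Fullness at every boundary is
#' recomputed from the observed events under the gut model.
#'
#' @param seq A [feeding_seq()] with pause classes resolved.
#' @param params A [feed_params()].
#' @param gut A [gut_model()].
#' @param x_init Fullness at window start; defaults to the sequence's
#'   `x_init` attribute (0 for fasted-start protocols).
#' @param by_event If `TRUE`, also return the per-component breakdown.
#' @return The log-likelihood (scalar), or a list with `loglik` and a
#'   component table when `by_event = TRUE`.
#' @export
sequence_loglik <- function(seq, params, gut = gut_model(), x_init = NULL,
                            by_event = FALSE) {
  params <- as_feed_params(params)
  d <- seq_lik_data(seq, gut, x_init)
  ll <- seq_loglik_terms(d, params, gut)
  if (!by_event) return(ll)
  comp <- c(
    bout_durations = sum(ifelse(d$bout_cens, -params[["lambda_F"]] * d$bout_dur,
                                log(params[["lambda_F"]]) -
                                  params[["lambda_F"]] * d$bout_dur)),
    bout_rates = sum(stats::dnorm(d$rate, params[["mu_F"]], params[["sigma_F"]],
                                  log = TRUE) -
                     stats::pnorm(0, params[["mu_F"]], params[["sigma_F"]],
                                  lower.tail = FALSE, log.p = TRUE)),
    routing = {
      a <- params[["T1"]] * (d$route_x - params[["T2"]])
      sum(ifelse(d$route_L, log_sigmoid(a), log_sigmoid(-a)))
    },
    short_pauses = sum(ifelse(d$s_cens, -params[["lambda_S"]] * d$s_dur,
                              log(params[["lambda_S"]]) -
                                params[["lambda_S"]] * d$s_dur)),
    imis = {
      tot <- 0
      for (j in seq_along(d$imi_dur)) {
        tot <- tot + if (d$imi_cens[j])
          imi_logsurvival(d$imi_dur[j], d$imi_x0[j], params, gut)
        else imi_logpdf(d$imi_dur[j], d$imi_x0[j], params, gut)
      }
      tot
    })
  list(loglik = ll, components = comp)
}

# fast path: value + gradient on the natural scale via compiled code
# (sqrt and linear emptying laws); falls back to R value + finite-difference
# gradient for other laws.
seq_loglik_grad <- function(d, p, gut) {
  if (gut$law %in% c("sqrt", "linear")) {
    law <- if (gut$law == "sqrt") 0L else 1L
    res <- seq_loglik_cpp(d$bout_dur, d$bout_cens, d$rate,
                          d$route_x, d$route_L, d$s_dur, d$s_cens,
                          d$imi_dur, d$imi_x0, d$imi_cens,
                          as.numeric(p[param_names()]), law, gut$k)
    list(value = res$value, grad = stats::setNames(res$grad, param_names()))
  } else {
    val <- seq_loglik_terms(d, p, gut)
    g <- vapply(param_names(), function(nm) {
      h <- max(abs(p[[nm]]), 1e-4) * 1e-6
      p1 <- p; p1[[nm]] <- p[[nm]] + h
      p2 <- p; p2[[nm]] <- p[[nm]] - h
      (seq_loglik_terms(d, p1, gut) - seq_loglik_terms(d, p2, gut)) / (2 * h)
    }, numeric(1))
    list(value = val, grad = g)
  }
}

# --- maximum likelihood -----------------------------------------------------

#' Maximum-likelihood fit of the feeding model to one subject
#'
#' Maximises [sequence_loglik()] over the eight behavioural parameters on the
#' transformed scale (log10 for positive-scale parameters, identity for `T1`,
#' `T2`) by BFGS with analytic gradients. Starting values come from moment
#' estimates and a logistic regression of the termination decisions on
#' fullness.
#'
#' @param seq A [feeding_seq()] (or list of sequences from the same subject,
#'   summed into one likelihood) with pause classes resolved.
#' @param gut A [gut_model()].
#' @param x_init Fullness at window start (see [sequence_loglik()]).
#' @param start Optional [feed_params()] starting point.
#' @return An object of class `"feed_mle"` with components `par` (a
#'   [feed_params()]), `loglik`, `vcov_transformed` (inverse observed
#'   information on the transformed scale), `convergence`, and `n_events`.
#' @export
feed_mle <- function(seq, gut = gut_model(), x_init = NULL, start = NULL) {
  seqs <- if (inherits(seq, "feeding_seq")) list(seq) else seq
  dats <- lapply(seqs, seq_lik_data, gut = gut, x_init = x_init)
  if (is.null(start)) start <- mle_start(dats)
  th0 <- param_transform(start)
  bad <- function(th) any(!is.finite(th)) || any(abs(th) > 15)
  negll <- function(th) {
    if (bad(th)) return(1e10)
    p <- param_backtransform(th)
    v <- -sum(vapply(dats, function(d) seq_loglik_terms(d, p, gut), numeric(1)))
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(th) {
    if (bad(th)) return(rep(0, 8))
    p <- param_backtransform(th)
    g <- Reduce(`+`, lapply(dats, function(d) seq_loglik_grad(d, p, gut)$grad))
    lg <- log_scaled_params()
    g[lg] <- g[lg] * unclass(p)[lg] * log(10)
    g[!is.finite(g)] <- 0
    -g
  }
  opt <- stats::optim(th0, negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  hess <- stats::optimHess(opt$par, negll, neggr)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA, 8, 8))
  n_ev <- sum(vapply(seqs, nrow, integer(1)))
  structure(list(par = param_backtransform(opt$par),
                 par_transformed = opt$par,
                 loglik = -opt$value, vcov_transformed = vc,
                 convergence = opt$convergence, n_events = n_ev,
                 gut = gut),
            class = "feed_mle")
}

mle_start <- function(dats) {
  bd <- unlist(lapply(dats, `[[`, "bout_dur"))
  rt <- unlist(lapply(dats, `[[`, "rate"))
  sd_ <- unlist(lapply(dats, `[[`, "s_dur"))
  im <- unlist(lapply(dats, `[[`, "imi_dur"))
  rx <- unlist(lapply(dats, `[[`, "route_x"))
  rl <- unlist(lapply(dats, `[[`, "route_L"))
  T1 <- 1; T2 <- if (length(rx)) stats::median(rx) else 1
  if (length(rx) >= 10 && length(unique(rl)) == 2L) {
    fit <- tryCatch(stats::glm(rl ~ rx, family = stats::binomial()),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(stats::coef(fit)[2]) &&
        stats::coef(fit)[2] > 0) {
      T1 <- unname(stats::coef(fit)[2])
      T2 <- unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
    }
  }
  feed_params(
    lambda_F = 1 / max(mean(bd), 1e-3),
    mu_F = max(mean(rt), 1e-6),
    sigma_F = max(stats::sd(rt), 1e-6),
    lambda_S = 1 / max(mean(sd_), 1e-3),
    T1 = T1, T2 = T2,
    L1 = max(mean(im) / 2, 1), L2 = max(mean(im) / 2, 1))
}

#' @export
print.feed_mle <- function(x, ...) {
  cat("Maximum-likelihood feeding-model fit\n")
  cat(sprintf("  log-likelihood %.2f over %d events (convergence %d)\n",
              x$loglik, x$n_events, x$convergence))
  print(x$par)
  invisible(x)
}

#' @export
coef.feed_mle <- function(object, ...) object$par

#' @export
logLik.feed_mle <- function(object, ...) {
  structure(object$loglik, df = 8L, class = "logLik")
}

#' @export
vcov.feed_mle <- function(object, ...) object$vcov_transformed
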