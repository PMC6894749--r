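# Exact event-sequence likelihood: normalisation, survival consistency,
# hand-computed toys, compiled-vs-reference agreement, invariances, and
# maximum-likelihood parameter recovery.

test_that("the intermeal density normalises and matches its survival", {
  gut <- default_gut()
  set.seed(55)
  for (rep in 1:6) {
    p <- feed_params(L1 = stats::runif(1, 500, 3000),
                     L2 = stats::runif(1, 0, 2500))
    x0 <- stats::runif(1, 0, 4)
    tmax <- 40 * (p[["L1"]] + p[["L2"]] * x0)  # survival there < 1e-17
    total <- stats::integrate(function(t)
      exp(imi_logpdf(t, x0, p, gut)), 0, tmax, rel.tol = 1e-9,
      subdivisions = 500L)$value
    expect_lt(abs(total - 1), 1e-6)
    # -d/dt survival = density (central differences)
    tt <- c(400, 2000, 6000)
    h <- 0.5
    s_hi <- exp(imi_logsurvival(tt + h, x0, p, gut))
    s_lo <- exp(imi_logsurvival(tt - h, x0, p, gut))
    expect_rel_equal(-(s_hi - s_lo) / (2 * h),
                     exp(imi_logpdf(tt, x0, p, gut)), 1e-5)
  }
  # L2 = 0 collapses to the exponential density
  p0 <- feed_params(L2 = 0)
  expect_equal(imi_logpdf(c(100, 900), 2, p0, gut),
               stats::dexp(c(100, 900), 1 / p0[["L1"]], log = TRUE))
  expect_identical(imi_logsurvival(0, 2, p0, gut), 0)
  surv <- exp(imi_logsurvival(seq(0, 1e4, by = 100), 3, feed_params(), gut))
  expect_true(all(diff(surv) < 0) && all(surv > 0 & surv <= 1))
})

test_that("a hand-summed two-event toy matches sequence_loglik", {
  gut <- default_gut()
  p <- feed_params()
  d1 <- 90; a1 <- 0.6; imi <- 2500
  s <- feeding_seq(data.frame(kind = c("bout", "pause"),
                              start = c(0, d1), duration = c(d1, imi),
                              amount = c(a1, NA),
                              pause_class = c(NA, "L")),
                   window = c(0, d1 + imi), x_init = 0)
  by_hand <- (log(p[["lambda_F"]]) - p[["lambda_F"]] * d1) +
    (stats::dnorm(a1 / d1, p[["mu_F"]], p[["sigma_F"]], log = TRUE) -
     stats::pnorm(0, p[["mu_F"]], p[["sigma_F"]], lower.tail = FALSE,
                  log.p = TRUE)) +
    stats::plogis(p[["T1"]] * (a1 - p[["T2"]]), log.p = TRUE) +
    imi_logpdf(imi, a1, p, gut)
  expect_equal(sequence_loglik(s, p, gut), by_hand, tolerance = 1e-12)
  # appending a near-zero censored pause leaves the likelihood unchanged
  s2 <- feeding_seq(rbind(as.data.frame(s),
                          data.frame(kind = "pause", start = d1 + imi,
                                     duration = 1e-7, amount = NA,
                                     pause_class = "L",
                                     fullness_start = NA, censored = TRUE)),
                    window = c(0, d1 + imi + 1e-7), x_init = 0)
  expect_equal(sequence_loglik(s2, p, gut), by_hand, tolerance = 1e-8)
})

test_that("the likelihood factorises over component families", {
  s <- sim_subject(seed = 61)
  p <- feed_params()
  res <- sequence_loglik(s, p, default_gut(), by_event = TRUE)
  expect_equal(sum(res$components), res$loglik, tolerance = 1e-9)
  expect_named(res$components, c("bout_durations", "bout_rates", "routing",
                                 "short_pauses", "imis"))
})

test_that("compiled gradient agrees with finite differences of the R value", {
  s <- sim_subject(seed = 63, hours = 6)
  for (law in c("sqrt", "linear")) {
    gut <- gut_model(law)
    d <- feedPDMP:::seq_lik_data(s, gut)
    p <- feed_params()
    res <- feedPDMP:::seq_loglik_grad(d, p, gut)
    expect_equal(res$value, feedPDMP:::seq_loglik_terms(d, p, gut),
                 tolerance = 1e-9)
    fd <- vapply(feedPDMP:::param_names(), function(nm) {
      h <- max(abs(p[[nm]]), 1e-4) * 1e-6
      p1 <- p; p1[[nm]] <- p[[nm]] + h
      p2 <- p; p2[[nm]] <- p[[nm]] - h
      (feedPDMP:::seq_loglik_terms(d, p1, gut) -
       feedPDMP:::seq_loglik_terms(d, p2, gut)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(res$grad - fd) / pmax(abs(fd), 1e-6)), 1e-4)
  }
})

test_that("rescaling time units shifts the likelihood by the exact Jacobian", {
  gut <- default_gut()
  p <- feed_params()
  s <- sim_subject(seed = 65, hours = 6)
  c_t <- 60  # seconds -> minutes
  ev <- as.data.frame(s)
  ev$start <- ev$start / c_t
  ev$duration <- ev$duration / c_t
  s_min <- feeding_seq(ev, window = attr(s, "window") / c_t)
  attr(s_min, "sham") <- FALSE
  p_min <- as_feed_params(c(lambda_F = p[["lambda_F"]] * c_t,
                            mu_F = p[["mu_F"]] * c_t,
                            sigma_F = p[["sigma_F"]] * c_t,
                            lambda_S = p[["lambda_S"]] * c_t,
                            T1 = p[["T1"]], T2 = p[["T2"]],
                            L1 = p[["L1"]] / c_t, L2 = p[["L2"]] / c_t))
  gut_min <- gut_model("sqrt", k = gut$k * c_t)
  d <- feedPDMP:::seq_lik_data(s, gut)
  n_dur <- sum(!d$bout_cens) + sum(!d$s_cens) + sum(!d$imi_cens)
  n_rate <- length(d$rate)
  shift <- (n_dur - n_rate) * log(c_t)
  expect_equal(sequence_loglik(s_min, p_min, gut_min),
               sequence_loglik(s, p, gut) + shift, tolerance = 1e-6)
})

test_that("maximum likelihood recovers the generator on a 500-meal subject", {
  gut <- default_gut()
  p_true <- feed_params()
  # enough meals that the 5 % tolerance sits ~3 sampling sd out
  set.seed(1)
  seqs <- lapply(1:100, function(i) simulate_feeding(p_true, gut, 12 * 3600))
  expect_gte(sum(vapply(seqs, function(s) attr(s, "n_terminations"),
                        integer(1))), 500L)
  fit <- feed_mle(seqs, gut)
  rel <- abs(unclass(coef(fit)) / unclass(p_true) - 1)
  expect_lt(max(rel[c("lambda_F", "mu_F", "sigma_F", "lambda_S")]), 0.05)
  expect_lt(max(rel[c("T1", "T2", "L1", "L2")]), 0.15)
  expect_equal(fit$convergence, 0L)
  expect_s3_class(coef(fit), "feed_params")
  expect_true(is.finite(logLik(fit)))
})

test_that("window censoring is handled without biasing the interval scale", {
  gut <- default_gut()
  p_true <- feed_params()
  # many short windows: a large share of intervals are cut by the window
  set.seed(2)
  seqs <- lapply(1:120, function(i) simulate_feeding(p_true, gut, 2 * 3600))
  frac_cens <- mean(unlist(lapply(seqs, function(s) {
    d <- feedPDMP:::seq_lik_data(s, gut); d$imi_cens
  })))
  expect_gt(frac_cens, 0.2)  # censoring is actually at play
  fit <- feed_mle(seqs, gut)
  expect_lt(abs(coef(fit)[["L1"]] / p_true[["L1"]] - 1), 0.2)
  # discarding the censored intervals instead shortens the apparent scale
  seqs_drop <- lapply(seqs, function(s) {
    ev <- as.data.frame(s)
    ev <- ev[!ev$censored, , drop = FALSE]
    out <- feeding_seq(ev, window = attr(s, "window"))
    attr(out, "sham") <- FALSE
    out
  })
  fit_drop <- feed_mle(seqs_drop, gut)
  expect_lt(coef(fit_drop)[["L1"]] + coef(fit_drop)[["L2"]] * 1.5,
            coef(fit)[["L1"]] + coef(fit)[["L2"]] * 1.5)
})

test_that("average log-likelihood peaks at the generating parameters", {
  gut <- default_gut()
  p_true <- feed_params()
  set.seed(3)
  seqs <- lapply(1:20, function(i) simulate_feeding(p_true, gut, 12 * 3600))
  ll <- function(p) sum(vapply(seqs, sequence_loglik, numeric(1),
                               params = p, gut = gut))
  ll0 <- ll(p_true)
  for (nm in c("lambda_F", "mu_F", "L1", "T2")) {
    for (f in c(0.7, 1.4)) {
      p2 <- unclass(p_true); p2[nm] <- p2[nm] * f
      expect_lt(ll(as_feed_params(p2)), ll0)
    }
  }
})
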