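# The MCMC-free assay: pooled regression estimators, the satiety-ratio
# baseline, and the model-free moving-window curve.

test_that("the logistic fit recovers the termination kernel", {
  set.seed(91)
  T1 <- 6; T2 <- 2
  x <- stats::runif(5000, 0, 4)
  y <- stats::runif(5000) < termination_probability(x, T1, T2)
  fit <- fit_termination_logistic(x, y)
  ci_slope <- fit$slope + c(-2, 2) * fit$se[["slope"]]
  expect_true(T1 >= ci_slope[1] && T1 <= ci_slope[2])
  expect_lt(abs(fit$T2 - T2), 0.15)
  # algebraic identity: the fitted curve IS the kernel reparametrised
  xx <- seq(0, 4, by = 0.5)
  expect_equal(stats::plogis(fit$intercept + fit$slope * xx),
               termination_probability(xx, fit$T1, fit$T2), tolerance = 1e-12)
})

test_that("fullness-independent termination yields a null slope", {
  set.seed(92)
  x <- stats::runif(3000, 0, 4)
  y <- stats::runif(3000) < 0.4
  fit <- fit_termination_logistic(x, y)
  ci <- fit$slope + c(-2, 2) * fit$se[["slope"]]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("complete separation is flagged and penalised, not fatal", {
  x <- c(stats::runif(50, 0, 1), stats::runif(50, 3, 4))
  y <- x > 2
  fit <- fit_termination_logistic(x, y)
  expect_true(fit$separation)
  expect_true(is.finite(fit$slope))
  expect_error(fit_termination_logistic(x, rep(TRUE, 100)), "both outcome")
})

test_that("the interval regression behaves in its limiting cases", {
  # exact collinear toy (perfect-fit warnings are the point here)
  fit0 <- suppressWarnings(fit_imi_linear(c(1, 2, 3), c(1000, 2000, 3000)))
  expect_equal(fit0$slope, 1000, tolerance = 1e-9)
  expect_lt(sum(stats::residuals(fit0$fit)^2), 1e-12)
  expect_error(fit_imi_linear(1:2, c(5, 10)), "at least 3")
  # constant-hazard generator: slope indistinguishable from zero,
  # intercept consistent with the interval scale L1
  gut <- default_gut()
  p0 <- feed_params(L2 = 0)
  set.seed(93)
  seqs <- lapply(1:25, function(i) simulate_feeding(p0, gut, 12 * 3600))
  a <- feed_assay(seqs, gut)
  ci <- a$imi$ci["fullness", ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
  expect_lt(abs(a$imi$intercept +
                a$imi$slope * mean(stats::model.frame(a$imi$fit)$fullness) -
                p0[["L1"]]) / p0[["L1"]], 0.1)
})

test_that("pooled estimators are consistent as data grow", {
  gut <- default_gut()
  p <- feed_params()
  errs <- vapply(c(4, 16, 64), function(nw) {
    set.seed(94)
    seqs <- lapply(seq_len(nw), function(i) simulate_feeding(p, gut, 12 * 3600))
    a <- feed_assay(seqs, gut)
    imp <- a$implied_params
    mean(abs(imp[c("lambda_F", "mu_F", "sigma_F", "lambda_S")] /
             unclass(p)[c("lambda_F", "mu_F", "sigma_F", "lambda_S")] - 1))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("assay termination estimates track the generator", {
  gut <- default_gut()
  p <- feed_params()
  set.seed(95)
  seqs <- lapply(1:40, function(i) simulate_feeding(p, gut, 12 * 3600))
  a <- feed_assay(seqs, gut)
  expect_lt(abs(a$termination$T1 - p[["T1"]]) / p[["T1"]], 0.25)
  expect_lt(abs(a$termination$T2 - p[["T2"]]) / p[["T2"]], 0.1)
  # the assay never touches posterior machinery: works straight off logs
  expect_true(all(c("termination", "imi", "bout", "rate") %in% names(a)))
})

test_that("satiety ratio is defined from the first meal only", {
  ev <- data.frame(
    kind = c("bout", "pause", "bout", "pause", "bout"),
    start = c(0, 600, 4200, 4500, 8100),
    duration = c(600, 3600, 300, 3600, 200),
    amount = c(2, NA, 1, NA, 0.5),
    pause_class = c(NA, "L", NA, "L", NA))
  s <- feeding_seq(ev, window = c(0, 8300))
  sr <- satiety_ratio(s)
  expect_equal(sr$ratio, 3600 / 2)
  expect_equal(sr$predictions$predicted_imi[1], 1800 * 1)
  expect_equal(sr$predictions$observed_imi[1], 3600)
  # identical meals and spacing: prediction is exact
  ev2 <- ev; ev2$amount[c(1, 3)] <- 1
  sr2 <- satiety_ratio(feeding_seq(ev2, window = c(0, 8300)))
  expect_equal(sr2$predictions$predicted_imi[1],
               sr2$predictions$observed_imi[1])
})

test_that("fullness-based interval prediction beats the satiety ratio", {
  gut <- default_gut()
  p <- feed_params()
  # expected interval from fullness at termination, by survival quadrature
  expected_imi <- function(x0) stats::integrate(function(t)
    exp(-integrated_imi_hazard(x0, t, p[["L1"]], p[["L2"]], gut)),
    0, Inf, rel.tol = 1e-8)$value
  set.seed(96)
  err_sat <- c(); err_ful <- c()
  for (i in 1:12) {
    s <- simulate_feeding(p, gut, 12 * 3600)
    sr <- try(satiety_ratio(s), silent = TRUE)
    if (inherits(sr, "try-error")) next
    pr <- sr$predictions[!is.na(sr$predictions$observed_imi), ]
    if (!nrow(pr)) next
    d <- feedPDMP:::seq_lik_data(s, gut)
    ok <- !d$imi_cens & d$imi_after_meal
    xs <- d$imi_x0[ok]; obs <- d$imi_dur[ok]
    # skip the first interval (used to define the ratio)
    err_sat <- c(err_sat, abs(pr$predicted_imi - pr$observed_imi))
    err_ful <- c(err_ful, abs(vapply(xs[-1], expected_imi, numeric(1)) -
                              obs[-1]))
  }
  expect_gt(mean(err_sat), mean(err_ful))
})

test_that("moving-window curve is flat without and rising with feedback", {
  set.seed(97)
  gut <- default_gut()
  # single record: flat curve at that interval
  one <- moving_window_imi(2, 1234)
  expect_equal(one$mean_imi, 1234)
  # pooled simulated records
  pool <- function(p, nw) {
    dd <- lapply(1:nw, function(i) {
      d <- feedPDMP:::seq_lik_data(simulate_feeding(p, gut, 12 * 3600), gut)
      ok <- !d$imi_cens & d$imi_after_meal
      data.frame(x = d$imi_x0[ok], t = d$imi_dur[ok])
    })
    do.call(rbind, dd)
  }
  flat <- pool(feed_params(L2 = 0), 30)
  cf <- suppressWarnings(moving_window_imi(flat$x, flat$t, min_count = 30))
  expect_lt(diff(range(cf$mean_imi)) / mean(cf$mean_imi), 0.5)
  rising <- pool(feed_params(), 30)
  cr <- suppressWarnings(moving_window_imi(rising$x, rising$t, min_count = 30))
  # stochastic monotonicity: late windows sit clearly above early ones
  k3 <- max(3, nrow(cr) %/% 3)
  expect_gt(mean(utils::tail(cr$mean_imi, k3)),
            mean(utils::head(cr$mean_imi, k3)))
  expect_gt(stats::cor(cr$fullness, cr$mean_imi, method = "spearman"), 0.5)
})
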