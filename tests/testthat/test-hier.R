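# Hierarchical machinery: LKJ transform and sampler, prior draws, the
# compiled posterior against the R reference, degenerate-group behaviour,
# and posterior-predictive simulation.

test_that("the unconstrained transform yields valid correlation factors", {
  set.seed(71)
  for (rep in 1:20) {
    y <- stats::rnorm(28, sd = 0.8)
    L <- feedPDMP:::lkj_chol_from_y(y, 8)
    R <- L %*% t(L)
    expect_equal(diag(R), rep(1, 8), tolerance = 1e-12)
    expect_true(all(eigen(R, only.values = TRUE)$values > 0))
    expect_true(all(L[upper.tri(L)] == 0))
  }
})

test_that("the direct LKJ sampler concentrates as its shape grows", {
  set.seed(72)
  mean_abs <- vapply(c(1, 10, 100), function(eta) {
    mean(replicate(300, {
      R <- feedPDMP:::rlkj(8, eta)
      mean(abs(R[lower.tri(R)]))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_abs) < 0))
  expect_lt(mean_abs[3], 0.1)
  # validity
  R <- feedPDMP:::rlkj(8, 2)
  expect_equal(diag(R), rep(1, 8))
  expect_true(all(eigen(R, only.values = TRUE)$values > 0))
})

test_that("group draws reproduce the requested covariance", {
  set.seed(73)
  mu <- param_transform(feed_params())
  tau <- c(0.3, 0.2, 0.25, 0.3, 0.5, 0.2, 0.3, 0.4)
  Omega <- feedPDMP:::rlkj(8, 2)
  gp <- sample_group_params(mu, tau, Omega, 1e5)
  emp <- stats::cov(gp$theta_tilde)
  Sigma <- diag(tau) %*% Omega %*% diag(tau)
  expect_lt(max(abs(emp - Sigma)), 0.02)
  expect_lt(max(abs(colMeans(gp$theta_tilde) - mu)), 0.02)
  # tau -> 0: individuals collapse onto the group mean
  gp0 <- sample_group_params(mu, rep(1e-10, 8), diag(8), 50)
  expect_lt(max(abs(t(gp0$theta_tilde) - mu)), 1e-8)
})

test_that("compiled posterior equals the R reference in every variant", {
  set.seed(74)
  g <- sim_group(J = 3, n_windows = 1, seed = 74, hours = 6)
  gut <- default_gut()
  dats <- lapply(g$data, function(dl) lapply(dl, feedPDMP:::seq_lik_data,
                                             gut = gut))
  gdat <- feedPDMP:::group_lik_data(dats)
  hyper <- hyper_prior()
  cases <- list(list(ft = NULL, po = FALSE), list(ft = NULL, po = TRUE),
                list(ft = rep(0.1, 8), po = FALSE))
  for (cs in cases) {
    tgC <- feedPDMP:::hier_target(gdat, gut, hyper, 3, cs$ft, cs$po)
    tgR <- feedPDMP:::hier_target_r(gdat, gut, hyper, 3, cs$ft, cs$po)
    ntau <- if (is.null(cs$ft)) 8 else 0
    for (rep in 1:3) {
      q <- c(param_transform(feed_params()) + 0.3 * stats::rnorm(8),
             if (ntau) stats::rnorm(8, log(0.2), 0.3),
             0.3 * stats::rnorm(28), stats::rnorm(24))
      a <- tgC(q); b <- tgR(q)
      expect_equal(a$value, unname(b$value), tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(a$grad, unname(b$grad), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("prior-only sampling reproduces the ancestral prior marginals", {
  # the MCMC path (LKJ transform + Jacobian + Half-Cauchy on the log scale)
  # must match independent direct draws from the same prior
  set.seed(75)
  g <- sim_group(J = 2, n_windows = 1, seed = 75, hours = 2)
  fit <- feed_hfit(g$data, tune = 300, draws = 1200, chains = 1,
                   seed = 76, prior_only = TRUE)
  mu_d <- group_mean_draws(fit)
  direct <- t(replicate(3000, {
    gp <- sample_group_prior(hyper_prior(), 1)
    gp$mu
  }))
  for (j in c(1, 5, 8)) {
    qs <- c(0.25, 0.5, 0.75)
    expect_lt(max(abs(stats::quantile(mu_d[, j], qs) -
                      stats::quantile(direct[, j], qs))), 0.35)
  }
  # correlation draws: mean |corr| of the sampled Omega matches direct LKJ
  dr <- feedPDMP:::pooled_draws(fit)
  ycols <- grep("^y", colnames(dr))
  macs <- vapply(seq(1, nrow(dr), by = 10), function(i) {
    L <- feedPDMP:::lkj_chol_from_y(dr[i, ycols], 8)
    R <- L %*% t(L)
    mean(abs(R[lower.tri(R)]))
  }, numeric(1))
  direct_mac <- mean(replicate(400, {
    R <- feedPDMP:::rlkj(8, 2)
    mean(abs(R[lower.tri(R)]))
  }))
  expect_lt(abs(mean(macs) - direct_mac), 0.05)
})

test_that("a degenerate single-individual group pins the mean to the MLE", {
  gut <- default_gut()
  set.seed(77)
  seqs <- lapply(1:8, function(i) simulate_feeding(feed_params(), gut,
                                                   12 * 3600))
  mle <- feed_mle(seqs, gut)
  fit <- feed_hfit(list(r1 = seqs), gut, tune = 300, draws = 300,
                   chains = 1, seed = 78, fixed_tau = rep(1e-3, 8))
  mu_post <- colMeans(group_mean_draws(fit))
  expect_lt(max(abs(mu_post - mle$par_transformed)), 0.05)
})

test_that("the hierarchical fit validates its inputs", {
  gut <- default_gut()
  s <- sim_subject(seed = 79, hours = 6)
  expect_error(feed_hfit(list(a = s), gut), "at least 2 individuals")
  # an individual without a complete meal is rejected by name
  tiny <- simulate_feeding(feed_params(L1 = 1e7, L2 = 0), gut,
                           window = 600, seed = 80)
  expect_error(feed_hfit(list(ok = s, empty = tiny), gut), "empty")
})

test_that("posterior-predictive intake grows with the window (coupled seeds)", {
  g <- sim_group(J = 4, n_windows = 1, seed = 81)
  fit <- feed_hfit(g$data, tune = 250, draws = 250, chains = 1, seed = 82,
                   max_divergence_frac = 0.25)
  set.seed(83)
  p4 <- posterior_predictive_intake(fit, 1, window = 4 * 3600, n_draws = 40)
  set.seed(83)
  p8 <- posterior_predictive_intake(fit, 1, window = 8 * 3600, n_draws = 40)
  expect_gt(p8$mean, p4$mean)
  expect_true(all(p4$values >= 0))
  # next-meal latency statistic is positive and finite for a fasted start
  set.seed(84)
  nm <- posterior_predictive_intake(fit, 1, window = 8 * 3600,
                                    n_draws = 30, statistic = "next_meal")
  expect_true(all(nm$values > 0, na.rm = TRUE))
})
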