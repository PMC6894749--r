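# Generative engine: distributional correctness of the primitive samplers,
# structural validity of simulated sequences, determinism, and coupling.

test_that("termination probability is the sigmoid kernel", {
  expect_equal(termination_probability(2, 6, 2), 0.5)
  expect_equal(termination_probability(c(-5, 0, 7), 0, 2), rep(0.5, 3))
  expect_gt(termination_probability(2.5, 50, 2), 0.999)
  expect_lt(termination_probability(1.5, 50, 2), 0.001)
})

test_that("bout sampler matches its analytic law", {
  p <- feed_params()
  set.seed(42)
  b <- sample_bout(p, 1e5)
  # exponential durations: mean within 3 standard errors
  expect_lt(abs(mean(b$duration) - 1 / p[["lambda_F"]]),
            3 / (p[["lambda_F"]] * sqrt(1e5)))
  # truncated-normal rates: goodness of fit against the analytic CDF
  ptr <- function(q) {
    p0 <- stats::pnorm(0, p[["mu_F"]], p[["sigma_F"]])
    (stats::pnorm(q, p[["mu_F"]], p[["sigma_F"]]) - p0) / (1 - p0)
  }
  # a couple of float-identical draws at n = 1e5 trip the ties warning
  expect_gt(suppressWarnings(stats::ks.test(b$rate, ptr))$p.value, 0.01)
  expect_true(all(b$rate > 0))
  expect_equal(b$amount, b$rate * b$duration)
  # degenerate spread: every rate equals the mean
  p0 <- feed_params(sigma_F = 1e-12)
  expect_equal(sample_bout(p0, 100)$rate, rep(p0[["mu_F"]], 100),
               tolerance = 1e-6)
})

test_that("intermeal sampler inverts the integrated hazard exactly", {
  gut <- default_gut()
  p <- feed_params()
  set.seed(7)
  # x0 = 0: plain exponential with mean L1
  d0 <- sample_imi_duration(0, p, gut, n = 1e4)
  expect_gt(stats::ks.test(d0, stats::pexp, rate = 1 / p[["L1"]])$p.value,
            0.01)
  # L2 = 0: exponential regardless of x0
  pL <- feed_params(L2 = 0)
  d1 <- sample_imi_duration(3, pL, gut, n = 1e4)
  expect_gt(stats::ks.test(d1, stats::pexp, rate = 1 / pL[["L1"]])$p.value,
            0.01)
  # general case: survival matches exp(-Lambda) via the hazard oracle
  x0 <- 2.5
  cdf <- function(q) 1 - exp(-integrated_imi_hazard(x0, q, p[["L1"]],
                                                    p[["L2"]], gut))
  d2 <- sample_imi_duration(x0, p, gut, n = 1e4)
  expect_gt(stats::ks.test(d2, cdf)$p.value, 0.01)
  # non-sqrt laws go through root finding and must agree too
  lin <- gut_model("linear")
  cdf_lin <- function(q) 1 - exp(-integrated_imi_hazard(x0, q, p[["L1"]],
                                                        p[["L2"]], lin))
  d3 <- sample_imi_duration(x0, p, lin, n = 3e3)
  expect_gt(stats::ks.test(d3, cdf_lin)$p.value, 0.01)
})

test_that("simulated sequences are structurally valid", {
  s <- sim_subject(seed = 5)
  ev <- as.data.frame(s)
  # alternating states, tiling the window without gaps
  expect_true(all(abs(ev$start[-1] - (ev$start + ev$duration)[-nrow(ev)])
                  < 1e-9))
  expect_true(all(ev$duration > 0))
  # bouts never adjacent: every bout is followed by a pause (or window end)
  b <- which(ev$kind == "bout")
  expect_true(all(ev$kind[b[b < nrow(ev)] + 1L] == "pause"))
  expect_true(all(ev$fullness_start >= 0))
  # last event censored flag only at the window edge
  expect_true(all(!ev$censored[-nrow(ev)]))
})

test_that("windows of zero length and degenerate kernels behave", {
  p <- feed_params()
  s0 <- simulate_feeding(p, window = c(0, 0), seed = 1)
  expect_equal(nrow(s0), 0L)
  # near-certain termination: meals are single bouts (no short pauses)
  p1 <- feed_params(T1 = 500, T2 = -5)
  s1 <- simulate_feeding(p1, window = 6 * 3600, seed = 2)
  expect_equal(sum(s1$kind == "pause" & s1$pause_class == "S"), 0L)
  expect_equal(summary(s1)$meal_count, sum(s1$kind == "bout"))
})

test_that("long-run intake rate matches the renewal-reward value", {
  # fullness-independent limit: T1 = 0 (fair-coin termination), L2 = 0
  p <- feed_params(T1 = 0, L2 = 0)
  gut <- default_gut()
  # meal: Geometric(1/2) bouts (mean 2), one short pause between bouts
  rho_bar <- p[["mu_F"]] + p[["sigma_F"]] *
    stats::dnorm(p[["mu_F"]] / p[["sigma_F"]]) /
    stats::pnorm(p[["mu_F"]] / p[["sigma_F"]])
  e_bouts <- 2
  e_size <- e_bouts * rho_bar / p[["lambda_F"]]
  e_meal_dur <- e_bouts / p[["lambda_F"]] + (e_bouts - 1) / p[["lambda_S"]]
  e_cycle <- e_meal_dur + p[["L1"]]
  rate_theory <- e_size / e_cycle
  set.seed(33)
  days <- 100
  intake <- vapply(seq_len(days), function(i) {
    s <- simulate_feeding(p, gut, 24 * 3600)
    sum(s$amount[s$kind == "bout"], na.rm = TRUE)
  }, numeric(1))
  rate_mc <- mean(intake) / (24 * 3600)
  se <- stats::sd(intake) / (24 * 3600) / sqrt(days)
  expect_lt(abs(rate_mc - rate_theory), 4 * se)
})

test_that("identical seeds give bit-identical logs; null interventions are exact", {
  p <- feed_params()
  a <- simulate_feeding(p, window = 8 * 3600, seed = 99)
  b <- simulate_feeding(p, window = 8 * 3600, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- simulate_feeding(p, window = 8 * 3600, seed = 99,
                        intervention = intervention_spec(refractory = 0,
                                                         sham = FALSE))
  expect_identical(as.data.frame(a), as.data.frame(d))
})

test_that("raising the termination probability shrinks meals (coupled seeds)", {
  p_lo <- feed_params()                 # T2 = 2
  p_hi <- feed_params(T2 = 1)           # earlier termination at all x
  sizes <- function(p) {
    set.seed(17)
    unlist(lapply(1:20, function(i)
      summary(simulate_feeding(p, window = 12 * 3600))$meal_sizes))
  }
  expect_gt(mean(sizes(p_lo)), mean(sizes(p_hi)))
})

test_that("summary is additive and consistent with the simulator state log", {
  toy <- feeding_seq(data.frame(kind = "bout", start = 10, duration = 50,
                                amount = 0.5), window = c(0, 100))
  sm <- summary(toy)
  expect_equal(sm$total_intake, 0.5)
  expect_equal(sm$meal_count, 1L)
  a <- sim_subject(seed = 41, hours = 6)
  b <- sim_subject(seed = 42, hours = 6)
  expect_equal(summary(bind_sequences(a, b))$total_intake,
               summary(a)$total_intake + summary(b)$total_intake)
  # meal count tracks the internal F -> L transition count
  for (seed in 43:47) {
    s <- sim_subject(seed = seed, hours = 12)
    mc <- summary(s)$meal_count
    nt <- attr(s, "n_terminations")
    expect_lte(abs(mc - nt), 1L)
    last <- s[nrow(s), ]
    if (last$kind == "pause" && !is.na(last$pause_class) &&
        last$pause_class == "L") expect_equal(mc, nt)
  }
})

test_that("summary refuses unresolved pause classes", {
  s <- sim_subject(seed = 3, hours = 3)
  ev <- as.data.frame(s)
  ev$pause_class[ev$kind == "pause"] <- "unknown"
  s2 <- feeding_seq(ev, window = attr(s, "window"))
  expect_error(summary(s2), "label_meals")
})

test_that("schedule switches apply to draws initiated after the switch", {
  p_a <- feed_params()
  p_b <- feed_params(mu_F = 1e-5, sigma_F = 1e-6)   # drug: barely eats
  sched <- data.frame(time = c(0, 6 * 3600), label = c("a", "b"))
  s <- simulate_feeding(list(a = p_a, b = p_b), window = 12 * 3600,
                        intervention = intervention_spec(schedule = sched),
                        seed = 8)
  b <- s[s$kind == "bout", ]
  first_half <- sum(b$amount[b$start < 6 * 3600])
  second_half <- sum(b$amount[b$start >= 6 * 3600])
  expect_gt(first_half, 10 * second_half)
  expect_error(simulate_feeding(list(a = p_a), window = 100,
                                intervention = intervention_spec(
                                  schedule = data.frame(time = 0, label = "zz"))),
               "zz")
})
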