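# Deterministic gut dynamics: closed forms against independent numerical
# oracles (ODE integration and adaptive quadrature), plus structural
# invariants of the fullness trajectory.

ode_empty <- function(x0, times, gut) {
  # independent oracle: numerical integration of the emptying ODE
  f <- function(t, y, parms) {
    x <- max(y[1], 0)
    list(-gut$k * x^gut$gamma)
  }
  out <- deSolve::ode(c(x = x0), c(0, times), f, NULL,
                      rtol = 1e-12, atol = 1e-14)
  pmax(out[-1, "x"], 0)
}

test_that("closed-form emptying matches the ODE oracle across laws", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  for (law in c("sqrt", "linear", "power")) {
    for (rep in 1:12) {
      k <- 10^stats::runif(1, -4, -2.5)
      gut <- gut_model(law, k = k, gamma = if (law == "power") 0.7,
                       epsilon_empty = 0)
      x0 <- stats::runif(1, 0.5, 6)
      tte <- time_to_empty(x0, gut)
      tmax <- if (is.finite(tte)) 0.9 * tte else 3 / k
      times <- sort(stats::runif(4, 0.01 * tmax, tmax))
      expect_rel_equal(empty_fullness(x0, times, gut),
                       ode_empty(x0, times, gut), 1e-8)
    }
  }
})

test_that("emptying handles fixed point, exact example, and domain errors", {
  gut <- gut_model()
  expect_identical(empty_fullness(0, 5000, gut), 0)
  # (sqrt(4) - 0.00055 * 1000 / 2)^2
  expect_equal(empty_fullness(4, 1000, gut), (2 - 0.275)^2, tolerance = 1e-12)
  expect_equal(empty_fullness(1, time_to_empty(1, gut), gut), 0)
  expect_error(empty_fullness(-1, 10, gut), "x0")
  expect_error(empty_fullness(1, -10, gut), "dt")
})

test_that("time_to_empty is exact and consistent with emptying", {
  gut <- gut_model()
  expect_identical(time_to_empty(0, gut), 0)
  expect_equal(time_to_empty(1, gut), 2 / 0.00055, tolerance = 1e-12)
  # numerically: fullness is positive just before and zero at the boundary
  tte <- time_to_empty(2.5, gut)
  expect_gt(empty_fullness(2.5, tte * 0.999, gut), 0)
  expect_equal(empty_fullness(2.5, tte, gut), 0)
  # linear law never empties without a floor
  lin0 <- gut_model("linear", epsilon_empty = 0)
  expect_identical(time_to_empty(1, lin0), Inf)
  lin <- gut_model("linear", epsilon_empty = 1e-9)
  expect_lt(empty_fullness(1, time_to_empty(1, lin) * 1.001, lin), 2e-9)
})

test_that("integrated hazard has closed-form limits and matches quadrature", {
  gut <- gut_model()
  # constant-hazard limits
  expect_equal(integrated_imi_hazard(3, c(10, 500), 1000, 0, gut),
               c(10, 500) / 1000)
  expect_identical(integrated_imi_hazard(2, 0, 1000, 500, gut), 0)
  # quadrature oracle over random parameter draws, sqrt and linear laws
  set.seed(202)
  for (law in c("sqrt", "linear")) {
    for (rep in 1:15) {
      gutl <- gut_model(law, k = 10^stats::runif(1, -4, -2.8))
      x0 <- stats::runif(1, 0.2, 5)
      L1 <- stats::runif(1, 300, 4000)
      L2 <- stats::runif(1, 0, 3000)
      t <- stats::runif(1, 100, 3 * 2 * sqrt(x0) / gutl$k)
      quad <- stats::integrate(function(tau)
        1 / (L1 + L2 * empty_fullness(x0, tau, gutl)),
        0, t, rel.tol = 1e-10, subdivisions = 500L)$value
      expect_rel_equal(integrated_imi_hazard(x0, t, L1, L2, gutl), quad, 1e-8)
    }
  }
  # the spec'd worked case agrees with quadrature too
  quad <- stats::integrate(function(tau)
    1 / (1000 + 800 * empty_fullness(2, tau, gut)), 0, 5000,
    rel.tol = 1e-10)$value
  expect_rel_equal(integrated_imi_hazard(2, 5000, 1000, 800, gut), quad, 1e-8)
})

test_that("integrated hazard is monotone in t, antitone in x0, and bounded", {
  gut <- gut_model()
  tt <- seq(0, 20000, length.out = 200)
  for (x0 in c(0.5, 2, 4)) {
    lam <- integrated_imi_hazard(x0, tt, 1500, 900, gut)
    expect_true(all(diff(lam) >= 0))
    expect_true(all(lam - tt / 1500 <= 1e-12))      # fuller slows the clock
    expect_true(all(is.finite(lam)))
  }
  l_low <- integrated_imi_hazard(1, tt, 1500, 900, gut)
  l_high <- integrated_imi_hazard(3, tt, 1500, 900, gut)
  expect_true(all(l_high <= l_low + 1e-12))
})

test_that("fullness trajectory composes bouts and pauses exactly", {
  gut <- gut_model()
  # empty sequence: pure emptying from x_init
  s0 <- feeding_seq(data.frame(kind = character(), start = numeric(),
                               duration = numeric()), window = c(0, 4000))
  tr <- fullness_trajectory(s0, gut, x_init = 1)
  expect_equal(eval_fullness(tr, 1500), empty_fullness(1, 1500, gut))
  # one bout from empty: fullness at bout end equals the amount
  s1 <- feeding_seq(data.frame(kind = "bout", start = 100, duration = 60,
                               amount = 0.5), window = c(0, 1000))
  tr1 <- fullness_trajectory(s1, gut, x_init = 0)
  expect_equal(eval_fullness(tr1, 160), 0.5)
  # two bouts: hand-composed closed forms
  s2 <- feeding_seq(data.frame(kind = c("bout", "pause", "bout"),
                               start = c(0, 120, 1620),
                               duration = c(120, 1500, 90),
                               amount = c(0.8, NA, 0.3),
                               pause_class = c(NA, "L", NA)),
                    window = c(0, 2000))
  tr2 <- fullness_trajectory(s2, gut, x_init = 0)
  expect_equal(eval_fullness(tr2, 1620), empty_fullness(0.8, 1500, gut),
               tolerance = 1e-12)
  expect_equal(eval_fullness(tr2, 1710),
               empty_fullness(0.8, 1500, gut) + 0.3, tolerance = 1e-12)
  expect_error(fullness_trajectory(
    feeding_seq(data.frame(kind = c("bout", "bout"), start = c(0, 50),
                           duration = c(100, 50), amount = c(0.1, 0.1)))),
    "overlap")
})

test_that("conservation at bout boundaries holds on simulated sequences", {
  for (law in c("sqrt", "linear")) {
    gut <- gut_model(law)
    s <- sim_subject(seed = 11, hours = 6, gut = gut)
    tr <- fullness_trajectory(s, gut, x_init = 0)
    b <- s[s$kind == "bout" & !s$censored, ]
    x_start <- eval_fullness(tr, b$start)
    x_end <- eval_fullness(tr, b$start + b$duration)
    expect_equal(x_end, x_start + b$amount, tolerance = 1e-9)
    expect_true(all(eval_fullness(tr, seq(0, 6 * 3600, by = 37)) >= 0))
  }
})

test_that("law swap preserves structural invariants downstream", {
  # every operation accepts any gut model; swapping laws keeps the
  # likelihood finite and the trajectory nonnegative/continuous
  s <- sim_subject(seed = 21, hours = 6)
  p <- feed_params()
  for (law in c("sqrt", "linear")) {
    g <- gut_model(law)
    ll <- sequence_loglik(s, p, g)
    expect_true(is.finite(ll))
    tr <- fullness_trajectory(s, g, 0)
    tt <- seq(0, 6 * 3600, length.out = 400)
    x <- eval_fullness(tr, tt)
    expect_true(all(x >= 0))
    expect_lt(max(abs(diff(x))), 1)  # no jumps on a fine grid
  }
  gp <- gut_model("power", gamma = 0.6)
  expect_true(is.finite(sequence_loglik(s, p, gp)))
})

test_that("trajectory grid export writes a readable two-column table", {
  s <- sim_subject(seed = 31, hours = 2)
  tr <- fullness_trajectory(s, default_gut(), 0)
  f <- tempfile(fileext = ".csv")
  write_fullness_grid(tr, f, by = 120)
  tab <- utils::read.csv(f)
  expect_named(tab, c("time_s", "fullness_g"))
  expect_equal(tab$fullness_g, eval_fullness(tr, tab$time_s),
               tolerance = 1e-12)
})
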