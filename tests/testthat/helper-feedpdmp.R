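# shared fixtures: everything is generated in code at test time

default_gut <- function() gut_model()

# a moderately-sized labelled subject (single 12-h dark-period window)
sim_subject <- function(seed = 1, hours = 12, params = feed_params(),
                        gut = default_gut(), ...) {
  simulate_feeding(params, gut, hours * 3600, x_init = 0, seed = seed, ...)
}

# group-level truth used across hierarchical tests: modest interindividual
# variation around the default "dark-period" parameters
group_truth <- function() {
  list(mu = param_transform(feed_params()),
       tau = c(lambda_F = 0.08, mu_F = 0.06, sigma_F = 0.08,
               lambda_S = 0.08, T1 = 0.25, T2 = 0.15, L1 = 0.08, L2 = 0.12),
       Omega = diag(8))
}

# simulate a group: J individuals x n_windows half-day windows
sim_group <- function(J, n_windows, seed = 1, hours = 12,
                      gut = default_gut()) {
  set.seed(seed)
  tr <- group_truth()
  gp <- sample_group_params(tr$mu, tr$tau, tr$Omega, J)
  data <- lapply(gp$params, function(p)
    lapply(seq_len(n_windows), function(w)
      simulate_feeding(p, gut, hours * 3600, x_init = 0)))
  names(data) <- paste0("rat", seq_len(J))
  list(data = data, params = gp$params, theta_tilde = gp$theta_tilde,
       mu = tr$mu, tau = tr$tau)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
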