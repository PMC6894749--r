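# Bayesian hierarchical model across individuals: group-level multivariate
# normal on the transformed parameter scale with an LKJ-separation covariance
# prior, fitted by Hamiltonian Monte Carlo over the non-centred
# parametrisation theta_tilde_j = mu + diag(tau) %*% L %*% z_j.

log_flags <- function() c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)

#' Draw groups of individuals from the hierarchical prior
#'
#' `sample_group_params()` draws `n` individual parameter vectors given fixed
#' group-level mean, scales, and correlation; `sample_group_prior()` first
#' draws the group level ancestrally from the hyper-prior
#' (\eqn{\mu \sim N(\mu^*, sd)}, \eqn{\tau_i \sim HalfCauchy},
#' \eqn{\Omega \sim LKJ(\eta)}). Both operate on the transformed scale and
#' back-transform the result.
#'
#' @param mu Group mean on the transformed scale (length 8).
#' @param tau Group standard deviations on the transformed scale (length 8).
#' @param Omega 8 x 8 correlation matrix.
#' @param n Number of individuals.
#' @return A list with `theta_tilde` (n x 8 matrix, transformed scale) and
#'   `params` (list of [feed_params()]); `sample_group_prior()` additionally
#'   returns the drawn `mu`, `tau`, `Omega`.
#' @export
sample_group_params <- function(mu, tau, Omega, n) {
  stopifnot(length(mu) == 8L, length(tau) == 8L,
            all(dim(Omega) == c(8L, 8L)))
  Lw <- t(chol(Omega))
  Z <- matrix(stats::rnorm(8L * n), 8L, n)
  tt <- t(mu + tau * (Lw %*% Z))
  colnames(tt) <- param_names()
  # heavy-tailed hyper-priors can put ancestral draws beyond double range on
  # the natural scale; such draws are kept (unvalidated) rather than hidden
  list(theta_tilde = tt,
       params = lapply(seq_len(n), function(j) {
         p <- tt[j, ]
         lg <- log_scaled_params()
         p[lg] <- 10^p[lg]
         structure(p[param_names()], class = "feed_params")
       }))
}

#' @rdname sample_group_params
#' @param hyper A [hyper_prior()].
#' @param n_individuals Number of individuals to draw.
#' @export
sample_group_prior <- function(hyper = hyper_prior(), n_individuals = 1) {
  stopifnot(n_individuals >= 1)
  mu <- stats::rnorm(8L, hyper$mu_star, hyper$mu_prior_sd)
  tau <- abs(stats::rcauchy(8L, 0, hyper$tau_scale))
  Omega <- rlkj(8L, hyper$lkj_eta)
  out <- sample_group_params(mu, tau, Omega, n_individuals)
  out$mu <- stats::setNames(mu, param_names())
  out$tau <- stats::setNames(tau, param_names())
  out$Omega <- Omega
  out
}

# concatenate decomposed likelihood terms across individuals (each element of
# 'dats' is a list of seq_lik_data() results for one individual)
group_lik_data <- function(dats) {
  pull <- function(field) unlist(lapply(dats, function(dl)
    unlist(lapply(dl, `[[`, field), use.names = FALSE)), use.names = FALSE)
  ids <- function(field) {
    unlist(lapply(seq_along(dats), function(j)
      rep(j - 1L, sum(vapply(dats[[j]], function(d)
        length(d[[field]]), integer(1))))), use.names = FALSE)
  }
  as_num <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  as_lgl <- function(x) if (is.null(x)) logical(0) else as.logical(x)
  as_int <- function(x) if (is.null(x)) integer(0) else as.integer(x)
  list(bout_dur = as_num(pull("bout_dur")), bout_cens = as_lgl(pull("bout_cens")),
       rate = as_num(pull("rate")), bout_id = as_int(ids("bout_dur")),
       route_x = as_num(pull("route_x")), route_L = as_lgl(pull("route_L")),
       route_id = as_int(ids("route_x")),
       s_dur = as_num(pull("s_dur")), s_cens = as_lgl(pull("s_cens")),
       s_id = as_int(ids("s_dur")),
       imi_dur = as_num(pull("imi_dur")), imi_x0 = as_num(pull("imi_x0")),
       imi_cens = as_lgl(pull("imi_cens")), imi_id = as_int(ids("imi_dur")))
}

# log posterior and gradient over the unconstrained vector
# q = [mu(8), log_tau(8) unless fixed, y(28), z(8J)].
# Fast path: single compiled call per evaluation.
hier_target <- function(gdat, gut, hyper, J, fixed_tau = NULL,
                        prior_only = FALSE) {
  law <- if (gut$law == "sqrt") 0L else 1L
  has_tau <- is.null(fixed_tau)
  ft <- if (has_tau) numeric(8) else as.numeric(fixed_tau)
  lf <- log_flags()
  function(q) {
    hier_target_cpp(q, gdat$bout_dur, gdat$bout_cens, gdat$rate,
                    gdat$bout_id, gdat$route_x, gdat$route_L, gdat$route_id,
                    gdat$s_dur, gdat$s_cens, gdat$s_id,
                    gdat$imi_dur, gdat$imi_x0, gdat$imi_cens, gdat$imi_id,
                    J, law, gut$k, as.numeric(hyper$mu_star),
                    hyper$mu_prior_sd, hyper$tau_scale, hyper$lkj_eta,
                    lf, has_tau, ft, prior_only)
  }
}

# pure-R reference implementation of the same target (kept for
# cross-validation in the test suite)
hier_target_r <- function(gdat, gut, hyper, J, fixed_tau = NULL,
                          prior_only = FALSE) {
  K <- 8L
  ny <- K * (K - 1L) / 2L
  law <- if (gut$law == "sqrt") 0L else 1L
  lf <- log_flags()
  ln10 <- log(10)
  has_tau <- is.null(fixed_tau)
  ntau <- if (has_tau) K else 0L
  # column index k per y entry (row-major rows 2..K), for the prior gradient
  ycol <- unlist(lapply(2:K, function(i) 1:(i - 1)))
  yfac <- K - ycol - 1 + 2 * hyper$lkj_eta
  function(q) {
    mu <- q[1:K]
    lt <- if (has_tau) q[K + 1:K] else NULL
    tau <- if (has_tau) exp(lt) else fixed_tau
    y <- q[K + ntau + 1:ny]
    z <- matrix(q[K + ntau + ny + 1:(K * J)], K, J)
    Lw <- lkj_chol_from_y(y, K)
    Lz <- Lw %*% z
    theta_tilde <- mu + tau * Lz          # K x J, recycled columnwise
    theta <- theta_tilde
    theta[lf, ] <- 10^theta[lf, ]
    if (!prior_only) {
      lik <- group_loglik_cpp(gdat$bout_dur, gdat$bout_cens, gdat$rate,
                              gdat$bout_id, gdat$route_x, gdat$route_L,
                              gdat$route_id, gdat$s_dur, gdat$s_cens,
                              gdat$s_id, gdat$imi_dur, gdat$imi_x0,
                              gdat$imi_cens, gdat$imi_id, theta, law, gut$k)
      ll <- lik$value
      g_tilde <- lik$grad
      g_tilde[lf, ] <- g_tilde[lf, ] * theta[lf, ] * ln10
    } else {
      ll <- 0
      g_tilde <- matrix(0, K, J)
    }
    # priors
    lp <- ll +
      sum(stats::dnorm(mu, hyper$mu_star, hyper$mu_prior_sd, log = TRUE)) +
      lkj_log_target(y, K, hyper$lkj_eta) -
      0.5 * sum(z^2) - 0.5 * K * J * log(2 * pi)
    g_mu <- rowSums(g_tilde) -
      (mu - hyper$mu_star) / hyper$mu_prior_sd^2
    g_y <- lkj_grad_to_y((tau * g_tilde) %*% t(z), y, K) - tanh(y) * yfac
    g_z <- crossprod(Lw, tau * g_tilde) - z
    if (has_tau) {
      ts <- hyper$tau_scale
      lp <- lp + sum(stats::dcauchy(tau, 0, ts, log = TRUE) + log(2)) +
        sum(lt)
      g_lt <- rowSums(g_tilde * Lz) * tau -
        2 * (tau / ts)^2 / (1 + (tau / ts)^2) + 1
      grad <- c(g_mu, g_lt, g_y, as.numeric(g_z))
    } else {
      grad <- c(g_mu, g_y, as.numeric(g_z))
    }
    list(value = lp, grad = grad)
  }
}

#' Fit the hierarchical feeding model to a group of individuals
#'
#' Samples the joint posterior of the group mean \eqn{\mu}, scales
#' \eqn{\tau}, correlation \eqn{\Omega} and per-individual parameter vectors
#' \eqn{\tilde\theta_j} given bout-level event logs, using Hamiltonian Monte
#' Carlo over the non-centred parametrisation
#' \eqn{\tilde\theta_j = \mu + diag(\tau) L_\Omega z_j}, using a dynamic
#' no-U-turn trajectory sampler. Initialisation jitters a cheap
#' moment-based point (no mode finding); the step size is tuned by dual
#' averaging and a (dense, shrunken) mass matrix is estimated in expanding
#' warmup windows.
#'
#' @param data A named list with one element per individual; each element is
#'   a [feeding_seq()] or a list of them (multiple recording windows).
#' @param gut A [gut_model()] (`"sqrt"` or `"linear"` law).
#' @param hyper A [hyper_prior()].
#' @param tune,draws Warmup and retained iterations per chain.
#' @param chains Number of chains.
#' @param seed Optional integer seed.
#' @param fixed_tau Optional fixed group scales (length 8, transformed
#'   scale); removes \eqn{\tau} from sampling. With a single individual this
#'   pins the group mean to that individual.
#' @param prior_only If `TRUE`, sample from the prior (likelihood off).
#' @param max_divergence_frac Fail if the post-warmup divergence fraction
#'   exceeds this (default 0.1).
#' @param max_treedepth Maximum doublings of the simulated trajectory per
#'   iteration.
#' @param target_accept Step-size adaptation target for the average
#'   acceptance statistic.
#' @return An object of class `"feed_hfit"`: per-chain draw matrices, split-Rhat
#'   and effective-sample-size diagnostics, divergence counts, and metadata.
#'   Use [group_mean_draws()], [individual_draws()], [group_mean_params()],
#'   [posterior_predictive_intake()] to work with it.
#' @export
feed_hfit <- function(data, gut = gut_model(), hyper = hyper_prior(),
                      tune = 500, draws = 500, chains = 2, seed = NULL,
                      fixed_tau = NULL, prior_only = FALSE,
                      max_divergence_frac = 0.1, max_treedepth = 8L,
                      target_accept = 0.85) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(data)) stop("'data' must be a list of individuals")
  data <- lapply(data, function(d)
    if (inherits(d, "feeding_seq")) list(d) else d)
  J <- length(data)
  if (is.null(fixed_tau) && J < 2 && !prior_only)
    stop("hierarchical fitting needs at least 2 individuals ",
         "(or a fixed 'fixed_tau')")
  ids <- names(data)
  if (is.null(ids)) ids <- paste0("ind", seq_len(J))
  dats <- lapply(data, function(dl) lapply(dl, seq_lik_data, gut = gut))
  if (!prior_only) {
    complete_meals <- vapply(dats, function(dl)
      sum(vapply(dl, function(d) sum(!d$imi_cens), integer(1))), integer(1))
    if (any(complete_meals < 1))
      stop("individual(s) without a complete meal: ",
           paste(ids[complete_meals < 1], collapse = ", "))
  }
  gdat <- group_lik_data(dats)
  K <- 8L; ny <- K * (K - 1L) / 2L
  ntau <- if (is.null(fixed_tau)) K else 0L
  dim_q <- K + ntau + ny + K * J
  target <- hier_target(gdat, gut, hyper, J, fixed_tau, prior_only)
  # data-informed initialisation: cheap moment / pooled-logistic estimates
  # per individual locate the bulk of the posterior (no mode finding)
  if (prior_only) {
    mu0 <- hyper$mu_star
    lt0 <- rep(log(0.5), K)
  } else {
    starts <- t(vapply(dats, function(dl) param_transform(mle_start(dl)),
                       numeric(K)))
    mu0 <- colMeans(starts)
    sd0 <- apply(starts, 2, stats::sd)
    sd0[!is.finite(sd0)] <- 0.2
    lt0 <- log(pmin(pmax(sd0, 0.05), 1))
  }
  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    q0 <- c(mu0 + 0.1 * stats::rnorm(K),
            if (ntau) lt0 + 0.1 * stats::rnorm(K),
            0.05 * stats::rnorm(ny),
            0.1 * stats::rnorm(K * J))
    chain_res[[ch]] <- hmc_chain(target, q0, tune, draws,
                                 max_treedepth = max_treedepth,
                                 target_accept = target_accept)
  }
  cn <- c(paste0("mu_", param_names()),
          if (ntau) paste0("log_tau_", param_names()),
          paste0("y", seq_len(ny)),
          paste0("z", rep(seq_len(J), each = K), "_", param_names()))
  for (ch in seq_len(chains)) colnames(chain_res[[ch]]$draws) <- cn
  div <- sum(vapply(chain_res, `[[`, 0, "divergences"))
  div_frac <- div / (chains * draws)
  if (div_frac > max_divergence_frac)
    stop(sprintf("sampler diverged in %.1f%% of iterations (limit %.1f%%)",
                 100 * div_frac, 100 * max_divergence_frac))
  dl <- lapply(chain_res, `[[`, "draws")
  rhat <- split_rhat(dl)
  ess <- ess_geyer(dl)
  names(rhat) <- names(ess) <- cn
  structure(list(chains = chain_res, draws_names = cn, J = J, ids = ids,
                 hyper = hyper, gut = gut, fixed_tau = fixed_tau,
                 prior_only = prior_only, tune = tune, draws = draws,
                 rhat = rhat, ess = ess, divergences = div,
                 dim = dim_q),
            class = "feed_hfit")
}

#' @export
print.feed_hfit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical feeding-model fit: %d individuals, %d chain(s) x %d draws\n",
    x$J, length(x$chains), x$draws))
  cat(sprintf("  max split-Rhat %.3f; min ESS %.0f; %d divergence(s)\n",
              max(x$rhat), min(x$ess), x$divergences))
  mu <- colMeans(group_mean_draws(x))
  cat("  posterior mean group parameters (natural scale):\n")
  print(group_mean_params(x))
  invisible(x)
}

#' @export
summary.feed_hfit <- function(object, ...) {
  mu <- group_mean_draws(object)
  qs <- t(apply(mu, 2, stats::quantile, c(0.05, 0.5, 0.95)))
  out <- data.frame(mean = colMeans(mu), qs, check.names = FALSE,
                    rhat = object$rhat[seq_len(8)],
                    ess = object$ess[seq_len(8)])
  names(out)[2:4] <- c("q5", "median", "q95")
  out
}

# pooled draw matrix across chains
pooled_draws <- function(fit) do.call(rbind, lapply(fit$chains, `[[`, "draws"))

#' Posterior draws of group-level quantities
#'
#' `group_mean_draws()` returns the posterior draws of the group mean
#' \eqn{\mu} (transformed scale); `group_tau_draws()` the group scales; and
#' `individual_draws()` the per-individual \eqn{\tilde\theta_j}
#' (reconstructed through the non-centred transform).
#'
#' @param fit A [feed_hfit()] object.
#' @return A draws x 8 matrix with parameter-named columns.
#' @export
group_mean_draws <- function(fit) {
  d <- pooled_draws(fit)[, 1:8, drop = FALSE]
  colnames(d) <- param_names()
  d
}

#' @rdname group_mean_draws
#' @export
group_tau_draws <- function(fit) {
  if (!is.null(fit$fixed_tau))
    return(matrix(fit$fixed_tau, 1, 8,
                  dimnames = list(NULL, param_names())))
  d <- exp(pooled_draws(fit)[, 8 + 1:8, drop = FALSE])
  colnames(d) <- param_names()
  d
}

#' @rdname group_mean_draws
#' @param individual Individual index or id.
#' @export
individual_draws <- function(fit, individual) {
  j <- if (is.character(individual)) match(individual, fit$ids)
       else as.integer(individual)
  if (is.na(j) || j < 1 || j > fit$J) stop("unknown individual")
  d <- pooled_draws(fit)
  K <- 8L; ny <- K * (K - 1L) / 2L
  ntau <- if (is.null(fit$fixed_tau)) K else 0L
  n <- nrow(d)
  out <- matrix(NA_real_, n, K, dimnames = list(NULL, param_names()))
  zcols <- K + ntau + ny + (j - 1L) * K + 1:K
  for (i in seq_len(n)) {
    tau <- if (ntau) exp(d[i, K + 1:K]) else fit$fixed_tau
    Lw <- lkj_chol_from_y(d[i, K + ntau + 1:ny], K)
    out[i, ] <- d[i, 1:K] + tau * as.numeric(Lw %*% d[i, zcols])
  }
  out
}

#' Posterior-mean group parameters on the natural scale
#'
#' Back-transforms the posterior mean of the group mean \eqn{\mu}; the
#' "typical individual" used as the plug-in for in-silico experiments.
#'
#' @param fit A [feed_hfit()] object.
#' @return A [feed_params()].
#' @export
group_mean_params <- function(fit) {
  param_backtransform(colMeans(group_mean_draws(fit)))
}

#' @export
coef.feed_hfit <- function(object, ...) group_mean_params(object)

#' Posterior-predictive feeding simulation
#'
#' For each retained posterior draw (subsampled to `n_draws`), back-transforms
#' the individual's parameter vector and simulates the observation window,
#' recording either the total food intake or the time of the first bout
#' (next-meal latency).
#'
#' @param fit A [feed_hfit()] object.
#' @param individual Individual index or id.
#' @param window Window (seconds, scalar or `c(start, end)`).
#' @param x_init Initial fullness (g).
#' @param n_draws Number of posterior draws to propagate.
#' @param statistic `"intake"` (grams consumed) or `"next_meal"` (seconds to
#'   first bout; `NA` if no bout occurs in the window).
#' @param gut Gut model; defaults to the one used in the fit.
#' @return A list with the simulated values, their `mean`, and central 50
#'   and 90 percent intervals.
#' @export
posterior_predictive_intake <- function(fit, individual, window = 8 * 3600,
                                        x_init = 0, n_draws = 100,
                                        statistic = c("intake", "next_meal"),
                                        gut = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(gut)) gut <- fit$gut
  th <- individual_draws(fit, individual)
  take <- if (nrow(th) <= n_draws) seq_len(nrow(th))
          else round(seq(1, nrow(th), length.out = n_draws))
  vals <- vapply(take, function(i) {
    p <- param_backtransform(th[i, ])
    s <- simulate_feeding(p, gut, window, x_init)
    if (statistic == "intake") {
      sum(s$amount[s$kind == "bout"], na.rm = TRUE)
    } else {
      b <- s$start[s$kind == "bout"]
      if (length(b)) min(b) - attr(s, "window")[1] else NA_real_
    }
  }, numeric(1))
  list(values = vals, mean = mean(vals, na.rm = TRUE),
       q50 = stats::quantile(vals, c(0.25, 0.75), na.rm = TRUE, names = FALSE),
       q90 = stats::quantile(vals, c(0.05, 0.95), na.rm = TRUE, names = FALSE))
}
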