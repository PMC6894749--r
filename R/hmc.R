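# Gradient-based MCMC internals: a Hamiltonian Monte Carlo sampler with
# dual-averaging step-size adaptation and diagonal mass-matrix estimation
# during warmup, plus split-Rhat / effective-sample-size diagnostics.
# Used by feed_hfit(); not exported.

# target: function(q) -> list(value, grad); q unconstrained
hmc_chain <- function(target, q0, n_tune, n_draws, target_accept = 0.85,
                      max_treedepth = 8L,
                      divergence_threshold = 1000, dense_mass = TRUE) {
  d <- length(q0)
  q <- q0
  cur <- target(q)
  if (!is.finite(cur$value))
    stop("non-finite log posterior at the initial point")
  inv_mass <- rep(1, d)
  mass_U <- NULL  # chol factor of the regularised draw covariance, if dense
  draw_p <- function() {
    if (is.null(mass_U)) stats::rnorm(d) / sqrt(inv_mass)
    else backsolve(mass_U, stats::rnorm(d))
  }
  velocity <- function(p) {
    if (is.null(mass_U)) inv_mass * p
    else crossprod(mass_U, mass_U %*% p)[, 1]  # Sigma-hat %*% p
  }
  kinetic <- function(p) 0.5 * sum(p * velocity(p))
  # dual averaging state (Hoffman & Gelman defaults)
  eps <- find_initial_step(target, q, draw_p, velocity)
  mu_da <- log(10 * eps)
  log_eps_bar <- log(eps); H_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75
  it_adapt <- 0L
  n_total <- n_tune + n_draws
  draws <- matrix(NA_real_, n_draws, d)
  lp <- numeric(n_draws)
  n_div <- 0L
  accept_sum <- 0
  # expanding mass-matrix adaptation windows (variance re-estimated and the
  # step-size clock restarted at each boundary), then a final step-only phase
  wbound <- unique(pmax(2L, floor(n_tune * c(0.15, 0.3, 0.5, 0.75, 0.9))))
  wbound <- wbound[wbound < n_tune]
  warm_buf <- matrix(NA_real_, n_tune, d)
  wb_start <- min(wbound[1], n_tune)  # start collecting after initial phase
  wb <- 0L
  for (it in seq_len(n_total)) {
    res_it <- nuts_iter(target, q, cur, eps, draw_p, velocity, kinetic,
                        max_depth = max_treedepth,
                        divergence_threshold = divergence_threshold)
    q <- res_it$q; cur <- res_it$cur
    alpha <- res_it$accept_stat
    if (res_it$divergent && it > n_tune) n_div <- n_div + 1L
    if (it <= n_tune) {
      # dual averaging (clock restarts when the mass matrix changes)
      it_adapt <- it_adapt + 1L
      frac <- 1 / (it_adapt + t0)
      H_bar <- (1 - frac) * H_bar + frac * (target_accept - alpha)
      log_eps <- mu_da - sqrt(it_adapt) / gamma_da * H_bar
      eta <- it_adapt^(-kappa)
      log_eps_bar <- (1 - eta) * log_eps_bar + eta * log_eps
      eps <- exp(log_eps)
      if (it >= wb_start) {
        wb <- wb + 1L
        warm_buf[wb, ] <- q
      }
      if (it %in% wbound && wb > 10L) {
        wbuf <- warm_buf[seq_len(wb), , drop = FALSE]
        if (dense_mass && wb > d + 10L) {
          # regularised covariance (shrunk toward its diagonal)
          S <- stats::cov(wbuf)
          wgt <- wb / (wb + 5)
          S <- wgt * S + (1 - wgt) * diag(pmax(diag(S), 1e-10), d)
          diag(S) <- pmax(diag(S), 1e-10)
          mass_U <- tryCatch(chol(S), error = function(e) NULL)
          if (is.null(mass_U)) inv_mass <- pmax(diag(S), 1e-10)
        } else {
          v <- apply(wbuf, 2, stats::var)
          inv_mass <- pmax(v, 1e-10)  # kinetic-energy scale ~ posterior var
          mass_U <- NULL
        }
        eps <- find_initial_step(target, q, draw_p, velocity)
        mu_da <- log(10 * eps)
        log_eps_bar <- log(eps); H_bar <- 0
        it_adapt <- 0L
        # buffer accumulates across windows: later estimates use more draws
      }
      if (it == n_tune) eps <- exp(log_eps_bar)
    } else {
      accept_sum <- accept_sum + alpha
      draws[it - n_tune, ] <- q
      lp[it - n_tune] <- cur$value
    }
  }
  list(draws = draws, lp = lp, step_size = eps, divergences = n_div,
       accept_rate = accept_sum / n_draws)
}

# One iteration of the dynamic-trajectory (no-U-turn) sampler with
# multinomial sampling across the trajectory (biased progressive variant).
nuts_iter <- function(target, q, cur, eps, draw_p, velocity, kinetic,
                      max_depth = 8L, divergence_threshold = 1000) {
  p0 <- draw_p()
  H0 <- -cur$value + kinetic(p0)
  # leaf states stored as lists: q, p, grad, value
  leapfrog <- function(st, dir) {
    p <- st$p + (dir * eps / 2) * st$grad
    qn <- st$q + dir * eps * velocity(p)
    tg <- target(qn)
    if (!is.finite(tg$value) || !all(is.finite(tg$grad)))
      return(NULL)
    p <- p + (dir * eps / 2) * tg$grad
    list(q = qn, p = p, grad = tg$grad, value = tg$value)
  }
  uturn <- function(minus, plus) {
    dq <- plus$q - minus$q
    (sum(dq * velocity(minus$p)) < 0) || (sum(dq * velocity(plus$p)) < 0)
  }
  n_alpha <- 0L; sum_alpha <- 0
  divergent <- FALSE
  # recursive doubling
  build <- function(st, dir, depth) {
    if (depth == 0L) {
      nxt <- leapfrog(st, dir)
      if (is.null(nxt)) {
        divergent <<- TRUE
        return(list(ok = FALSE))
      }
      H <- -nxt$value + kinetic(nxt$p)
      dH <- H - H0
      n_alpha <<- n_alpha + 1L
      sum_alpha <<- sum_alpha + min(1, exp(-dH))
      if (!is.finite(dH) || dH > divergence_threshold) {
        divergent <<- TRUE
        return(list(ok = FALSE))
      }
      return(list(ok = TRUE, minus = nxt, plus = nxt, prop = nxt,
                  logw = -dH))
    }
    t1 <- build(st, dir, depth - 1L)
    if (!t1$ok) return(t1)
    t2 <- build(if (dir == 1) t1$plus else t1$minus, dir, depth - 1L)
    if (!t2$ok) return(t2)
    logw <- max(t1$logw, t2$logw) +
      log(exp(t1$logw - max(t1$logw, t2$logw)) +
          exp(t2$logw - max(t1$logw, t2$logw)))
    prop <- if (log(stats::runif(1)) < t2$logw - logw) t2$prop else t1$prop
    minus <- if (dir == 1) t1$minus else t2$minus
    plus <- if (dir == 1) t2$plus else t1$plus
    if (uturn(minus, plus)) return(list(ok = FALSE))
    list(ok = TRUE, minus = minus, plus = plus, prop = prop, logw = logw)
  }
  st0 <- list(q = q, p = p0, grad = cur$grad, value = cur$value)
  minus <- st0; plus <- st0
  prop <- st0
  logw <- 0  # log weight of the initial point (H - H0 = 0)
  for (depth in 0:(max_depth - 1L)) {
    dir <- if (stats::runif(1) < 0.5) 1 else -1
    sub <- build(if (dir == 1) plus else minus, dir, depth)
    if (!sub$ok) break
    # biased progressive sampling: favour the new subtree
    if (log(stats::runif(1)) < sub$logw - logw) prop <- sub$prop
    logw <- max(logw, sub$logw) +
      log(exp(logw - max(logw, sub$logw)) +
          exp(sub$logw - max(logw, sub$logw)))
    if (dir == 1) plus <- sub$plus else minus <- sub$minus
    if (uturn(minus, plus)) break
  }
  list(q = prop$q,
       cur = list(value = prop$value, grad = prop$grad),
       accept_stat = if (n_alpha > 0) sum_alpha / n_alpha else 0,
       divergent = divergent)
}

find_initial_step <- function(target, q, draw_p, velocity, eps = 0.1) {
  cur <- target(q)
  kin <- function(p) 0.5 * sum(p * velocity(p))
  hamil <- function(eps) {
    p <- draw_p()
    H0 <- -cur$value + kin(p)
    pn <- p + 0.5 * eps * cur$grad
    qn <- q + eps * velocity(pn)
    prop <- target(qn)
    if (!is.finite(prop$value) || !all(is.finite(prop$grad))) return(Inf)
    pn <- pn + 0.5 * eps * prop$grad
    (-prop$value + kin(pn)) - H0
  }
  set_ok <- FALSE
  for (i in 1:30) {
    dH <- hamil(eps)
    if (!is.finite(dH) || dH > 0.7) eps <- eps / 2
    else if (dH < 0.1) { eps <- eps * 2; set_ok <- TRUE }
    else { set_ok <- TRUE; break }
    if (eps < 1e-10 || eps > 1e3) break
  }
  if (!set_ok) eps <- max(eps, 1e-6)
  min(eps, 1)
}

# split-Rhat over a list of draw matrices (one per chain, iterations x params)
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch) %/% 2L
    halves <- c(halves, list(ch[seq_len(n), , drop = FALSE],
                             ch[n + seq_len(n), , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  d <- ncol(halves[[1]])
  vapply(seq_len(d), function(j) {
    x <- vapply(halves, function(h) h[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# effective sample size (Geyer initial positive sequence, pooled chains)
ess_geyer <- function(chains) {
  d <- ncol(chains[[1]])
  vapply(seq_len(d), function(j) {
    n <- nrow(chains[[1]])
    m <- length(chains)
    W <- mean(vapply(chains, function(ch) stats::var(ch[, j]), numeric(1)))
    B <- if (m > 1) n * stats::var(vapply(chains, function(ch)
      mean(ch[, j]), numeric(1))) else 0
    varplus <- (n - 1) / n * W + B / n
    if (varplus < 1e-300) return(n * m)
    maxlag <- min(n - 2L, 400L)
    acov <- vapply(chains, function(ch) {
      x <- ch[, j] - mean(ch[, j])
      vapply(0:maxlag, function(l)
        sum(x[seq_len(n - l)] * x[l + seq_len(n - l)]) / n, numeric(1))
    }, numeric(maxlag + 1L))
    acov <- rowMeans(acov)
    rho <- 1 - (W - acov) / varplus
    # Geyer: sum consecutive pairs while positive
    tau <- 0; t <- 1
    while (t + 1 <= length(rho)) {
      pair <- rho[t] + rho[t + 1]
      if (pair < 0) break
      tau <- tau + pair
      t <- t + 2
    }
    tau <- max(2 * tau - 1, 1 / (n * m))
    min(n * m / tau, n * m)
  }, numeric(1))
}

# --- LKJ-Cholesky transform -------------------------------------------------

# unconstrained y (length K(K-1)/2, row-major for rows 2..K) -> lower
# Cholesky factor L of a correlation matrix via canonical partial
# correlations w = tanh(y)
lkj_chol_from_y <- function(y, K) {
  L <- diag(K)
  w <- tanh(y)
  idx <- 0L
  for (i in 2:K) {
    r <- 1
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      L[i, j] <- w[idx] * sqrt(r)
      r <- r * (1 - w[idx]^2)
    }
    L[i, i] <- sqrt(r)
  }
  L
}

# log prior of LKJ(eta) on L plus log-Jacobian of y -> L (tanh and
# sqrt(remaining) factors)
lkj_log_target <- function(y, K, eta) {
  w <- tanh(y)
  lp <- 0
  idx <- 0L
  for (i in 2:K) {
    logr <- 0
    for (j in 1:(i - 1)) {
      idx <- idx + 1L
      l1mw2 <- log1p(-w[idx]^2)
      # Jacobian: dL_ij/dw_ij = sqrt(r_ij); dw/dy = (1 - w^2)
      lp <- lp + 0.5 * logr + l1mw2
      logr <- logr + l1mw2
    }
    # LKJ density on the Cholesky factor: L_ii^(K - i + 2 eta - 2)
    lp <- lp + (K - i + 2 * eta - 2) * 0.5 * logr
  }
  lp
}

# gradient of a scalar function of L (grad_L, lower triangular incl.
# diagonal) pulled back to y, given w = tanh(y)
lkj_grad_to_y <- function(grad_L, y, K) {
  w <- tanh(y)
  gy <- numeric(length(y))
  idx0 <- 0L
  for (i in 2:K) {
    nw <- i - 1L
    wi <- w[idx0 + seq_len(nw)]
    r <- cumprod(c(1, (1 - wi^2)))       # r[j] = prod_{k<j}(1-w_k^2)
    Li <- numeric(i)
    for (j in seq_len(nw)) Li[j] <- wi[j] * sqrt(r[j])
    Li[i] <- sqrt(r[nw + 1L])
    gL <- grad_L[i, seq_len(i)]
    for (kk in seq_len(nw)) {
      acc <- sqrt(r[kk]) * gL[kk]
      # later entries in the row (incl. diagonal) depend on w_k through r
      later <- (kk + 1L):i
      acc <- acc - wi[kk] / (1 - wi[kk]^2) * sum(Li[later] * gL[later])
      gy[idx0 + kk] <- acc * (1 - wi[kk]^2)
    }
    idx0 <- idx0 + nw
  }
  gy
}

# direct LKJ(eta) correlation-matrix sampler (onion method); used for
# ancestral prior draws and as an independent check on the MCMC transform
rlkj <- function(K, eta) {
  if (K == 1) return(matrix(1, 1, 1))
  beta <- eta + (K - 2) / 2
  u <- stats::rbeta(1, beta, beta)
  R <- matrix(c(1, 2 * u - 1, 2 * u - 1, 1), 2, 2)
  if (K == 2) return(R)
  for (m in 2:(K - 1)) {
    beta <- beta - 0.5
    yv <- stats::rbeta(1, m / 2, beta)
    un <- stats::rnorm(m)
    un <- un / sqrt(sum(un^2))
    wv <- sqrt(yv) * un
    A <- t(chol(R))
    zv <- as.numeric(A %*% wv)
    R <- rbind(cbind(R, zv), c(zv, 1))
    dimnames(R) <- NULL
  }
  R
}
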