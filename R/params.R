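#' Behavioural parameters of the feeding model
#'
#' One individual's parameter vector for the three-state feeding process.
#' Bout durations are Exponential(`lambda_F`); per-bout feeding rates are
#' Normal(`mu_F`, `sigma_F`) truncated below at zero; short within-meal
#' pauses are Exponential(`lambda_S`); after each bout the meal terminates
#' with probability \eqn{1/(1 + e^{-T_1 (x - T_2)})} at the current fullness
#' \eqn{x}; and the intermeal interval has hazard
#' \eqn{\lambda_L(x) = 1/(L_1 + L_2 x)}.
#'
#' @param lambda_F Bout termination rate (1/s, > 0); mean bout duration is
#'   `1/lambda_F`.
#' @param mu_F Mean feeding rate within a bout (g/s, > 0).
#' @param sigma_F Spread of per-bout feeding rates (g/s, > 0).
#' @param lambda_S Short-pause termination rate (1/s, > 0).
#' @param T1 Meal-termination sharpness (1/g). Positive values make
#'   termination more likely at higher fullness; the group-level prior leaves
#'   the sign unrestricted.
#' @param T2 Meal-termination fullness threshold (g; termination probability
#'   is 1/2 at `x = T2`).
#' @param L1 Fullness-independent intermeal-interval scale (s, > 0); with
#'   `L2 = 0` intermeal intervals are Exponential with mean `L1`.
#' @param L2 Fullness-dependent intermeal-interval scale (s/g, >= 0).
#' @return An object of class `"feed_params"` (a named numeric vector).
#' @examples
#' p <- feed_params()
#' 1 / p["lambda_F"]  # mean bout duration, seconds
#' @export
feed_params <- function(lambda_F = 1 / 80, mu_F = 0.006, sigma_F = 0.0015,
                        lambda_S = 1 / 40, T1 = 1.5, T2 = 2,
                        L1 = 2000, L2 = 1500) {
  p <- c(lambda_F = lambda_F, mu_F = mu_F, sigma_F = sigma_F,
         lambda_S = lambda_S, T1 = T1, T2 = T2, L1 = L1, L2 = L2)
  validate_params(p)
  structure(p, class = "feed_params")
}

param_names <- function() {
  c("lambda_F", "mu_F", "sigma_F", "lambda_S", "T1", "T2", "L1", "L2")
}

#' @rdname feed_params
#' @param x A named numeric vector with entries `lambda_F`, `mu_F`,
#'   `sigma_F`, `lambda_S`, `T1`, `T2`, `L1`, `L2` (any order).
#' @export
as_feed_params <- function(x) {
  if (inherits(x, "feed_params")) return(x)
  x <- unlist(x)
  if (!all(param_names() %in% names(x)))
    stop("missing parameter(s): ",
         paste(setdiff(param_names(), names(x)), collapse = ", "))
  p <- x[param_names()]
  validate_params(p)
  structure(p, class = "feed_params")
}

validate_params <- function(p) {
  pos <- c("lambda_F", "mu_F", "sigma_F", "lambda_S", "L1")
  if (any(!is.finite(p))) stop("parameters must be finite")
  bad <- pos[p[pos] <= 0]
  if (length(bad)) stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  if (p[["L2"]] < 0) stop("'L2' must be >= 0")
  invisible(p)
}

#' @export
print.feed_params <- function(x, digits = 4, ...) {
  cat("Feeding-model parameters:\n")
  print(signif(unclass(x), digits))
  cat(sprintf("  mean bout duration 1/lambda_F = %.1f s; mean short pause = %.1f s\n",
              1 / x[["lambda_F"]], 1 / x[["lambda_S"]]))
  invisible(x)
}

# --- transform between natural and inference (log10 / identity) scales -----

#' Transform parameters to and from the inference scale
#'
#' Group-level inference operates on a transformed scale: log10 for the six
#' positive-scale parameters (`lambda_F`, `mu_F`, `sigma_F`, `lambda_S`,
#' `L1`, `L2`) and the identity for the termination parameters `T1`, `T2`.
#' `param_transform()` maps natural-scale parameters to that scale and
#' `param_backtransform()` inverts it exactly.
#'
#' @param p A [feed_params()] (for `param_transform`) or a numeric 8-vector on
#'   the transformed scale (for `param_backtransform`).
#' @return A named numeric 8-vector (transformed scale), or a
#'   [feed_params()] object.
#' @export
param_transform <- function(p) {
  p <- as_feed_params(p)
  out <- unclass(p)
  lg <- log_scaled_params()
  out[lg] <- log10(out[lg])
  out
}

#' @rdname param_transform
#' @export
param_backtransform <- function(p) {
  stopifnot(length(p) == 8L)
  if (is.null(names(p))) names(p) <- param_names()
  lg <- log_scaled_params()
  p[lg] <- 10^p[lg]
  as_feed_params(p)
}

log_scaled_params <- function() {
  c("lambda_F", "mu_F", "sigma_F", "lambda_S", "L1", "L2")
}

# --- hyper-prior configuration ---------------------------------------------

#' Hyper-prior for the hierarchical feeding model
#'
#' Configuration of the group-level prior. Individual parameter vectors (on
#' the transformed scale, see [param_transform()]) are modelled as
#' \eqn{\tilde\theta_j \sim N(\mu, \Sigma)} with the separation prior
#' \eqn{\Sigma = diag(\tau)\,\Omega\,diag(\tau)},
#' \eqn{\tau_i \sim HalfCauchy(2.5)}, \eqn{\Omega \sim LKJ(\eta)}, and
#' \eqn{\mu \sim N(\mu^*, 2)} componentwise.
#'
#' @param mu_star Prior mean of the group mean on the transformed scale;
#'   default `c(-3, -3, -3, 1, 1, -1, 3, 3)` in the order `lambda_F`, `mu_F`,
#'   `sigma_F`, `lambda_S`, `T1`, `T2`, `L1`, `L2`.
#' @param mu_prior_sd Prior standard deviation of each component of the group
#'   mean (default 2).
#' @param tau_scale Half-Cauchy scale for the group standard deviations
#'   (default 2.5).
#' @param lkj_eta LKJ shape for the correlation matrix (default 2, a weak
#'   preference for moderate correlations).
#' @return An object of class `"hyper_prior"`.
#' @export
hyper_prior <- function(mu_star = c(-3, -3, -3, 1, 1, -1, 3, 3),
                        mu_prior_sd = 2, tau_scale = 2.5, lkj_eta = 2) {
  if (length(mu_star) != 8L) stop("'mu_star' must have length 8")
  if (tau_scale <= 0) stop("'tau_scale' must be > 0")
  if (lkj_eta <= 0) stop("'lkj_eta' must be > 0")
  if (mu_prior_sd <= 0) stop("'mu_prior_sd' must be > 0")
  structure(list(mu_star = stats::setNames(as.numeric(mu_star), param_names()),
                 mu_prior_sd = mu_prior_sd, tau_scale = tau_scale,
                 lkj_eta = lkj_eta),
            class = "hyper_prior")
}

#' @export
print.hyper_prior <- function(x, ...) {
  cat("Hierarchical hyper-prior:\n")
  cat("  mu ~ N(mu*,", x$mu_prior_sd, ") with mu* =",
      paste(x$mu_star, collapse = ", "), "\n")
  cat("  tau_i ~ HalfCauchy(", x$tau_scale, "), Omega ~ LKJ(",
      x$lkj_eta, ")\n")
  invisible(x)
}
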