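## Conjugate validation models with closed-form marginal likelihoods. These
## are the acceptance oracle for the whole pipeline: run the power posterior
## machinery on them and compare the estimate with the analytic value.

#' Normal model with known variance and conjugate normal prior
#'
#' Observations y_i ~ Normal(theta, sigma2) with known sigma2 and prior
#' theta ~ Normal(mu0, tau2). The marginal likelihood integrates theta out in
#' closed form, and the power posterior at any beta is itself normal, so both
#' the estimators and the sampler's per-stone moments can be checked exactly.
#'
#' The default observation vector is a fixed ten-value data set shipped with
#' the package so validation runs are reproducible.
#'
#' @param y numeric observation vector.
#' @param sigma2 known likelihood variance, > 0.
#' @param mu0,tau2 prior mean and variance of theta.
#' @param delta sliding-window half-width for the theta move.
#' @return a \code{\link{pp_model}} with the analytic pieces attached as
#'   attributes \code{hyper}.
#' @export
normal_conjugate_model <- function(y = c(1.262, 0.314, 1.323, 2.757, 0.532,
                                         1.717, 0.891, -0.350, 1.252, 1.778),
                                   sigma2 = 1, mu0 = 0, tau2 = 1,
                                   delta = 1.5) {
  stopifnot(sigma2 > 0, tau2 > 0, length(y) >= 1)
  force(y); force(sigma2); force(mu0); force(tau2)
  sd_l <- sqrt(sigma2); sd_p <- sqrt(tau2)
  m <- pp_model(
    name = "normal_conjugate",
    log_prior = function(values) {
      stats::dnorm(values$theta, mu0, sd_p, log = TRUE)
    },
    log_likelihood = function(values) {
      sum(stats::dnorm(y, values$theta, sd_l, log = TRUE))
    },
    moves = list(move_sliding("theta", delta = delta)),
    initial_state = function() list(theta = stats::rnorm(1, mu0, sd_p))
  )
  attr(m, "hyper") <- list(y = y, sigma2 = sigma2, mu0 = mu0, tau2 = tau2)
  m
}

#' Closed-form log marginal likelihood of the conjugate normal model
#'
#' With n observations, \eqn{\bar y} their mean and S their centred sum of
#' squares, the marginal likelihood of y with theta integrated out is
#' \deqn{-\tfrac{n}{2}\ln(2\pi\sigma^2)
#'   + \tfrac12 \ln\frac{\sigma^2}{\sigma^2 + n\tau^2}
#'   - \frac{S}{2\sigma^2}
#'   - \frac{n(\bar y - \mu_0)^2}{2(\sigma^2 + n\tau^2)}.}
#'
#' @param model a \code{\link{normal_conjugate_model}}.
#' @return the log marginal likelihood.
#' @export
normal_log_marginal <- function(model) {
  h <- attr(model, "hyper")
  n <- length(h$y)
  ybar <- mean(h$y)
  S <- sum((h$y - ybar)^2)
  v <- h$sigma2 + n * h$tau2
  -n / 2 * log(2 * pi * h$sigma2) + 0.5 * log(h$sigma2 / v) -
    S / (2 * h$sigma2) - n * (ybar - h$mu0)^2 / (2 * v)
}

# mean and variance of the power posterior of theta at a given beta
# (likelihood^beta x prior is normal: precision beta*n/sigma2 + 1/tau2)
normal_power_posterior_moments <- function(model, beta) {
  h <- attr(model, "hyper")
  n <- length(h$y)
  prec <- beta * n / h$sigma2 + 1 / h$tau2
  mean <- (beta * sum(h$y) / h$sigma2 + h$mu0 / h$tau2) / prec
  list(mean = mean, var = 1 / prec)
}

#' Beta-binomial model
#'
#' k_obs successes in n_obs Bernoulli trials with success probability p and
#' prior p ~ Beta(a, b). The marginal likelihood is the beta-binomial
#' probability of k_obs. The p move is a sliding window reflected at 0 and 1,
#' which stays symmetric (zero Hastings term).
#'
#' @param k_obs,n_obs observed successes and trials.
#' @param a,b prior shape parameters, > 0.
#' @param delta sliding-window half-width for the p move.
#' @return a \code{\link{pp_model}} with hyperparameters in attribute
#'   \code{hyper}.
#' @export
beta_binomial_model <- function(k_obs = 7, n_obs = 20, a = 2, b = 2,
                                delta = 0.2) {
  stopifnot(k_obs >= 0, k_obs <= n_obs, a > 0, b > 0)
  force(k_obs); force(n_obs); force(a); force(b)
  m <- pp_model(
    name = "beta_binomial",
    log_prior = function(values) {
      stats::dbeta(values$p, a, b, log = TRUE)
    },
    log_likelihood = function(values) {
      stats::dbinom(k_obs, n_obs, values$p, log = TRUE)
    },
    moves = list(move_sliding("p", delta = delta, lower = 0, upper = 1)),
    initial_state = function() list(p = stats::rbeta(1, a, b))
  )
  attr(m, "hyper") <- list(k_obs = k_obs, n_obs = n_obs, a = a, b = b)
  m
}

#' Closed-form log marginal likelihood of the beta-binomial model
#'
#' \eqn{\ln [ C(n, k) B(a + k, b + n - k) / B(a, b) ]}.
#'
#' @param model a \code{\link{beta_binomial_model}}.
#' @return the log marginal likelihood.
#' @export
betabinom_log_marginal <- function(model) {
  h <- attr(model, "hyper")
  lchoose(h$n_obs, h$k_obs) +
    lbeta(h$a + h$k_obs, h$b + h$n_obs - h$k_obs) - lbeta(h$a, h$b)
}
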