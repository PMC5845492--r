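#' Outcome-model log likelihood
#'
#' Log likelihood of the two-level Poisson outcome model
#' \deqn{y_{ij} \sim \mathrm{Poisson}(r_{ij}\lambda_{ij}), \quad
#'   \log\lambda_{ij} = \beta_0 + u_{j} + \beta_1 x_{ij} + \sum_k \beta_k z_{ijk},}
#' evaluated at an explicit exposure vector `x` (which may be the latent
#' imputation, the first assessment in the naive model, or the simulated
#' truth).
#'
#' @param data An `mc_data` object.
#' @param state An `mc_state` object supplying `beta0`, `beta1`, `beta_k`, `u`.
#' @param x Binary vector, one entry per subject.
#' @return The summed Poisson log likelihood (a single finite number for
#'   finite inputs).
#' @export
outcome_loglik <- function(data, state, x) {
  check_state_dims(data, state, "naive", outcome = TRUE, exposure = FALSE)
  if (length(x) != data$n)
    mc_stop(sprintf("`x` has length %d but data have %d subjects", length(x), data$n),
            "miscount_dim_error")
  eta <- state$beta0 + state$u[data$cluster] + state$beta1 * x
  if (ncol(data$Zy)) eta <- eta + drop(data$Zy %*% state$beta_k)
  sum(dpois(data$y, data$r * exp(eta), log = TRUE))
}

#' Exposure-model log likelihood
#'
#' Log likelihood of the hierarchical logistic exposure model
#' \deqn{x_{ij} \sim \mathrm{Bernoulli}(\pi_{ij}), \quad
#'   \mathrm{logit}\,\pi_{ij} = \gamma_0 + v_j + \sum_k \gamma_k z_{ijk}.}
#'
#' @inheritParams outcome_loglik
#' @param x Binary vector of (true or imputed) exposures.
#' @return Summed Bernoulli log likelihood.
#' @export
exposure_loglik <- function(data, state, x) {
  check_state_dims(data, state, "one_test", outcome = FALSE, exposure = TRUE)
  if (length(x) != data$n)
    mc_stop(sprintf("`x` has length %d but data have %d subjects", length(x), data$n),
            "miscount_dim_error")
  eta <- state$gamma0 + state$v[data$cluster]
  if (ncol(data$Zx)) eta <- eta + drop(data$Zx %*% state$gamma_k)
  sum(dbinom(x, 1L, plogis(eta), log = TRUE))
}

#' Measurement-model log likelihood, single assessment
#'
#' Nondifferential misclassification kernel: given true exposure `x = 1` the
#' assessment is Bernoulli with success probability `S1` (sensitivity); given
#' `x = 0` it is Bernoulli with success probability `1 - C1` (one minus
#' specificity).
#'
#' @param x1 Binary vector of observed assessments.
#' @param x Binary vector of true exposures, same length.
#' @param S1,C1 Sensitivity and specificity in the open interval `(0, 1)`.
#' @return Summed measurement log likelihood.
#' @export
measurement_loglik_one <- function(x1, x, S1, C1) {
  for (nm in c("S1", "C1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      mc_stop(sprintf("`%s` must lie in the open interval (0, 1)", nm),
              "miscount_state_error")
  }
  if (length(x1) != length(x))
    mc_stop(sprintf("`x1` has length %d but `x` has length %d", length(x1), length(x)),
            "miscount_dim_error")
  p <- ifelse(x == 1, S1, 1 - C1)
  sum(dbinom(x1, 1L, p, log = TRUE))
}

#' Measurement-model log likelihood, two conditionally independent assessments
#'
#' The two assessments are assumed conditionally independent given the true
#' exposure, so the joint kernel is the product of two single-assessment
#' kernels.
#'
#' @param x1,x2 Binary vectors of observed assessments.
#' @param x Binary vector of true exposures.
#' @param S1,C1,S2,C2 Operating characteristics of the two tests.
#' @return Summed measurement log likelihood.
#' @export
measurement_loglik_two <- function(x1, x2, x, S1, C1, S2, C2) {
  measurement_loglik_one(x1, x, S1, C1) + measurement_loglik_one(x2, x, S2, C2)
}

#' Joint prior log density
#'
#' Sum of the log prior densities of every parameter active in `mode`:
#' independent mean-zero normals (parameterized by variance) on all regression
#' coefficients, `N(0, sigma^2)` on each outcome random intercept and
#' `N(0, nu^2)` on each exposure one, uniform `(0, sd_upper)` on `sigma` and
#' `nu` (returning `-Inf` outside the support), and beta priors on each
#' sensitivity/specificity present.
#'
#' @param state An `mc_state`.
#' @param priors An `mc_priors`.
#' @param mode Model mode; defaults to the mode the priors were built for.
#' @return Log prior density (possibly `-Inf`).
#' @export
prior_logdensity <- function(state, priors, mode = priors$mode) {
  check_mode(mode)
  lp <- sum(dnorm(c(state$beta0, state$beta1, state$beta_k),
                  0, sqrt(priors$beta_var), log = TRUE))
  lp <- lp + dunif(state$sigma, 0, priors$sd_upper, log = TRUE)
  if (is.finite(lp)) lp <- lp + sum(dnorm(state$u, 0, state$sigma, log = TRUE))
  if (mode != "naive") {
    lp <- lp + sum(dnorm(c(state$gamma0, state$gamma_k),
                         0, sqrt(priors$gamma_var), log = TRUE))
    lp <- lp + dunif(state$nu, 0, priors$sd_upper, log = TRUE)
    if (is.finite(lp)) lp <- lp + sum(dnorm(state$v, 0, state$nu, log = TRUE))
    lp <- lp + dbeta(state$S1, priors$s1[1], priors$s1[2], log = TRUE) +
      dbeta(state$C1, priors$c1[1], priors$c1[2], log = TRUE)
    if (mode == "two_test")
      lp <- lp + dbeta(state$S2, priors$s2[1], priors$s2[2], log = TRUE) +
        dbeta(state$C2, priors$c2[1], priors$c2[2], log = TRUE)
  }
  lp
}

#' Joint log posterior (up to an additive constant)
#'
#' Sum of the outcome, exposure, and measurement log likelihoods and the prior
#' log density, i.e. the log of the joint posterior kernel. In `naive` mode
#' the first assessment `x1` is treated as the true exposure and the exposure
#' and measurement models drop out; in `one_test`/`two_test` mode the current
#' latent imputation `state$x_latent` enters all three model components.
#'
#' @inheritParams prior_logdensity
#' @param data An `mc_data`.
#' @return Log posterior kernel (possibly `-Inf`).
#' @export
joint_log_posterior <- function(data, state, priors, mode = priors$mode) {
  check_mode(mode)
  check_state_dims(data, state, mode)
  if (mode == "naive")
    return(outcome_loglik(data, state, data$x1) + prior_logdensity(state, priors, mode))
  x <- state$x_latent
  if (is.null(x))
    mc_stop("`state$x_latent` is required outside naive mode", "miscount_state_error")
  ll <- outcome_loglik(data, state, x) + exposure_loglik(data, state, x)
  ll <- ll + if (mode == "one_test") {
    measurement_loglik_one(data$x1, x, state$S1, state$C1)
  } else {
    if (is.null(data$x2))
      mc_stop("two_test mode requires an `x2` assessment column", "miscount_data_error")
    measurement_loglik_two(data$x1, data$x2, x, state$S1, state$C1, state$S2, state$C2)
  }
  ll + prior_logdensity(state, priors, mode)
}

#' Full conditional probability of latent exposure
#'
#' For each subject, the exact Bernoulli full-conditional probability that the
#' true exposure is 1 given the data, assessments, and all other parameters:
#' \deqn{P(x_{ij}=1 \mid \cdot) = \frac{A}{A + B}} with
#' `A = pi * Poisson(y; r*lambda(x=1)) * f(assessments | x=1)` and `B` the
#' `x = 0` analogue. This is the distribution the data-augmentation step of
#' the Gibbs sampler draws from.
#'
#' @param data An `mc_data`.
#' @param state An `mc_state` (all parameters except `x_latent` are used).
#' @param mode `"one_test"` or `"two_test"`.
#' @return Numeric vector of probabilities in `[0, 1]`, one per subject.
#' @export
latent_x_prob <- function(data, state, mode = "one_test") {
  check_mode(mode)
  if (mode == "naive")
    mc_stop("latent exposure has no distribution in naive mode", "miscount_mode_error")
  check_state_dims(data, state, mode)
  eta_x <- state$gamma0 + state$v[data$cluster]
  if (ncol(data$Zx)) eta_x <- eta_x + drop(data$Zx %*% state$gamma_k)
  eta0 <- state$beta0 + state$u[data$cluster]
  if (ncol(data$Zy)) eta0 <- eta0 + drop(data$Zy %*% state$beta_k)
  lam0 <- data$r * exp(eta0)
  # log A - log B, assembled on the log-odds scale for numerical stability
  lo <- eta_x + data$y * state$beta1 - lam0 * (exp(state$beta1) - 1)
  lo <- lo + ifelse(data$x1 == 1, log(state$S1 / (1 - state$C1)),
                    log((1 - state$S1) / state$C1))
  if (mode == "two_test") {
    if (is.null(data$x2))
      mc_stop("two_test mode requires an `x2` assessment column", "miscount_data_error")
    lo <- lo + ifelse(data$x2 == 1, log(state$S2 / (1 - state$C2)),
                      log((1 - state$S2) / state$C2))
  }
  if (any(is.na(lo)))
    mc_stop("non-finite latent-exposure log odds; check parameter values",
            "miscount_numeric_error")
  plogis(lo)
}
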