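# Fixtures are built in code; nothing is read from disk.

# small dataset drawn from the generative model (two tests unless disabled)
tiny_data <- function(n_per_cluster = 10, N = 2, seed = 42, two_tests = TRUE) {
  des <- sim_design(N = N, n_per_cluster = n_per_cluster,
                    gamma_true = c(-0.5, 0.4, -0.3),
                    beta_true = c(0.3, 0.5, 0.2, -0.25),
                    sigma_true = 0.2, nu_true = 0.2,
                    S1 = 0.8, C1 = 0.9,
                    S2 = if (two_tests) 0.7 else NULL,
                    C2 = if (two_tests) 0.85 else NULL)
  simulate_misclass_data(des, seed = seed)
}

# random interior parameter state for a dataset
rand_state <- function(data, mode = "two_test", seed = 1) {
  set.seed(seed)
  corrected <- mode != "naive"
  param_state(
    beta0 = rnorm(1, 0, 0.5), beta1 = rnorm(1, 0, 0.5),
    beta_k = rnorm(ncol(data$Zy), 0, 0.3),
    u = rnorm(data$N, 0, 0.2), sigma = runif(1, 0.05, 0.5),
    gamma0 = if (corrected) rnorm(1, 0, 0.5) else NULL,
    gamma_k = if (corrected) rnorm(ncol(data$Zx), 0, 0.3) else NULL,
    v = if (corrected) rnorm(data$N, 0, 0.2) else NULL,
    nu = if (corrected) runif(1, 0.05, 0.5) else NULL,
    S1 = if (corrected) runif(1, 0.55, 0.95) else NULL,
    C1 = if (corrected) runif(1, 0.55, 0.95) else NULL,
    S2 = if (corrected) runif(1, 0.55, 0.95) else NULL,
    C2 = if (corrected) runif(1, 0.55, 0.95) else NULL,
    x_latent = if (corrected) rbinom(data$n, 1, 0.5) else NULL)
}

# independent brute-force re-implementation of the joint log posterior:
# everything is summed subject by subject / cluster by cluster with stats::d*
oracle_joint_lp <- function(data, state, priors, mode) {
  lp <- 0
  x <- if (mode == "naive") data$x1 else state$x_latent
  for (i in seq_len(data$n)) {
    j <- data$cluster[i]
    eta_y <- state$beta0 + state$u[j] + state$beta1 * x[i] +
      sum(data$Zy[i, ] * state$beta_k)
    lp <- lp + dpois(data$y[i], data$r[i] * exp(eta_y), log = TRUE)
    if (mode != "naive") {
      eta_x <- state$gamma0 + state$v[j] + sum(data$Zx[i, ] * state$gamma_k)
      p <- 1 / (1 + exp(-eta_x))
      lp <- lp + x[i] * log(p) + (1 - x[i]) * log(1 - p)
      p1 <- if (x[i] == 1) state$S1 else 1 - state$C1
      lp <- lp + data$x1[i] * log(p1) + (1 - data$x1[i]) * log(1 - p1)
      if (mode == "two_test") {
        p2 <- if (x[i] == 1) state$S2 else 1 - state$C2
        lp <- lp + data$x2[i] * log(p2) + (1 - data$x2[i]) * log(1 - p2)
      }
    }
  }
  for (nm in c(state$beta0, state$beta1, state$beta_k))
    lp <- lp + dnorm(nm, 0, sqrt(priors$beta_var), log = TRUE)
  lp <- lp + dunif(state$sigma, 0, priors$sd_upper, log = TRUE) +
    sum(dnorm(state$u, 0, state$sigma, log = TRUE))
  if (mode != "naive") {
    for (nm in c(state$gamma0, state$gamma_k))
      lp <- lp + dnorm(nm, 0, sqrt(priors$gamma_var), log = TRUE)
    lp <- lp + dunif(state$nu, 0, priors$sd_upper, log = TRUE) +
      sum(dnorm(state$v, 0, state$nu, log = TRUE))
    lp <- lp + dbeta(state$S1, priors$s1[1], priors$s1[2], log = TRUE) +
      dbeta(state$C1, priors$c1[1], priors$c1[2], log = TRUE)
    if (mode == "two_test")
      lp <- lp + dbeta(state$S2, priors$s2[1], priors$s2[2], log = TRUE) +
        dbeta(state$C2, priors$c2[1], priors$c2[2], log = TRUE)
  }
  lp
}

# brute-force two-point Bayes enumeration of P(x_i = 1 | everything else)
oracle_latent_prob <- function(data, state, mode, i) {
  j <- data$cluster[i]
  w <- numeric(2)
  for (xv in 0:1) {
    eta_y <- state$beta0 + state$u[j] + state$beta1 * xv +
      sum(data$Zy[i, ] * state$beta_k)
    eta_x <- state$gamma0 + state$v[j] + sum(data$Zx[i, ] * state$gamma_k)
    p <- plogis(eta_x)
    w[xv + 1] <- dbinom(xv, 1, p) *
      dpois(data$y[i], data$r[i] * exp(eta_y)) *
      dbinom(data$x1[i], 1, if (xv == 1) state$S1 else 1 - state$C1)
    if (mode == "two_test")
      w[xv + 1] <- w[xv + 1] *
        dbinom(data$x2[i], 1, if (xv == 1) state$S2 else 1 - state$C2)
  }
  w[2] / sum(w)
}

study_priors_default <- function() {
  list(naive = prior_spec("naive"),
       one_test = prior_spec("one_test", s1 = c(10, 8), c1 = c(165.7, 9.7)),
       two_test = prior_spec("two_test"))
}
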