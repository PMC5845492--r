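# Oracles: textbook density evaluations and per-subject brute-force sums,
# independent of the vectorized implementation.

one_subject <- function(y = 0, r = 1, x1 = 0, x2 = NULL, z = NULL) {
  df <- data.frame(y = y, r = r, cluster = 1, x1 = x1)
  if (!is.null(z)) df$z1 <- z
  if (!is.null(x2)) df$x2 <- x2
  mc_data(df, r = "r",
          z_outcome = if (is.null(z)) character() else "z1",
          z_exposure = if (is.null(z)) character() else "z1",
          x2 = if (is.null(x2)) NULL else "x2")
}

test_that("outcome log likelihood matches the Poisson log pmf", {
  d0 <- one_subject(y = 0)
  st <- param_state(beta0 = 0, beta1 = 0, u = 0, sigma = 0.1)
  # Poisson(0; 1) = e^-1
  expect_equal(outcome_loglik(d0, st, x = 0), -1)

  d2 <- one_subject(y = 2)
  st2 <- param_state(beta0 = 0.85, beta1 = 0.4, u = 0, sigma = 0.1)
  expect_equal(outcome_loglik(d2, st2, x = 1), dpois(2, exp(1.25), log = TRUE))

  # doubling the offset with y and lambda fixed shifts the log lik by
  # y*log(2) - r*lambda (Poisson log-pmf algebra, checked numerically)
  dA <- one_subject(y = 3, r = 1); dB <- one_subject(y = 3, r = 2)
  lam <- exp(0.85)
  expect_equal(outcome_loglik(dB, st2, x = 0) - outcome_loglik(dA, st2, x = 0),
               3 * log(2) - 1 * lam, tolerance = 1e-12)

  err <- tryCatch(outcome_loglik(d0, param_state(beta_k = c(1, 2), u = 0), x = 0),
                  error = identity)
  expect_s3_class(err, "miscount_dim_error")
  expect_match(conditionMessage(err), "length 2.*0 column")
  expect_error(outcome_loglik(d0, st, x = c(0, 1)), class = "miscount_dim_error")
})

test_that("exposure log likelihood matches the Bernoulli-logit oracle", {
  d <- tiny_data(n_per_cluster = 10, N = 2, seed = 3)
  st <- param_state(u = rep(0, 2), gamma0 = 0, gamma_k = rep(0, ncol(d$Zx)),
                    v = rep(0, 2), nu = 0.1)
  # all gamma = 0, v = 0: pi = 1/2 everywhere
  expect_equal(exposure_loglik(d, st, x = rep(1L, d$n)), d$n * log(0.5))

  d1 <- one_subject(y = 0, x1 = 1)
  st1 <- param_state(u = 0, gamma0 = -1.5, v = 0, nu = 0.1)
  expect_equal(exposure_loglik(d1, st1, x = 1), log(plogis(-1.5)))

  # label-switching symmetry: (x, gamma) and (1-x, -gamma) give the same value
  stf <- rand_state(d, "one_test", seed = 8)
  stn <- stf
  stn$gamma0 <- -stf$gamma0; stn$gamma_k <- -stf$gamma_k; stn$v <- -stf$v
  x <- rbinom(d$n, 1, 0.5)
  expect_equal(exposure_loglik(d, stf, x), exposure_loglik(d, stn, 1L - x),
               tolerance = 1e-12)
})

test_that("measurement kernels evaluate, normalize, and factorize", {
  expect_equal(measurement_loglik_one(1L, 1L, S1 = 0.55, C1 = 0.95), log(0.55))
  expect_equal(measurement_loglik_one(0L, 0L, S1 = 0.55, C1 = 0.95), log(0.95))
  expect_equal(measurement_loglik_two(1L, 0L, 1L, 0.55, 0.95, 0.7, 0.8),
               log(0.55 * 0.3))
  expect_error(measurement_loglik_one(1L, 1L, S1 = 1, C1 = 0.9),
               class = "miscount_state_error")
  expect_error(measurement_loglik_one(c(1L, 0L), 1L, 0.5, 0.5),
               class = "miscount_dim_error")

  # normalization over assessment outcomes, and two-test factorization
  set.seed(101)
  for (rep in 1:20) {
    S1 <- runif(1, 0.01, 0.99); C1 <- runif(1, 0.01, 0.99)
    S2 <- runif(1, 0.01, 0.99); C2 <- runif(1, 0.01, 0.99)
    for (xv in 0:1) {
      tot1 <- sum(vapply(0:1, function(a)
        exp(measurement_loglik_one(a, xv, S1, C1)), numeric(1)))
      expect_equal(tot1, 1, tolerance = 1e-12)
      grid <- expand.grid(a = 0:1, b = 0:1)
      tot2 <- sum(mapply(function(a, b)
        exp(measurement_loglik_two(a, b, xv, S1, C1, S2, C2)), grid$a, grid$b))
      expect_equal(tot2, 1, tolerance = 1e-12)
    }
    n <- 15
    x <- rbinom(n, 1, 0.5); a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    expect_equal(measurement_loglik_two(a, b, x, S1, C1, S2, C2),
                 measurement_loglik_one(a, x, S1, C1) +
                   measurement_loglik_one(b, x, S2, C2),
                 tolerance = 1e-12)
  }
})

test_that("prior log density matches textbook densities and support rules", {
  d <- tiny_data(n_per_cluster = 5, N = 2, seed = 2)
  pr <- prior_spec("one_test", s1 = c(10, 8), c1 = c(165.7, 9.7))
  st <- rand_state(d, "one_test", seed = 4)

  # sigma outside (0, sd_upper) kills the density
  st_bad <- st; st_bad$sigma <- pr$sd_upper + 0.5
  expect_identical(prior_logdensity(st_bad, pr, "one_test"), -Inf)

  # beta(1, 1) contributes 0; an informative beta matches dbeta
  pr2 <- prior_spec("two_test")
  st2 <- rand_state(d, "two_test", seed = 4)
  base <- prior_logdensity(st2, pr2, "two_test")
  st2b <- st2; st2b$S1 <- 0.31
  expect_equal(prior_logdensity(st2b, pr2, "two_test"), base)
  st_s <- st; st_s$S1 <- 0.55
  st_o <- st; st_o$S1 <- 0.4
  expect_equal(prior_logdensity(st_s, pr, "one_test") -
                 prior_logdensity(st_o, pr, "one_test"),
               dbeta(0.55, 10, 8, log = TRUE) - dbeta(0.4, 10, 8, log = TRUE),
               tolerance = 1e-12)
})

test_that("joint log posterior agrees with the per-subject brute-force oracle", {
  for (mode in c("naive", "one_test", "two_test")) {
    d <- tiny_data(n_per_cluster = 10, N = 2, seed = 11)
    pr <- switch(mode,
                 naive = prior_spec("naive"),
                 one_test = prior_spec("one_test", s1 = c(10, 8), c1 = c(165.7, 9.7)),
                 two_test = prior_spec("two_test", s2 = c(2, 3)))
    for (s in 1:5) {
      st <- rand_state(d, mode, seed = 100 + s)
      expect_equal(joint_log_posterior(d, st, pr, mode),
                   oracle_joint_lp(d, st, pr, mode), tolerance = 1e-10)
    }
  }
})

test_that("naive joint posterior is outcome likelihood plus its priors only", {
  d <- tiny_data(n_per_cluster = 10, N = 2, seed = 12)
  pr <- prior_spec("naive")
  st <- rand_state(d, "naive", seed = 5)
  manual <- outcome_loglik(d, st, d$x1) +
    sum(dnorm(c(st$beta0, st$beta1, st$beta_k), 0, sqrt(pr$beta_var), log = TRUE)) +
    dunif(st$sigma, 0, pr$sd_upper, log = TRUE) +
    sum(dnorm(st$u, 0, st$sigma, log = TRUE))
  expect_equal(joint_log_posterior(d, st, pr, "naive"), manual, tolerance = 1e-12)

  # the posterior depends on the data
  d2 <- d; d2$y <- d$y + 1
  expect_false(isTRUE(all.equal(joint_log_posterior(d2, st, pr, "naive"),
                                joint_log_posterior(d, st, pr, "naive"))))
})

test_that("log densities are finite inside the support", {
  d <- tiny_data(n_per_cluster = 10, N = 2, seed = 13)
  pr <- prior_spec("two_test")
  for (s in 1:10) {
    st <- rand_state(d, "two_test", seed = 300 + s)
    expect_true(is.finite(joint_log_posterior(d, st, pr, "two_test")))
  }
})
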