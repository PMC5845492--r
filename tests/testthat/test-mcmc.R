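test_that("latent-exposure full conditional equals brute-force Bayes enumeration", {
  for (mode in c("one_test", "two_test")) {
    d <- tiny_data(n_per_cluster = 12, N = 3, seed = 21)
    for (s in 1:6) {
      st <- rand_state(d, mode, seed = 400 + s)
      p <- latent_x_prob(d, st, mode)
      expect_true(all(p >= 0 & p <= 1))
      oracle <- vapply(seq_len(d$n), function(i) oracle_latent_prob(d, st, mode, i),
                      numeric(1))
      expect_equal(p, oracle, tolerance = 1e-12)
    }
  }
})

test_that("uninformative test and null exposure effect leave the prior probability", {
  # S = C = 1/2 carries no information; with beta1 = 0 the counts carry none
  d <- tiny_data(n_per_cluster = 10, N = 2, seed = 22)
  st <- rand_state(d, "one_test", seed = 7)
  st$S1 <- 0.5; st$C1 <- 0.5; st$beta1 <- 0
  eta_x <- st$gamma0 + st$v[d$cluster] + drop(d$Zx %*% st$gamma_k)
  expect_equal(latent_x_prob(d, st, "one_test"), plogis(eta_x), tolerance = 1e-12)

  # degenerate exposure probability pi -> 1 forces the conditional to 1
  st$gamma0 <- 60; st$gamma_k <- rep(0, ncol(d$Zx)); st$v <- rep(0, d$N)
  expect_equal(latent_x_prob(d, st, "one_test"), rep(1, d$n), tolerance = 1e-9)
})

test_that("zero proposal scales freeze every Metropolis block", {
  d <- tiny_data(n_per_cluster = 10, N = 2, seed = 23)
  pr <- prior_spec("two_test")
  st <- init_state(d, pr, "two_test")
  set.seed(1)
  out <- gibbs_step(d, st, pr, "two_test", scales = 1e-12)
  for (nm in c("beta0", "beta1", "beta_k", "u", "gamma0", "gamma_k", "v"))
    expect_equal(out[[nm]], st[[nm]], tolerance = 1e-10)
  # sigma/nu move multiplicatively by at most exp(eps), eps ~ N(0, 1e-12)
  expect_equal(out$sigma, st$sigma, tolerance = 1e-9)
})

test_that("sensitivity update is the conjugate beta posterior", {
  # pin the latent exposure at 1 for everyone (pi ~ 1 via a huge frozen
  # gamma0), so S1 | x, x1 ~ beta(1 + #{x1=1}, 1 + #{x1=0}) exactly
  df <- data.frame(y = rep(0L, 10), cluster = 1L,
                   x1 = c(rep(1L, 7), rep(0L, 3)),
                   x2 = rbinom(10, 1, 0.5))
  d <- mc_data(df, x2 = "x2")
  pr <- prior_spec("two_test")
  st <- init_state(d, pr, "two_test")
  st$gamma0 <- 20   # pins pi ~ 1 while keeping log(1 - pi) representable
  st$beta1 <- 0
  set.seed(99)
  draws <- replicate(4000, gibbs_step(d, st, pr, "two_test", scales = 1e-12)$S1)
  # oracle: beta(8, 4) posterior, mean 8/12, sd ~ 0.1306
  expect_equal(mean(draws), 8 / 12, tolerance = 0.02)
  expect_equal(sd(draws), sqrt(8 * 4 / (12^2 * 13)), tolerance = 0.05)
})

test_that("chains are deterministic given the seed", {
  d <- tiny_data(n_per_cluster = 15, N = 3, seed = 24)
  pr <- prior_spec("two_test")
  cfg <- chain_config(n_iter = 200, n_burn = 100, seed = 77)
  # tiny data with flat beta(1, 1) priors legitimately trips the
  # label-switching diagnostic; silence it here
  f1 <- suppressWarnings(run_chain(d, pr, config = cfg))
  f2 <- suppressWarnings(run_chain(d, pr, config = cfg))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(
    run_chain(d, pr, config = chain_config(n_iter = 200, n_burn = 100, seed = 78)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("thinning and dimensions of the retained draws are as configured", {
  d <- tiny_data(n_per_cluster = 8, N = 2, seed = 25)
  f <- run_chain(d, prior_spec("naive"),
                 config = chain_config(n_iter = 300, n_burn = 50, thin = 3, seed = 1))
  expect_identical(nrow(f$draws), 100L)
  expect_identical(colnames(f$draws),
                   c("beta0", "beta1", "beta2", "beta3", "sigma"))
  expect_true(all(f$accept >= 0 & f$accept <= 1, na.rm = TRUE))
})

test_that("posterior summaries follow the declared quantile rule", {
  # order-statistics oracle for R's type-7 rule on draws 1..100
  draws <- cbind(par = as.numeric(1:100))
  s <- miscount:::summarize_draws(draws)
  h_lo <- 1 + 0.025 * 99; h_hi <- 1 + 0.975 * 99
  o_lo <- floor(h_lo) + (h_lo - floor(h_lo))  # values are 1..100
  o_hi <- floor(h_hi) + (h_hi - floor(h_hi))
  expect_equal(s$lower95, o_lo)
  expect_equal(s$upper95, o_hi)
  expect_equal(s$mean, 50.5)
  expect_equal(s$sd, sd(1:100))

  # constant chain: degenerate interval
  s0 <- miscount:::summarize_draws(cbind(c = rep(3.2, 50)))
  expect_equal(unlist(s0[c("mean", "sd", "lower95", "upper95")], use.names = FALSE),
               c(3.2, 0, 3.2, 3.2))

  # large pseudo-chain reproduces normal quantiles
  set.seed(42)
  sn <- miscount:::summarize_draws(cbind(z = rnorm(1e5)))
  expect_equal(sn$lower95, -1.96, tolerance = 0.03)
  expect_equal(sn$upper95, 1.96, tolerance = 0.03)

  expect_error(miscount:::summarize_draws(cbind(z = 1)),
               class = "miscount_summary_error")
})

test_that("naive intercept-only fit agrees with the Poisson MLE", {
  # sigma_true = 0, no covariates: posterior mean of exp(beta0) ~ mean(y)
  des <- sim_design(N = 5, n_per_cluster = 200,
                    gamma_true = -1.5, beta_true = c(0.85, 0.4),
                    sigma_true = 0, nu_true = 0, S1 = 0.55, C1 = 0.95,
                    S2 = NULL, C2 = NULL,
                    z_dist = function(n, q) matrix(0, n, 0))
  d <- simulate_misclass_data(des, seed = 31)
  d$x1 <- rep(0L, d$n)  # remove the exposure term entirely
  f <- run_chain(d, prior_spec("naive"),
                 config = chain_config(n_iter = 2000, n_burn = 1000, seed = 5))
  expect_equal(mean(exp(f$draws[, "beta0"])), mean(d$y), tolerance = 0.05)
})

test_that("one-test fit recovers the exposure effect on benchmark data", {
  d <- simulate_misclass_data(sim_design(), seed = 61)
  f <- run_chain(d, prior_spec("one_test", s1 = c(10, 8), c1 = c(165.7, 9.7)),
                 config = chain_config(n_iter = 2000, n_burn = 1000, seed = 6))
  s <- summary(f)
  i <- match("beta1", s$parameter)
  expect_lt(abs(s$mean[i] - 0.4), 2 * s$sd[i] + 0.05)
})

test_that("corrected fit on a near-perfect test matches the naive fit on clean data", {
  # when x1 == x_true and the S/C priors concentrate near 1, the corrected
  # model collapses to the naive one
  des <- sim_design(N = 4, n_per_cluster = 100,
                    gamma_true = c(-0.5, 0.4), beta_true = c(0.5, 0.4, 0.2),
                    sigma_true = 0.1, nu_true = 0.1,
                    S1 = 0.999, C1 = 0.999, S2 = NULL, C2 = NULL)
  d <- simulate_misclass_data(des, seed = 32)
  fn <- run_chain(d, prior_spec("naive"),
                  config = chain_config(n_iter = 1500, n_burn = 800, seed = 7))
  fc <- run_chain(d, prior_spec("one_test", s1 = c(5000, 1), c1 = c(5000, 1)),
                  config = chain_config(n_iter = 1500, n_burn = 800, seed = 8))
  b_n <- mean(fn$draws[, "beta1"]); b_c <- mean(fc$draws[, "beta1"])
  mc_err <- sd(fc$draws[, "beta1"])
  expect_lt(abs(b_n - b_c), 2 * mc_err)
})

test_that("invalid fits raise structured errors", {
  d1 <- tiny_data(n_per_cluster = 8, N = 2, seed = 26, two_tests = FALSE)
  expect_error(run_chain(d1, prior_spec("two_test")), class = "miscount_data_error")
  pr <- prior_spec("one_test", s1 = c(10, 8), c1 = c(165.7, 9.7))
  expect_error(run_chain(d1, pr, mode = "two_test"), class = "miscount_prior_error")
  st <- init_state(d1, pr, "one_test")
  st$u <- rep(800, d1$N)   # overflows the Poisson rate
  expect_error(run_chain(d1, pr, config = chain_config(10, 10), init = st),
               class = "miscount_numeric_error")
})

test_that("two chains at different seeds agree by the R-hat diagnostic", {
  d <- tiny_data(n_per_cluster = 30, N = 3, seed = 27)
  pr <- prior_spec("one_test", s1 = c(16, 4), c1 = c(18, 2))
  f1 <- run_chain(d, pr, config = chain_config(n_iter = 800, n_burn = 400, seed = 21))
  f2 <- run_chain(d, pr, config = chain_config(n_iter = 800, n_burn = 400, seed = 22))
  r <- rhat2(f1, f2)
  expect_identical(names(r), colnames(f1$draws))
  expect_true(all(r < 1.3))
  f3 <- run_chain(d, prior_spec("naive"),
                  config = chain_config(n_iter = 800, n_burn = 400, seed = 23))
  expect_error(rhat2(f1, f3), class = "miscount_summary_error")
})
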