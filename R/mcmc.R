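#' MCMC chain configuration
#'
#' @param n_iter Number of post-burn-in draws to retain (before thinning).
#' @param n_burn Number of burn-in sweeps. Proposal scales adapt toward a
#'   `target_accept` per-block acceptance rate during burn-in only and are
#'   frozen afterwards, so the post-burn-in kernel satisfies detailed balance.
#' @param seed Integer RNG seed; identical seeds give bitwise-identical chains.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param adapt Adapt proposal scales during burn-in (Robbins-Monro on the log
#'   scale).
#' @param target_accept Target per-block acceptance rate for adaptation.
#' @param init_scale Initial random-walk proposal SD for every block.
#' @param monitor_ranef Also store the cluster random intercepts `u` (and `v`)?
#'   Off by default to limit output size.
#' @return An object of class `mc_chain_config`.
#' @export
chain_config <- function(n_iter = 3000, n_burn = 1500, seed = 1, thin = 1,
                         adapt = TRUE, target_accept = 0.44, init_scale = 0.1,
                         monitor_ranef = FALSE) {
  for (nm in c("n_iter", "n_burn", "thin")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v))
      mc_stop(sprintf("`%s` must be a positive integer", nm), "miscount_config_error")
  }
  if (init_scale <= 0) mc_stop("`init_scale` must be positive", "miscount_config_error")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 seed = as.integer(seed), thin = as.integer(thin),
                 adapt = isTRUE(adapt), target_accept = target_accept,
                 init_scale = init_scale, monitor_ranef = isTRUE(monitor_ranef)),
            class = "mc_chain_config")
}

monitored_names <- function(data, mode, monitor_ranef = FALSE) {
  py <- ncol(data$Zy); qx <- ncol(data$Zx)
  nm <- c("beta0", "beta1", if (py) paste0("beta", seq_len(py) + 1L))
  if (mode != "naive") {
    nm <- c(nm, "gamma0", if (qx) paste0("gamma", seq_len(qx)), "S1", "C1",
            if (mode == "two_test") c("S2", "C2"))
  }
  nm <- c(nm, "sigma", if (mode != "naive") "nu")
  if (monitor_ranef) {
    nm <- c(nm, paste0("u", seq_len(data$N)),
            if (mode != "naive") paste0("v", seq_len(data$N)))
  }
  nm
}

block_names <- function(data, mode) {
  py <- ncol(data$Zy); qx <- ncol(data$Zx)
  c("beta0", "beta1", if (py) paste0("beta", seq_len(py) + 1L),
    if (mode != "naive") c("gamma0", if (qx) paste0("gamma", seq_len(qx))),
    "u", "v", "log_sigma", "log_nu")
}

check_fit_inputs <- function(data, priors, mode) {
  if (!inherits(data, "mc_data")) mc_stop("`data` must be an mc_data object", "miscount_data_error")
  if (!inherits(priors, "mc_priors")) mc_stop("`priors` must be an mc_priors object", "miscount_prior_error")
  check_mode(mode)
  if (priors$mode != mode)
    mc_stop(sprintf("priors were built for mode '%s' but the fit requests '%s'",
                    priors$mode, mode), "miscount_prior_error")
  if (mode == "two_test" && is.null(data$x2))
    mc_stop("two_test mode requires an `x2` assessment column", "miscount_data_error")
  invisible(TRUE)
}

call_sampler <- function(data, state, priors, mode, config, n_burn, n_iter,
                         adapt, scales) {
  mode_i <- match(mode, mc_modes) - 1L
  init <- unclass(state)
  .run_mcmc_cpp(
    as.numeric(data$y), as.numeric(data$r), data$cluster - 1L,
    data$Zy, data$Zx,
    data$x1, if (is.null(data$x2)) integer() else data$x2,
    mode_i, init, unclass(priors),
    list(n_burn = as.integer(n_burn), n_iter = as.integer(n_iter),
         thin = as.integer(config$thin), adapt = adapt,
         target_accept = config$target_accept,
         monitor_ranef = config$monitor_ranef,
         scales = as.numeric(scales)))
}

#' One full Gibbs sweep
#'
#' Performs a single sweep of the Metropolis-within-Gibbs sampler: exact
#' Bernoulli draws of every latent exposure indicator, scalar random-walk
#' Metropolis updates of each regression coefficient, per-cluster random-walk
#' updates of the random intercepts, log-scale random-walk updates of the
#' random-intercept SDs, and conjugate beta draws of each
#' sensitivity/specificity from the augmented-data likelihood. Draws consume
#' R's RNG stream, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param data An `mc_data`.
#' @param state An `mc_state` satisfying the mode's requirements.
#' @param priors An `mc_priors`.
#' @param mode Model mode; defaults to the priors' mode.
#' @param config An `mc_chain_config`; only the proposal-scale settings are
#'   used (no adaptation is performed in a single sweep).
#' @param scales Optional numeric vector of per-block proposal SDs (recycled
#'   if length 1), overriding `config$init_scale`.
#' @return The updated `mc_state`.
#' @export
gibbs_step <- function(data, state, priors, mode = priors$mode,
                       config = chain_config(), scales = NULL) {
  check_fit_inputs(data, priors, mode)
  check_state_dims(data, state, mode)
  lp <- joint_log_posterior(data, state, priors, mode)
  if (!is.finite(lp))
    mc_stop("joint log posterior is not finite at the supplied state",
            "miscount_numeric_error")
  if (is.null(scales)) scales <- config$init_scale
  res <- call_sampler(data, state, priors, mode, config,
                      n_burn = 0L, n_iter = 1L, adapt = FALSE, scales = scales)
  fin <- res$final
  do.call(param_state, fin[intersect(names(fin), names(formals(param_state)))])
}

#' Fit the model by MCMC
#'
#' Runs the data-augmentation Metropolis-within-Gibbs sampler. `run_chain()`
#' and `fit_misclass()` are the same function; the latter name reads better at
#' the top level.
#'
#' In `one_test` and `two_test` modes a warning is emitted when a
#' non-negligible fraction of retained draws has `S1 + C1 < 1`: posterior mass
#' on that side of the `S + C = 1` line indicates label switching between
#' (S, C) and (1-C, 1-S), i.e. the priors were not informative enough to pin
#' down the labelling of the latent exposure.
#'
#' @param data An `mc_data`.
#' @param priors An `mc_priors` (its mode determines the default `mode`).
#' @param mode `"naive"`, `"one_test"`, or `"two_test"`.
#' @param config An `mc_chain_config`.
#' @param init Optional initial `mc_state`; defaults to [init_state()].
#' @return An object of class `mc_fit`: list with `draws` (matrix, one row per
#'   retained draw, one column per monitored quantity), `accept` (named
#'   per-block post-burn-in acceptance rates), `x_prob` (per-subject posterior
#'   probability of true exposure; corrected modes only), `mode`, `config`,
#'   `priors`, and the final `state`.
#' @examples
#' d <- simulate_misclass_data(sim_design(N = 5, n_per_cluster = 40), seed = 1)
#' f <- run_chain(d, prior_spec("naive"), config = chain_config(500, 250, seed = 1))
#' summary(f)
#' @export
run_chain <- function(data, priors, mode = priors$mode, config = chain_config(),
                      init = NULL) {
  check_fit_inputs(data, priors, mode)
  if (is.null(init)) init <- init_state(data, priors, mode)
  check_state_dims(data, init, mode)
  lp <- joint_log_posterior(data, init, priors, mode)
  if (!is.finite(lp))
    mc_stop("joint log posterior is not finite at the initial state",
            "miscount_numeric_error")
  set.seed(config$seed)
  res <- call_sampler(data, init, priors, mode, config,
                      n_burn = config$n_burn, n_iter = config$n_iter,
                      adapt = config$adapt, scales = config$init_scale)
  draws <- res$draws
  colnames(draws) <- monitored_names(data, mode, config$monitor_ranef)
  accept <- as.numeric(res$accept)
  names(accept) <- block_names(data, mode)
  if (mode == "naive") accept <- accept[!names(accept) %in% c("v", "log_nu")]
  if (mode != "naive") {
    flipped <- mean(draws[, "S1"] + draws[, "C1"] < 1)
    if (flipped > 0.01)
      warning(sprintf(paste("%.1f%% of retained draws have S1 + C1 < 1:",
                            "possible label switching; consider more informative",
                            "sensitivity/specificity priors"), 100 * flipped))
  }
  structure(list(draws = draws, accept = accept,
                 x_prob = if (mode == "naive") NULL else as.numeric(res$x_prob),
                 scales = as.numeric(res$scales),
                 mode = mode, config = config, priors = priors,
                 state = do.call(param_state,
                                 res$final[intersect(names(res$final),
                                                     names(formals(param_state)))]),
                 n = data$n, N = data$N),
            class = "mc_fit")
}

#' @rdname run_chain
#' @export
fit_misclass <- run_chain

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<mc_fit> mode=%s: %d retained draws (burn-in %d, thin %d) on %d subjects / %d clusters\n",
              x$mode, nrow(x$draws), x$config$n_burn, x$config$thin, x$n, x$N))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Posterior summaries
#'
#' Posterior mean, sample SD, and equal-tailed 95% credible interval (2.5% and
#' 97.5% empirical quantiles, R's default type-7 rule) for every monitored
#' quantity.
#'
#' @param object An `mc_fit`.
#' @param ... Unused.
#' @return A data frame of class `mc_summary` with columns `parameter`,
#'   `mean`, `sd`, `lower95`, `upper95`.
#' @export
summary.mc_fit <- function(object, ...) {
  summarize_draws(object$draws)
}

summarize_draws <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L,
                                           dimnames = list(NULL, "draw"))
  if (nrow(draws) < 2L)
    mc_stop("need at least 2 retained draws to summarize", "miscount_summary_error")
  q <- apply(draws, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    sd = apply(draws, 2L, sd),
                    lower95 = q[1L, ], upper95 = q[2L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mc_summary", "data.frame")
  out
}

#' @export
print.mc_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Basic two-chain convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction factor computed from two fits of the
#' same model (typically the same data and settings at two seeds). Values near
#' 1 indicate the chains agree; values above ~1.1 suggest running longer. This
#' is a quick sanity check, not a full multi-chain orchestration.
#'
#' @param fit1,fit2 Two `mc_fit` objects with identical monitored quantities
#'   and equal numbers of retained draws.
#' @return Named numeric vector of split-free R-hat values per monitored
#'   quantity.
#' @export
rhat2 <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "mc_fit"), inherits(fit2, "mc_fit"))
  if (!identical(colnames(fit1$draws), colnames(fit2$draws)) ||
      nrow(fit1$draws) != nrow(fit2$draws))
    mc_stop("the two fits must monitor the same quantities over the same number of draws",
            "miscount_summary_error")
  n <- nrow(fit1$draws)
  vapply(colnames(fit1$draws), function(p) {
    ch <- cbind(fit1$draws[, p], fit2$draws[, p])
    W <- mean(apply(ch, 2L, stats::var))
    B <- n * stats::var(colMeans(ch))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Write posterior draws and summaries to CSV
#'
#' @param fit An `mc_fit`.
#' @param draws_path,summary_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, draws_path = NULL, summary_path = NULL) {
  stopifnot(inherits(fit, "mc_fit"))
  if (!is.null(draws_path))
    write.csv(as.data.frame(fit$draws), draws_path, row.names = FALSE)
  if (!is.null(summary_path))
    write.csv(as.data.frame(summary(fit)), summary_path, row.names = FALSE)
  invisible(c(draws = draws_path, summary = summary_path))
}
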