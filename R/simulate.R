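#' Simulation design
#'
#' Describes one generative configuration for the synthetic-data simulator:
#' a two-level Poisson outcome driven by a binary exposure that is itself
#' generated from a hierarchical logistic model, observed only through one or
#' two fallible assessments. The defaults are the benchmark configuration used
#' throughout the package's simulation experiments: 25 clusters of 200
#' subjects; exposure model
#' `logit pi = -1.5 + v_j - 0.21 z1 - 0.16 z2 + 0.19 z3 - 0.29 z4`;
#' outcome model
#' `log lambda = 0.85 + u_j + 0.4 x + 0.25 z1 - 0.2 z2 - 0.18 z3 - 0.05 z4`;
#' both random-intercept SDs 0.1; test 1 with sensitivity 0.55 and specificity
#' 0.95, test 2 with sensitivity 0.7 and specificity 0.8. The same four
#' error-free covariates enter both models and are drawn independent standard
#' normal by default (`z_dist`); the offset is identically 1.
#'
#' @param N Number of clusters.
#' @param n_per_cluster Subjects per cluster.
#' @param gamma_true Exposure-model coefficients `(intercept, slopes...)`.
#' @param beta_true Outcome-model coefficients
#'   `(intercept, exposure effect, slopes...)`; the slope count must equal
#'   `length(gamma_true) - 1` since the two models share covariates.
#' @param sigma_true,nu_true Random-intercept SDs (outcome, exposure); may be 0.
#' @param S1,C1 Sensitivity/specificity of the first assessment.
#' @param S2,C2 Second assessment; set both `NULL` to simulate one test only.
#' @param z_dist Function `(n, q)` returning an `n x q` covariate matrix.
#' @return An object of class `mc_sim_design`.
#' @export
sim_design <- function(N = 25, n_per_cluster = 200,
                       gamma_true = c(-1.5, -0.21, -0.16, 0.19, -0.29),
                       beta_true = c(0.85, 0.4, 0.25, -0.2, -0.18, -0.05),
                       sigma_true = 0.1, nu_true = 0.1,
                       S1 = 0.55, C1 = 0.95, S2 = 0.7, C2 = 0.8,
                       z_dist = function(n, q) matrix(rnorm(n * q), n, q)) {
  if (N < 1 || n_per_cluster < 1)
    mc_stop("`N` and `n_per_cluster` must be at least 1", "miscount_design_error")
  if (length(beta_true) != length(gamma_true) + 1L)
    mc_stop(sprintf("`beta_true` must have one more element than `gamma_true` (got %d and %d)",
                    length(beta_true), length(gamma_true)), "miscount_design_error")
  if (sigma_true < 0 || nu_true < 0)
    mc_stop("random-effect SDs must be nonnegative", "miscount_design_error")
  two <- !is.null(S2) || !is.null(C2)
  for (nm in c("S1", "C1", if (two) c("S2", "C2"))) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      mc_stop(sprintf("`%s` must lie in (0, 1]", nm), "miscount_design_error")
  }
  structure(list(N = as.integer(N), n_per_cluster = as.integer(n_per_cluster),
                 gamma_true = gamma_true, beta_true = beta_true,
                 sigma_true = sigma_true, nu_true = nu_true,
                 S1 = S1, C1 = C1, S2 = if (two) S2 else NULL,
                 C2 = if (two) C2 else NULL, z_dist = z_dist),
            class = "mc_sim_design")
}

#' Named truth vector for a design
#'
#' Maps a design onto the monitored-parameter names of each mode, for bias and
#' coverage bookkeeping in simulation studies.
#'
#' @param design An `mc_sim_design`.
#' @param mode Model mode.
#' @return Named numeric vector of generating values.
#' @export
design_truth <- function(design, mode = "two_test") {
  check_mode(mode)
  q <- length(design$gamma_true) - 1L
  tr <- c(beta0 = design$beta_true[1], beta1 = design$beta_true[2])
  if (q) tr <- c(tr, stats::setNames(design$beta_true[-(1:2)], paste0("beta", seq_len(q) + 1L)))
  if (mode != "naive") {
    tr <- c(tr, gamma0 = design$gamma_true[1])
    if (q) tr <- c(tr, stats::setNames(design$gamma_true[-1], paste0("gamma", seq_len(q))))
    tr <- c(tr, S1 = design$S1, C1 = design$C1)
    if (mode == "two_test") tr <- c(tr, S2 = design$S2, C2 = design$C2)
  }
  tr <- c(tr, sigma = design$sigma_true)
  if (mode != "naive") tr <- c(tr, nu = design$nu_true)
  tr
}

#' Simulate a dataset
#'
#' Draws cluster random intercepts, covariates, true exposure, Poisson counts,
#' and one or two fallible assessments from the generative model described by
#' `design`. The assessments are conditionally independent given the true
#' exposure: `P(x1 = 1 | x = 1) = S1`, `P(x1 = 0 | x = 0) = C1`, and likewise
#' for test 2. The true exposure is kept in the `x_true` column for
#' evaluation; it is never visible to the fitting functions.
#'
#' @param design An `mc_sim_design`.
#' @param seed Integer seed; identical `(design, seed)` give identical data.
#' @return An `mc_data` object with `x_true`.
#' @examples
#' d <- simulate_misclass_data(sim_design(N = 3, n_per_cluster = 10), seed = 7)
#' table(d$x_true, d$x1)
#' @export
simulate_misclass_data <- function(design, seed = 1L) {
  stopifnot(inherits(design, "mc_sim_design"))
  set.seed(seed)
  N <- design$N; ni <- design$n_per_cluster
  n <- N * ni
  q <- length(design$gamma_true) - 1L
  cl <- rep(seq_len(N), each = ni)
  v <- rnorm(N, 0, design$nu_true)
  u <- rnorm(N, 0, design$sigma_true)
  z <- design$z_dist(n, q)
  if (!is.matrix(z) || nrow(z) != n || ncol(z) != q)
    mc_stop(sprintf("`z_dist` must return a %d x %d matrix", n, q),
            "miscount_design_error")
  if (q) colnames(z) <- paste0("z", seq_len(q))
  eta_x <- design$gamma_true[1] + v[cl] + drop(z %*% design$gamma_true[-1])
  x_true <- rbinom(n, 1L, plogis(eta_x))
  eta_y <- design$beta_true[1] + u[cl] + design$beta_true[2] * x_true +
    drop(z %*% design$beta_true[-(1:2)])
  y <- rpois(n, exp(eta_y))
  x1 <- rbinom(n, 1L, ifelse(x_true == 1, design$S1, 1 - design$C1))
  df <- data.frame(y = y, r = 1, cluster = cl, x1 = x1)
  if (q) df <- cbind(df[c("y", "r", "cluster")], as.data.frame(z), x1 = x1)
  if (!is.null(design$S2)) {
    df$x2 <- rbinom(n, 1L, ifelse(x_true == 1, design$S2, 1 - design$C2))
  }
  df$x_true <- x_true
  zn <- colnames(z)
  mc_data(df, y = "y", r = "r", cluster = "cluster",
          z_outcome = zn, z_exposure = zn,
          x1 = "x1", x2 = if (!is.null(design$S2)) "x2" else NULL,
          x_true = "x_true")
}
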