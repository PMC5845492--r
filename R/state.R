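#' One full configuration of the model unknowns
#'
#' Collects every unknown of the joint model into a single object: outcome
#' coefficients (`beta0` grand intercept, `beta1` exposure effect, `beta_k`
#' other covariates), outcome random intercepts `u` with SD `sigma`, exposure
#' coefficients (`gamma0`, `gamma_k`), exposure random intercepts `v` with SD
#' `nu`, measurement operating characteristics `S1`/`C1` (and `S2`/`C2` with a
#' second test), and the current imputation `x_latent` of the true exposure.
#' Components that a given mode does not use may be left `NULL`.
#'
#' @param beta0,beta1 Outcome grand intercept and exposure effect.
#' @param beta_k Numeric vector of outcome coefficients for the error-free
#'   covariates (one per column of `Zy`).
#' @param u Numeric vector of outcome random intercepts, one per cluster.
#' @param sigma Positive SD of `u`.
#' @param gamma0 Exposure grand intercept.
#' @param gamma_k Exposure coefficients (one per column of `Zx`).
#' @param v Exposure random intercepts, one per cluster.
#' @param nu Positive SD of `v`.
#' @param S1,C1,S2,C2 Sensitivities/specificities in `(0, 1)`.
#' @param x_latent Integer 0/1 vector, current imputed true exposure.
#' @return An object of class `mc_state`.
#' @export
param_state <- function(beta0 = 0, beta1 = 0, beta_k = numeric(),
                        u = numeric(), sigma = 0.1,
                        gamma0 = NULL, gamma_k = NULL, v = NULL, nu = NULL,
                        S1 = NULL, C1 = NULL, S2 = NULL, C2 = NULL,
                        x_latent = NULL) {
  st <- list(beta0 = beta0, beta1 = beta1, beta_k = as.numeric(beta_k),
             u = as.numeric(u), sigma = sigma,
             gamma0 = gamma0, gamma_k = if (is.null(gamma_k)) NULL else as.numeric(gamma_k),
             v = if (is.null(v)) NULL else as.numeric(v), nu = nu,
             S1 = S1, C1 = C1, S2 = S2, C2 = C2,
             x_latent = if (is.null(x_latent)) NULL else as.integer(x_latent))
  if (!is.finite(st$sigma) || st$sigma <= 0)
    mc_stop("`sigma` must be positive", "miscount_state_error")
  if (!is.null(st$nu) && (!is.finite(st$nu) || st$nu <= 0))
    mc_stop("`nu` must be positive", "miscount_state_error")
  for (nm in c("S1", "C1", "S2", "C2")) {
    v0 <- st[[nm]]
    if (!is.null(v0) && (!is.finite(v0) || v0 <= 0 || v0 >= 1))
      mc_stop(sprintf("`%s` must lie in the open interval (0, 1)", nm),
              "miscount_state_error")
  }
  if (!is.null(st$x_latent) && !all(st$x_latent %in% c(0L, 1L)))
    mc_stop("`x_latent` must be binary 0/1", "miscount_state_error")
  class(st) <- "mc_state"
  st
}

#' Default initial state for a fit
#'
#' Coefficients start at 0, both random-intercept SDs at 0.1, sensitivities and
#' specificities at their prior means, and the latent exposure at the first
#' assessment `x1`.
#'
#' @param data An `mc_data` object.
#' @param priors An `mc_priors` object.
#' @param mode Model mode.
#' @return An `mc_state`.
#' @export
init_state <- function(data, priors, mode = priors$mode) {
  check_mode(mode)
  pm <- function(s) s[1] / (s[1] + s[2])
  corrected <- mode != "naive"
  param_state(
    beta0 = 0, beta1 = 0, beta_k = rep(0, ncol(data$Zy)),
    u = rep(0, data$N), sigma = 0.1,
    gamma0 = if (corrected) 0 else NULL,
    gamma_k = if (corrected) rep(0, ncol(data$Zx)) else NULL,
    v = if (corrected) rep(0, data$N) else NULL,
    nu = if (corrected) 0.1 else NULL,
    S1 = if (corrected) pm(priors$s1) else NULL,
    C1 = if (corrected) pm(priors$c1) else NULL,
    S2 = if (mode == "two_test") pm(priors$s2) else NULL,
    C2 = if (mode == "two_test") pm(priors$c2) else NULL,
    x_latent = if (corrected) data$x1 else NULL
  )
}

# dimension checks shared by the log-density functions
check_state_dims <- function(data, state, mode, outcome = TRUE,
                             exposure = mode != "naive") {
  if (outcome) {
    if (length(state$beta_k) != ncol(data$Zy))
      mc_stop(sprintf("outcome coefficient vector has length %d but z matrix has %d column(s)",
                      length(state$beta_k), ncol(data$Zy)), "miscount_dim_error")
    if (length(state$u) != data$N)
      mc_stop(sprintf("`u` has length %d but data have %d clusters",
                      length(state$u), data$N), "miscount_dim_error")
  }
  if (exposure) {
    if (length(state$gamma_k) != ncol(data$Zx))
      mc_stop(sprintf("exposure coefficient vector has length %d but z matrix has %d column(s)",
                      length(state$gamma_k), ncol(data$Zx)), "miscount_dim_error")
    if (length(state$v) != data$N)
      mc_stop(sprintf("`v` has length %d but data have %d clusters",
                      length(state$v), data$N), "miscount_dim_error")
  }
  invisible(TRUE)
}
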