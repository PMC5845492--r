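#' Prior specification
#'
#' Bundles the hyperparameters of every prior in the joint model. Normal priors
#' on regression coefficients are parameterized by their VARIANCE (the shipped
#' defaults are variance 10 for the logistic exposure-model coefficients and
#' variance 100 for the Poisson outcome-model coefficients) -- note that BUGS
#' dialects parameterize the normal by precision, so `normal(0, 10)` there is
#' not the same prior as here. The random-intercept standard deviations `sigma`
#' (outcome) and `nu` (exposure) get uniform priors on `(0, sd_upper)`.
#' Sensitivities and specificities get beta priors.
#'
#' With a single fallible assessment the measurement model is not identifiable
#' from the data alone, so `one_test` mode refuses to default the beta shapes:
#' `s1` and `c1` must be supplied explicitly, and flat `c(1, 1)` shapes trigger
#' a warning. With two conditionally independent assessments the model is
#' identifiable and flat `beta(1, 1)` priors are the default.
#'
#' @param mode One of `"naive"`, `"one_test"`, `"two_test"`.
#' @param gamma_var Prior variance for every exposure-model coefficient.
#' @param beta_var Prior variance for every outcome-model coefficient.
#' @param sd_upper Upper bound of the uniform prior on both random-intercept
#'   standard deviations.
#' @param s1,c1 Length-2 positive shape vectors of the beta priors on the first
#'   test's sensitivity and specificity. Required in `one_test` mode.
#' @param s2,c2 Beta shapes for the second test (`two_test` mode only).
#' @return An object of class `mc_priors`.
#' @examples
#' prior_spec("two_test")
#' prior_spec("one_test", s1 = c(10, 8), c1 = c(165.7, 9.7))
#' @export
prior_spec <- function(mode = "two_test", gamma_var = 10, beta_var = 100,
                       sd_upper = 3, s1 = NULL, c1 = NULL, s2 = NULL, c2 = NULL) {
  check_mode(mode)
  for (nm in c("gamma_var", "beta_var", "sd_upper")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      mc_stop(sprintf("`%s` must be a single positive number", nm), "miscount_prior_error")
  }
  chk_shape <- function(s, nm) {
    if (!is.numeric(s) || length(s) != 2L || any(!is.finite(s)) || any(s <= 0))
      mc_stop(sprintf("`%s` must be two positive beta shape parameters", nm),
              "miscount_prior_error")
    as.numeric(s)
  }
  if (mode == "naive") {
    s1 <- c1 <- s2 <- c2 <- NULL
  } else if (mode == "one_test") {
    if (is.null(s1) || is.null(c1))
      mc_stop(paste("one_test mode requires explicit informative beta shapes for",
                    "`s1` and `c1`: with a single assessment the sensitivity and",
                    "specificity are not identifiable from the data"),
              "miscount_prior_error")
    s1 <- chk_shape(s1, "s1"); c1 <- chk_shape(c1, "c1")
    if (all(s1 == 1) && all(c1 == 1))
      warning("flat beta(1, 1) priors on S1 and C1: the one-test model is not identifiable")
    s2 <- c2 <- NULL
  } else {
    s1 <- chk_shape(if (is.null(s1)) c(1, 1) else s1, "s1")
    c1 <- chk_shape(if (is.null(c1)) c(1, 1) else c1, "c1")
    s2 <- chk_shape(if (is.null(s2)) c(1, 1) else s2, "s2")
    c2 <- chk_shape(if (is.null(c2)) c(1, 1) else c2, "c2")
  }
  structure(list(mode = mode, gamma_var = gamma_var, beta_var = beta_var,
                 sd_upper = sd_upper, s1 = s1, c1 = c1, s2 = s2, c2 = c2),
            class = "mc_priors")
}

#' @export
print.mc_priors <- function(x, ...) {
  cat(sprintf("<mc_priors> mode=%s\n", x$mode))
  cat(sprintf("  coefficients: gamma ~ N(0, var %.3g), beta ~ N(0, var %.3g)\n",
              x$gamma_var, x$beta_var))
  cat(sprintf("  random-effect SDs: uniform(0, %.3g)\n", x$sd_upper))
  sh <- function(s) sprintf("beta(%.6g, %.6g)", s[1], s[2])
  if (!is.null(x$s1)) cat(sprintf("  S1 ~ %s, C1 ~ %s\n", sh(x$s1), sh(x$c1)))
  if (!is.null(x$s2)) cat(sprintf("  S2 ~ %s, C2 ~ %s\n", sh(x$s2), sh(x$c2)))
  invisible(x)
}
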