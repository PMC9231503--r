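#' Asymptotic growth-curve parameters
#'
#' Three-parameter asymptotic regression for body weight as a function of
#' age: `w(age) = c + (d - c) * (1 - exp(-age / e))`, where `c` is the
#' lower limit of the curve (weight at age zero), `d` its asymptote (adult
#' weight) and `e` the rate scale in days (age over which roughly 63% of
#' the gap to the asymptote is closed).
#'
#' @param lower_limit `c`, grams; must satisfy `0 < c < d`.
#' @param asymptote `d`, grams.
#' @param rate_scale `e`, days; must be positive.
#' @return an object of class `growth_params`.
#' @examples
#' gp <- growth_params(300, 1400, 200)
#' growth_weight(200, gp) # 300 + 1100 * (1 - exp(-1))
#' @export
growth_params <- function(lower_limit, asymptote, rate_scale) {
  lower_limit <- assert_number(lower_limit, "lower_limit", lower = 0, open_lower = TRUE)
  asymptote <- assert_number(asymptote, "asymptote", lower = lower_limit, open_lower = TRUE)
  rate_scale <- assert_number(rate_scale, "rate_scale", lower = 0, open_lower = TRUE)
  structure(list(lower_limit = lower_limit, asymptote = asymptote,
                 rate_scale = rate_scale),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("asymptotic growth curve: c = %.1f g, d = %.1f g, e = %.1f d\n",
              x$lower_limit, x$asymptote, x$rate_scale))
  invisible(x)
}

#' Expected weight at a given age
#'
#' Evaluates the asymptotic growth curve. Strictly increasing in age and
#' bounded above by the asymptote.
#'
#' @param age_days age in days; vectorized, must be non-negative.
#' @param params a [growth_params()] object.
#' @return expected weight in grams.
#' @export
growth_weight <- function(age_days, params) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.numeric(age_days) || anyNA(age_days) || any(age_days < 0))
    stop("age_days must be non-negative", call. = FALSE)
  params$lower_limit + (params$asymptote - params$lower_limit) *
    (1 - exp(-age_days / params$rate_scale))
}

# fit the curve by nonlinear least squares (self-started); returns
# estimates on the (c, d, e) scale with standard errors, or a
# non-convergence flag
fit_growth_curve <- function(age_days, weight_g) {
  df <- data.frame(age = as.numeric(age_days), w = as.numeric(weight_g))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 5)
    return(list(converged = FALSE, reason = "fewer than 5 points"))
  fit <- tryCatch(
    suppressWarnings(
      nls(w ~ SSasymp(age, Asym, R0, lrc), data = df,
          # scaleOffset makes the convergence test well-defined on
          # zero-residual (noise-free) data
          control = stats::nls.control(maxiter = 200, warnOnly = FALSE,
                                       scaleOffset = 1))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(converged = FALSE, reason = "nls failed"))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  names(se) <- names(cf)
  # SSasymp: w = Asym + (R0 - Asym) exp(-exp(lrc) * age) so e = exp(-lrc)
  e_hat <- exp(-cf[["lrc"]])
  list(converged = TRUE,
       lower_limit = unname(cf[["R0"]]), asymptote = unname(cf[["Asym"]]),
       rate_scale = unname(e_hat),
       se_lower_limit = unname(se[["R0"]]), se_asymptote = unname(se[["Asym"]]),
       # delta method on e = exp(-lrc)
       se_rate_scale = unname(e_hat * se[["lrc"]]),
       fit = fit)
}
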