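# User-facing mixed-model interface over the compiled Laplace engine.

#' Specify a mixed model
#'
#' @param response name of the response column (binomial: 0/1 outcomes or
#'   a successes column used together with `size`).
#' @param terms character vector of fixed-effect predictor columns
#'   (intercept always included).
#' @param random character vector of grouping-factor columns, each giving
#'   one random intercept.
#' @param family `"binomial"` (logit), `"gaussian"` or `"poisson"` (log).
#' @param olre add an observation-level random intercept (overdispersion
#'   absorption for counts).
#' @param size optional column of binomial trial sizes (defaults to 1).
#' @return a `model_spec` object.
#' @export
model_spec <- function(response, terms = character(),
                       random = character(),
                       family = c("binomial", "gaussian", "poisson"),
                       olre = FALSE, size = NULL) {
  family <- match.arg(family)
  terms <- unique(as.character(terms))
  random <- as.character(random)
  if (anyDuplicated(random))
    stop("duplicated random terms", call. = FALSE)
  structure(list(response = response, terms = terms, random = random,
                 family = family, olre = isTRUE(olre), size = size),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- paste(c("1", x$terms,
                 sprintf("(1 | %s)", c(x$random, if (x$olre) "<obs>"))),
               collapse = " + ")
  cat(sprintf("%s model: %s ~ %s\n", x$family, x$response, rhs))
  invisible(x)
}

#' Scale predictor columns to zero mean and unit variance
#'
#' Centers and scales each column by its sample mean and SD, recording the
#' constants so estimates can be back-transformed.
#'
#' @param data data frame or matrix.
#' @param cols columns to scale (default: all numeric columns).
#' @return list of class `predictor_scaling`: `data` (scaled), `center`,
#'   `scale`.
#' @export
scale_predictors <- function(data, cols = NULL) {
  df <- as.data.frame(data)
  cols <- cols %||% names(df)[vapply(df, is.numeric, TRUE)]
  ctr <- scl <- setNames(numeric(length(cols)), cols)
  for (cc in cols) {
    s <- sd(df[[cc]])
    if (!is.finite(s) || s == 0)
      stop(sprintf("cannot scale constant predictor '%s'", cc), call. = FALSE)
    ctr[cc] <- mean(df[[cc]]); scl[cc] <- s
    df[[cc]] <- (df[[cc]] - ctr[cc]) / s
  }
  structure(list(data = df, center = ctr, scale = scl),
            class = "predictor_scaling")
}

#' Invert a predictor scaling
#'
#' @param scaling a `predictor_scaling` object.
#' @param data scaled data frame (defaults to `scaling$data`).
#' @return data frame on the original predictor scale.
#' @export
unscale_predictors <- function(scaling, data = scaling$data) {
  df <- as.data.frame(data)
  for (cc in names(scaling$center))
    df[[cc]] <- df[[cc]] * scaling$scale[cc] + scaling$center[cc]
  df
}

.family_code <- function(family)
  match(family, c("binomial", "poisson", "gaussian")) - 1L

#' Fit a mixed model by Laplace-approximate maximum likelihood
#'
#' Maximizes the Laplace-approximate marginal likelihood jointly over the
#' fixed effects and the log random-effect standard deviations
#' (quasi-Newton with analytic gradients; inner Newton for the
#' random-effect modes). ML throughout (no REML), so log-likelihoods are
#' comparable across fixed-effect structures for information criteria and
#' likelihood-ratio tests.
#'
#' @param spec a [model_spec()].
#' @param data data frame with the response, predictor and grouping
#'   columns.
#' @param start optional warm start: a previous fit's `psi` vector.
#' @param start_u optional warm start for the random-effect modes.
#' @param fix_sigma_zero fit with all random-effect SDs pinned at zero
#'   (the plain-GLM limit).
#' @return an object of class `rhp_glmm`: coefficients `beta` with `se`
#'   and `vcov`, random-effect SDs `sigma`, Laplace `loglik`, parameter
#'   count `k` (fixed effects + variance components, + residual for
#'   gaussian), `n`, `converged` and `flags`.
#' @export
fit_glmm <- function(spec, data, start = NULL, start_u = NULL,
                     fix_sigma_zero = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  n <- nrow(data)
  y <- as.numeric(data[[spec$response]])
  m <- if (!is.null(spec$size)) as.numeric(data[[spec$size]]) else rep(1, n)
  if (spec$family == "binomial" && (any(y < 0) || any(y > m)))
    stop("binomial response must lie in [0, size]", call. = FALSE)
  if (spec$family == "poisson" && any(y < 0))
    stop("poisson response must be non-negative", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, spec$terms, drop = FALSE]))
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  fac <- lapply(spec$random, function(r) factor(data[[r]]))
  names(fac) <- spec$random
  if (spec$olre) fac <- c(fac, list(`(obs)` = factor(seq_len(n))))
  q <- vapply(fac, nlevels, 1L)
  fidx <- if (length(fac))
    do.call(cbind, lapply(fac, function(f) as.integer(f) - 1L))
  else matrix(0L, n, 0)
  p <- ncol(X)
  nf <- length(fac)
  d <- p + nf + (spec$family == "gaussian")
  psi0 <- if (!is.null(start) && length(start) == d) start else {
    b0 <- rep(0, p)
    b0[1] <- switch(spec$family,
                    binomial = qlogis(min(max(mean(y / m), 0.02), 0.98)),
                    poisson = log(max(mean(y), 0.1)),
                    gaussian = mean(y))
    c(b0, rep(log(0.5), nf),
      if (spec$family == "gaussian") log(max(sd(y), 1e-3)))
  }
  fixed <- rep(0L, d)
  if (fix_sigma_zero && nf) {
    psi0[p + seq_len(nf)] <- -10
    fixed[p + seq_len(nf)] <- 1L
  }
  res <- glmm_laplace_cpp(X, y, m, fidx, q, .family_code(spec$family),
                          psi0, start_u %||% numeric(0), fixed,
                          matrix(0, 0, 0), FALSE)
  beta <- setNames(drop(res$beta), colnames(X))
  flags <- character(0)
  if (!res$converged) flags <- c(flags, "non-convergence")
  if (spec$family == "binomial" && any(abs(beta) > 15))
    flags <- c(flags, "separation")
  k <- p + nf + (spec$family == "gaussian")
  u <- res$u
  usplit <- if (nf) split(u, rep(seq_len(nf), q)) else list()
  names(usplit) <- names(fac)
  for (f in names(fac)) names(usplit[[f]]) <- levels(fac[[f]])
  structure(list(
    spec = spec, beta = beta, se = setNames(drop(res$se), colnames(X)),
    vcov = structure(res$vcov, dimnames = list(colnames(X), colnames(X))),
    sigma = setNames(drop(res$sigma), names(fac)),
    sigma_resid = if (spec$family == "gaussian") res$sigma_resid else NULL,
    loglik = res$loglik, k = k, n = n,
    converged = res$converged, flags = flags,
    grad_norm = res$grad_norm, psi = drop(res$psi), u = usplit),
    class = "rhp_glmm")
}

#' Fit a Gaussian linear mixed model
#'
#' Convenience wrapper around [fit_glmm()] with `family = "gaussian"`
#' (maximum likelihood, suitable for likelihood-ratio tests).
#'
#' @inheritParams fit_glmm
#' @export
fit_lmm <- function(spec, data, ...) {
  spec$family <- "gaussian"
  fit_glmm(spec, data, ...)
}

#' Fit a Poisson mixed model with an observation-level random effect
#'
#' Lognormal-Poisson fit: a per-observation random intercept absorbs
#' overdispersion; its SD is reported in `sigma["(obs)"]`.
#'
#' @inheritParams fit_glmm
#' @export
fit_poisson_olre <- function(spec, data, ...) {
  spec$family <- "poisson"
  spec$olre <- TRUE
  fit_glmm(spec, data, ...)
}

#' @export
print.rhp_glmm <- function(x, ...) {
  print(x$spec)
  cat(sprintf("logLik %.3f (k = %d, n = %d)%s\n", x$loglik, x$k, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  tab <- cbind(Estimate = x$beta, `Std. Error` = x$se,
               z = x$beta / x$se)
  print(round(tab, 4))
  if (length(x$sigma))
    cat("random-effect SDs:",
        paste(sprintf("%s = %.3f", names(x$sigma), x$sigma), collapse = ", "),
        "\n")
  if (!is.null(x$sigma_resid))
    cat(sprintf("residual SD: %.3f\n", x$sigma_resid))
  invisible(x)
}

#' @export
logLik.rhp_glmm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.rhp_glmm <- function(object, ...) object$beta

#' @export
vcov.rhp_glmm <- function(object, ...) object$vcov

#' Single-term-deletion likelihood-ratio test
#'
#' Refits the model without one fixed-effect term (same random structure,
#' ML) and compares likelihoods: `chisq = 2 * (loglik_full -
#' loglik_reduced)` on 1 df.
#'
#' @param full a converged [fit_glmm()] result.
#' @param term name of the fixed term to drop.
#' @param data the data used for the full fit.
#' @return list of class `lr_test`: `chisq`, `df`, `p`, plus both fits'
#'   log-likelihoods.
#' @export
drop1_lr <- function(full, term, data) {
  stopifnot(inherits(full, "rhp_glmm"))
  if (!term %in% full$spec$terms)
    stop(sprintf("term '%s' not in the model", term), call. = FALSE)
  if (!full$converged) stop("full model did not converge", call. = FALSE)
  red_spec <- full$spec
  red_spec$terms <- setdiff(full$spec$terms, term)
  red <- fit_glmm(red_spec, data)
  if (!red$converged)
    stop("reduced model did not converge", call. = FALSE)
  chisq <- max(0, 2 * (full$loglik - red$loglik))
  structure(list(term = term, chisq = chisq, df = 1L,
                 p = pchisq(chisq, 1, lower.tail = FALSE),
                 loglik_full = full$loglik, loglik_reduced = red$loglik),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR test dropping '%s': chisq(%d) = %.3f, p = %.4g\n",
              x$term, x$df, x$chisq, x$p))
  invisible(x)
}

# variance inflation factors of the fixed terms (collinearity guard)
vif_check <- function(data, terms, threshold = 10) {
  if (length(terms) < 2) return(setNames(rep(1, length(terms)), terms))
  R <- stats::cor(as.matrix(data[, terms, drop = FALSE]))
  v <- diag(solve(R))
  names(v) <- terms
  v
}
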