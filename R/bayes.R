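# Bayesian contest model with the focal/rival symmetry constraint: the
# two group random effects have equal variance and correlation -1,
# i.e. logit P(focal wins) = X beta + a_focal - a_rival with
# a_g ~ Normal(0, sigma_a^2). Non-centered parameterization a_g =
# sigma_a * z_g; random-walk Metropolis-within-Gibbs with adaptive step
# scaling during warmup.

#' Log posterior of the constrained contest model
#'
#' Built-in antisymmetry: swapping every contest's focal/rival labels and
#' flipping outcomes leaves the value unchanged at matched parameters (the
#' `a_focal - a_rival` term self-negates).
#'
#' @param beta named fixed-effect vector (first element intercept).
#' @param z standardized group abilities (named by group id).
#' @param sigma_a ability SD (>= 0).
#' @param X design matrix (intercept column first).
#' @param y 0/1 outcomes.
#' @param focal,rival group ids per contest.
#' @param prior_beta_sd,prior_sigma_sd prior scales: Normal(0,
#'   prior_beta_sd^2) on each beta, half-Normal(0, prior_sigma_sd^2) on
#'   sigma_a.
#' @return log posterior density (unnormalized).
#' @export
constrained_log_posterior <- function(beta, z, sigma_a, X, y, focal, rival,
                                      prior_beta_sd = 2.5,
                                      prior_sigma_sd = 1) {
  if (sigma_a < 0) return(-Inf)
  eta <- drop(X %*% beta) + sigma_a * (z[focal] - z[rival])
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + sum(dnorm(beta, 0, prior_beta_sd, log = TRUE)) +
    sum(dnorm(z, 0, 1, log = TRUE)) +
    dnorm(sigma_a, 0, prior_sigma_sd, log = TRUE)
}

#' Fit the constrained contest model by MCMC
#'
#' @param data data frame with scaled predictors, `focal_win`,
#'   `focal_group_id`, `rival_group_id`.
#' @param terms fixed-effect predictor columns.
#' @param prior_beta_sd,prior_sigma_sd prior scales (see
#'   [constrained_log_posterior()]).
#' @param chains,iter,warmup MCMC settings; `iter` includes warmup.
#' @param seed integer seed.
#' @param rhat_max convergence requirement; exceeding it is an error.
#' @return object of class `constrained_fit`: `summary` (posterior mean,
#'   SD, central 95% interval, R-hat, effective sample size per
#'   parameter), `draws` (post-warmup, pooled), `acceptance` per chain,
#'   and the model terms.
#' @export
fit_constrained_contest <- function(data, terms, prior_beta_sd = 2.5,
                                    prior_sigma_sd = 1, chains = 3,
                                    iter = 3000, warmup = 1000, seed = 1L,
                                    rhat_max = 1.05) {
  stopifnot(iter > warmup, warmup >= 0)
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, terms, drop = FALSE]))
  y <- data$focal_win
  groups <- sort(unique(c(as.character(data$focal_group_id),
                          as.character(data$rival_group_id))))
  G <- length(groups)
  fi <- match(as.character(data$focal_group_id), groups)
  ri <- match(as.character(data$rival_group_id), groups)
  n <- length(y)
  p <- ncol(X)
  # signed incidence of each group's z on eta
  gidx <- lapply(seq_len(G), function(g) {
    i <- c(which(fi == g), which(ri == g))
    list(i = i, s = rep(c(1, -1), c(sum(fi == g), sum(ri == g))))
  })
  loglik_rows <- function(eta, rows = NULL) {
    if (is.null(rows)) sum(y * eta - log1p(exp(eta)))
    else sum(y[rows] * eta[rows] - log1p(exp(eta[rows])))
  }
  par_names <- c(colnames(X), paste0("z_", groups), "sigma_a")
  npar <- p + G + 1
  all_draws <- vector("list", chains)
  acc_rate <- numeric(chains)
  n_keep <- iter - warmup
  for (ch in seq_len(chains)) {
    with_seed(derive_seed(seed, ch), {
      beta <- rnorm(p, 0, 0.1)
      z <- rnorm(G, 0, 0.1)
      ls <- log(0.5) + rnorm(1, 0, 0.1)  # log sigma_a
      step <- rep(0.2, npar)
      step_asis <- 0.3
      acc <- att <- rep(0, npar)
      acc_asis <- att_asis <- 0
      etaX <- drop(X %*% beta)
      dz <- z[fi] - z[ri]
      sig <- exp(ls)
      lp_beta_prior <- function(b) sum(dnorm(b, 0, prior_beta_sd, log = TRUE))
      draws <- matrix(NA_real_, n_keep, npar)
      acc_total <- att_total <- 0
      for (s in seq_len(iter)) {
        # beta coordinates
        for (j in seq_len(p)) {
          prop <- beta[j] + step[j] * rnorm(1)
          etaX_new <- etaX + (prop - beta[j]) * X[, j]
          d <- loglik_rows(etaX_new + sig * dz) -
            loglik_rows(etaX + sig * dz) +
            dnorm(prop, 0, prior_beta_sd, log = TRUE) -
            dnorm(beta[j], 0, prior_beta_sd, log = TRUE)
          att[j] <- att[j] + 1
          if (log(runif(1)) < d) {
            beta[j] <- prop; etaX <- etaX_new; acc[j] <- acc[j] + 1
          }
        }
        # z coordinates (only their contests change)
        eta <- etaX + sig * dz
        for (g in seq_len(G)) {
          jj <- p + g
          gi <- gidx[[g]]
          prop <- z[g] + step[jj] * rnorm(1)
          delta <- sig * (prop - z[g]) * gi$s
          eta_new_rows <- eta[gi$i] + delta
          d <- sum(y[gi$i] * eta_new_rows - log1p(exp(eta_new_rows))) -
            loglik_rows(eta, gi$i) +
            dnorm(prop, log = TRUE) - dnorm(z[g], log = TRUE)
          att[jj] <- att[jj] + 1
          if (length(gi$i) == 0 || log(runif(1)) < d) {
            eta[gi$i] <- eta_new_rows
            dz[gi$i] <- dz[gi$i] + (prop - z[g]) * gi$s
            z[g] <- prop; acc[jj] <- acc[jj] + 1
          }
        }
        # log sigma_a (Jacobian-corrected half-normal prior)
        jj <- npar
        prop <- ls + step[jj] * rnorm(1)
        sig_new <- exp(prop)
        d <- loglik_rows(etaX + sig_new * dz) - loglik_rows(etaX + sig * dz) +
          dnorm(sig_new, 0, prior_sigma_sd, log = TRUE) -
          dnorm(sig, 0, prior_sigma_sd, log = TRUE) + prop - ls
        att[jj] <- att[jj] + 1
        if (log(runif(1)) < d) { ls <- prop; sig <- sig_new; acc[jj] <- acc[jj] + 1 }
        # interweaving step (ancillarity-sufficiency): update sigma in the
        # centered parameterization holding the abilities a = sigma * z
        # fixed, then back-transform z. Breaks the sigma-z random-walk
        # coupling that otherwise mixes slowly.
        a_val <- sig * z
        prop2 <- ls + step_asis * rnorm(1)
        sig2 <- exp(prop2)
        d2 <- sum(dnorm(a_val, 0, sig2, log = TRUE)) -
          sum(dnorm(a_val, 0, sig, log = TRUE)) +
          dnorm(sig2, 0, prior_sigma_sd, log = TRUE) -
          dnorm(sig, 0, prior_sigma_sd, log = TRUE) + prop2 - ls
        # translation move: the likelihood depends on z only through
        # differences, so it is exactly flat along the all-ones direction
        # and the level of z is identified by the prior alone. Gibbs-draw
        # that coordinate: mean(z) | rest ~ Normal(0, 1/G). eta and dz are
        # unchanged.
        z <- z - mean(z) + rnorm(1, 0, 1 / sqrt(G))
        att_asis <- att_asis + 1
        if (is.finite(d2) && log(runif(1)) < d2) {
          dz <- dz * (sig / sig2)  # sigma * dz (hence eta) is unchanged
          ls <- prop2
          sig <- sig2
          z <- a_val / sig
          acc_asis <- acc_asis + 1
        }
        # warmup adaptation toward ~0.3 acceptance
        if (s <= warmup && s %% 50 == 0) {
          rate <- acc / pmax(att, 1)
          step <- step * exp(1.5 * (rate - 0.3))
          step <- pmin(pmax(step, 1e-3), 10)
          step_asis <- min(max(step_asis *
                                 exp(1.5 * (acc_asis / max(att_asis, 1) - 0.3)),
                               1e-3), 10)
          acc_total <- acc_total + sum(acc); att_total <- att_total + sum(att)
          acc[] <- 0; att[] <- 0; acc_asis <- 0; att_asis <- 0
        }
        if (s > warmup) draws[s - warmup, ] <- c(beta, z, sig)
      }
      acc_rate[ch] <- sum(acc) / max(sum(att), 1)
      all_draws[[ch]] <- draws
    })
  }
  rhat <- vapply(seq_len(npar), function(j)
    split_rhat(lapply(all_draws, function(d) d[, j])), 0)
  ess <- vapply(seq_len(npar), function(j)
    ess_basic(lapply(all_draws, function(d) d[, j])), 0)
  pooled <- do.call(rbind, all_draws)
  colnames(pooled) <- par_names
  summ <- data.frame(
    parameter = par_names,
    mean = colMeans(pooled), sd = apply(pooled, 2, sd),
    q2.5 = apply(pooled, 2, pctl, probs = 2.5),
    q97.5 = apply(pooled, 2, pctl, probs = 97.5),
    rhat = rhat, ess = ess, row.names = NULL, stringsAsFactors = FALSE)
  if (any(rhat >= rhat_max, na.rm = TRUE))
    stop(sprintf("MCMC did not converge: max R-hat = %.3f (parameters: %s)",
                 max(rhat, na.rm = TRUE),
                 paste(par_names[which(rhat >= rhat_max)], collapse = ", ")),
         call. = FALSE)
  structure(list(summary = summ, draws = pooled, acceptance = acc_rate,
                 terms = terms, groups = groups, chains = chains),
            class = "constrained_fit")
}

# split-half R-hat (Gelman et al.)
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  nn <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- nn * var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# crude effective sample size from pooled pairwise autocorrelations
ess_basic <- function(chain_list, max_lag = 100) {
  n_total <- sum(lengths(chain_list))
  rho <- sapply(chain_list, function(x) {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
    a
  })
  rho <- rowMeans(rho)
  # truncate at first negative paired sum
  tau <- 1
  for (l in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[l] + rho[l + 1]
    if (is.na(pair) || pair < 0) break
    tau <- tau + 2 * pair
  }
  n_total / tau
}

#' @export
print.constrained_fit <- function(x, ...) {
  cat(sprintf("constrained Bayesian contest model (%d chains, mean acceptance %.2f)\n",
              x$chains, mean(x$acceptance)))
  show <- x$summary[x$summary$parameter %in%
                      c("(Intercept)", x$terms, "sigma_a"), ]
  print(show, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Compare the Bayesian and maximum-likelihood contest fits
#'
#' @param posterior a [fit_constrained_contest()] result.
#' @param ml_fit an [fit_glmm()] result with the same fixed terms.
#' @return data frame per fixed effect: posterior mean/SD, MLE and SE,
#'   sign agreement, and the standardized difference
#'   `(posterior mean - MLE) / SE`.
#' @export
compare_to_ml <- function(posterior, ml_fit) {
  terms <- c("(Intercept)", posterior$terms)
  if (!setequal(terms, names(ml_fit$beta)))
    stop("fixed terms differ between the Bayesian and ML fits", call. = FALSE)
  s <- posterior$summary
  pm <- setNames(s$mean, s$parameter)[terms]
  psd <- setNames(s$sd, s$parameter)[terms]
  data.frame(term = terms, posterior_mean = unname(pm),
             posterior_sd = unname(psd),
             mle = unname(ml_fit$beta[terms]), se = unname(ml_fit$se[terms]),
             sign_agree = sign(pm) == sign(ml_fit$beta[terms]) |
               abs(pm) < 0.05,
             std_diff = unname((pm - ml_fit$beta[terms]) / ml_fit$se[terms]),
             row.names = NULL, stringsAsFactors = FALSE)
}
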