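test_that("predictor scaling is exact, idempotent and invertible", {
  sc <- scale_predictors(data.frame(x = c(1, 2, 3)))
  expect_equal(sc$data$x, c(-1, 0, 1))
  df <- data.frame(a = rnorm(50, 5, 2), b = runif(50))
  sc1 <- scale_predictors(df)
  expect_equal(unname(colMeans(sc1$data)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(vapply(sc1$data, sd, 0)), c(1, 1), tolerance = 1e-12)
  sc2 <- scale_predictors(sc1$data)
  expect_equal(sc2$data, sc1$data, tolerance = 1e-12)
  back <- unscale_predictors(sc1)
  expect_equal(back, df, tolerance = 1e-12)
  expect_error(scale_predictors(data.frame(k = rep(2, 10))), "k")
})

test_that("binomial GLMM with sigma fixed at zero reproduces glm exactly", {
  set.seed(1)
  d <- direct_contest_data(400, beta = c(rel_n_males = 0.8,
                                         rel_max_age_males = -0.4))
  spec <- model_spec("focal_win", c("rel_n_males", "rel_max_age_males"),
                     random = c("focal_group_id", "rival_group_id"))
  fit <- fit_glmm(spec, d, fix_sigma_zero = TRUE)
  ref <- glm(focal_win ~ rel_n_males + rel_max_age_males, binomial, d)
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-3)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-6)
})

test_that("poisson and gaussian families reach their GLM/LM limits", {
  set.seed(2)
  n <- 300
  x <- rnorm(n)
  cnt <- rpois(n, exp(1 + 0.5 * x))
  dp <- data.frame(y = cnt, x = x, g = sample(letters[1:8], n, TRUE))
  fp <- fit_glmm(model_spec("y", "x", random = "g", family = "poisson"),
                 dp, fix_sigma_zero = TRUE)
  rp <- glm(y ~ x, poisson, dp)
  expect_lt(max(abs(fp$beta - coef(rp))), 1e-3)
  expect_lt(abs(fp$loglik - as.numeric(logLik(rp))), 1e-6)
  yy <- 3 + 2 * x + rnorm(n)
  dg <- data.frame(y = yy, x = x, g = dp$g)
  fg <- fit_glmm(model_spec("y", "x", random = "g", family = "gaussian"),
                 dg, fix_sigma_zero = TRUE)
  rg <- lm(y ~ x, dg)
  expect_lt(max(abs(fg$beta - coef(rg))), 1e-3)
  expect_lt(abs(fg$loglik - as.numeric(logLik(rg))), 1e-5)
})

test_that("crossed-random-intercept fits agree with an independent mixed-model engine", {
  skip_if_not_installed("lme4")
  set.seed(3)
  d <- direct_contest_data(400, beta = c(rel_n_males = 1), ability_sd = 0.6,
                           n_groups = 12)
  spec <- model_spec("focal_win", "rel_n_males",
                     random = c("focal_group_id", "rival_group_id"))
  fit <- fit_glmm(spec, d)
  ref <- lme4::glmer(focal_win ~ rel_n_males + (1 | focal_group_id) +
                       (1 | rival_group_id), data = d, family = binomial)
  expect_lt(max(abs(fit$beta - lme4::fixef(ref))), 2e-3)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-4)
  expect_lt(max(abs(fit$se - sqrt(diag(as.matrix(vcov(ref)))))), 0.02)
  # gaussian: ML lmer equality
  id <- rep(1:40, each = 5)
  val <- 10 + rnorm(40, 0, 2)[id] + rnorm(200)
  dg <- data.frame(value = val, individual_id = id)
  fg <- fit_glmm(model_spec("value", random = "individual_id",
                            family = "gaussian"), dg)
  rg <- lme4::lmer(value ~ 1 + (1 | individual_id), dg, REML = FALSE)
  expect_equal(fg$loglik, as.numeric(logLik(rg)), tolerance = 1e-6)
  expect_equal(unname(fg$sigma), attr(lme4::VarCorr(rg)$individual_id,
                                      "stddev")[[1]], tolerance = 1e-4)
})

test_that("mirrored designs give a zero intercept", {
  set.seed(4)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  d <- data.frame(y = c(y, 1 - y), x = c(x, -x),
                  g1 = rep(sprintf("a%d", 1:5), 80),
                  g2 = rep(sprintf("b%d", 1:5), each = 80))
  fit <- fit_glmm(model_spec("y", "x", random = c("g1", "g2")), d,
                  fix_sigma_zero = TRUE)
  expect_lt(abs(fit$beta[["(Intercept)"]]), 1e-6)
})

test_that("poisson OLRE recovers overdispersion and slope", {
  set.seed(5)
  reps <- 30
  sd_hat <- slope_hat <- numeric(reps)
  for (r in 1:reps) {
    n <- 250
    x <- rnorm(n)
    y <- rpois(n, exp(1 + 0.8 * x + rnorm(n, 0, 0.5)))
    d <- data.frame(y = y, x = x)
    fit <- fit_poisson_olre(model_spec("y", "x"), d)
    sd_hat[r] <- fit$sigma[["(obs)"]]
    slope_hat[r] <- fit$beta[["x"]]
  }
  expect_lt(abs(median(sd_hat) - 0.5), 0.1)
  expect_lt(abs(median(slope_hat) - 0.8), 0.1)
  # equidispersed data: OLRE variance collapses
  set.seed(6)
  y0 <- rpois(400, exp(1 + 0.5 * rnorm(400)))
  x0 <- rnorm(400)
  y0 <- rpois(400, exp(1 + 0.5 * x0))
  f0 <- fit_poisson_olre(model_spec("y", "x"),
                         data.frame(y = y0, x = x0))
  expect_lt(f0$sigma[["(obs)"]]^2, 0.05)
})

test_that("fixed-effect estimates are invariant to exact row duplication", {
  # exact duplication doubles every sufficient statistic, so fixed-effect
  # point estimates are unchanged in the fixed-effects limit (in a mixed
  # model duplication changes per-individual replication and hence the
  # shrinkage weighting, so only the sigma-fixed limit has this property)
  set.seed(7)
  id <- rep(1:30, each = 3)
  d <- data.frame(value = 5 + rnorm(30, 0, 1.5)[id] + rnorm(90),
                  sex_male = rbinom(90, 1, 0.5), individual_id = id)
  spec <- model_spec("value", "sex_male", random = "individual_id",
                     family = "gaussian")
  f1 <- fit_glmm(spec, d, fix_sigma_zero = TRUE)
  f2 <- fit_glmm(spec, rbind(d, d), fix_sigma_zero = TRUE)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)  # optimizer precision
  # and the mixed fit on duplicated data matches the independent engine
  skip_if_not_installed("lme4")
  g2 <- fit_glmm(spec, rbind(d, d))
  ref <- lme4::lmer(value ~ sex_male + (1 | individual_id), rbind(d, d),
                    REML = FALSE)
  expect_equal(unname(g2$beta), unname(lme4::fixef(ref)), tolerance = 1e-5)
})

test_that("drop1 likelihood-ratio test is definitionally consistent and calibrated", {
  set.seed(8)
  d <- direct_contest_data(250, beta = c(rel_n_males = 0.7))
  spec <- model_spec("focal_win", c("rel_n_males", "rel_max_age_males"),
                     random = c("focal_group_id", "rival_group_id"))
  fit <- fit_glmm(spec, d)
  lr <- drop1_lr(fit, "rel_max_age_males", d)
  expect_equal(lr$chisq, 2 * (lr$loglik_full - lr$loglik_reduced),
               tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$chisq, 1, lower.tail = FALSE))
  expect_error(drop1_lr(fit, "not_there", d), "not in the model")
  # null calibration: p approximately uniform for a no-effect term
  ps <- numeric(120)
  set.seed(9)
  for (r in seq_along(ps)) {
    dd <- data.frame(y = rbinom(150, 1, 0.5), x = rnorm(150),
                     g = sample(letters[1:6], 150, TRUE))
    ff <- fit_glmm(model_spec("y", "x", random = "g"), dd)
    ps[r] <- drop1_lr(ff, "x", dd)$p
  }
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("relabeling all contests leaves the maximized likelihood unchanged", {
  set.seed(10)
  d <- direct_contest_data(300, beta = c(rel_n_males = 1), ability_sd = 0.5)
  spec <- model_spec("focal_win", "rel_n_males",
                     random = c("focal_group_id", "rival_group_id"))
  f1 <- fit_glmm(spec, d)
  d2 <- d
  d2$focal_win <- 1L - d$focal_win
  d2$focal_group_id <- d$rival_group_id
  d2$rival_group_id <- d$focal_group_id
  d2$rel_n_males <- -d$rel_n_males
  f2 <- fit_glmm(spec, d2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$beta[["rel_n_males"]], f2$beta[["rel_n_males"]],
               tolerance = 1e-5)
})

test_that("estimates are invariant to affine transforms of raw predictors", {
  set.seed(11)
  d <- direct_contest_data(250, beta = c(rel_n_males = 0.8))
  raw <- data.frame(x = 3 + 40 * d$rel_n_males)
  sc <- scale_predictors(raw)
  d$x <- sc$data$x
  spec_a <- model_spec("focal_win", "rel_n_males",
                       random = c("focal_group_id", "rival_group_id"))
  spec_b <- model_spec("focal_win", "x",
                       random = c("focal_group_id", "rival_group_id"))
  fa <- fit_glmm(spec_a, d)
  fb <- fit_glmm(spec_b, d)
  expect_equal(unname(fa$beta), unname(fb$beta), tolerance = 1e-5)
})

test_that("recovery at the generator's contest model, with CI coverage", {
  # scaled-down analogue of the full recovery experiment (the acceptance
  # suite runs it at 500 contests x 200 replicates)
  set.seed(12)
  reps <- 25
  est <- matrix(NA_real_, reps, 2)
  cover <- matrix(NA, reps, 2)
  for (r in 1:reps) {
    d <- direct_contest_data(400, beta = c(rel_n_males = 1,
                                           rel_max_age_males = 0.6),
                             ability_sd = 0.5, n_groups = 11, seed = 400 + r)
    fit <- fit_glmm(model_spec("focal_win",
                               c("rel_n_males", "rel_max_age_males"),
                               random = c("focal_group_id",
                                          "rival_group_id")), d)
    est[r, ] <- fit$beta[c("rel_n_males", "rel_max_age_males")]
    truth <- c(1, 0.6)
    ci_lo <- est[r, ] - 1.96 * fit$se[c("rel_n_males", "rel_max_age_males")]
    ci_hi <- est[r, ] + 1.96 * fit$se[c("rel_n_males", "rel_max_age_males")]
    cover[r, ] <- truth >= ci_lo & truth <= ci_hi
  }
  expect_lt(abs(median(est[, 1]) - 1), 0.15)
  expect_lt(abs(median(est[, 2]) - 0.6), 0.15)
  expect_gt(mean(cover), 0.85)
})
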