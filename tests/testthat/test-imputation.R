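test_that("missing-fraction eligibility uses the inclusive 20% boundary", {
  mk <- function(n, n_miss) {
    data.frame(contest_id = "C1", group_id = "G1",
               side = rep(c("focal", "rival"), each = n),
               individual_id = paste0("i", 1:(2 * n)), sex = "M",
               age_days = 1000, dominant = FALSE,
               weight_g = c(c(rep(NA, n_miss), rep(1400, n - n_miss)),
                            rep(1400, n)),
               pregnant = FALSE, stringsAsFactors = FALSE)
  }
  el <- roster_eligibility(mk(10, 2))   # 2/10 = 0.2: eligible
  expect_true(all(el$eligible))
  el3 <- roster_eligibility(mk(10, 3))  # 0.3: focal side ineligible
  expect_false(el3$eligible[el3$side == "focal"])
  expect_length(attr(el3, "eligible_contests"), 0)
  el0 <- roster_eligibility(mk(10, 0))
  expect_true(all(el0$eligible))
  expect_equal(el0$missing_fraction, c(0, 0))
  expect_error(roster_eligibility(mk(10, 0)[0, ]), "empty")
})

test_that("reference sets respect group, sex, pregnancy and the 60-day band", {
  history <- data.frame(
    individual_id = c("m1", "m2", "m3", "m4", "f1", "f2", "t"),
    group_id = c("G1", "G1", "G1", "G2", "G1", "G1", "G1"),
    sex = c("M", "M", "M", "M", "F", "F", "M"),
    obs_age_days = c(1000, 1060, 1061, 1000, 1000, 1010, 1005),
    weight_g = c(1300, 1500, 1700, 1900, 1100, 1150, 1400),
    pregnant = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  side <- data.frame(contest_id = "C1", group_id = "G1", side = "focal",
                     individual_id = c("t", "f3"), sex = c("M", "F"),
                     age_days = c(1000, 1000), dominant = FALSE,
                     weight_g = NA_real_, pregnant = c(FALSE, FALSE),
                     stringsAsFactors = FALSE)
  refs <- reference_set(side, "t", history = history)
  # m1 (same age) and m2 (60 d older) qualify; m3 is 61 d older, m4 is in
  # another group, the target's own history is excluded
  expect_setequal(refs, c(1300, 1500))
  # females must match pregnancy status
  refs_f <- reference_set(side, "f3", history = history)
  expect_equal(refs_f, 1150)
  # empty set for a lone age band
  side2 <- side; side2$age_days <- c(5000, 5000)
  expect_length(reference_set(side2, "t", history = history), 0)
})

test_that("contemporary mode uses roster mates within the age band", {
  cfg <- imputation_config(reference_mode = "contemporary")
  side <- data.frame(contest_id = "C1", group_id = "G1", side = "focal",
                     individual_id = c("t", "a", "b", "c", "d"),
                     sex = "M", age_days = c(1000, 1000, 1060, 1061, 940),
                     dominant = FALSE,
                     weight_g = c(NA, 1300, 1500, 1700, 1250),
                     pregnant = FALSE, stringsAsFactors = FALSE)
  expect_setequal(reference_set(side, "t", cfg), c(1300, 1500, 1250))
  side$age_days[5] <- 939  # 61 d younger: excluded
  expect_setequal(reference_set(side, "t", cfg), c(1300, 1500))
})

test_that("truncated-normal draws respect bounds and match quadrature moments", {
  set.seed(42)
  x <- sample_truncnorm(10000, 1400, 100, 1200, 1600)
  expect_true(all(x >= 1200 & x <= 1600))
  # oracle: truncated-normal mean by numerical integration
  Z <- integrate(function(v) dnorm(v, 1400, 100), 1200, 1600)$value
  m1 <- integrate(function(v) v * dnorm(v, 1400, 100) / Z, 1200, 1600)$value
  m2 <- integrate(function(v) v^2 * dnorm(v, 1400, 100) / Z, 1200, 1600)$value
  tsd <- sqrt(m2 - m1^2)
  x2 <- sample_truncnorm(50000, 1400, 100, 1200, 1600)
  expect_lt(abs(mean(x2) - m1), 3 * tsd / sqrt(50000))
  # asymmetric bounds shift the mean as the oracle predicts
  Z2 <- integrate(function(v) dnorm(v, 0, 1), -0.5, 3)$value
  m1b <- integrate(function(v) v * dnorm(v, 0, 1) / Z2, -0.5, 3)$value
  xb <- sample_truncnorm(50000, 0, 1, -0.5, 3)
  expect_lt(abs(mean(xb) - m1b), 0.02)
  expect_error(sample_truncnorm(5, 0, 1, 2, 1), "inverted")
})

test_that("imputation completes rosters without touching observed weights", {
  sim <- simulate_contest_study(
    pop_config = population_config(n_groups = 6, adults_per_group = 14),
    c_config = contest_config(n_contests = 80), seed = 8)
  history <- weight_history(sim$tables)
  res <- impute_rosters(sim$roster, seed = 5, history = history)
  expect_false(anyNA(res$roster$weight_g))
  # observed weights unchanged
  merged <- merge(res$roster, sim$roster,
                  by = c("contest_id", "individual_id"))
  obs <- !is.na(merged$weight_g.y)
  expect_equal(merged$weight_g.x[obs], merged$weight_g.y[obs])
  # draws lie inside their reference bounds and log is consistent
  expect_true(all(res$draws$reference_n >= 1))
  expect_equal(nrow(res$draws),
               sum(is.na(sim$roster$weight_g[
                 sim$roster$contest_id %in% res$roster$contest_id])))
  # determinism and independence across seeds
  res2 <- impute_rosters(sim$roster, seed = 5, history = history)
  expect_identical(res$roster$weight_g, res2$roster$weight_g)
  res3 <- impute_rosters(sim$roster, seed = 6, history = history)
  expect_false(identical(res$roster$weight_g, res3$roster$weight_g))
})

test_that("single-reference members get the reference value verbatim", {
  history <- data.frame(individual_id = "ref", group_id = "G1", sex = "M",
                        obs_age_days = 1000, weight_g = 1400,
                        pregnant = FALSE, stringsAsFactors = FALSE)
  roster <- data.frame(
    contest_id = "C1", group_id = c("G1", "G1", "G2", "G2"),
    side = rep(c("focal", "rival"), each = 2),
    individual_id = c("t", "u", "v", "w"), sex = "M",
    age_days = 1000, dominant = FALSE,
    weight_g = c(NA, 1350, 1380, 1390), pregnant = FALSE,
    stringsAsFactors = FALSE)
  res <- impute_rosters(roster, imputation_config(max_missing_fraction = 0.6),
                        seed = 1, history = history)
  expect_equal(res$roster$weight_g[res$roster$individual_id == "t"], 1400)
  expect_equal(res$draws$reference_n, 1)
})

test_that("imputed age/sex strata track the true stratum distribution", {
  # the imputed distribution for a stratum should be close to the truth the
  # generator used (two-sample KS on a moderate sample)
  sim <- simulate_contest_study(
    pop_config = population_config(n_groups = 8, adults_per_group = 16),
    c_config = contest_config(n_contests = 120), seed = 15)
  history <- weight_history(sim$tables)
  ps <- numeric(20)
  for (k in 1:20) {
    res <- impute_rosters(sim$roster, seed = k, history = history)
    imp <- merge(res$draws,
                 sim$roster_full[, c("contest_id", "individual_id",
                                     "weight_g")],
                 by = c("contest_id", "individual_id"))
    ps[k] <- suppressWarnings(
      ks.test(imp$imputed_weight_g, imp$weight_g)$p.value)
  }
  expect_gt(median(ps), 0.01)
})

test_that("growth validation flags nothing when nothing was imputed", {
  sim <- simulate_contest_study(
    pop_config = population_config(n_groups = 4, adults_per_group = 12),
    c_config = contest_config(n_contests = 40), missing_rate = 0, seed = 3)
  df <- data.frame(group_id = sim$roster$group_id,
                   age_days = sim$roster$age_days,
                   weight_g = sim$roster$weight_g)
  v <- validate_growth(df, df)
  conv <- v[v$converged, ]
  expect_gt(nrow(conv), 0)
  expect_true(all(conv$diff == 0))
})
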