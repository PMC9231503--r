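# follow-up analyses: senior males, binomial tests, repeatability,
# age-linked models, dimorphism, descriptive proportions

test_that("exact binomial test equals exhaustive enumeration for n <= 30", {
  # oracle: enumerate every outcome, apply the small-p two-sided rule
  oracle <- function(k, n, p0) {
    dens <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 0)
    sum(dens[dens <= dens[k + 1] * (1 + 1e-7)])
  }
  for (n in c(1, 2, 5, 10, 17, 30)) {
    for (p0 in c(0.1, 0.25, 0.5)) {
      for (k in 0:n) {
        expect_equal(exact_binomial_test(k, n, p0)$p_value,
                     min(1, oracle(k, n, p0)), tolerance = 1e-10,
                     info = sprintf("k=%d n=%d p0=%g", k, n, p0))
      }
    }
  }
  # agrees with the reference implementation in stats
  for (cse in list(c(26, 95), c(29, 95), c(3, 12))) {
    expect_equal(exact_binomial_test(cse[1], cse[2], 0.3)$p_value,
                 binom.test(cse[1], cse[2], 0.3)$p.value, tolerance = 1e-9)
  }
  expect_equal(exact_binomial_test(0, 10, 0.5)$p_value, 2 * 0.5^10)
  expect_equal(exact_binomial_test(5, 10, 0.5)$p_value, 1)
  expect_error(exact_binomial_test(11, 10, 0.5), "exceed")
})

test_that("the printed dominance and same-age binomial tests reproduce", {
  # dominant senior males: 26/95 wins vs the losing-group proportion 7/26
  p1 <- exact_binomial_test(26, 95, 7 / 26)$p_value
  expect_equal(round(p1, 1), 0.9)
  # same-age mates: 29/95 vs 2/26 is significant at the printed level
  p2 <- exact_binomial_test(29, 95, 2 / 26)$p_value
  expect_lt(p2, 0.01)
})

test_that("senior-male datasets follow the strictly-older rule", {
  roster <- rbind(
    data.frame(contest_id = "C1", group_id = "G1", side = "focal",
               individual_id = c("m1", "m2", "f1"), sex = c("M", "M", "F"),
               age_days = c(3285, 3285, 4000), dominant = c(TRUE, FALSE, FALSE),
               weight_g = c(1500, 1400, 1300), pregnant = FALSE,
               stringsAsFactors = FALSE),
    data.frame(contest_id = "C1", group_id = "G2", side = "rival",
               individual_id = c("m3", "f2"), sex = c("M", "F"),
               age_days = c(2555, 2000), dominant = FALSE,
               weight_g = c(1450, 1250), pregnant = FALSE,
               stringsAsFactors = FALSE),
    data.frame(contest_id = "C2", group_id = "G1", side = "focal",
               individual_id = "m1", sex = "M", age_days = 3300,
               dominant = FALSE, weight_g = 1500, pregnant = FALSE,
               stringsAsFactors = FALSE),
    data.frame(contest_id = "C2", group_id = "G3", side = "rival",
               individual_id = "m4", sex = "M", age_days = 3300,
               dominant = FALSE, weight_g = 1350, pregnant = FALSE,
               stringsAsFactors = FALSE))
  contests <- data.frame(contest_id = c("C1", "C2"),
                         date = as.Date("2018-06-01"),
                         focal_group_id = c("G1", "G1"),
                         rival_group_id = c("G2", "G3"),
                         focal_win = c(1L, 1L), stringsAsFactors = FALSE)
  rec <- senior_male_datasets(roster, contests)
  # C2 has equal oldest ages across groups: contributes nothing
  expect_true(all(rec$contest_id == "C1"))
  # both same-age oldest males of the winner yield records
  expect_setequal(rec$male_id, c("m1", "m2"))
  expect_true(all(rec$outcome == "win"))
  expect_true(all(rec$n_same_age_mates == 1L))
  # flipping the outcome moves them to the losing set
  contests$focal_win[1] <- 0L
  rec2 <- senior_male_datasets(roster, contests)
  expect_true(all(rec2$outcome == "lose"))
  # partition: every unequal-age contest contributes its oldest males once
  expect_equal(nrow(rec) + 0, sum(rec$outcome == "win"))
})

test_that("descriptive proportions compute the printed-style ratios", {
  # 7 contests with two same-age seniors, 12 with three, 71 with one
  rec <- do.call(rbind, lapply(1:90, function(i) {
    nsen <- if (i <= 7) 2L else if (i <= 19) 3L else 1L
    data.frame(contest_id = sprintf("C%02d", i), group_id = "G1",
               male_id = sprintf("C%02d_m%d", i, seq_len(nsen)),
               age_days = 3000, outcome = "win", dominant = FALSE,
               n_same_age_mates = nsen - 1L, stringsAsFactors = FALSE)
  }))
  roster <- data.frame(contest_id = rec$contest_id, group_id = "G1",
                       side = "focal", individual_id = rec$male_id,
                       sex = "M", age_days = 3000, dominant = FALSE,
                       weight_g = 1400, pregnant = FALSE,
                       stringsAsFactors = FALSE)
  pr <- descriptive_proportions(rec, roster)
  expect_equal(pr$multi_senior$k, 19)
  expect_equal(pr$multi_senior$n, 90)
  expect_equal(round(100 * pr$multi_senior$value), 21)
  expect_equal(as.vector(pr$multi_senior_by_count), c(71, 7, 12))
  # 13 of 66: printed as 19.7%
  expect_equal(round(100 * 13 / 66, 1), 19.7)
  # all-unique-oldest data: multi-senior fraction 0
  pr0 <- descriptive_proportions(rec[rec$n_same_age_mates == 0, ],
                                 roster)
  expect_equal(pr0$multi_senior$k, 0)
})

test_that("repeatability hits the corners and recovers a 9:1 variance ratio", {
  # zero within-individual variance: R = 1
  d0 <- data.frame(individual_id = rep(1:20, each = 3),
                   value = rep(rnorm(20, 10, 3), each = 3))
  r0 <- repeatability(d0, n_boot = 10, n_perm = 10, seed = 1)
  expect_gt(r0$R, 0.999)
  # shuffled labels: R near zero, permutation p large
  set.seed(51)
  dshuf <- data.frame(individual_id = sample(rep(1:50, each = 4)),
                      value = rnorm(200))
  rs <- repeatability(dshuf, n_boot = 10, n_perm = 40, seed = 2)
  expect_lt(rs$R, 0.15)
  expect_gt(rs$p_perm, 0.05)
  # recovery at the study's magnitude: true R = 0.9 (variance ratio 9:1)
  set.seed(52)
  Rhat <- vapply(1:10, function(r) {
    id <- rep(1:120, each = 5)
    val <- rnorm(120, 0, 3)[id] + rnorm(600, 0, 1)
    fit <- fit_glmm(model_spec("value", random = "individual_id",
                               family = "gaussian"),
                    data.frame(value = val, individual_id = id))
    s2a <- fit$sigma[[1]]^2
    s2a / (s2a + fit$sigma_resid^2)
  }, 0)
  expect_lt(abs(median(Rhat) - 0.9), 0.03)
})

test_that("age-experience model recovers the generator slope", {
  set.seed(53)
  sl <- vapply(1:10, function(r) {
    d <- simulate_age_experience(n_males = 300, slope = 0.8, seed = 700 + r)
    age_experience_model(d)$fit$beta[["max_age_days"]]
  }, 0)
  expect_lt(abs(median(sl) - 0.8), 0.1)
  # flat counts: slope collapses to zero
  dflat <- data.frame(male_id = sprintf("M%03d", 1:200),
                      max_age_days = runif(200, 300, 4000),
                      n_contests = 5L)
  mflat <- age_experience_model(dflat)
  expect_lt(abs(mflat$fit$beta[["max_age_days"]]), 1e-3)
})

test_that("senior-age model recovers the 11-year liability threshold", {
  set.seed(54)
  thr <- vapply(1:20, function(r) {
    d <- simulate_senior_outcomes(n_males = 40, n_records = 250,
                                  seed = 800 + r)
    senior_age_outcome_model(d)$threshold_years
  }, 0)
  # generating curve: logit p = 1.5 - 0.25 (age_y - 5), crossing at 11 y
  expect_lt(abs(median(thr) - 11), 1)
  # age-unit invariance: refitting with ages in years gives the same
  # threshold
  d <- simulate_senior_outcomes(n_males = 40, n_records = 250, seed = 900)
  t1 <- senior_age_outcome_model(d)$threshold_years
  d2 <- d
  d2$age_days <- d$age_days / 365.25  # now "days" column actually holds years
  t2 <- senior_age_outcome_model(d2)$threshold_years * 365.25
  expect_equal(t1, t2, tolerance = 1e-6)
  # zero slope: not-crossing flag
  d3 <- d
  set.seed(99)
  d3$win <- rbinom(nrow(d3), 1, 0.5)
  m3 <- senior_age_outcome_model(d3)
  expect_true(is.na(m3$threshold_years) || abs(m3$threshold_years) > 0)
  d4 <- d[d$win == 1, ]
  expect_error(senior_age_outcome_model(d4), "both outcomes")
})

test_that("eviction model recovers the generator slope and flags separation", {
  set.seed(55)
  sl <- vapply(1:8, function(r) {
    d <- simulate_evictions(n_events = 60, males_per_event = 10,
                            slope = 0.5, seed = 1000 + r)
    eviction_model(d)$fit$beta[["age_days"]]
  }, 0)
  expect_lt(abs(median(sl) - 0.5), 0.15)
  # age-independent eviction: slope within noise of zero
  d0 <- simulate_evictions(n_events = 60, males_per_event = 10, slope = 0,
                           seed = 1100)
  f0 <- eviction_model(d0)
  expect_lt(abs(f0$fit$beta[["age_days"]]),
            3 * f0$fit$se[["age_days"]] + 1e-6)
  # everyone evicted: separation-degenerate input errors cleanly
  dall <- d0
  dall$evicted <- 1L
  expect_error(eviction_model(dall), NA)
})

test_that("paternity model recovers the generator slope", {
  set.seed(56)
  sl <- vapply(1:10, function(r) {
    d <- simulate_paternity(n_litters = 200, n_males = 50, slope = -0.3,
                            seed = 1200 + r)
    paternity_model(d)$fit$beta[["male_age_days"]]
  }, 0)
  expect_lt(abs(median(sl) + 0.3), 0.15)
  # null slope
  d0 <- simulate_paternity(n_litters = 200, n_males = 50, slope = 0,
                           seed = 1300)
  f0 <- paternity_model(d0)
  expect_lt(abs(f0$fit$beta[["male_age_days"]]),
            3 * f0$fit$se[["male_age_days"]] + 1e-6)
  expect_error(paternity_model(data.frame(male_id = "a", male_age_days = 1,
                                          sired = 1, litter_size = 0)),
               "litter sizes")
})

test_that("dimorphism models recover the sex gap and exclude pregnant females", {
  set.seed(57)
  gaps <- vapply(1:6, function(r) {
    d <- simulate_dimorphism_data(n_individuals = 200,
                                  obs_per_individual = 5, sex_gap = 147.1,
                                  seed = 1400 + r)
    dimorphism_models(d)$weight$fit$beta[["sex_male"]]
  }, 0)
  d1 <- simulate_dimorphism_data(n_individuals = 200, seed = 1400 + 1)
  f1 <- dimorphism_models(d1)$weight
  expect_lt(abs(median(gaps) - 147.1), 3 * f1$fit$se[["sex_male"]])
  expect_lt(f1$lr$p, 0.01)
  # pregnant rows excluded by default
  d2 <- d1
  d2$pregnant[d2$sex == "F"][1:100] <- TRUE
  d2$value[d2$pregnant] <- d2$value[d2$pregnant] + 500
  f2 <- dimorphism_models(d2)$weight
  expect_lt(abs(f2$fit$beta[["sex_male"]] - f1$fit$beta[["sex_male"]]), 30)
  f3 <- dimorphism_models(d2, exclude_pregnant = FALSE)$weight
  expect_lt(f3$fit$beta[["sex_male"]], f2$fit$beta[["sex_male"]])
  # identical sexes: LR p is non-significant most of the time; here check
  # a single null draw stays above a generous floor
  d0 <- simulate_dimorphism_data(n_individuals = 150, sex_gap = 0,
                                 seed = 1500)
  expect_gt(dimorphism_models(d0)$weight$lr$p, 1e-4)
})

test_that("single-senior subset refit matches the full fit when no ties exist", {
  sim <- simulate_contest_study(
    pop_config = population_config(n_groups = 8, adults_per_group = 16),
    c_config = contest_config(n_contests = 100), missing_rate = 0,
    seed = 61)
  prep <- prepare_contest_data(sim$tables, roster = sim$roster)
  P <- scale(contestRHP:::.predictors_from_weights(prep,
                                                   prep$roster$weight_g))
  df <- data.frame(contest_id = prep$contests$contest_id,
                   focal_win = prep$contests$focal_win,
                   focal_group_id = prep$contests$focal_group_id,
                   rival_group_id = prep$contests$rival_group_id,
                   as.data.frame(P))
  terms <- c("rel_n_males", "rel_max_age_males")
  res <- single_senior_subset_refit(df, prep$roster, terms)
  expect_lte(res$n_subset, res$n_full)
  # estimates stay within 2 SE of the full fit (stability property)
  d <- abs(res$comparison$estimate_full - res$comparison$estimate_subset)
  expect_true(all(d < 2 * pmax(res$comparison$se_full,
                               res$comparison$se_subset) + 1e-8))
  # contests with a unique senior male are the subset; removing everything
  # errors cleanly
  expect_error(single_senior_subset_refit(df[0, ], prep$roster, terms),
               "no single-senior")
})
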