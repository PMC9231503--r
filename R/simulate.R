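# Synthetic-data generators with known ground truth. Defaults emulate the
# study population: ~11 groups of ~20 adults, male-biased sex ratio
# (1.6 males : 1 female), asymptotic weight growth with male asymptote
# ~1440 g and female ~1293 g, ~0.3 of males dominant per breeding cycle,
# and ~22% of contest-relevant weights missing.

#' Configuration for the synthetic population
#'
#' @param n_groups number of social groups (>= 2).
#' @param adults_per_group adults per group (>= 2).
#' @param male_fraction proportion of adults that are male, in (0, 1);
#'   the default reflects a 1.6:1 male-biased adult sex ratio.
#' @param birth_date_range two dates delimiting adult birth dates.
#' @param cohort_interval_days days between a group's communal litters;
#'   females birth synchronously, so groupmates born in the same litter
#'   share a birth date exactly (this is what makes near-age imputation
#'   reference sets non-empty, as in the field data).
#' @param cohort_decay_years exponential scale favoring recent cohorts
#'   (survival: older cohorts contribute fewer living adults).
#' @param study_start,study_end observation window for weights, contests
#'   and mate-guarding records.
#' @param growth_params_by_sex named list (`M`, `F`) of [growth_params()].
#' @param weight_noise_sd gram-scale Gaussian noise around the growth curve.
#' @param weighing_interval days between weight observations (free
#'   parameter; the field cadence is not part of the emulated conditions).
#' @param immigrant_fraction proportion of adults that are immigrants.
#' @param pregnant_fraction probability a female weight observation is
#'   taken while pregnant.
#' @param pregnancy_effect multiplicative weight effect of pregnancy.
#' @param dominant_fraction probability a male mate-guards (is dominant) in
#'   a given breeding cycle.
#' @param breeding_cycle_days days between breeding cycles.
#' @param seed integer seed.
#' @return a `population_config` object.
#' @export
population_config <- function(n_groups = 11, adults_per_group = 20,
                              male_fraction = 1.6 / 2.6,
                              birth_date_range = as.Date(c("2004-06-01",
                                                           "2017-06-01")),
                              cohort_interval_days = 90,
                              cohort_decay_years = 2.5,
                              study_start = as.Date("2018-01-01"),
                              study_end = as.Date("2018-12-31"),
                              growth_params_by_sex = list(
                                M = growth_params(300, 1440, 200),
                                F = growth_params(300, 1293, 200)),
                              weight_noise_sd = 50,
                              weighing_interval = 30,
                              immigrant_fraction = 0.05,
                              pregnant_fraction = 0.2,
                              pregnancy_effect = 1.05,
                              dominant_fraction = 0.3,
                              breeding_cycle_days = 90,
                              seed = 1L) {
  cfg <- list(
    n_groups = assert_count(n_groups, "n_groups", min = 2L),
    adults_per_group = assert_count(adults_per_group, "adults_per_group", min = 2L),
    male_fraction = assert_number(male_fraction, "male_fraction", 0, 1,
                                  open_lower = TRUE, open_upper = TRUE),
    birth_date_range = as_date(birth_date_range),
    cohort_interval_days = assert_count(cohort_interval_days,
                                        "cohort_interval_days"),
    cohort_decay_years = assert_number(cohort_decay_years,
                                       "cohort_decay_years", 0,
                                       open_lower = TRUE),
    study_start = as_date(study_start), study_end = as_date(study_end),
    growth_params_by_sex = growth_params_by_sex,
    weight_noise_sd = assert_number(weight_noise_sd, "weight_noise_sd", 0),
    weighing_interval = assert_count(weighing_interval, "weighing_interval"),
    immigrant_fraction = assert_number(immigrant_fraction, "immigrant_fraction", 0, 1),
    pregnant_fraction = assert_number(pregnant_fraction, "pregnant_fraction", 0, 1),
    pregnancy_effect = assert_number(pregnancy_effect, "pregnancy_effect", 0,
                                     open_lower = TRUE, upper = Inf),
    dominant_fraction = assert_number(dominant_fraction, "dominant_fraction", 0, 1),
    breeding_cycle_days = assert_count(breeding_cycle_days, "breeding_cycle_days"),
    seed = assert_count(seed, "seed", min = 0L))
  if (!all(c("M", "F") %in% names(cfg$growth_params_by_sex)) ||
      !all(vapply(cfg$growth_params_by_sex, inherits, TRUE, "growth_params")))
    stop_config("growth_params_by_sex", "must be a list with growth_params for M and F")
  if (length(cfg$birth_date_range) != 2 ||
      cfg$birth_date_range[1] >= cfg$birth_date_range[2])
    stop_config("birth_date_range", "must be an increasing date interval")
  structure(cfg, class = "population_config")
}

#' Generate a synthetic population
#'
#' Produces the individuals, memberships, weight-observation and
#' mate-guarding tables of the data model. Weight observations follow the
#' sex-specific asymptotic growth curve plus a pregnancy effect and
#' Gaussian noise, on a per-individual grid at the configured weighing
#' interval. Deterministic given the config (including its seed).
#'
#' @param config a [population_config()].
#' @return named list of data frames: `individuals`, `memberships`,
#'   `weights`, `mateguard_events`, plus the `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  with_seed(config$seed, {
    n <- config$n_groups * config$adults_per_group
    group_ids <- sprintf("G%02d", seq_len(config$n_groups))
    gid <- rep(group_ids, each = config$adults_per_group)
    iid <- sprintf("%s_I%03d", gid, sequence(rep(config$adults_per_group,
                                                 config$n_groups)))
    sex <- ifelse(runif(n) < config$male_fraction, "M", "F")
    # eligibility needs males in every group; guarantee two per group
    for (g in group_ids) {
      idx <- which(gid == g)
      males <- which(sex[idx] == "M")
      need <- 2 - length(males)
      if (need > 0) sex[idx[setdiff(seq_along(idx), males)[seq_len(need)]]] <- "M"
    }
    # births in synchronous communal litters: per group, cohort dates at a
    # fixed interval with a group-specific phase; recent cohorts are more
    # likely (older cohorts have fewer surviving adults)
    birth <- as_date(rep(NA, n))
    for (g in group_ids) {
      idx <- which(gid == g)
      cohorts <- seq(config$birth_date_range[1] +
                       sample.int(config$cohort_interval_days, 1) - 1,
                     config$birth_date_range[2],
                     by = config$cohort_interval_days)
      age_y <- as.numeric(config$birth_date_range[2] - cohorts) / 365.25
      birth[idx] <- sample(cohorts, length(idx), replace = TRUE,
                           prob = exp(-age_y / config$cohort_decay_years))
    }
    immigrant <- runif(n) < config$immigrant_fraction
    immigration_date <- as_date(rep(NA, n))
    immigration_date[immigrant] <- birth[immigrant] + 730
    individuals <- data.frame(individual_id = iid, sex = sex,
                              birth_date = birth, immigrant = immigrant,
                              immigration_date = immigration_date,
                              stringsAsFactors = FALSE)
    start <- birth
    start[immigrant] <- immigration_date[immigrant]  # known only after arrival
    memberships <- data.frame(individual_id = iid, group_id = gid,
                              start_date = start,
                              end_date = config$study_end + 60,
                              stringsAsFactors = FALSE)
    # weight observations on a jittered per-individual grid covering each
    # individual's whole life: the imputation reference rule draws on the
    # group's full growth history, as the long-term field dataset does
    grid0 <- seq(config$birth_date_range[1], config$study_end,
                 by = config$weighing_interval)
    phase <- floor(runif(n) * config$weighing_interval)
    obs <- data.frame(
      individual_id = rep(iid, each = length(grid0)),
      date = rep(grid0, times = n) + rep(phase, each = length(grid0)),
      stringsAsFactors = FALSE)
    # immigrants are weighed on arrival (first capture)
    if (any(immigrant))
      obs <- rbind(obs, data.frame(individual_id = iid[immigrant],
                                   date = immigration_date[immigrant],
                                   stringsAsFactors = FALSE))
    obs <- merge(obs, cbind(individuals[, c("individual_id", "sex",
                                            "birth_date")],
                            obs_from = start),
                 by = "individual_id")
    obs$age <- as.numeric(as_date(obs$date) - obs$birth_date)
    obs <- obs[obs$age >= 0 & as_date(obs$date) >= obs$obs_from &
                 as_date(obs$date) <= config$study_end, ]
    obs$pregnant <- obs$sex == "F" & runif(nrow(obs)) < config$pregnant_fraction
    base <- numeric(nrow(obs))
    for (s in c("M", "F")) {
      k <- obs$sex == s
      base[k] <- growth_weight(obs$age[k], config$growth_params_by_sex[[s]])
    }
    obs$weight_g <- base * ifelse(obs$pregnant, config$pregnancy_effect, 1) +
      rnorm(nrow(obs), 0, config$weight_noise_sd)
    weights <- obs[order(obs$individual_id, obs$date),
                   c("individual_id", "date", "weight_g", "pregnant")]
    weights$date <- as_date(weights$date)
    rownames(weights) <- NULL
    # mate-guarding: per breeding cycle, each male dominant with fixed prob
    cycles <- seq(config$study_start - 200, config$study_end,
                  by = config$breeding_cycle_days)
    males <- individuals$individual_id[individuals$sex == "M"]
    mg <- data.frame(individual_id = rep(males, times = length(cycles)),
                     date = rep(cycles, each = length(males)),
                     stringsAsFactors = FALSE)
    mg <- mg[runif(nrow(mg)) < config$dominant_fraction, ]
    mg$date <- as_date(mg$date)
    mg <- mg[order(mg$individual_id, mg$date), ]
    rownames(mg) <- NULL
    list(individuals = individuals, memberships = memberships,
         weights = weights, mateguard_events = mg, config = config)
  })
}

#' Configuration for synthetic contests
#'
#' @param n_contests number of contests to generate.
#' @param true_beta named vector of true coefficients on the *scaled*
#'   relative predictors; names must be among [predictor_names()].
#' @param ability_sd standard deviation (logit units) of latent group
#'   abilities entering the outcome as `a_focal - a_rival`.
#' @param seed integer seed.
#' @return a `contest_config` object.
#' @export
contest_config <- function(n_contests = 300,
                           true_beta = c(rel_n_males = 1.0,
                                         rel_max_age_males = 0.6),
                           ability_sd = 0.5, seed = 1L) {
  if (length(true_beta) && (is.null(names(true_beta)) ||
      !all(names(true_beta) %in% predictor_names())))
    stop_config("true_beta", "names must be among the 15 relative predictors")
  structure(list(
    n_contests = assert_count(n_contests, "n_contests"),
    true_beta = true_beta,
    ability_sd = assert_number(ability_sd, "ability_sd", 0),
    seed = assert_count(seed, "seed", min = 0L)), class = "contest_config")
}

#' Generate synthetic contests with known ground truth
#'
#' Contest dates and group pairings are drawn uniformly; pairings for which
#' either group lacks a male or a subordinate male on the contest date are
#' resampled (bounded). Outcomes are Bernoulli draws from
#' `logit P(focal wins) = sum(beta * x_scaled) + a_focal - a_rival`,
#' where `x_scaled` are the unit-variance-scaled relative predictors
#' computed from the full (pre-missingness) weight data and `a` are
#' i.i.d. Normal(0, ability_sd) latent group abilities.
#'
#' @param population result of [generate_population()].
#' @param config a [contest_config()].
#' @return list with `contests` (data frame), `roster` (long roster used),
#'   and `truth` (a `synthetic_truth` object: `true_beta`,
#'   `group_abilities`, `growth_params`, `missing_rate`).
#' @export
generate_contests <- function(population, config) {
  stopifnot(inherits(config, "contest_config"))
  pcfg <- population$config
  if (pcfg$n_groups < 2) stop("population must have at least 2 groups", call. = FALSE)
  with_seed(config$seed, {
    group_ids <- sort(unique(population$memberships$group_id))
    abilities <- setNames(rnorm(length(group_ids), 0, config$ability_sd),
                          group_ids)
    days <- as.numeric(pcfg$study_end - pcfg$study_start)
    accepted <- NULL
    need <- config$n_contests
    for (round in 1:100) {
      if (need == 0) break
      date <- pcfg$study_start + floor(runif(need) * (days + 1))
      g1 <- sample(group_ids, need, replace = TRUE)
      g2 <- vapply(g1, function(g) sample(setdiff(group_ids, g), 1), "")
      cand <- data.frame(contest_id = sprintf("tmp%05d", seq_len(need)),
                         date = date, focal_group_id = g1,
                         rival_group_id = unname(g2), focal_win = NA_integer_,
                         stringsAsFactors = FALSE)
      ros <- build_rosters(population, cand)
      elig <- contest_eligibility(ros)
      ok <- cand$contest_id %in% elig$contest_id[elig$eligible]
      accepted <- rbind(accepted, cand[ok, ])
      need <- config$n_contests - nrow(accepted)
    }
    if (need > 0)
      stop("could not generate eligible contest pairings after bounded resampling",
           call. = FALSE)
    accepted <- accepted[order(accepted$date), ]
    accepted$contest_id <- sprintf("C%05d", seq_len(nrow(accepted)))
    roster <- build_rosters(population, accepted)
    X <- predictor_matrix(roster, accepted$contest_id)
    eta <- if (length(config$true_beta)) {
      Xs <- scale(X[, names(config$true_beta), drop = FALSE])
      Xs[!is.finite(Xs)] <- 0  # a constant predictor carries no signal
      drop(Xs %*% config$true_beta)
    } else rep(0, nrow(accepted))
    eta <- eta + abilities[accepted$focal_group_id] -
      abilities[accepted$rival_group_id]
    accepted$focal_win <- rbinom(nrow(accepted), 1L, plogis(unname(eta)))
    rownames(accepted) <- NULL
    truth <- structure(list(true_beta = config$true_beta,
                            group_abilities = abilities,
                            growth_params = pcfg$growth_params_by_sex,
                            missing_rate = 0),
                       class = "synthetic_truth")
    list(contests = accepted, roster = roster, truth = truth)
  })
}

#' Mask contest-relevant weights completely at random
#'
#' Each observed weight in the long roster is independently set to missing
#' with probability `rate`; already-missing weights stay missing. An
#' optional age-dependent mode makes the masking probability increase with
#' member age (missing-at-random), for robustness experiments.
#'
#' @param roster long roster from [build_rosters()].
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed (mask is reproducible).
#' @param mode `"mcar"` (default): independent masking at `rate`.
#'   `"age"`: age-dependent masking (missing-at-random) with the same
#'   marginal rate. `"clustered"`: the masking probability varies by
#'   contest-side, Beta-distributed with mean `rate` and shape calibrated
#'   so that ~72% of group-sightings contain at least one missing member
#'   at the study's 22% marginal rate — the group-level clustering the
#'   field data display (habituation differs between groups).
#' @param cluster_shape first Beta shape parameter for `"clustered"`.
#' @return the roster with masked `weight_g` (and an attribute
#'   `missing_mask` giving the masked row indices).
#' @export
apply_missingness <- function(roster, rate, seed,
                              mode = c("mcar", "age", "clustered"),
                              cluster_shape = 0.4645) {
  rate <- assert_number(rate, "rate", 0, 1, open_upper = TRUE)
  mode <- match.arg(mode)
  with_seed(seed, {
    observed <- which(!is.na(roster$weight_g))
    p <- rep(rate, length(observed))
    if (mode == "age" && length(observed)) {
      a <- roster$age_days[observed]
      w <- (a - min(a)) / max(1, diff(range(a)))   # older -> more missing
      p <- pmin(0.999, rate * (0.5 + w) / mean(0.5 + w))
    } else if (mode == "clustered" && length(observed) && rate > 0) {
      key <- factor(paste(roster$contest_id, roster$side))[observed]
      pg <- rbeta(nlevels(key), cluster_shape,
                  cluster_shape * (1 - rate) / rate)
      p <- pg[as.integer(key)]
    }
    mask <- observed[runif(length(observed)) < p]
    roster$weight_g[mask] <- NA_real_
    attr(roster, "missing_mask") <- mask
    roster
  })
}

#' Simulate a complete contest study
#'
#' Convenience wrapper: population, contests and missingness in one call,
#' returning the tables, roster and ground truth used throughout the
#' validation suite.
#'
#' @param pop_config a [population_config()].
#' @param c_config a [contest_config()].
#' @param missing_rate fraction of contest-relevant weights to mask
#'   (the study's observed rate was 22.1%).
#' @param missing_mode masking mode (see [apply_missingness()]); the
#'   default `"clustered"` reproduces the group-level clustering of
#'   missingness the field data display.
#' @param seed integer seed controlling all stages.
#' @return list with `tables` (the data model), `contests`, `roster`
#'   (with missingness applied), `roster_full` (pre-missingness), `truth`.
#' @export
simulate_contest_study <- function(pop_config = population_config(),
                                   c_config = contest_config(),
                                   missing_rate = 0.221,
                                   missing_mode = "clustered",
                                   seed = 1L) {
  pop_config$seed <- derive_seed(seed, 1L)
  pop <- generate_population(pop_config)
  c_config$seed <- derive_seed(seed, 2L)
  gen <- generate_contests(pop, c_config)
  roster <- apply_missingness(gen$roster, missing_rate, derive_seed(seed, 3L),
                              mode = missing_mode)
  gen$truth$missing_rate <- missing_rate
  tables <- pop[c("individuals", "memberships", "weights", "mateguard_events")]
  tables$contests <- gen$contests
  list(tables = tables, contests = gen$contests, roster = roster,
       roster_full = gen$roster, truth = gen$truth)
}

# ---- follow-up ground-truth generators -------------------------------------
# Each emulates one follow-up dataset at the magnitudes reported for the
# study population, so recovery tests have known truth.

#' Simulate repeated weight measurements for dimorphism and repeatability
#'
#' Individuals get a sex-specific mean (male - female gap `sex_gap`),
#' an individual random intercept and residual noise.
#'
#' @param n_individuals,obs_per_individual sample sizes.
#' @param sex_gap male minus female mean difference (grams; default the
#'   study-scale adult weight gap 1440.1 - 1293.0 ~ 147 g).
#' @param sd_individual,sd_residual variance components (grams).
#' @param female_mean baseline female mean weight.
#' @param seed integer seed.
#' @return data frame: `individual_id`, `sex`, `value`, `pregnant`.
#' @export
simulate_dimorphism_data <- function(n_individuals = 300,
                                     obs_per_individual = 5,
                                     sex_gap = 147.1,
                                     sd_individual = 150, sd_residual = 80,
                                     female_mean = 1293, seed = 1L) {
  with_seed(seed, {
    sex <- rep(c("M", "F"), length.out = n_individuals)
    b <- rnorm(n_individuals, 0, sd_individual)
    id <- rep(seq_len(n_individuals), each = obs_per_individual)
    mu <- female_mean + (sex == "M") * sex_gap
    data.frame(individual_id = sprintf("I%04d", id),
               sex = sex[id],
               value = mu[id] + b[id] + rnorm(length(id), 0, sd_residual),
               pregnant = FALSE, stringsAsFactors = FALSE)
  })
}

#' Simulate lifetime contest-participation counts versus age
#'
#' Log-linear in scaled age with log-normal overdispersion, matching the
#' age-experience model's structure (Poisson with observation-level random
#' effect).
#'
#' @param n_males number of males.
#' @param slope effect of scaled maximum age on log counts.
#' @param intercept log baseline count.
#' @param olre_sd log-normal overdispersion SD.
#' @param seed integer seed.
#' @return data frame: `male_id`, `max_age_days`, `n_contests`.
#' @export
simulate_age_experience <- function(n_males = 300, slope = 0.8,
                                    intercept = 1.5, olre_sd = 0.5,
                                    seed = 1L) {
  with_seed(seed, {
    age <- runif(n_males, 200, 12 * 365.25)
    x <- drop(scale(age))
    lambda <- exp(intercept + slope * x + rnorm(n_males, 0, olre_sd))
    data.frame(male_id = sprintf("M%04d", seq_len(n_males)),
               max_age_days = age, n_contests = rpois(n_males, lambda),
               stringsAsFactors = FALSE)
  })
}

#' Simulate senior-male contest records with an age-linked decline
#'
#' Win probability follows `logit P(win) = intercept + slope_per_year *
#' (age_years - ref_age_years)` plus an individual random intercept; with
#' the defaults the fixed-effect curve crosses P = 0.5 at 11 years, the
#' liability threshold reported for the study population.
#'
#' @param n_males unique senior males.
#' @param n_records total contest records (males recur).
#' @param intercept,slope_per_year,ref_age_years fixed-effect curve;
#'   threshold = `ref_age_years - intercept / slope_per_year`.
#' @param id_sd SD of the male random intercept.
#' @param age_range_years sampled senior-male age range.
#' @param seed integer seed.
#' @return data frame: `male_id`, `age_days`, `win`.
#' @export
simulate_senior_outcomes <- function(n_males = 25, n_records = 121,
                                     intercept = 1.5, slope_per_year = -0.25,
                                     ref_age_years = 5, id_sd = 0.3,
                                     age_range_years = c(4, 14), seed = 1L) {
  with_seed(seed, {
    base_age <- runif(n_males, age_range_years[1], age_range_years[2])
    b <- rnorm(n_males, 0, id_sd)
    idx <- sample(n_males, n_records, replace = TRUE)
    age_y <- base_age[idx] + runif(n_records, 0, 1)
    eta <- intercept + slope_per_year * (age_y - ref_age_years) + b[idx]
    data.frame(male_id = sprintf("SM%03d", idx),
               age_days = age_y * 365.25,
               win = rbinom(n_records, 1, plogis(eta)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate male eviction records
#'
#' Binary evicted outcome per male per eviction event, log-odds linear in
#' scaled age with male, group and event random intercepts.
#'
#' @param n_events eviction events.
#' @param males_per_event candidate males per event.
#' @param n_groups groups events are nested in.
#' @param slope effect of scaled age (study-scale default 0.5).
#' @param intercept baseline log-odds of eviction.
#' @param sd_male,sd_group,sd_event random-intercept SDs.
#' @param seed integer seed.
#' @return data frame: `individual_id`, `group_id`, `eviction_id`,
#'   `age_days`, `evicted`.
#' @export
simulate_evictions <- function(n_events = 50, males_per_event = 10,
                               n_groups = 11, slope = 0.5, intercept = -1,
                               sd_male = 0.3, sd_group = 0.3, sd_event = 0.3,
                               seed = 1L) {
  with_seed(seed, {
    n_males <- n_events * males_per_event %/% 2
    bm <- rnorm(n_males, 0, sd_male)
    bg <- rnorm(n_groups, 0, sd_group)
    be <- rnorm(n_events, 0, sd_event)
    ev <- rep(seq_len(n_events), each = males_per_event)
    grp <- rep(sample(n_groups, n_events, replace = TRUE), each = males_per_event)
    male <- unlist(lapply(seq_len(n_events),
                          function(e) sample(n_males, males_per_event)))
    age <- runif(length(ev), 200, 12 * 365.25)
    x <- drop(scale(age))
    eta <- intercept + slope * x + bm[male] + bg[grp] + be[ev]
    data.frame(individual_id = sprintf("M%04d", male),
               group_id = sprintf("G%02d", grp),
               eviction_id = sprintf("E%03d", ev),
               age_days = age,
               evicted = rbinom(length(ev), 1, plogis(eta)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate senior-male paternity shares
#'
#' Pups sired per litter are binomial with log-odds linear in scaled senior
#' age plus a male random intercept (study-scale default slope -0.3).
#'
#' @param n_litters litters.
#' @param n_males unique senior males.
#' @param litter_range inclusive litter-size range.
#' @param slope effect of scaled age on sired log-odds.
#' @param intercept baseline log-odds.
#' @param sd_male male random-intercept SD.
#' @param seed integer seed.
#' @return data frame: `male_id`, `male_age_days`, `sired`, `litter_size`.
#' @export
simulate_paternity <- function(n_litters = 133, n_males = 46,
                               litter_range = c(2, 6), slope = -0.3,
                               intercept = 0.5, sd_male = 0.4, seed = 1L) {
  with_seed(seed, {
    b <- rnorm(n_males, 0, sd_male)
    idx <- sample(n_males, n_litters, replace = TRUE)
    age <- runif(n_litters, 4 * 365, 13 * 365)
    x <- drop(scale(age))
    size <- sample(litter_range[1]:litter_range[2], n_litters, replace = TRUE)
    p <- plogis(intercept + slope * x + b[idx])
    data.frame(male_id = sprintf("SM%03d", idx), male_age_days = age,
               sired = rbinom(n_litters, size, p), litter_size = size,
               stringsAsFactors = FALSE)
  })
}
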