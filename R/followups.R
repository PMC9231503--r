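# Follow-up analyses: senior-male datasets and descriptive proportions,
# exact binomial tests, repeatability, and the age-linked senior-male
# models (experience, contest success with liability threshold, eviction,
# paternity) plus sexual-dimorphism models.

#' Senior-male winning and losing datasets
#'
#' The senior male of a contest is the oldest male across the two groups.
#' When one group's oldest male is strictly older than the other's, that
#' group "has" the senior male: its oldest male(s) enter the winning set
#' if the group won and the losing set if it lost. Contests whose two
#' oldest males are exactly the same age contribute no records; several
#' same-age oldest males within the senior group each yield a record.
#'
#' @param roster long roster from [build_rosters()].
#' @param contests contests data frame (for outcomes).
#' @param mateguard_events optional mate-guarding table for the
#'   `ever_dominant` flag.
#' @return data frame of senior-male records: `contest_id`, `group_id`,
#'   `male_id`, `age_days`, `outcome` ("win"/"lose"), `dominant`,
#'   `ever_dominant`, `n_same_age_mates`.
#' @export
senior_male_datasets <- function(roster, contests, mateguard_events = NULL) {
  males <- roster[roster$sex == "M", , drop = FALSE]
  recs <- list()
  for (cid in unique(contests$contest_id)) {
    cc <- contests[contests$contest_id == cid, ]
    mm <- males[males$contest_id == cid, , drop = FALSE]
    f <- mm[mm$side == "focal", , drop = FALSE]
    r <- mm[mm$side == "rival", , drop = FALSE]
    if (!nrow(f) || !nrow(r)) next
    af <- max(f$age_days); ar <- max(r$age_days)
    if (af == ar) next
    senior_side <- if (af > ar) f else r
    senior_won <- if (af > ar) cc$focal_win == 1 else cc$focal_win == 0
    amax <- max(senior_side$age_days)
    seniors <- senior_side[senior_side$age_days == amax, , drop = FALSE]
    recs[[length(recs) + 1]] <- data.frame(
      contest_id = cid, group_id = seniors$group_id[1],
      male_id = seniors$individual_id, age_days = seniors$age_days,
      outcome = if (senior_won) "win" else "lose",
      dominant = seniors$dominant,
      n_same_age_mates = nrow(seniors) - 1L,
      date = cc$date, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    return(data.frame(contest_id = character(), group_id = character(),
                      male_id = character(), age_days = numeric(),
                      outcome = character(), dominant = logical(),
                      ever_dominant = logical(),
                      n_same_age_mates = integer(),
                      stringsAsFactors = FALSE))
  out$ever_dominant <- NA
  if (!is.null(mateguard_events) && nrow(mateguard_events)) {
    di <- nearest_prior_obs(out$male_id, as_date(out$date),
                            mateguard_events$individual_id,
                            as_date(mateguard_events$date), Inf)
    out$ever_dominant <- !is.na(di)
  }
  out$date <- NULL
  rownames(out) <- NULL
  out
}

#' Exact binomial test by enumeration
#'
#' Exact tail probabilities of the binomial distribution. The two-sided
#' p-value sums the probabilities of all outcomes no more probable than
#' the observed one (the small-p rule used by `binom.test`).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param sided `"two"`, `"less"` or `"greater"`.
#' @return list of class `binom_exact` with `p_value`, `k`, `n`, `p0`.
#' @export
exact_binomial_test <- function(k, n, p0, sided = c("two", "less", "greater")) {
  sided <- match.arg(sided)
  k <- assert_count(k, "k", min = 0L)
  n <- assert_count(n, "n", min = 1L)
  p0 <- assert_number(p0, "p0", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  dens <- dbinom(0:n, n, p0)
  p <- switch(sided,
    less = sum(dens[seq_len(k + 1)]),
    greater = sum(dens[(k + 1):(n + 1)]),
    two = sum(dens[dens <= dens[k + 1] * (1 + 1e-7)]))
  structure(list(p_value = min(p, 1), k = k, n = n, p0 = p0, sided = sided),
            class = "binom_exact")
}

#' @export
print.binom_exact <- function(x, ...) {
  cat(sprintf("exact binomial test: %d/%d vs p0 = %.4g (%s-sided), p = %.4g\n",
              x$k, x$n, x$p0, x$sided, x$p_value))
  invisible(x)
}

#' Repeatability (intraclass correlation) of repeated measurements
#'
#' `R = sigma2_among / (sigma2_among + sigma2_within)` from a
#' variance-components fit of `value ~ 1 + (1 | individual)`. The
#' confidence interval comes from a parametric bootstrap (simulate from
#' the fitted model, refit); the p-value from permuting individual labels.
#'
#' @param data data frame with `individual_id` and `value`.
#' @param n_boot parametric-bootstrap replicates.
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @return list of class `repeatability`: `R`, `ci` (2.5/97.5
#'   percentiles), `p_perm`, and the variance components.
#' @export
repeatability <- function(data, n_boot = 200, n_perm = 200, seed = 1L) {
  counts <- table(data$individual_id)
  if (length(counts) < 2 || !any(counts >= 2))
    stop("need at least 2 individuals and repeated measurements", call. = FALSE)
  spec <- model_spec("value", random = "individual_id", family = "gaussian")
  point <- function(df, start = NULL) {
    fit <- fit_glmm(spec, df, start = start)
    s2a <- fit$sigma[["individual_id"]]^2
    s2w <- fit$sigma_resid^2
    list(R = s2a / (s2a + s2w), fit = fit)
  }
  obs <- point(data)
  with_seed(seed, {
    n_i <- table(data$individual_id)
    ids <- names(n_i)
    boot <- replicate(n_boot, {
      b <- rnorm(length(ids), 0, obs$fit$sigma[["individual_id"]])
      names(b) <- ids
      sim <- data
      sim$value <- obs$fit$beta[["(Intercept)"]] +
        b[as.character(data$individual_id)] +
        rnorm(nrow(data), 0, obs$fit$sigma_resid)
      point(sim, start = obs$fit$psi)$R
    })
    perm <- replicate(n_perm, {
      shuf <- data
      shuf$individual_id <- sample(data$individual_id)
      point(shuf, start = obs$fit$psi)$R
    })
  })
  structure(list(R = obs$R,
                 ci = pctl(boot, c(2.5, 97.5)),
                 p_perm = (1 + sum(perm >= obs$R)) / (n_perm + 1),
                 sigma_among = obs$fit$sigma[["individual_id"]],
                 sigma_within = obs$fit$sigma_resid,
                 boot = boot, perm = perm), class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("repeatability R = %.3f (95%% CI %.3f-%.3f), permutation p = %.4g\n",
              x$R, x$ci[1], x$ci[2], x$p_perm))
  invisible(x)
}

#' Age versus lifetime contest experience
#'
#' Poisson mixed model (log link, observation-level random effect) of a
#' male's lifetime contest count on his scaled maximum age, with a
#' single-term-deletion likelihood-ratio test for age.
#'
#' @param data data frame with `male_id`, `max_age_days`, `n_contests`.
#' @return list: `fit` (an `rhp_glmm`), `lr` (an `lr_test`), `scaling`.
#' @export
age_experience_model <- function(data) {
  sc <- scale_predictors(data, "max_age_days")
  spec <- model_spec("n_contests", "max_age_days", family = "poisson",
                     olre = TRUE)
  fit <- fit_poisson_olre(spec, sc$data)
  list(fit = fit, lr = drop1_lr(fit, "max_age_days", sc$data), scaling = sc)
}

#' Senior-male age and contest success, with the liability threshold
#'
#' Binomial mixed model of win/lose on scaled senior-male age with a male
#' random intercept. The liability threshold is the age at which the
#' fixed-effect curve predicts P(win) = 0.5, reported in years; when the
#' curve never crosses 0.5 (zero slope) a `crosses = FALSE` flag is
#' returned instead.
#'
#' @param records senior-male records (see [senior_male_datasets()]) or
#'   any data frame with `male_id`, `age_days`, `win` (0/1) or `outcome`.
#' @return list: `fit`, `lr`, `threshold_years`, `crosses`, `scaling`.
#' @export
senior_age_outcome_model <- function(records) {
  df <- records
  if (!"win" %in% names(df)) df$win <- as.integer(df$outcome == "win")
  if (length(unique(df$win)) < 2)
    stop("both outcomes must be present", call. = FALSE)
  sc <- scale_predictors(df, "age_days")
  spec <- model_spec("win", "age_days", random = "male_id",
                     family = "binomial")
  fit <- fit_glmm(spec, sc$data)
  b0 <- fit$beta[["(Intercept)"]]
  b1 <- fit$beta[["age_days"]]
  crosses <- abs(b1) > 1e-8
  thr <- if (crosses) {
    xs <- -b0 / b1
    (xs * sc$scale[["age_days"]] + sc$center[["age_days"]]) / 365.25
  } else NA_real_
  list(fit = fit, lr = drop1_lr(fit, "age_days", sc$data),
       threshold_years = thr, crosses = crosses, scaling = sc)
}

#' Refit the best-fit contest model on single-senior-male contests
#'
#' Subsets the contest data to contests in which the senior-male-holding
#' group has exactly one oldest male, refits the given fixed terms, and
#' reports full-data and subset estimates side by side.
#'
#' @param data contest data frame with scaled predictors, `contest_id`,
#'   `focal_win`, `focal_group_id`, `rival_group_id`.
#' @param roster long roster used to identify senior males.
#' @param terms fixed terms of the best-fit model.
#' @return list: `comparison` (term, full and subset estimates and SEs),
#'   `n_full`, `n_subset`, both fits.
#' @export
single_senior_subset_refit <- function(data, roster, terms) {
  males <- roster[roster$sex == "M", , drop = FALSE]
  single <- vapply(data$contest_id, function(cid) {
    mm <- males[males$contest_id == cid, , drop = FALSE]
    af <- suppressWarnings(max(mm$age_days[mm$side == "focal"]))
    ar <- suppressWarnings(max(mm$age_days[mm$side == "rival"]))
    if (!is.finite(af) || !is.finite(ar) || af == ar) return(FALSE)
    side <- if (af > ar) "focal" else "rival"
    sum(mm$age_days[mm$side == side] == max(af, ar)) == 1
  }, TRUE)
  sub <- data[single, , drop = FALSE]
  if (!nrow(sub)) stop("no single-senior-male contests in the data", call. = FALSE)
  spec <- model_spec("focal_win", terms,
                     random = c("focal_group_id", "rival_group_id"),
                     family = "binomial")
  full_fit <- fit_glmm(spec, data)
  if (nrow(sub) <= length(terms) + 3)
    stop("single-senior subset too small to refit the model", call. = FALSE)
  sub_fit <- fit_glmm(spec, sub)
  comparison <- data.frame(
    term = names(full_fit$beta),
    estimate_full = unname(full_fit$beta), se_full = unname(full_fit$se),
    estimate_subset = unname(sub_fit$beta), se_subset = unname(sub_fit$se),
    row.names = NULL, stringsAsFactors = FALSE)
  list(comparison = comparison, n_full = nrow(data), n_subset = nrow(sub),
       fit_full = full_fit, fit_subset = sub_fit)
}

#' Male eviction probability versus age
#'
#' Binomial mixed model of evicted (0/1) on scaled age with crossed random
#' intercepts for male, group and eviction event.
#'
#' @param data data frame with `individual_id`, `group_id`, `eviction_id`,
#'   `age_days`, `evicted`.
#' @return list: `fit`, `lr`, `scaling`.
#' @export
eviction_model <- function(data) {
  if (!any(data$evicted == 1)) stop("no eviction events", call. = FALSE)
  sc <- scale_predictors(data, "age_days")
  spec <- model_spec("evicted", "age_days",
                     random = c("individual_id", "group_id", "eviction_id"),
                     family = "binomial")
  fit <- fit_glmm(spec, sc$data)
  list(fit = fit, lr = drop1_lr(fit, "age_days", sc$data), scaling = sc)
}

#' Senior-male within-group paternity versus age
#'
#' Binomial mixed model of pups sired out of litter size on scaled senior
#' age with a male random intercept.
#'
#' @param data data frame with `male_id`, `male_age_days`, `sired`,
#'   `litter_size`.
#' @return list: `fit`, `lr`, `scaling`.
#' @export
paternity_model <- function(data) {
  if (any(data$litter_size < 1)) stop("litter sizes must be >= 1", call. = FALSE)
  sc <- scale_predictors(data, "male_age_days")
  spec <- model_spec("sired", "male_age_days", random = "male_id",
                     family = "binomial", size = "litter_size")
  fit <- fit_glmm(spec, sc$data)
  list(fit = fit, lr = drop1_lr(fit, "male_age_days", sc$data), scaling = sc)
}

#' Sexual-dimorphism models for weight and head width
#'
#' Gaussian mixed models `trait ~ sex + (1 | individual)` (ML) with
#' likelihood-ratio tests for sex. Pregnant females are excluded from the
#' weight model by default.
#'
#' @param weight_data data frame with `individual_id`, `sex`, `value`,
#'   optionally `pregnant`.
#' @param head_width_data same structure for head width (optional).
#' @param exclude_pregnant drop pregnant-female weight rows.
#' @return list with `weight` and (optionally) `head_width` components,
#'   each `list(fit, lr)`; the sex coefficient is the male minus female
#'   trait difference.
#' @export
dimorphism_models <- function(weight_data, head_width_data = NULL,
                              exclude_pregnant = TRUE) {
  one <- function(df) {
    if (length(unique(df$sex)) < 2) stop("both sexes required", call. = FALSE)
    if (length(unique(df$individual_id)) < 4)
      stop("insufficient replication across individuals", call. = FALSE)
    df$sex_male <- as.numeric(df$sex == "M")
    spec <- model_spec("value", "sex_male", random = "individual_id",
                       family = "gaussian")
    fit <- fit_glmm(spec, df)
    list(fit = fit, lr = drop1_lr(fit, "sex_male", df))
  }
  wd <- weight_data
  if (exclude_pregnant && "pregnant" %in% names(wd))
    wd <- wd[!(wd$pregnant %in% TRUE), , drop = FALSE]
  out <- list(weight = one(wd))
  if (!is.null(head_width_data)) out$head_width <- one(head_width_data)
  out
}

#' Descriptive senior-male proportions
#'
#' The printed-style summary quantities: how often the senior group has
#' multiple same-age senior males; the winning/losing same-age-mate and
#' dominance proportions; and how often the oldest male is also the
#' heaviest (and, when head widths are supplied, the widest-headed) male
#' of his group.
#'
#' @param records senior-male records from [senior_male_datasets()].
#' @param roster long roster (for within-group weight comparisons).
#' @param head_widths optional head-width table; the most recent
#'   measurement within `window` days of the contest is used.
#' @param window days within which a head-width measurement counts.
#' @return list of proportions, each with numerator, denominator and
#'   value.
#' @export
descriptive_proportions <- function(records, roster, head_widths = NULL,
                                    window = 120) {
  prop <- function(k, n) list(k = k, n = n,
                              value = if (n > 0) k / n else NA_real_)
  per_contest <- unique(records[, c("contest_id", "n_same_age_mates")])
  multi <- tapply(records$n_same_age_mates, records$contest_id, max)
  n_contests <- length(multi)
  win <- records[records$outcome == "win", , drop = FALSE]
  lose <- records[records$outcome == "lose", , drop = FALSE]
  # oldest-also-heaviest within his group's roster for that contest
  males <- roster[roster$sex == "M", , drop = FALSE]
  key <- paste(males$contest_id, males$group_id)
  wsplit <- split(males, key)
  heaviest <- mapply(function(cid, gid, mid) {
    g <- wsplit[[paste(cid, gid)]]
    if (is.null(g) || all(is.na(g$weight_g))) return(NA)
    w <- g$weight_g[g$individual_id == mid]
    if (!length(w) || is.na(w)) return(NA)
    w >= max(g$weight_g, na.rm = TRUE)
  }, records$contest_id, records$group_id, records$male_id)
  out <- list(
    n_senior_records = nrow(records),
    n_contests_with_senior = n_contests,
    multi_senior = prop(sum(multi >= 1), n_contests),
    multi_senior_by_count = table(factor(multi + 1, levels = 1:3)),
    same_age_mates_winning = prop(sum(win$n_same_age_mates), nrow(win)),
    same_age_mates_losing = prop(sum(lose$n_same_age_mates), nrow(lose)),
    dominant_winning = prop(sum(win$dominant), nrow(win)),
    dominant_losing = prop(sum(lose$dominant), nrow(lose)),
    oldest_also_heaviest = prop(sum(heaviest %in% TRUE),
                                sum(!is.na(heaviest))))
  if (!is.null(head_widths) && "date" %in% names(roster)) {
    hw_of <- function(ids, dates) {
      i <- nearest_prior_obs(ids, dates, head_widths$individual_id,
                             as_date(head_widths$date), window)
      out <- rep(NA_real_, length(ids))
      out[!is.na(i)] <- head_widths$head_width_mm[i[!is.na(i)]]
      out
    }
    widest <- mapply(function(cid, gid, mid) {
      g <- wsplit[[paste(cid, gid)]]
      if (is.null(g)) return(NA)
      hw <- hw_of(g$individual_id, as_date(g$date))
      mine <- hw[g$individual_id == mid]
      if (!length(mine) || is.na(mine) || all(is.na(hw))) return(NA)
      mine >= max(hw, na.rm = TRUE)
    }, records$contest_id, records$group_id, records$male_id)
    out$oldest_also_widest <- prop(sum(widest %in% TRUE),
                                   sum(!is.na(widest)))
  }
  out
}
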