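# Truncated-normal imputation of missing contest weights from same-group,
# same-sex, near-age reference individuals.

#' Imputation configuration
#'
#' @param max_missing_fraction a group's roster may have at most this
#'   fraction of members with missing weight ("20% or less" rule; the
#'   boundary is inclusive).
#' @param age_window half-width in days of the reference age band (a
#'   reference must be between `age_window` days younger and `age_window`
#'   days older than the target).
#' @param weight_window days before the contest within which reference
#'   weights must have been observed (already enforced during roster
#'   construction).
#' @param truncation bounds rule for the sampling distribution:
#'   `"reference-range"` truncates at the min and max of the reference
#'   weights (guarantees biologically plausible draws), `"nonnegative"`
#'   truncates at zero only, `"none"` does not truncate.
#' @param reference_mode `"history"` (default): references are age-matched
#'   observations from the group's weight history -- observations of
#'   same-group, same-sex individuals taken when *they* were within the
#'   age window of the target's current age. `"contemporary"`: references
#'   are the target's current roster mates within the age window, using
#'   their roster weights.
#' @return an `imputation_config` object.
#' @export
imputation_config <- function(max_missing_fraction = 0.2, age_window = 60,
                              weight_window = 120,
                              truncation = c("reference-range",
                                             "nonnegative", "none"),
                              reference_mode = c("history", "contemporary")) {
  structure(list(
    max_missing_fraction = assert_number(max_missing_fraction,
                                         "max_missing_fraction", 0, 1,
                                         open_lower = TRUE, open_upper = TRUE),
    age_window = assert_number(age_window, "age_window", 0, open_lower = TRUE),
    weight_window = assert_number(weight_window, "weight_window", 0,
                                  open_lower = TRUE),
    truncation = match.arg(truncation),
    reference_mode = match.arg(reference_mode)), class = "imputation_config")
}

#' Per-group weight history with observation ages
#'
#' Joins the weight observations with individual sex and group membership
#' and computes each individual's age at each observation — the lookup
#' table behind history-mode imputation references.
#'
#' @param tables data model tables (`weights`, `individuals`,
#'   `memberships`).
#' @return data frame: `individual_id`, `group_id`, `sex`, `obs_age_days`,
#'   `weight_g`, `pregnant`.
#' @export
weight_history <- function(tables) {
  w <- merge(tables$weights,
             tables$individuals[, c("individual_id", "sex", "birth_date",
                                    "immigrant", "immigration_date")],
             by = "individual_id")
  w <- merge(w, tables$memberships[, c("individual_id", "group_id",
                                       "start_date", "end_date")],
             by = "individual_id")
  w <- w[as_date(w$start_date) <= as_date(w$date) &
           as_date(w$date) <= as_date(w$end_date), , drop = FALSE]
  w$obs_age_days <- compute_age(w, as_date(w$date))
  out <- w[, c("individual_id", "group_id", "sex", "obs_age_days",
               "weight_g", "pregnant")]
  out[order(out$group_id, out$sex, out$obs_age_days), ]
}

#' Missing-weight eligibility of contests
#'
#' A contest stays in the dataset only when, for both groups, the fraction
#' of roster members with missing weight is at most
#' `max_missing_fraction`.
#'
#' @param roster long roster from [build_rosters()].
#' @param config an [imputation_config()].
#' @return data frame with `contest_id`, `side`, `missing_fraction`,
#'   `eligible` (per side), plus attribute `eligible_contests`.
#' @export
roster_eligibility <- function(roster, config = imputation_config()) {
  if (!nrow(roster)) stop("empty roster", call. = FALSE)
  agg <- aggregate(list(missing_fraction = is.na(roster$weight_g)),
                   by = list(contest_id = roster$contest_id,
                             side = roster$side), FUN = mean)
  agg$eligible <- agg$missing_fraction <= config$max_missing_fraction
  keep <- tapply(agg$eligible, agg$contest_id, all)
  attr(agg, "eligible_contests") <- names(keep)[as.vector(keep)]
  agg
}

#' Reference weights for one missing-weight member
#'
#' In `"history"` mode (default) the references are weight observations of
#' other same-group, same-sex individuals (same pregnancy status for
#' females) taken when the observed individual's age was within
#' `age_window` days of the target's age at the contest; when a reference
#' individual has several observations in the band, the one nearest the
#' target's age is used. In `"contemporary"` mode the references are the
#' target's current roster mates within the age window, using their roster
#' weights (each already the nearest observation within the weight
#' window).
#'
#' @param roster_side one side's roster data frame for one contest.
#' @param target_id individual id of the member with missing weight.
#' @param config an [imputation_config()].
#' @param history [weight_history()] table (required for `"history"`
#'   mode).
#' @return numeric vector of reference weights (possibly empty).
#' @export
reference_set <- function(roster_side, target_id,
                          config = imputation_config(), history = NULL) {
  t <- roster_side[roster_side$individual_id == target_id, , drop = FALSE]
  if (nrow(t) != 1) stop("target not found in roster side", call. = FALSE)
  if (config$reference_mode == "history") {
    if (is.null(history))
      stop("history-mode reference sets need a weight_history() table",
           call. = FALSE)
    cand <- history[history$group_id == t$group_id &
                      history$sex == t$sex &
                      history$individual_id != target_id &
                      abs(history$obs_age_days - t$age_days) <=
                        config$age_window, , drop = FALSE]
    if (t$sex == "F")
      cand <- cand[cand$pregnant %in% t$pregnant, , drop = FALSE]
    if (!nrow(cand)) return(numeric(0))
    # nearest-in-age observation per reference individual
    cand <- cand[order(cand$individual_id,
                       abs(cand$obs_age_days - t$age_days)), ]
    cand$weight_g[!duplicated(cand$individual_id)]
  } else {
    cand <- roster_side[roster_side$individual_id != target_id &
                          roster_side$sex == t$sex &
                          !is.na(roster_side$weight_g) &
                          abs(roster_side$age_days - t$age_days) <=
                            config$age_window, , drop = FALSE]
    if (t$sex == "F")
      cand <- cand[cand$pregnant %in% t$pregnant, , drop = FALSE]
    cand$weight_g
  }
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampling; parameterized by the mean and SD of the
#' *untruncated* normal.
#'
#' @param n number of draws.
#' @param mean,sd untruncated mean and SD (vectorized).
#' @param lower,upper truncation bounds (vectorized; may be infinite).
#' @return numeric vector of draws, all within `[lower, upper]`.
#' @export
sample_truncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(upper < lower)) stop("inverted truncation bounds", call. = FALSE)
  sd0 <- sd <= 0
  pl <- pnorm(lower, mean, pmax(sd, .Machine$double.eps))
  pu <- pnorm(upper, mean, pmax(sd, .Machine$double.eps))
  x <- qnorm(pl + runif(n) * (pu - pl), mean, pmax(sd, .Machine$double.eps))
  x <- pmin(pmax(x, lower), upper)  # guard the extreme tails
  if (any(sd0)) x[sd0] <- pmin(pmax(mean, lower), upper)[sd0]
  x
}

# Precompute everything an imputation pass needs so repeated draws are
# cheap: which contests survive the missing-fraction rule and have
# non-empty reference sets, and per missing member the reference moments
# and truncation bounds.
prepare_imputation <- function(roster, config = imputation_config(),
                               history = NULL) {
  if (config$reference_mode == "history" && is.null(history))
    stop("history-mode imputation needs a weight_history() table",
         call. = FALSE)
  elig <- roster_eligibility(roster, config)
  keep_ids <- attr(elig, "eligible_contests")
  dropped_missing <- setdiff(unique(roster$contest_id), keep_ids)
  sub <- roster[roster$contest_id %in% keep_ids, , drop = FALSE]
  rownames(sub) <- NULL
  miss <- which(is.na(sub$weight_g))
  stats <- matrix(NA_real_, length(miss), 5,
                  dimnames = list(NULL, c("n", "mean", "sd", "lo", "hi")))
  skey <- paste(sub$contest_id, sub$side)
  side_split <- split(seq_len(nrow(sub)), skey)
  for (j in seq_along(miss)) {
    i <- miss[j]
    rows <- side_split[[paste(sub$contest_id[i], sub$side[i])]]
    side_df <- sub[rows, , drop = FALSE]
    refs <- reference_set(side_df, sub$individual_id[i], config, history)
    if (length(refs))
      stats[j, ] <- c(length(refs), mean(refs),
                      if (length(refs) > 1) sd(refs) else 0,
                      min(refs), max(refs))
  }
  no_ref <- miss[is.na(stats[, "n"])]
  dropped_noref <- unique(sub$contest_id[no_ref])
  keep2 <- !(sub$contest_id %in% dropped_noref)
  keep_rows <- which(keep2)
  sel <- sub$contest_id[miss] %in% setdiff(unique(sub$contest_id), dropped_noref)
  structure(list(
    roster = sub[keep2, , drop = FALSE],
    miss_rows = match(miss[sel], keep_rows),
    stats = stats[sel, , drop = FALSE],
    contests_kept = setdiff(keep_ids, dropped_noref),
    dropped = data.frame(
      contest_id = c(dropped_missing, dropped_noref),
      reason = rep(c("missing fraction above threshold",
                     "empty reference set"),
                   c(length(dropped_missing), length(dropped_noref))),
      stringsAsFactors = FALSE),
    truncation = config$truncation), class = "imputation_prep")
}

# one vector of imputed weights for the prepared missing members
impute_draws <- function(prep, seed) {
  with_seed(seed, {
    s <- prep$stats
    if (!nrow(s)) return(numeric(0))
    bounds <- switch(prep$truncation,
      "reference-range" = list(lo = s[, "lo"], hi = s[, "hi"]),
      "nonnegative" = list(lo = rep(0, nrow(s)), hi = rep(Inf, nrow(s))),
      "none" = list(lo = rep(-Inf, nrow(s)), hi = rep(Inf, nrow(s))))
    draws <- sample_truncnorm(nrow(s), s[, "mean"], s[, "sd"],
                              bounds$lo, bounds$hi)
    single <- s[, "n"] == 1
    draws[single] <- s[single, "mean"]  # lone reference used verbatim
    draws
  })
}

#' Impute missing contest weights
#'
#' For each contest surviving the missing-fraction rule, every missing
#' weight is replaced by one draw from a truncated normal whose mean and
#' SD are those of the member's reference set (see [reference_set()]) and
#' whose bounds follow the configured truncation rule. A reference set of
#' size one is used verbatim (its SD is undefined). Contests in which any
#' missing member has an empty reference set are dropped and logged.
#' Observed weights are never modified; results are reproducible from
#' `seed`.
#'
#' @param roster long roster from [build_rosters()].
#' @param config an [imputation_config()].
#' @param seed integer seed for the draws.
#' @param history [weight_history()] table (required for `"history"`
#'   reference mode).
#' @return list: `roster` (completed, only retained contests), `draws`
#'   (audit log: contest, individual, imputed value, reference n/mean/sd),
#'   `dropped` (contest ids with reasons).
#' @export
impute_rosters <- function(roster, config = imputation_config(), seed = 1L,
                           history = NULL) {
  prep <- prepare_imputation(roster, config, history)
  vals <- impute_draws(prep, seed)
  out <- prep$roster
  out$weight_g[prep$miss_rows] <- vals
  log <- data.frame(
    contest_id = prep$roster$contest_id[prep$miss_rows],
    individual_id = prep$roster$individual_id[prep$miss_rows],
    imputed_weight_g = vals,
    reference_n = prep$stats[, "n"],
    reference_mean = prep$stats[, "mean"],
    reference_sd = prep$stats[, "sd"],
    stringsAsFactors = FALSE)
  list(roster = out, draws = log, dropped = prep$dropped)
}

#' Compare growth curves before and after imputation
#'
#' Fits the three-parameter asymptotic growth curve to each group's
#' (age, weight) data without and with imputed values and reports the
#' parameter estimates, their differences and whether each difference is
#' within two joint standard errors (the imputation-validity check).
#'
#' @param pre data frame with `group_id`, `age_days`, `weight_g`
#'   (imputed members excluded).
#' @param post same, with imputed values included.
#' @return data frame, one row per group and parameter, with estimates,
#'   SEs, `diff`, `joint_se`, `within_2se`, and a `converged` flag.
#' @export
validate_growth <- function(pre, post) {
  groups <- sort(unique(c(pre$group_id, post$group_id)))
  out <- list()
  for (g in groups) {
    a <- fit_growth_curve(pre$age_days[pre$group_id == g],
                          pre$weight_g[pre$group_id == g])
    b <- fit_growth_curve(post$age_days[post$group_id == g],
                          post$weight_g[post$group_id == g])
    conv <- isTRUE(a$converged) && isTRUE(b$converged)
    for (p in c("lower_limit", "asymptote", "rate_scale")) {
      if (conv) {
        d <- b[[p]] - a[[p]]
        jse <- sqrt(a[[paste0("se_", p)]]^2 + b[[paste0("se_", p)]]^2)
        out[[length(out) + 1]] <- data.frame(
          group_id = g, parameter = p, converged = TRUE,
          est_pre = a[[p]], est_post = b[[p]],
          se_pre = a[[paste0("se_", p)]], se_post = b[[paste0("se_", p)]],
          diff = d, joint_se = jse,
          within_2se = is.finite(jse) && abs(d) < 2 * jse,
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1]] <- data.frame(
          group_id = g, parameter = p, converged = FALSE,
          est_pre = NA_real_, est_post = NA_real_, se_pre = NA_real_,
          se_post = NA_real_, diff = NA_real_, joint_se = NA_real_,
          within_2se = NA, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
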