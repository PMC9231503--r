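# Tabular data model: schemas, CSV round-trip, per-contest rosters and
# relative predictors.

# column types for each table; dates are ISO-8601 in the CSV files
.schemas <- list(
  individuals = c(individual_id = "character", sex = "character",
                  birth_date = "Date", immigrant = "logical",
                  immigration_date = "Date"),
  memberships = c(individual_id = "character", group_id = "character",
                  start_date = "Date", end_date = "Date"),
  weights = c(individual_id = "character", date = "Date",
              weight_g = "numeric", pregnant = "logical"),
  head_widths = c(individual_id = "character", date = "Date",
                  head_width_mm = "numeric"),
  contests = c(contest_id = "character", date = "Date",
               focal_group_id = "character", rival_group_id = "character",
               focal_win = "integer"),
  mateguard_events = c(individual_id = "character", date = "Date"),
  evictions = c(eviction_id = "character", date = "Date",
                group_id = "character", individual_id = "character",
                evicted = "integer"),
  litters = c(litter_id = "character", date = "Date", group_id = "character",
              male_id = "character", male_age_days = "numeric",
              sired = "integer", litter_size = "integer")
)

#' Names of the fifteen relative predictors
#'
#' Focal-minus-rival differences of five group summaries (member count,
#' mean and maximum weight, mean and maximum age) for three member
#' classes: all adults, males, and subordinate males.
#'
#' @return character vector of length 15.
#' @export
predictor_names <- function() {
  as.vector(t(outer(c("all", "males", "submales"),
                    c("rel_n", "rel_mean_weight", "rel_max_weight",
                      "rel_mean_age", "rel_max_age"),
                    function(cl, m) paste0(m, "_", cl))))
}

#' Write the tabular data model to CSV files
#'
#' One file per table, ISO-8601 dates. [read_contest_tables()] restores the
#' tables exactly.
#'
#' @param tables named list of data frames (any subset of the schema names).
#' @param dir output directory, created if absent.
#' @return invisibly, the written file paths.
#' @export
write_contest_tables <- function(tables, dir) {
  stopifnot(is.list(tables))
  unknown <- setdiff(names(tables), names(.schemas))
  if (length(unknown))
    stop("unknown table(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (col in names(.schemas[[nm]]))
      if (.schemas[[nm]][[col]] == "Date" && col %in% names(df))
        df[[col]] <- format(as_date(df[[col]]), "%Y-%m-%d")
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read the tabular data model from CSV files
#'
#' @param dir directory holding files written by [write_contest_tables()].
#' @return named list of data frames with schema column types restored.
#' @export
read_contest_tables <- function(dir) {
  out <- list()
  for (nm in names(.schemas)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) next
    sch <- .schemas[[nm]]
    cls <- ifelse(sch == "Date", "character", sch)
    df <- read.csv(p, colClasses = NA, stringsAsFactors = FALSE)
    for (col in names(sch)) {
      if (!col %in% names(df)) next
      df[[col]] <- switch(sch[[col]],
        Date = as.Date(df[[col]]),
        logical = as.logical(df[[col]]),
        integer = as.integer(df[[col]]),
        numeric = as.numeric(df[[col]]),
        character = as.character(df[[col]]))
    }
    out[[nm]] <- df
  }
  out
}

#' Age of individuals on a given date
#'
#' Natives: days since birth. Immigrants (birth date unknown in the field
#' data) are assumed to be 2 years (730 days) old on the date of their
#' immigration, so age is `730 + days since immigration`.
#'
#' @param individuals data frame with columns `birth_date`, `immigrant`,
#'   `immigration_date` (rows are recycled against `on_date`).
#' @param on_date date(s) on which to compute ages.
#' @return integer ages in days.
#' @export
compute_age <- function(individuals, on_date) {
  on_date <- as_date(on_date)
  imm <- individuals$immigrant %in% TRUE
  age <- as.integer(on_date - as_date(individuals$birth_date))
  if (any(imm)) {
    since <- as.integer(on_date[if (length(on_date) > 1) imm else TRUE] -
                          as_date(individuals$immigration_date[imm]))
    if (any(is.na(since)) || any(since < 0))
      stop("date before immigration for an immigrant individual", call. = FALSE)
    age[imm] <- 730L + since
  }
  if (any(is.na(age[!imm])) || any(age[!imm] < 0))
    stop("date before birth for a native individual", call. = FALSE)
  age
}

# nearest prior observation lookup: for each (id, date) query, the index in
# `obs` (id, date sorted within id) of the latest observation with
# obs_date <= date and date - obs_date <= window; NA when none qualifies
nearest_prior_obs <- function(query_id, query_date, obs_id, obs_date, window) {
  n <- length(query_id)
  res <- rep(NA_integer_, n)
  ord <- order(obs_id, obs_date)
  obs_id <- obs_id[ord]; obs_date <- obs_date[ord]
  qsplit <- split(seq_len(n), query_id)
  osplit <- split(seq_along(obs_id), obs_id)
  for (id in names(qsplit)) {
    oi <- osplit[[id]]
    if (is.null(oi)) next
    qi <- qsplit[[id]]
    pos <- findInterval(as.numeric(query_date[qi]), as.numeric(obs_date[oi]))
    ok <- pos >= 1
    ok[ok] <- (as.numeric(query_date[qi][ok]) -
                 as.numeric(obs_date[oi][pos[ok]])) <= window
    res[qi[ok]] <- ord[oi[pos[ok]]]
  }
  res
}

#' Build per-contest group rosters
#'
#' For every contest and both groups, lists the adult members (age > 183
#' days) with their sex, age, dominance status and most recent usable
#' weight. A weight is attached only when the individual was weighed within
#' `weight_window` days before (or on) the contest date; otherwise it is
#' missing. A male is dominant when he has a mate-guarding event within
#' `dominance_window` days before (or on) the contest date.
#'
#' @param tables list with `individuals`, `memberships`, `weights`,
#'   `contests` and optionally `mateguard_events` data frames.
#' @param contests optional subset of contests (defaults to
#'   `tables$contests`).
#' @param adult_age_days adulthood threshold in days (exclusive).
#' @param weight_window days before the contest within which a weight
#'   observation is usable (closed interval).
#' @param dominance_window days before the contest within which a
#'   mate-guarding event confers dominance (closed interval).
#' @return data frame (long roster) with one row per contest, side and
#'   member: `contest_id`, `group_id`, `side`, `individual_id`, `sex`,
#'   `age_days`, `dominant`, `weight_g`, `weight_obs_date`, `pregnant`.
#' @export
build_rosters <- function(tables, contests = NULL, adult_age_days = 183,
                          weight_window = 120, dominance_window = 180) {
  contests <- contests %||% tables$contests
  stopifnot(!is.null(contests), !is.null(tables$individuals),
            !is.null(tables$memberships), !is.null(tables$weights))
  if (any(contests$focal_group_id == contests$rival_group_id))
    stop("focal and rival group must differ", call. = FALSE)
  pairs <- rbind(
    data.frame(contest_id = contests$contest_id, date = as_date(contests$date),
               group_id = contests$focal_group_id, side = "focal",
               stringsAsFactors = FALSE),
    data.frame(contest_id = contests$contest_id, date = as_date(contests$date),
               group_id = contests$rival_group_id, side = "rival",
               stringsAsFactors = FALSE))
  mem <- tables$memberships
  long <- merge(pairs, mem, by = "group_id")
  long <- long[as_date(long$start_date) <= long$date &
                 long$date <= as_date(long$end_date), , drop = FALSE]
  ind <- tables$individuals
  long <- merge(long, ind[, c("individual_id", "sex", "birth_date",
                              "immigrant", "immigration_date")],
                by = "individual_id")
  long$age_days <- compute_age(long, long$date)
  long <- long[long$age_days > adult_age_days, , drop = FALSE]
  # weights: nearest observation within the window before the contest
  w <- tables$weights
  wi <- nearest_prior_obs(long$individual_id, long$date,
                          w$individual_id, as_date(w$date), weight_window)
  has <- !is.na(wi)
  long$weight_g <- NA_real_
  long$weight_g[has] <- w$weight_g[wi[has]]
  long$weight_obs_date <- as_date(rep(NA, nrow(long)))
  long$weight_obs_date[has] <- as_date(w$date)[wi[has]]
  long$pregnant <- FALSE
  long$pregnant[has] <- w$pregnant[wi[has]] %in% TRUE
  long$pregnant <- long$pregnant & long$sex == "F"
  # dominance from mate-guarding events
  long$dominant <- FALSE
  mg <- tables$mateguard_events
  if (!is.null(mg) && nrow(mg)) {
    di <- nearest_prior_obs(long$individual_id, long$date,
                            mg$individual_id, as_date(mg$date),
                            dominance_window)
    long$dominant <- !is.na(di) & long$sex == "M"
  }
  long <- long[order(long$contest_id, long$side, long$individual_id),
               c("contest_id", "group_id", "side", "date", "individual_id",
                 "sex", "age_days", "dominant", "weight_g",
                 "weight_obs_date", "pregnant")]
  rownames(long) <- NULL
  long
}

#' Roster for a single contest
#'
#' @inheritParams build_rosters
#' @param contest one-row data frame (a row of the contests table).
#' @return list with `focal` and `rival` roster data frames.
#' @export
build_roster <- function(tables, contest, ...) {
  long <- build_rosters(tables, contests = contest, ...)
  list(focal = long[long$side == "focal", , drop = FALSE],
       rival = long[long$side == "rival", , drop = FALSE])
}

#' Contest eligibility from rosters
#'
#' A contest enters the analysis only when each of the two groups has at
#' least one male and at least one subordinate male on the contest date.
#'
#' @param roster long roster from [build_rosters()].
#' @return data frame with `contest_id`, `eligible`, and per-side male and
#'   subordinate-male counts.
#' @export
contest_eligibility <- function(roster) {
  per_side <- aggregate(
    cbind(n_males = roster$sex == "M",
          n_submales = roster$sex == "M" & !roster$dominant),
    by = list(contest_id = roster$contest_id, side = roster$side), FUN = sum)
  ok <- tapply(per_side$n_males >= 1 & per_side$n_submales >= 1,
               per_side$contest_id, all)
  sides <- tapply(per_side$side, per_side$contest_id, length)
  data.frame(contest_id = names(ok),
             eligible = as.vector(ok) & as.vector(sides) == 2,
             stringsAsFactors = FALSE)
}

# group summaries for one member class of one roster side
.class_summary <- function(members) {
  if (!nrow(members))
    return(c(n = 0, mean_weight = NA_real_, max_weight = NA_real_,
             mean_age = NA_real_, max_age = NA_real_))
  c(n = nrow(members),
    mean_weight = mean(members$weight_g),
    max_weight = max(members$weight_g),
    mean_age = mean(members$age_days),
    max_age = max(members$age_days))
}

#' Relative (focal minus rival) predictors for one contest
#'
#' Fifteen values: for each member class (all adults, males, subordinate
#' males), the focal-minus-rival difference in member count, mean weight,
#' maximum weight, mean age and maximum age. Requires complete weights
#' (impute first); antisymmetric under focal/rival swap.
#'
#' @param focal,rival roster data frames (one side each) from
#'   [build_roster()].
#' @return named numeric vector of length 15 (see [predictor_names()]).
#' @export
relative_predictors <- function(focal, rival) {
  if (anyNA(focal$weight_g) || anyNA(rival$weight_g))
    stop("rosters contain missing weights; impute them first (see impute_rosters)",
         call. = FALSE)
  out <- numeric(0)
  for (cl in c("all", "males", "submales")) {
    pick <- switch(cl,
      all = function(df) df,
      males = function(df) df[df$sex == "M", , drop = FALSE],
      submales = function(df) df[df$sex == "M" & !df$dominant, , drop = FALSE])
    s <- .class_summary(pick(focal)) - .class_summary(pick(rival))
    names(s) <- paste0(c("rel_n", "rel_mean_weight", "rel_max_weight",
                         "rel_mean_age", "rel_max_age"), "_", cl)
    out <- c(out, s)
  }
  out[predictor_names()]
}

#' Relative predictors for every contest in a long roster
#'
#' Vectorized equivalent of [relative_predictors()] applied per contest.
#'
#' @param roster long roster from [build_rosters()] with complete weights.
#' @param contest_ids optional ordering of contests for the result rows.
#' @return numeric matrix, one row per contest, 15 predictor columns;
#'   rownames are contest ids.
#' @export
predictor_matrix <- function(roster, contest_ids = NULL) {
  if (anyNA(roster$weight_g))
    stop("roster contains missing weights; impute them first (see impute_rosters)",
         call. = FALSE)
  contest_ids <- contest_ids %||% unique(roster$contest_id)
  cmat <- matrix(NA_real_, nrow = length(contest_ids), ncol = 15,
                 dimnames = list(contest_ids, predictor_names()))
  sgn <- ifelse(roster$side == "focal", 1, -1)
  for (cl in c("all", "males", "submales")) {
    keep <- switch(cl, all = rep(TRUE, nrow(roster)),
                   males = roster$sex == "M",
                   submales = roster$sex == "M" & !roster$dominant)
    sub <- roster[keep, , drop = FALSE]
    ssgn <- sgn[keep]
    key <- factor(sub$contest_id, levels = contest_ids)
    skey <- interaction(key, sub$side, drop = FALSE)
    n <- tapply(rep(1, nrow(sub)), skey, sum, default = 0)
    mw <- tapply(sub$weight_g, skey, mean)
    xw <- tapply(sub$weight_g, skey, max)
    ma <- tapply(sub$age_days, skey, mean)
    xa <- tapply(sub$age_days, skey, max)
    take <- function(v) {
      m <- matrix(v, ncol = 2)  # columns: focal, rival (interaction order)
      m[, 1] - m[, 2]
    }
    cmat[, paste0("rel_n_", cl)] <- take(n)
    cmat[, paste0("rel_mean_weight_", cl)] <- take(mw)
    cmat[, paste0("rel_max_weight_", cl)] <- take(xw)
    cmat[, paste0("rel_mean_age_", cl)] <- take(ma)
    cmat[, paste0("rel_max_age_", cl)] <- take(xa)
  }
  cmat
}

#' Randomize focal/rival labels
#'
#' Each contest keeps or swaps its focal/rival labels with probability 1/2;
#' on a swap the recorded outcome is flipped. Reproducible from `seed`.
#'
#' @param contests contests data frame.
#' @param seed integer seed.
#' @return contests data frame with randomized labels.
#' @export
assign_focal <- function(contests, seed) {
  with_seed(seed, {
    swap <- runif(nrow(contests)) < 0.5
    out <- contests
    out$focal_group_id[swap] <- contests$rival_group_id[swap]
    out$rival_group_id[swap] <- contests$focal_group_id[swap]
    out$focal_win[swap] <- 1L - contests$focal_win[swap]
    out
  })
}
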