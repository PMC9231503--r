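# small hand-built tables for boundary tests; larger inputs come from the
# package's own generators

tiny_tables <- function() {
  individuals <- data.frame(
    individual_id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "IM1"),
    sex = c("M", "M", "F", "F", "M", "M", "F", "M"),
    birth_date = as.Date(c("2010-01-01", "2010-01-01", "2012-04-01",
                           "2016-06-01", "2009-06-15", "2013-01-01",
                           "2011-03-01", "2014-06-01")),
    immigrant = c(rep(FALSE, 7), TRUE),
    immigration_date = as.Date(c(rep(NA, 7), "2016-06-01")),
    stringsAsFactors = FALSE)
  memberships <- data.frame(
    individual_id = individuals$individual_id,
    group_id = c(rep("GA", 4), rep("GB", 3), "GB"),
    start_date = c(individuals$birth_date[1:7],
                   individuals$immigration_date[8]),
    end_date = as.Date("2020-12-31"),
    stringsAsFactors = FALSE)
  weights <- data.frame(
    individual_id = c("A1", "A2", "A3", "B1", "B2", "IM1"),
    date = as.Date(c("2016-12-20", "2016-09-02", "2016-12-01",
                     "2016-11-15", "2016-12-30", "2016-10-01")),
    weight_g = c(1500, 1400, 1300, 1550, 1350, 1420),
    pregnant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  mateguard_events <- data.frame(
    individual_id = c("A1", "B1"),
    date = as.Date(c("2016-07-06", "2015-01-01")),  # 179 d and long before
    stringsAsFactors = FALSE)
  contests <- data.frame(
    contest_id = "C1", date = as.Date("2017-01-01"),
    focal_group_id = "GA", rival_group_id = "GB", focal_win = 1L,
    stringsAsFactors = FALSE)
  list(individuals = individuals, memberships = memberships,
       weights = weights, mateguard_events = mateguard_events,
       contests = contests)
}

# a small complete-weight roster pair for predictor arithmetic
toy_roster_pair <- function() {
  focal <- data.frame(
    contest_id = "C1", group_id = "G1", side = "focal",
    individual_id = paste0("F", 1:4),
    sex = c("M", "M", "F", "F"),
    age_days = c(3000, 1000, 2000, 800),
    dominant = c(TRUE, FALSE, FALSE, FALSE),
    weight_g = c(1500, 1300, 1250, 1100),
    pregnant = FALSE, stringsAsFactors = FALSE)
  rival <- data.frame(
    contest_id = "C1", group_id = "G2", side = "rival",
    individual_id = paste0("R", 1:3),
    sex = c("M", "M", "F"),
    age_days = c(2500, 1500, 1800),
    dominant = c(FALSE, FALSE, FALSE),
    weight_g = c(1450, 1350, 1200),
    pregnant = FALSE, stringsAsFactors = FALSE)
  list(focal = focal, rival = rival)
}

# quick synthetic contest dataset with scaled predictors, bypassing rosters:
# predictors drawn directly, outcome from the stated logistic model
direct_contest_data <- function(n = 300, beta = c(rel_n_males = 1),
                                ability_sd = 0, n_groups = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, predictor_names()))
  f <- sample(n_groups, n, TRUE)
  r <- vapply(f, function(g) sample(setdiff(seq_len(n_groups), g), 1), 1L)
  a <- rnorm(n_groups, 0, ability_sd)
  eta <- drop(scale(X[, names(beta), drop = FALSE]) %*% beta) + a[f] - a[r]
  data.frame(focal_win = rbinom(n, 1, plogis(eta)),
             focal_group_id = sprintf("G%02d", f),
             rival_group_id = sprintf("G%02d", r),
             scale(X))
}
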