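# The repeated imputation x model-selection loop, the cross-iteration
# occurrence filter, and percentile aggregation.

#' Iteration configuration
#'
#' @param n_iterations imputation/model-selection iterations (the field
#'   analysis used 10,000; validation runs use a few hundred).
#' @param occurrence_min_fraction retain a model only if it appears in the
#'   post-nesting set in at least this fraction of iterations (inclusive:
#'   models occurring in *fewer than* 50% of iterations are removed).
#' @param percentiles reported percentile levels.
#' @param base_seed seed from which each iteration's seed is derived (see
#'   [derive_seed()]); iterations are order-independent.
#' @param max_skip_fraction error out if more than this fraction of
#'   iterations fail (no converged candidate).
#' @return an `iteration_config` object.
#' @export
iteration_config <- function(n_iterations = 200,
                             occurrence_min_fraction = 0.5,
                             percentiles = c(2.5, 50, 97.5),
                             base_seed = 1L, max_skip_fraction = 0.01) {
  structure(list(
    n_iterations = assert_count(n_iterations, "n_iterations"),
    occurrence_min_fraction = assert_number(occurrence_min_fraction,
                                            "occurrence_min_fraction", 0, 1,
                                            open_lower = TRUE),
    percentiles = sort(percentiles),
    base_seed = assert_count(base_seed, "base_seed", min = 0L),
    max_skip_fraction = assert_number(max_skip_fraction, "max_skip_fraction",
                                      0, 1)), class = "iteration_config")
}

#' Prepare contest data for the iterated analysis
#'
#' Randomizes focal/rival labels (once; imputation is the only
#' per-iteration randomness), builds rosters, applies the male /
#' subordinate-male eligibility rule and the missing-fraction rule, and
#' precomputes the reference-set statistics and aggregation indices that
#' make repeated imputation passes cheap.
#'
#' @param tables data model tables (see [build_rosters()]).
#' @param imp_config an [imputation_config()].
#' @param focal_seed seed for focal/rival randomization (NULL keeps the
#'   recorded labels).
#' @param roster optionally, a prebuilt long roster (with missingness) to
#'   use instead of rebuilding from `tables`.
#' @return a `contest_prep` object.
#' @export
prepare_contest_data <- function(tables, imp_config = imputation_config(),
                                 focal_seed = NULL, roster = NULL) {
  contests <- tables$contests
  if (!is.null(focal_seed)) contests <- assign_focal(contests, focal_seed)
  if (is.null(roster)) roster <- build_rosters(tables, contests)
  elig <- contest_eligibility(roster)
  ok_ids <- elig$contest_id[elig$eligible]
  roster <- roster[roster$contest_id %in% ok_ids, , drop = FALSE]
  history <- if (imp_config$reference_mode == "history")
    weight_history(tables)
  prep <- prepare_imputation(roster, imp_config, history)
  contests <- contests[contests$contest_id %in% prep$contests_kept, ,
                       drop = FALSE]
  contests <- contests[order(contests$contest_id), , drop = FALSE]
  ros <- prep$roster
  nc <- nrow(contests)
  # (contest, side) enumeration: focal = 2i-1, rival = 2i
  cix <- match(ros$contest_id, contests$contest_id)
  gidx <- 2L * cix - (ros$side == "focal")
  classes <- list(all = rep(TRUE, nrow(ros)),
                  males = ros$sex == "M",
                  submales = ros$sex == "M" & !ros$dominant)
  # padded row-index matrices for fast per-iteration weight aggregates
  wmach <- lapply(classes, function(mask) {
    rows <- which(mask)
    g <- gidx[rows]
    counts <- tabulate(g, 2L * nc)
    maxm <- max(counts)
    im <- matrix(0L, 2L * nc, maxm)
    pos <- integer(2L * nc)
    for (r in seq_along(rows)) {
      gg <- g[r]
      pos[gg] <- pos[gg] + 1L
      im[gg, pos[gg]] <- rows[r]
    }
    list(idx = im, counts = counts)
  })
  # constant predictor columns: counts and ages never change
  const_cols <- matrix(NA_real_, nc, 9)
  colnames(const_cols) <- as.vector(outer(c("rel_n", "rel_mean_age",
                                            "rel_max_age"),
                                          names(classes), paste, sep = "_"))
  for (cl in names(classes)) {
    mach <- wmach[[cl]]
    cnt <- mach$counts
    asum <- .group_sums(ros$age_days, mach$idx)
    amax <- .group_maxs(ros$age_days, mach$idx)
    dif <- function(v) v[seq(1, 2 * nc, 2)] - v[seq(2, 2 * nc, 2)]
    const_cols[, paste0("rel_n_", cl)] <- dif(cnt)
    const_cols[, paste0("rel_mean_age_", cl)] <- dif(asum / pmax(cnt, 1))
    const_cols[, paste0("rel_max_age_", cl)] <- dif(amax)
  }
  structure(list(contests = contests, roster = ros, imp = prep,
                 imp_config = imp_config, wmach = wmach,
                 const_cols = const_cols, n_contests = nc),
            class = "contest_prep")
}

# lean candidate fitting for the hot loop: prebuilt design columns and
# factor codes, warm-started (psi, u, BFGS curvature) per candidate,
# no SE/vcov computation
.fit_candidates_fast <- function(Ps, y, fidx, q, candidates, warm) {
  n <- length(y)
  m <- rep(1, n)
  nono <- integer(0)
  out <- vector("list", length(candidates))
  keys <- vapply(candidates, term_key, "")
  for (i in seq_along(candidates)) {
    terms <- candidates[[i]]
    X <- cbind(1, Ps[, terms, drop = FALSE])
    key <- digest_key(keys[i])
    ws <- warm[[key]]
    d <- ncol(X) + length(q)
    psi0 <- if (!is.null(ws) && length(ws$psi) == d) ws$psi else
      c(rep(0, ncol(X)), rep(log(0.5), length(q)))
    fit <- glmm_laplace_cpp(X, y, m, fidx, q, 0L, psi0,
                            ws$u %||% numeric(0), nono,
                            ws$B %||% matrix(0, 0, 0), TRUE)
    warm[[key]] <- list(psi = fit$psi, u = fit$u, B = fit$B)
    k <- ncol(X) + length(q)
    beta <- setNames(drop(fit$beta), c("(Intercept)", terms))
    row <- data.frame(key = keys[i], k = k, loglik = fit$loglik,
                      AICc = aicc(fit$loglik, k, n),
                      converged = fit$converged, vif_max = NA_real_,
                      stringsAsFactors = FALSE)
    row$terms <- list(terms)
    row$beta <- list(beta)
    out[[i]] <- row
  }
  do.call(rbind, out)
}

.group_sums <- function(v, idx) {
  va <- c(0, v)
  m <- matrix(va[idx + 1L], nrow(idx), ncol(idx))
  rowSums(m)
}

.group_maxs <- function(v, idx) {
  va <- c(-Inf, v)
  m <- matrix(va[idx + 1L], nrow(idx), ncol(idx))
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# predictor matrix (15 columns, unscaled) for a complete weight vector
.predictors_from_weights <- function(prep, wvec) {
  nc <- prep$n_contests
  out <- matrix(NA_real_, nc, 15, dimnames = list(prep$contests$contest_id,
                                                  predictor_names()))
  out[, colnames(prep$const_cols)] <- prep$const_cols
  for (cl in names(prep$wmach)) {
    mach <- prep$wmach[[cl]]
    wsum <- .group_sums(wvec, mach$idx)
    wmax <- .group_maxs(wvec, mach$idx)
    dif <- function(v) v[seq(1, 2 * nc, 2)] - v[seq(2, 2 * nc, 2)]
    out[, paste0("rel_mean_weight_", cl)] <- dif(wsum / pmax(mach$counts, 1))
    out[, paste0("rel_max_weight_", cl)] <- dif(wmax)
  }
  out
}

#' Run the iterated imputation and model-selection loop
#'
#' Each iteration re-imputes the missing weights (seed derived from
#' `(base_seed, i)`), rebuilds and rescales the relative predictors,
#' refits all candidate models, applies the Delta-AICc and nesting
#' filters, and records the resulting model set with its averaged
#' coefficients. Candidates containing no weight predictor have identical
#' data in every iteration and are fitted once.
#'
#' @param prep a [prepare_contest_data()] result.
#' @param config an [iteration_config()].
#' @param catalog a [global_model_catalog()].
#' @param delta_max Delta-AICc retention window.
#' @return list of class `iteration_raw`: per-iteration model sets and
#'   averaged estimates, plus bookkeeping.
#' @export
run_iterations <- function(prep, config = iteration_config(),
                           catalog = global_model_catalog(), delta_max = 6) {
  stopifnot(inherits(prep, "contest_prep"))
  candidates <- enumerate_submodels(catalog)
  has_weight <- vapply(candidates, function(tt) any(grepl("weight", tt)), TRUE)
  wf_cand <- candidates[!has_weight]
  wd_cand <- candidates[has_weight]
  nc <- prep$n_contests
  wvec <- prep$roster$weight_g
  y <- prep$contests$focal_win
  f1 <- factor(prep$contests$focal_group_id)
  f2 <- factor(prep$contests$rival_group_id)
  fidx <- cbind(as.integer(f1) - 1L, as.integer(f2) - 1L)
  q <- c(nlevels(f1), nlevels(f2))
  warm <- new.env(parent = emptyenv())
  wf_fits <- NULL
  iter_sets <- vector("list", config$n_iterations)
  iter_avg <- vector("list", config$n_iterations)
  skipped <- logical(config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    seed_i <- derive_seed(config$base_seed, i)
    wfill <- wvec
    wfill[prep$imp$miss_rows] <- impute_draws(prep$imp, seed_i)
    P <- .predictors_from_weights(prep, wfill)
    Ps <- scale(P)
    res <- tryCatch({
      if (is.null(wf_fits))
        wf_fits <- .fit_candidates_fast(Ps, y, fidx, q, wf_cand, warm)
      wd_fits <- .fit_candidates_fast(Ps, y, fidx, q, wd_cand, warm)
      fits <- rbind(wf_fits, wd_fits)
      top <- nesting_rule(build_top_set(fits, delta_max))
      top <- weights_and_likelihoods(top)
      list(set = top, avg = model_average(top))
    }, error = function(e) NULL)
    if (is.null(res)) { skipped[i] <- TRUE; next }
    iter_sets[[i]] <- res$set[, c("key", "AICc", "delta", "likelihood",
                                  "weight", "terms", "beta")]
    iter_avg[[i]] <- res$avg
  }
  n_skip <- sum(skipped)
  if (n_skip > config$max_skip_fraction * config$n_iterations)
    stop(sprintf("%d of %d iterations failed (no converged candidates)",
                 n_skip, config$n_iterations), call. = FALSE)
  structure(list(iter_sets = iter_sets[!skipped],
                 iter_avg = iter_avg[!skipped],
                 n_iterations = config$n_iterations, n_skipped = n_skip,
                 config = config, n_contests = nc),
            class = "iteration_raw")
}

#' Cross-iteration model occurrence filter
#'
#' A model (identified by its term set) is retained only if it appears in
#' the post-nesting model set in at least `occurrence_min_fraction` of the
#' non-skipped iterations; models occurring less often are treated as
#' artifacts of the random imputation.
#'
#' @param raw a [run_iterations()] result.
#' @param config the [iteration_config()] (for the threshold).
#' @return data frame of retained models: `key`, `occurrence`.
#' @export
occurrence_filter <- function(raw, config = raw$config) {
  n <- length(raw$iter_sets)
  if (!n) stop("no successful iterations", call. = FALSE)
  keys <- unlist(lapply(raw$iter_sets, `[[`, "key"))
  occ <- table(keys) / n
  retained <- occ[occ >= config$occurrence_min_fraction]
  if (!length(retained))
    stop("occurrence filter removed every model; inspect the raw results",
         call. = FALSE)
  data.frame(key = names(retained), occurrence = as.vector(retained),
             stringsAsFactors = FALSE)
}

#' Aggregate the iterated results into percentile summaries
#'
#' Restricts each iteration's model set to the occurrence-retained models,
#' recomputes that iteration's Akaike weights, model-averaged coefficients
#' and variable importance over the restricted set, and reports empirical
#' percentiles across iterations (type-7 estimator).
#'
#' @param raw a [run_iterations()] result.
#' @param retained an [occurrence_filter()] result.
#' @param config the [iteration_config()].
#' @return list of class `iteration_summary`: `models` (per-model
#'   occurrence and AICc/likelihood/weight percentiles), `predictors`
#'   (coefficient and importance percentiles), and `coef_draws` /
#'   `importance_draws` matrices (iterations x predictors) for plotting.
#' @export
aggregate_iterations <- function(raw, retained = occurrence_filter(raw),
                                 config = raw$config) {
  n <- length(raw$iter_sets)
  keys <- retained$key
  probs <- config$percentiles
  preds <- predictor_names()
  coef_draws <- imp_draws <- matrix(NA_real_, n, length(preds),
                                    dimnames = list(NULL, preds))
  model_stats <- lapply(setNames(keys, keys), function(k)
    matrix(NA_real_, n, 3, dimnames = list(NULL, c("AICc", "likelihood",
                                                   "weight"))))
  for (i in seq_len(n)) {
    s <- raw$iter_sets[[i]]
    s <- s[s$key %in% keys, , drop = FALSE]
    if (!nrow(s)) next
    s$delta <- s$AICc - min(s$AICc)
    s$likelihood <- exp(-0.5 * s$delta)
    s$weight <- s$likelihood / sum(s$likelihood)
    avg <- model_average(s, preds)
    coef_draws[i, ] <- avg$coef_avg
    imp_draws[i, ] <- avg$importance
    for (j in seq_len(nrow(s)))
      model_stats[[s$key[j]]][i, ] <- c(s$AICc[j], s$likelihood[j],
                                        s$weight[j])
  }
  pt <- function(m) apply(m, 2, pctl, probs = probs)
  models <- do.call(rbind, lapply(keys, function(k) {
    st <- model_stats[[k]]
    qs <- apply(st, 2, pctl, probs = probs)
    out <- data.frame(key = k,
                      occurrence = retained$occurrence[retained$key == k])
    for (v in colnames(st))
      for (pi in seq_along(probs))
        out[[sprintf("%s_p%g", v, probs[pi])]] <- qs[pi, v]
    out
  }))
  models <- models[order(models$AICc_p50), , drop = FALSE]
  rownames(models) <- NULL
  cq <- pt(coef_draws); iq <- pt(imp_draws)
  predictors <- data.frame(predictor = preds, stringsAsFactors = FALSE)
  for (pi in seq_along(probs)) {
    predictors[[sprintf("coef_p%g", probs[pi])]] <- cq[pi, ]
    predictors[[sprintf("importance_p%g", probs[pi])]] <- iq[pi, ]
  }
  predictors <- predictors[order(-predictors$importance_p50), , drop = FALSE]
  rownames(predictors) <- NULL
  structure(list(models = models, predictors = predictors,
                 coef_draws = coef_draws, importance_draws = imp_draws,
                 n_iterations_used = n, n_skipped = raw$n_skipped),
            class = "iteration_summary")
}

#' @export
print.iteration_summary <- function(x, ...) {
  cat(sprintf("iterated model comparison: %d iterations (%d skipped)\n",
              x$n_iterations_used + x$n_skipped, x$n_skipped))
  cat("\nretained models (occurrence, median AICc / weight):\n")
  print(x$models[, c("key", "occurrence", "AICc_p50", "weight_p50")],
        digits = 4)
  cat("\npredictors (median averaged coefficient, median importance):\n")
  print(x$predictors[, c("predictor", "coef_p50", "importance_p50")],
        digits = 3)
  invisible(x)
}

#' End-to-end contest analysis
#'
#' Prepare, iterate, filter and aggregate in one call.
#'
#' @param tables data model tables.
#' @param iter_config an [iteration_config()].
#' @param imp_config an [imputation_config()].
#' @param catalog a [global_model_catalog()].
#' @param focal_seed seed for focal/rival randomization (NULL keeps
#'   recorded labels).
#' @param roster optional prebuilt roster (see
#'   [prepare_contest_data()]).
#' @return an `iteration_summary` (with the `contest_prep` attached as
#'   attribute `prep`).
#' @export
contest_pipeline <- function(tables, iter_config = iteration_config(),
                             imp_config = imputation_config(),
                             catalog = global_model_catalog(),
                             focal_seed = NULL, roster = NULL) {
  prep <- prepare_contest_data(tables, imp_config, focal_seed, roster)
  raw <- run_iterations(prep, iter_config, catalog)
  summ <- aggregate_iterations(raw, occurrence_filter(raw, iter_config),
                               iter_config)
  attr(summ, "prep") <- prep
  summ
}
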