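# Information-theoretic machinery: the 12 global contest models,
# all-subsets enumeration, AICc, the Delta-AICc and nesting filters,
# Akaike weights, model averaging and variable importance.

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`. Undefined (NA, with
#' a warning) when `n <= k + 1`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (fixed effects + variance
#'   components, + residual variance for gaussian models).
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  bad <- n <= k + 1
  if (any(bad)) {
    warning("AICc undefined for n <= k + 1; returning NA", call. = FALSE)
  }
  out <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  out[bad] <- NA_real_
  out
}

#' The catalog of global contest models
#'
#' Twelve global binomial mixed models, one per combination of member
#' class (all adults, males, subordinate males), weight aggregation (mean
#' or max) and age aggregation (mean or max). Each global model's fixed
#' terms are the class's relative member count, one relative weight
#' aggregate and one relative age aggregate; all share random intercepts
#' for focal and rival group identity. Together the globals span all 15
#' relative predictors while avoiding mean/max collinearity within any one
#' model.
#'
#' @param classes,weight_aggs,age_aggs override the default grid.
#' @return list of class `global_catalog`; each element has `terms` and a
#'   descriptive `label`.
#' @export
global_model_catalog <- function(classes = c("all", "males", "submales"),
                                 weight_aggs = c("mean_weight", "max_weight"),
                                 age_aggs = c("mean_age", "max_age")) {
  out <- list()
  for (cl in classes) for (w in weight_aggs) for (a in age_aggs) {
    terms <- paste0("rel_", c("n", w, a), "_", cl)
    terms[1] <- paste0("rel_n_", cl)
    out[[length(out) + 1]] <- list(
      terms = terms,
      label = sprintf("class=%s, weight=%s, age=%s", cl, w, a))
  }
  structure(out, class = "global_catalog")
}

# canonical key for a term set
term_key <- function(terms) {
  if (!length(terms)) "(intercept)" else paste(sort(terms), collapse = " + ")
}

#' Enumerate the deduplicated all-subsets candidate models
#'
#' All subsets of each global model's fixed terms (including the
#' intercept-only model), pooled over the catalog and deduplicated by term
#' set.
#'
#' @param catalog a [global_model_catalog()].
#' @return list of unique candidate term sets (character vectors), named
#'   by their canonical key; the intercept-only model appears exactly once.
#' @export
enumerate_submodels <- function(catalog = global_model_catalog()) {
  seen <- list()
  for (g in catalog) {
    nt <- length(g$terms)
    for (mask in 0:(2^nt - 1)) {
      sub <- sort(g$terms[bitwAnd(mask, 2^(seq_len(nt) - 1)) > 0])
      seen[[term_key(sub)]] <- sub
    }
  }
  seen[order(names(seen))]
}

#' Fit a set of candidate contest models
#'
#' Fits each candidate term set as a binomial mixed model with focal- and
#' rival-group random intercepts, computing AICc for each. Non-converged
#' fits are flagged and excluded downstream. Warm starts may be supplied
#' to speed repeated refits of the same candidates on perturbed data.
#'
#' @param candidates list of term sets (see [enumerate_submodels()]).
#' @param data data frame with scaled predictors, `focal_win`,
#'   `focal_group_id`, `rival_group_id`.
#' @param warm optional environment carrying warm starts keyed by model.
#' @param vif_threshold variance-inflation threshold for the collinearity
#'   log (fit is retained either way unless non-converged).
#' @return data frame with list-columns `terms` and `beta` plus `key`,
#'   `k`, `loglik`, `AICc`, `converged`, `vif_max`.
#' @export
fit_candidate_set <- function(candidates, data, warm = NULL,
                              vif_threshold = 10) {
  n <- nrow(data)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    terms <- candidates[[i]]
    key <- term_key(terms)
    spec <- model_spec("focal_win", terms,
                       random = c("focal_group_id", "rival_group_id"),
                       family = "binomial")
    ws <- if (!is.null(warm)) warm[[digest_key(key)]] else NULL
    fit <- fit_glmm(spec, data, start = ws$psi, start_u = ws$u)
    if (!is.null(warm))
      warm[[digest_key(key)]] <- list(psi = fit$psi, u = unlist(fit$u,
                                                                use.names = FALSE))
    vmax <- if (length(terms) >= 2) max(vif_check(data, terms)) else 1
    rows[[i]] <- data.frame(key = key, k = fit$k, loglik = fit$loglik,
                            AICc = aicc(fit$loglik, fit$k, n),
                            converged = fit$converged,
                            vif_max = vmax, stringsAsFactors = FALSE)
    rows[[i]]$terms <- list(terms)
    rows[[i]]$beta <- list(fit$beta)
  }
  do.call(rbind, rows)
}

digest_key <- function(key) gsub("[^A-Za-z0-9_]", ".", key)

#' Retain candidates within a Delta-AICc window of the best model
#'
#' Delta-AICc is computed from the pooled minimum over converged fits;
#' retention uses the strict inequality `Delta < delta_max`.
#'
#' @param fits data frame from [fit_candidate_set()].
#' @param delta_max window width (default 6).
#' @return `model_set` data frame with `delta` added, sorted by AICc.
#' @export
build_top_set <- function(fits, delta_max = 6) {
  fits <- fits[fits$converged & is.finite(fits$AICc), , drop = FALSE]
  if (!nrow(fits)) stop("no converged candidate fits", call. = FALSE)
  fits$delta <- fits$AICc - min(fits$AICc)
  out <- fits[fits$delta < delta_max, , drop = FALSE]
  out <- out[order(out$AICc), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("model_set", "data.frame"))
}

#' Remove models dominated by a simpler nested model
#'
#' A model is removed when some other retained candidate whose term set is
#' a strict subset has lower-or-equal AICc (ties remove the more complex
#' model, by parsimony). Equivalent to a brute-force pairwise filter.
#'
#' @param set a [build_top_set()] result.
#' @return filtered `model_set` (deltas recomputed within the set).
#' @export
nesting_rule <- function(set) {
  n <- nrow(set)
  if (n <= 1) return(set)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ti <- set$terms[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      tj <- set$terms[[j]]
      if (length(tj) < length(ti) && all(tj %in% ti) &&
          set$AICc[j] <= set$AICc[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- set[keep, , drop = FALSE]
  out$delta <- out$AICc - min(out$AICc)
  rownames(out) <- NULL
  structure(out, class = c("model_set", "data.frame"))
}

#' Akaike likelihoods and weights
#'
#' `l_i = exp(-0.5 * Delta_i)` and `w_i = l_i / sum(l_j)` over the
#' retained set; weights sum to one.
#'
#' @param set a `model_set`.
#' @return the set with `likelihood` and `weight` columns.
#' @export
weights_and_likelihoods <- function(set) {
  if (!nrow(set)) stop("empty model set", call. = FALSE)
  set$delta <- set$AICc - min(set$AICc)
  set$likelihood <- exp(-0.5 * set$delta)
  set$weight <- set$likelihood / sum(set$likelihood)
  set
}

#' Model-averaged coefficients and variable importance
#'
#' The model-averaged coefficient of a predictor is the weight-weighted
#' mean of its estimates across the retained models, taking zero where the
#' predictor is absent. Variable importance is the summed weight of the
#' models containing the predictor.
#'
#' @param set a `model_set` with weights (see
#'   [weights_and_likelihoods()]).
#' @param predictors predictor universe (default the 15 relative
#'   predictors).
#' @return data frame: `predictor`, `coef_avg`, `importance`.
#' @export
model_average <- function(set, predictors = predictor_names()) {
  if (!"weight" %in% names(set)) set <- weights_and_likelihoods(set)
  coef_avg <- importance <- setNames(rep(0, length(predictors)), predictors)
  for (i in seq_len(nrow(set))) {
    b <- set$beta[[i]]
    for (p in intersect(names(b), predictors)) {
      coef_avg[p] <- coef_avg[p] + set$weight[i] * b[[p]]
      importance[p] <- importance[p] + set$weight[i]
    }
  }
  data.frame(predictor = predictors, coef_avg = unname(coef_avg),
             importance = unname(importance), stringsAsFactors = FALSE)
}

#' One full model-comparison pass
#'
#' Enumerates and fits the all-subsets candidates, applies the Delta-AICc
#' and nesting filters, and computes weights, model-averaged coefficients
#' and variable importance.
#'
#' @param data contest data frame with scaled relative predictors,
#'   `focal_win`, `focal_group_id`, `rival_group_id`.
#' @param catalog a [global_model_catalog()].
#' @param delta_max Delta-AICc retention window.
#' @return list: `model_set` (post-nesting, with weights), `averaged`,
#'   `fits` (all candidates).
#' @export
select_models <- function(data, catalog = global_model_catalog(),
                          delta_max = 6) {
  candidates <- enumerate_submodels(catalog)
  fits <- fit_candidate_set(candidates, data)
  top <- build_top_set(fits, delta_max)
  top <- nesting_rule(top)
  top <- weights_and_likelihoods(top)
  list(model_set = top, averaged = model_average(top), fits = fits)
}
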