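# DIC-based model ranking: posterior mean deviance, effective number of
# parameters, DIC weights, the confidence set and plausibility ratios.

# deviance at a named parameter vector, on the fit's collapsed data
deviance_from_params <- function(fit, params) {
  cd <- fit$collapsed
  if (is.null(cd)) stop("fit carries no design; refit with fit_detection_model()",
                        call. = FALSE)
  beta <- params[colnames(cd$X)]
  eta <- as.vector(cd$X %*% beta)
  if (length(cd$sec_levels)) {
    eta <- eta + params[paste0("u_section[", cd$sec_levels, "]")][cd$sec]
  }
  if (length(cd$tr_levels)) {
    eta <- eta + params[paste0("u_transect[", cd$tr_levels, "]")][cd$tr]
  }
  -2 * (sum(cd$succ * eta) - sum(cd$trials * log1p_exp(eta)))
}

#' Deviance information criterion of a fitted model
#'
#' `deviance_bar` is the posterior mean of the per-draw deviance; `pD`
#' (effective number of parameters) is `deviance_bar - D(theta_bar)`, where
#' `theta_bar` plugs in the posterior means of all sampled quantities
#' (including random intercepts when present); `DIC = deviance_bar + pD`,
#' equivalently `D(theta_bar) + 2 pD`. Smaller DIC indicates a better
#' approximating model.
#'
#' @param fit a `posterior_fit` with deviance draws.
#' @return named numeric vector `c(deviance_bar, pD, DIC)`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (is.null(fit$deviance)) stop("fit has no deviance draws", call. = FALSE)
  dbar <- mean(unlist(fit$deviance))
  theta_bar <- colMeans(pooled_draws(fit))
  dhat <- deviance_from_params(fit, theta_bar)
  pd <- dbar - dhat
  c(deviance_bar = dbar, pD = pd, DIC = dbar + pd)
}

#' DIC weights of a candidate set
#'
#' `w_i = exp(-dDIC_i / 2) / sum_j exp(-dDIC_j / 2)` over the supplied
#' models, order preserved. Weights are invariant to adding a constant to
#' every DIC.
#'
#' @param dics numeric vector of DIC values.
#' @return numeric weights summing to 1.
#' @examples
#' round_half_up(dic_weights(c(0, 0.75, 1.74, 2.45, 3.32)))
#' # 0.39 0.27 0.16 0.11 0.07
#' @export
dic_weights <- function(dics) {
  if (length(dics) == 0L || any(!is.finite(dics))) {
    stop("dics must be a non-empty vector of finite values", call. = FALSE)
  }
  w <- exp(-(dics - min(dics)) / 2)
  w / sum(w)
}

#' Rank candidate model fits by DIC
#'
#' @param fits list of `posterior_fit` objects for the candidate models.
#' @param labels optional character labels (defaults to each spec's label).
#' @return a `model_comparison` data frame sorted by ascending DIC (ties
#'   broken by input order) with columns `model`, `deviance_bar`, `pD`,
#'   `DIC`, `dDIC`, `weight` and an empty `p_value` column that
#'   [bayesian_p_value()] results can be written into.
#' @export
compare_models <- function(fits, labels = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(labels)) {
    labels <- vapply(fits, function(f) {
      if (!is.null(f$spec)) f$spec$label else ""
    }, "")
  }
  stats <- t(vapply(fits, dic, c(deviance_bar = 0, pD = 0, DIC = 0)))
  ord <- order(stats[, "DIC"])  # stable: ties keep enumeration order
  out <- data.frame(model = labels[ord],
                    deviance_bar = stats[ord, "deviance_bar"],
                    pD = stats[ord, "pD"],
                    DIC = stats[ord, "DIC"],
                    row.names = NULL)
  out$dDIC <- out$DIC - out$DIC[1]
  out$weight <- dic_weights(out$DIC)
  out$p_value <- NA_real_
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Confidence set of a model comparison
#'
#' Retains the models whose DIC weight is at least `threshold` times the
#' best model's weight (default 10%), preserving the ranking. A
#' `weight_conf` column renormalizes the weights over the retained set
#' (the convention the published weight table follows); the original
#' full-set `weight` column is kept alongside. The operation is idempotent.
#'
#' @param comparison a `model_comparison` from [compare_models()].
#' @param threshold retention threshold relative to the best weight.
#' @return the retained subset, a `model_comparison`.
#' @export
confidence_set <- function(comparison, threshold = 0.10) {
  stopifnot(inherits(comparison, "model_comparison"))
  keep <- comparison$weight >= threshold * max(comparison$weight)
  out <- comparison[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$weight_conf <- out$weight / sum(out$weight)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Plausibility ratios of the best model over its competitors
#'
#' Ratio of the best model's DIC weight to each other model's weight. To
#' match the convention of the published values, weights are first rounded
#' to 2 decimals (half-up) and the ratios rounded likewise; the unrounded
#' ratios `exp(dDIC / 2)` are attached as attribute `"unrounded"`.
#'
#' @param x a `model_comparison` (its `weight` column is used, best model
#'   first) or a numeric vector of weights in ranked order.
#' @return numeric vector of length `length(weights) - 1`.
#' @examples
#' plausibility_ratios(dic_weights(c(0, 0.75, 1.74, 2.45, 3.32)))
#' # 1.44 2.44 3.55 5.57
#' @export
plausibility_ratios <- function(x) {
  w <- if (inherits(x, "model_comparison")) x$weight else as.numeric(x)
  if (length(w) < 2L) stop("need at least two models", call. = FALSE)
  w <- w[order(-w)]
  r <- round_half_up(w, 2)
  out <- round_half_up(r[1] / r[-1], 2)
  attr(out, "unrounded") <- w[1] / w[-1]
  out
}

#' Fit and rank an all-subsets candidate set
#'
#' Enumerates every subset of `predictors` (see [enumerate_candidates()]),
#' fits each by MCMC and returns the DIC ranking.
#'
#' @inheritParams enumerate_candidates
#' @param table a `sample_table`.
#' @param std standardizations for the continuous covariates.
#' @param config an [mcmc_config()]; chain seeds are derived per model so
#'   the whole selection is reproducible from one seed.
#' @return a `model_comparison` with one row per candidate.
#' @export
select_models <- function(table, predictors, priors = prior_spec(),
                          random_structure = "none",
                          std = paper_standardization(),
                          config = mcmc_config()) {
  specs <- enumerate_candidates(predictors, priors, random_structure)
  fits <- lapply(seq_along(specs), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    fit_detection_model(table, specs[[i]], std, cfg)
  })
  compare_models(fits)
}

#' Write a model comparison as CSV
#'
#' @param comparison a `model_comparison`.
#' @param path output CSV path.
#' @export
write_comparison <- function(comparison, path) {
  out <- as.data.frame(comparison)
  names(out)[names(out) == "deviance_bar"] <- "Deviance"
  names(out)[names(out) == "pD"] <- "pd"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
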