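# Per-sample false-positive rate from control-pond data and projection of
# the expected number of false positives in a stocked-pond sample set.
#
# With zero detections among the control samples the posterior is
# prior-dominated, so a prior-sensitivity table accompanies the estimate.

#' Fit the intercept-only false-positive model to control data
#'
#' Any detection in a fishless control pond is by definition a false
#' positive; with no covariates available (and typically no detections) a
#' single intercept-only Bernoulli model is fit. The per-sample
#' false-positive probability is summarised as the posterior mean of
#' `plogis(beta0)` over the draws (not `plogis` of the posterior mean).
#'
#' @param control a `sample_table` of control-pond samples.
#' @param priors a [prior_spec()]; must be proper (it is what identifies the
#'   rate when there are zero detections). Use `fixed_family = "logistic"`
#'   for a prior that is flat on the probability scale, under which the
#'   posterior is conjugate Beta(1 + y, 1 + n - y).
#' @param config an [mcmc_config()].
#' @return a `posterior_fit` for the intercept-only model.
#' @export
fit_false_positive <- function(control, priors = prior_spec(),
                               config = mcmc_config()) {
  stopifnot(inherits(control, "sample_table"))
  if (nrow(control) == 0L) stop("control table is empty", call. = FALSE)
  if (sum(control$detection) == 0L &&
      priors$fixed_family == "normal" && !is.finite(priors$fixed_sd)) {
    stop(paste("zero detections in the control data: a proper prior on the",
               "intercept is required (finite fixed_sd)"), call. = FALSE)
  }
  spec <- model_spec(character(), random_structure = "none", priors = priors)
  fit_detection_model(control, spec, std = list(), config = config)
}

#' Posterior draws of the per-sample false-positive probability
#' @param fit intercept-only `posterior_fit` from [fit_false_positive()].
#' @return numeric vector of probability draws.
#' @export
false_positive_draws <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  stats::plogis(pooled_draws(fit)[, "(Intercept)"])
}

#' Expected false positives in a projected sample set
#'
#' Projects a posterior for the per-sample false-positive probability onto
#' `n_project` samples: the expected count `n_project * mean(p)`, a central
#' predictive interval, and the min-max range of simulated
#' `Binomial(n_project, p)` counts with `p` drawn from the posterior.
#'
#' @param p posterior draws of the per-sample probability (a numeric
#'   vector, e.g. from [false_positive_draws()]), or a single fixed value.
#' @param n_project number of samples to project onto (>= 1).
#' @param level coverage of the central predictive interval (default 0.95).
#' @param seed seed for the predictive simulation.
#' @return a `false_positive_estimate` list: `per_sample_p` (posterior
#'   mean), `expected_count`, `predictive_interval`, `predictive_range`
#'   (min-max of simulated counts) and `n_project`.
#' @examples
#' expected_false_positives(0.0149, 243)$expected_count # 3.62 (2 dp)
#' @export
expected_false_positives <- function(p, n_project, level = 0.95, seed = 1L) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), n_project >= 1)
  n_project <- as.integer(n_project)
  set.seed(seed)
  counts <- stats::rbinom(max(length(p), 4000L), n_project, p)
  a <- (1 - level) / 2
  structure(list(
    per_sample_p = mean(p),
    expected_count = n_project * mean(p),
    predictive_interval = unname(stats::quantile(counts, c(a, 1 - a))),
    predictive_range = c(min(counts), max(counts)),
    level = level,
    n_project = n_project
  ), class = "false_positive_estimate")
}

#' Full false-positive report with prior sensitivity
#'
#' Fits the intercept-only model to the control data, projects the expected
#' number of false positives onto `n_project` samples, and — whenever the
#' control data contain zero detections, where the posterior is
#' prior-dominated — refits under several prior SDs and reports the
#' per-sample probability under each.
#'
#' @inheritParams fit_false_positive
#' @param n_project sample size to project onto (default 243, the stocked
#'   samples of the bundled study).
#' @param sensitivity_sds prior SDs for the sensitivity refits.
#' @param level predictive-interval coverage.
#' @return a `false_positive_report` list: `fit`, `intercept_summary`,
#'   `estimate` and (for zero-detection data) a `sensitivity` data frame.
#' @export
false_positive_report <- function(control, priors = prior_spec(),
                                  config = mcmc_config(), n_project = 243L,
                                  sensitivity_sds = c(2.5, 5, 10),
                                  level = 0.95) {
  fit <- fit_false_positive(control, priors, config)
  p_draws <- false_positive_draws(fit)
  est <- expected_false_positives(p_draws, n_project, level = level,
                                  seed = config$seed)
  sens <- NULL
  if (sum(control$detection) == 0L) {
    sens <- do.call(rbind, lapply(sensitivity_sds, function(s) {
      f <- fit_false_positive(control,
                              prior_spec(fixed_sd = s,
                                         fixed_family = priors$fixed_family),
                              config)
      pd <- false_positive_draws(f)
      data.frame(prior_sd = s, per_sample_p = mean(pd),
                 expected_count = n_project * mean(pd))
    }))
  }
  structure(list(fit = fit, intercept_summary = posterior_summary(fit),
                 estimate = est, sensitivity = sens),
            class = "false_positive_report")
}

#' @export
print.false_positive_estimate <- function(x, ...) {
  cat(sprintf(
    "per-sample false-positive probability: %.4f\nexpected count in %d samples: %.2f (central %.0f%% predictive interval %d-%d, range %d-%d)\n",
    x$per_sample_p, x$n_project, x$expected_count, 100 * x$level,
    x$predictive_interval[1], x$predictive_interval[2],
    x$predictive_range[1], x$predictive_range[2]))
  invisible(x)
}

#' @export
print.false_positive_report <- function(x, ...) {
  print(x$estimate)
  if (!is.null(x$sensitivity)) {
    cat("prior sensitivity (zero-detection data; estimate is prior-dominated):\n")
    print(x$sensitivity, row.names = FALSE)
  }
  invisible(x)
}
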