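# Survey design: per-sample detection probabilities from fitted
# coefficients, cumulative detection curves, and the number of 1-L samples
# required to reach a target certainty.

#' Per-sample detection probability at a covariate setting
#'
#' Plug-in probability `plogis(b0 + b_density z(density) +
#' b_temperature z(temperature) + position offset)` at fixed-effect values
#' `coefs` (typically posterior means). Terms absent from `coefs`
#' contribute nothing; in particular position offsets not in the model are
#' zero.
#'
#' @param coefs named numeric vector with `"(Intercept)"` and any of
#'   `middle`, `bottom`, `density`, `temperature`, `day`.
#' @param std named list of `standardization` objects for the continuous
#'   covariates present in `coefs`.
#' @param density fish density (fish/m^3).
#' @param temperature water temperature (degrees C).
#' @param position `"surface"`, `"middle"` or `"bottom"`.
#' @param day study day (only used when `coefs` has a `day` term, which
#'   enters unstandardized).
#' @return detection probability in [0, 1]; vectorised over `density`.
#' @export
per_sample_probability <- function(coefs, std = paper_standardization(),
                                   density = 0, temperature = 0,
                                   position = "surface", day = 0) {
  position <- match.arg(position, POSITIONS)
  if (!"(Intercept)" %in% names(coefs)) stop("coefs needs an '(Intercept)'",
                                             call. = FALSE)
  eta <- coefs[["(Intercept)"]]
  if ("density" %in% names(coefs)) {
    eta <- eta + coefs[["density"]] * standardize(density, std$density)
  }
  if ("temperature" %in% names(coefs)) {
    eta <- eta + coefs[["temperature"]] * standardize(temperature, std$temperature)
  }
  if ("day" %in% names(coefs)) eta <- eta + coefs[["day"]] * day
  if (position == "middle" && "middle" %in% names(coefs)) {
    eta <- eta + coefs[["middle"]]
  }
  if (position == "bottom" && "bottom" %in% names(coefs)) {
    eta <- eta + coefs[["bottom"]]
  }
  unname(stats::plogis(eta))
}

#' Posterior-averaged per-sample detection probability
#'
#' Averages `plogis` of the linear predictor over the posterior draws
#' instead of plugging in posterior means; with a skewed posterior the two
#' conventions differ.
#'
#' @param fit a `posterior_fit`.
#' @inheritParams per_sample_probability
#' @return posterior mean detection probability; vectorised over `density`.
#' @export
posterior_mean_probability <- function(fit, std = fit$std, density = 0,
                                       temperature = 0, position = "surface",
                                       day = 0) {
  draws <- pooled_draws(fit)
  nm <- fixed_effect_names(fit)
  sapply(density, function(d) {
    mean(apply(draws[, nm, drop = FALSE], 1, function(b) {
      per_sample_probability(b, std, d, temperature, position, day)
    }))
  })
}

#' Cumulative detection probability
#'
#' Probability of at least one detection in `n` independent samples with
#' per-sample detection probability `p`: `1 - (1 - p)^n`.
#'
#' @param p per-sample probability in [0, 1].
#' @param n number of samples (>= 0); vectorised.
#' @return probability.
#' @examples
#' cumulative_detection(0.55, 5) # 0.9815
#' @export
cumulative_detection <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 0))
  1 - (1 - p)^n
}

#' Samples required to reach a target detection certainty
#'
#' Smallest integer `n` with `1 - (1 - p)^n >= target`, i.e.
#' `ceiling(log(1 - target) / log(1 - p))`.
#'
#' @param p per-sample detection probability, strictly between 0 and 1.
#' @param target target cumulative detection probability, in (0, 1);
#'   default 0.95.
#' @return integer number of samples.
#' @examples
#' samples_required(0.07, 0.95) # 42
#' @export
samples_required <- function(p, target = 0.95) {
  stopifnot(all(target > 0 & target < 1))
  if (any(p <= 0)) stop("target certainty unreachable at p = 0", call. = FALSE)
  if (any(p >= 1)) stop("p must be < 1", call. = FALSE)
  # tiny slack guards against e.g. log(0.05)/log(0.05) = 1 + eps
  as.integer(ceiling(log1p(-target) / log1p(-p) - 1e-9))
}

#' Cumulative detection curves over a density grid
#'
#' Evaluates the plug-in per-sample detection probability at each density
#' (at a fixed temperature and position) and expands it into a cumulative
#' detection curve for 1..`max_n` samples, together with the number of
#' samples required to reach `target`.
#'
#' @inheritParams per_sample_probability
#' @param densities numeric vector of fish densities (fish/m^3).
#' @param max_n largest number of samples on the curve.
#' @param target target certainty for the samples-required summary.
#' @return a `detection_design` data frame with columns `density`,
#'   `temperature`, `position`, `n`, `per_sample_p`, `cumulative_p`, and an
#'   attribute `"n_required"` (data frame of density, per_sample_p,
#'   n_required; NA where the target is unreachable).
#' @export
detection_curve <- function(coefs, densities, temperature = 28,
                            position = "surface",
                            std = paper_standardization(),
                            max_n = 100L, target = 0.95) {
  stopifnot(length(densities) >= 1L, max_n >= 1L)
  out <- do.call(rbind, lapply(densities, function(d) {
    p <- per_sample_probability(coefs, std, d, temperature, position)
    data.frame(density = d, temperature = temperature, position = position,
               n = seq_len(max_n), per_sample_p = p,
               cumulative_p = cumulative_detection(p, seq_len(max_n)))
  }))
  req <- data.frame(
    density = densities,
    per_sample_p = per_sample_probability(coefs, std, densities, temperature,
                                          position),
    n_required = vapply(densities, function(d) {
      p <- per_sample_probability(coefs, std, d, temperature, position)
      if (p <= 0 || p >= 1) NA_integer_ else samples_required(p, target)
    }, 1L)
  )
  attr(out, "n_required") <- req
  class(out) <- c("detection_design", "data.frame")
  out
}
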