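# Posterior inference for the hierarchical logistic detection model.
#
# The sampler is an adaptive componentwise random-walk Metropolis scheme
# over the fixed effects, the log random-intercept SDs and the random
# intercepts. Proposal scales adapt toward a 0.44 acceptance rate during
# burn-in and are frozen afterwards, so the retained chain is Markovian.
# The Bernoulli likelihood is evaluated on data collapsed to unique
# (covariate row, section, transect) patterns as binomial counts, which is
# exactly equal to the record-level Bernoulli log-likelihood.

# overflow-safe log(1 + exp(x))
log1p_exp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

log_prior_fixed <- function(b, priors) {
  if (priors$fixed_family == "logistic") {
    sum(stats::dlogis(b, log = TRUE))
  } else {
    sum(stats::dnorm(b, 0, priors$fixed_sd, log = TRUE))
  }
}

#' MCMC run configuration
#'
#' Defaults match the full analysis profile (200,000 iterations with a
#' 50,000-iteration burn-in). A reduced profile (e.g. 20,000 / 5,000) is
#' adequate for exploratory fits and is what the test suite uses.
#'
#' @param iterations total iterations per chain.
#' @param burn_in iterations discarded from the start of each chain; must be
#'   smaller than `iterations`.
#' @param chains number of chains (>= 2 needed for convergence diagnostics).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain-specific sub-seeds are derived from it.
#' @return an `mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 200000L, burn_in = 50000L, chains = 3L,
                        thin = 1L, seed = 1L) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  chains <- as.integer(chains); thin <- as.integer(thin)
  if (is.na(iterations) || is.na(burn_in) || burn_in >= iterations || burn_in < 0L) {
    stop("require 0 <= burn_in < iterations", call. = FALSE)
  }
  if (chains < 1L) stop("chains must be >= 1", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in, chains = chains,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_config")
}

# Collapse a row-level design to unique (X row, section, transect) patterns
# with binomial successes/trials. Dropping the binomial coefficient makes the
# collapsed log-likelihood exactly the Bernoulli record-level one.
collapse_design <- function(dm) {
  use_sec <- dm$spec$random_structure %in% c("section", "section+transect")
  use_tr <- dm$spec$random_structure %in% c("transect", "section+transect")
  sec <- if (use_sec) as.integer(dm$section) else rep(1L, length(dm$response))
  tr <- if (use_tr) as.integer(dm$transect) else rep(1L, length(dm$response))
  key <- do.call(paste, c(as.data.frame(dm$X),
                          list(sec, tr, sep = "\r")))
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  list(
    X = dm$X[first, , drop = FALSE],
    succ = as.vector(tapply(dm$response, idx, sum)),
    trials = as.vector(tapply(dm$response, idx, length)),
    sec = if (use_sec) sec[first] else NULL,
    tr = if (use_tr) tr[first] else NULL,
    sec_levels = if (use_sec) levels(dm$section) else character(0),
    tr_levels = if (use_tr) levels(dm$transect) else character(0)
  )
}

param_names <- function(cd) {
  c(colnames(cd$X),
    if (length(cd$sec_levels)) c("sigma_section",
                                 paste0("u_section[", cd$sec_levels, "]")),
    if (length(cd$tr_levels)) c("sigma_transect",
                                paste0("u_transect[", cd$tr_levels, "]")))
}

# one adaptive Metropolis chain on collapsed data; returns draws + deviance
mh_chain <- function(cd, priors, iterations, burn_in, thin, seed) {
  set.seed(seed)
  X <- cd$X; succ <- cd$succ; trials <- cd$trials
  p <- ncol(X)
  nsec <- length(cd$sec_levels); ntr <- length(cd$tr_levels)
  sd_lo <- priors$random_sd_params[1]; sd_hi <- priors$random_sd_params[2]

  beta <- stats::rnorm(p, 0, 2)                       # over-dispersed starts
  ls_sec <- if (nsec) log(stats::runif(1, max(0.2, sd_lo + 1e-6), 2)) else NULL
  u_sec <- if (nsec) stats::rnorm(nsec, 0, exp(ls_sec)) else numeric(0)
  ls_tr <- if (ntr) log(stats::runif(1, max(0.2, sd_lo + 1e-6), 2)) else NULL
  u_tr <- if (ntr) stats::rnorm(ntr, 0, exp(ls_tr)) else numeric(0)

  sec_rows <- if (nsec) lapply(seq_len(nsec), function(g) which(cd$sec == g))
  tr_rows <- if (ntr) lapply(seq_len(ntr), function(g) which(cd$tr == g))

  eta <- as.vector(X %*% beta)
  if (nsec) eta <- eta + u_sec[cd$sec]
  if (ntr) eta <- eta + u_tr[cd$tr]
  ll <- sum(succ * eta) - sum(trials * log1p_exp(eta))

  ncomp <- p + (nsec > 0) * (1L + nsec) + (ntr > 0) * (1L + ntr)
  step <- rep(0.5, ncomp)
  acc <- integer(ncomp)
  nstore <- (iterations - burn_in) %/% thin
  draws <- matrix(NA_real_, nstore, p + (nsec > 0) * (1L + nsec) +
                    (ntr > 0) * (1L + ntr))
  dev <- numeric(nstore)
  stored <- 0L

  lpf_one <- function(b) {
    if (priors$fixed_family == "logistic") stats::dlogis(b, log = TRUE)
    else stats::dnorm(b, 0, priors$fixed_sd, log = TRUE)
  }

  for (it in seq_len(iterations)) {
    k <- 0L
    for (j in seq_len(p)) {
      k <- k + 1L
      d <- stats::rnorm(1, 0, step[k])
      etan <- eta + X[, j] * d
      lln <- sum(succ * etan) - sum(trials * log1p_exp(etan))
      if (log(stats::runif(1)) <
          lln - ll + lpf_one(beta[j] + d) - lpf_one(beta[j])) {
        beta[j] <- beta[j] + d; eta <- etan; ll <- lln; acc[k] <- acc[k] + 1L
      }
    }
    if (nsec) {
      k <- k + 1L  # sigma_section (random walk on log scale, + Jacobian)
      d <- stats::rnorm(1, 0, step[k])
      sig_new <- exp(ls_sec + d)
      if (sig_new > sd_lo && sig_new < sd_hi) {
        dlp <- sum(stats::dnorm(u_sec, 0, sig_new, log = TRUE)) -
          sum(stats::dnorm(u_sec, 0, exp(ls_sec), log = TRUE)) + d
        if (log(stats::runif(1)) < dlp) { ls_sec <- ls_sec + d; acc[k] <- acc[k] + 1L }
      }
      sig <- exp(ls_sec)
      for (g in seq_len(nsec)) {
        k <- k + 1L
        d <- stats::rnorm(1, 0, step[k])
        rows <- sec_rows[[g]]
        etan_g <- eta[rows] + d
        dll <- sum(succ[rows] * etan_g) - sum(trials[rows] * log1p_exp(etan_g)) -
          (sum(succ[rows] * eta[rows]) - sum(trials[rows] * log1p_exp(eta[rows])))
        dlp <- stats::dnorm(u_sec[g] + d, 0, sig, log = TRUE) -
          stats::dnorm(u_sec[g], 0, sig, log = TRUE)
        if (log(stats::runif(1)) < dll + dlp) {
          u_sec[g] <- u_sec[g] + d; eta[rows] <- etan_g; ll <- ll + dll
          acc[k] <- acc[k] + 1L
        }
      }
    }
    if (ntr) {
      k <- k + 1L
      d <- stats::rnorm(1, 0, step[k])
      sig_new <- exp(ls_tr + d)
      if (sig_new > sd_lo && sig_new < sd_hi) {
        dlp <- sum(stats::dnorm(u_tr, 0, sig_new, log = TRUE)) -
          sum(stats::dnorm(u_tr, 0, exp(ls_tr), log = TRUE)) + d
        if (log(stats::runif(1)) < dlp) { ls_tr <- ls_tr + d; acc[k] <- acc[k] + 1L }
      }
      sig <- exp(ls_tr)
      for (g in seq_len(ntr)) {
        k <- k + 1L
        d <- stats::rnorm(1, 0, step[k])
        rows <- tr_rows[[g]]
        etan_g <- eta[rows] + d
        dll <- sum(succ[rows] * etan_g) - sum(trials[rows] * log1p_exp(etan_g)) -
          (sum(succ[rows] * eta[rows]) - sum(trials[rows] * log1p_exp(eta[rows])))
        dlp <- stats::dnorm(u_tr[g] + d, 0, sig, log = TRUE) -
          stats::dnorm(u_tr[g], 0, sig, log = TRUE)
        if (log(stats::runif(1)) < dll + dlp) {
          u_tr[g] <- u_tr[g] + d; eta[rows] <- etan_g; ll <- ll + dll
          acc[k] <- acc[k] + 1L
        }
      }
    }
    if (it <= burn_in && it %% 50L == 0L) {
      rate <- acc / 50
      step <- pmin(10, pmax(1e-3, step * exp(0.6 * (rate - 0.44))))
      acc[] <- 0L
    }
    if (it %% 1000L == 0L) {  # kill incremental round-off drift
      eta <- as.vector(X %*% beta)
      if (nsec) eta <- eta + u_sec[cd$sec]
      if (ntr) eta <- eta + u_tr[cd$tr]
      ll <- sum(succ * eta) - sum(trials * log1p_exp(eta))
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      stored <- stored + 1L
      draws[stored, ] <- c(beta,
                           if (nsec) c(exp(ls_sec), u_sec),
                           if (ntr) c(exp(ls_tr), u_tr))
      dev[stored] <- -2 * ll
    }
  }
  colnames(draws) <- param_names(cd)
  list(draws = draws, deviance = dev)
}

#' Construct a posterior fit object
#'
#' Low-level constructor, mainly useful for building degenerate or synthetic
#' posteriors in tests and worked examples; [fit_detection_model()] builds
#' these from data.
#'
#' @param draws list of per-chain draw matrices (iterations x parameters,
#'   identical column names across chains).
#' @param deviance list of per-chain numeric deviance vectors (may be NULL
#'   when only summaries are needed).
#' @param spec,std,config,dm optional metadata as attached by
#'   [fit_detection_model()].
#' @return a `posterior_fit` object.
#' @export
posterior_fit <- function(draws, deviance = NULL, spec = NULL, std = NULL,
                          config = NULL, dm = NULL) {
  stopifnot(is.list(draws), length(draws) >= 1L, all(vapply(draws, is.matrix, TRUE)))
  nm <- colnames(draws[[1]])
  if (is.null(nm)) stop("draw matrices must have column names", call. = FALSE)
  structure(list(draws = draws, deviance = deviance, spec = spec, std = std,
                 config = config, dm = dm,
                 collapsed = if (!is.null(dm)) collapse_design(dm)),
            class = "posterior_fit")
}

#' Log posterior density of the detection model
#'
#' Bernoulli log-likelihood at `plogis(linear predictor + random
#' intercepts)` plus the log prior densities of the fixed effects, the
#' random-intercept SDs (uniform) and the random intercepts given their SD.
#' Returns `-Inf` only for parameters outside the prior support.
#'
#' @param params named numeric vector: one entry per fixed-effect column of
#'   `dm$X`, plus — when the model has random intercepts — `sigma_section`
#'   and/or `sigma_transect` (natural scale) and one `u_section[...]` /
#'   `u_transect[...]` entry per group.
#' @param dm an `edna_design` from [build_design_matrix()].
#' @param priors a [prior_spec()]; defaults to the priors in `dm$spec`.
#' @return scalar log posterior density (up to the normalising constant).
#' @export
log_posterior <- function(params, dm, priors = dm$spec$priors) {
  stopifnot(inherits(dm, "edna_design"))
  cd_names <- param_names(collapse_design(dm))
  if (length(params) != length(cd_names) || !all(cd_names %in% names(params))) {
    stop("parameter vector does not match the model: expected ",
         paste(cd_names, collapse = ", "), call. = FALSE)
  }
  beta <- params[colnames(dm$X)]
  eta <- as.vector(dm$X %*% beta)
  lp <- log_prior_fixed(beta, priors)
  for (comp in c("section", "transect")) {
    if (!dm$spec$random_structure %in% c(comp, "section+transect")) next
    sig <- params[[paste0("sigma_", comp)]]
    lo <- priors$random_sd_params[1]; hi <- priors$random_sd_params[2]
    if (!is.finite(sig) || sig <= lo || sig >= hi) return(-Inf)
    grp <- dm[[comp]]
    u <- params[paste0("u_", comp, "[", levels(grp), "]")]
    eta <- eta + u[as.integer(grp)]
    lp <- lp + sum(stats::dnorm(u, 0, sig, log = TRUE)) - log(hi - lo)
  }
  y <- dm$response
  lp + sum(y * eta) - sum(log1p_exp(eta))
}

#' Fit a detection model by MCMC
#'
#' Runs `config$chains` adaptive random-walk Metropolis chains from
#' over-dispersed starting values (fixed effects drawn from N(0, 2) with
#' distinct chain sub-seeds) and stores post-burn-in draws together with the
#' per-draw deviance `D = -2 * log-likelihood`. The inverse-logit is
#' evaluated with overflow-safe branches, so extreme linear predictors do
#' not produce non-finite likelihoods. Zero-detection data are fit like any
#' other (the proper priors keep the posterior proper).
#'
#' @param table a non-empty `sample_table`.
#' @param spec a [model_spec()].
#' @param std standardizations passed to [build_design_matrix()].
#' @param config an [mcmc_config()].
#' @return a `posterior_fit` holding per-chain draw matrices, per-chain
#'   deviance vectors, the spec, standardizations, config and design.
#' @examples
#' \donttest{
#' stocked <- subset_samples(builtin_pond_study(), pond_id != 1)
#' spec <- model_spec(c("middle", "density", "temperature"))
#' fit <- fit_detection_model(stocked, spec,
#'   config = mcmc_config(20000, 5000, chains = 3, seed = 1))
#' posterior_summary(fit)
#' }
#' @export
fit_detection_model <- function(table, spec, std = paper_standardization(),
                                config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  dm <- build_design_matrix(table, spec, std)
  cd <- collapse_design(dm)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)
  chains <- lapply(chain_seeds, function(s) {
    mh_chain(cd, spec$priors, config$iterations, config$burn_in, config$thin, s)
  })
  fit <- posterior_fit(draws = lapply(chains, `[[`, "draws"),
                       deviance = lapply(chains, `[[`, "deviance"),
                       spec = spec, std = std, config = config, dm = dm)
  fit$data_fingerprint <- c(n = length(dm$response), detections = sum(dm$response))
  fit
}

pooled_draws <- function(fit) do.call(rbind, fit$draws)

fixed_effect_names <- function(fit) {
  nm <- colnames(fit$draws[[1]])
  nm[!grepl("^(sigma_|u_section\\[|u_transect\\[)", nm)]
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter, computed from the
#' between- and within-chain variances of the retained draws:
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values above 1.1 are flagged.
#'
#' @param fit a `posterior_fit` with at least two chains.
#' @return named numeric vector of PSRF values, with attribute `flagged`
#'   naming parameters above 1.1.
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  m <- length(fit$draws)
  if (m < 2L) {
    stop("Gelman-Rubin diagnostics need at least 2 chains; rerun with chains >= 2",
         call. = FALSE)
  }
  n <- nrow(fit$draws[[1]])
  means <- sapply(fit$draws, colMeans)
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  vars <- sapply(fit$draws, function(d) apply(d, 2, stats::var))
  if (is.null(dim(vars))) vars <- matrix(vars, nrow = 1)
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)
  psrf <- ifelse(W > 0, sqrt(((n - 1) / n * W + B_over_n) / W),
                 ifelse(B_over_n > 0, Inf, 1))
  names(psrf) <- colnames(fit$draws[[1]])
  attr(psrf, "flagged") <- names(psrf)[psrf > 1.1]
  psrf
}

#' Summarize a posterior fit
#'
#' Per-parameter posterior mean, SD and central 95% credible interval
#' (2.5th / 97.5th percentiles) over the pooled chains, with the odds ratio
#' `exp(posterior mean)` for fixed effects.
#'
#' @param fit a `posterior_fit`.
#' @return a `posterior_summary` data frame with columns `parameter`,
#'   `mean`, `sd`, `lower95`, `upper95`, `or` (NA for non-fixed parameters).
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  d <- pooled_draws(fit)
  fixed <- fixed_effect_names(fit)
  out <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    lower95 = apply(d, 2, stats::quantile, probs = 0.025),
    upper95 = apply(d, 2, stats::quantile, probs = 0.975),
    row.names = NULL
  )
  out$or <- ifelse(out$parameter %in% fixed, exp(out$mean), NA_real_)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
summary.posterior_fit <- function(object, ...) posterior_summary(object)

#' @export
print.posterior_summary <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print(y, ...)
  invisible(x)
}

#' Round half away from zero
#'
#' Reported values follow the half-up convention of the published tables
#' rather than R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Export posterior draws as a data frame / CSV
#'
#' One row per retained draw with `chain` and `iteration` columns followed
#' by one column per parameter.
#'
#' @param x a `posterior_fit`.
#' @param ... unused.
#' @return data frame of draws.
#' @export
as.data.frame.posterior_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$draws), function(ch) {
    d <- as.data.frame(x$draws[[ch]])
    cbind(chain = ch, iteration = seq_len(nrow(d)), d)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname as.data.frame.posterior_fit
#' @param fit a `posterior_fit`.
#' @param path output CSV path.
#' @export
write_draws <- function(fit, path) {
  utils::write.csv(as.data.frame(fit), path, row.names = FALSE)
  invisible(path)
}

#' Write a posterior summary as CSV
#'
#' Columns follow the published table layout (Parameter, Mean, SD,
#' Lower 95%, Upper 95%, OR).
#'
#' @param summary a `posterior_summary` (or a `posterior_fit`, which is
#'   summarised first).
#' @param path output CSV path.
#' @export
write_summary <- function(summary, path) {
  if (inherits(summary, "posterior_fit")) summary <- posterior_summary(summary)
  out <- as.data.frame(summary)
  names(out) <- c("Parameter", "Mean", "SD", "Lower95", "Upper95", "OR")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
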