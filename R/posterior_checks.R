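# Posterior-predictive goodness of fit: Bayesian p-values from a
# discrepancy measure compared between observed and model-replicated data.

DISCREPANCIES <- c("pearson", "deviance", "pearson_cell")

#' Posterior-predictive Bayesian p-value
#'
#' For each retained posterior draw, simulates a replicate dataset from the
#' fitted model at that draw and computes a discrepancy measure T for the
#' observed and replicated data; the Bayesian p-value is the fraction of
#' draws with `T(replicate) >= T(observed)`. Values near 0.5 indicate an
#' adequate model; extreme values (<= 0.05 or >= 0.95) indicate misfit.
#'
#' Discrepancies:
#' \describe{
#'   \item{`pearson`}{per-observation Pearson chi-square,
#'     `sum((y - p)^2 / (p (1 - p)))` (default).}
#'   \item{`deviance`}{`-2 *` Bernoulli log-likelihood.}
#'   \item{`pearson_cell`}{Pearson chi-square on detection counts aggregated
#'     over pond-day-position cells. For binary data the per-observation
#'     measures reduce to functions of the total detection count under an
#'     intercept-only model and so cannot flag structural misfit; the
#'     cell-aggregated measure can.}
#' }
#'
#' @param fit a `posterior_fit` from [fit_detection_model()].
#' @param dm the `edna_design` the model was fit to (defaults to the one
#'   stored in the fit).
#' @param discrepancy one of `"pearson"`, `"deviance"`, `"pearson_cell"`.
#' @param seed seed for the replicate simulations.
#' @param max_draws cap on the number of posterior draws used (evenly
#'   thinned across the pooled chains; default 5000 keeps the Monte-Carlo
#'   error of the p-value below about 0.01).
#' @return a `ppc_result` list: `bayesian_p`, `discrepancy`, `draws_used`.
#' @export
bayesian_p_value <- function(fit, dm = fit$dm,
                             discrepancy = c("pearson", "deviance", "pearson_cell"),
                             seed = 1L, max_draws = 5000L) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (is.character(discrepancy) && length(discrepancy) == 1L &&
      !discrepancy %in% DISCREPANCIES) {
    stop("unknown discrepancy: ", discrepancy, "; available: ",
         paste(DISCREPANCIES, collapse = ", "), call. = FALSE)
  }
  discrepancy <- match.arg(discrepancy)
  if (is.null(dm)) stop("no design available; pass dm", call. = FALSE)
  draws <- pooled_draws(fit)
  if (nrow(draws) > max_draws) {
    draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), , drop = FALSE]
  }
  S <- nrow(draws)
  y <- dm$response
  n <- length(y)
  eta <- dm$X %*% t(draws[, colnames(dm$X), drop = FALSE])   # n x S
  if (dm$spec$random_structure %in% c("section", "section+transect")) {
    u <- draws[, paste0("u_section[", levels(dm$section), "]"), drop = FALSE]
    eta <- eta + t(u[, as.integer(dm$section), drop = FALSE])
  }
  if (dm$spec$random_structure %in% c("transect", "section+transect")) {
    u <- draws[, paste0("u_transect[", levels(dm$transect), "]"), drop = FALSE]
    eta <- eta + t(u[, as.integer(dm$transect), drop = FALSE])
  }
  P <- stats::plogis(eta)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  set.seed(seed)
  Yrep <- matrix(stats::runif(n * S) < P, n, S) * 1
  tvals <- switch(discrepancy,
    pearson = {
      V <- P * (1 - P)
      list(obs = colSums((y - P)^2 / V), rep = colSums((Yrep - P)^2 / V))
    },
    deviance = {
      list(obs = -2 * colSums(y * log(P) + (1 - y) * log(1 - P)),
           rep = -2 * colSums(Yrep * log(P) + (1 - Yrep) * log(1 - P)))
    },
    pearson_cell = {
      g <- dm$cell
      O <- as.vector(rowsum(y, g))
      E <- rowsum(P, g)
      V <- rowsum(P * (1 - P), g)
      list(obs = colSums((O - E)^2 / V),
           rep = colSums((rowsum(Yrep, g) - E)^2 / V))
    }
  )
  structure(list(bayesian_p = mean(tvals$rep >= tvals$obs),
                 discrepancy = discrepancy, draws_used = S),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Bayesian p-value: %.3f (%s discrepancy, %d draws)\n",
              x$bayesian_p, x$discrepancy, x$draws_used))
  if (x$bayesian_p <= 0.05 || x$bayesian_p >= 0.95) {
    cat("extreme p-value: the model does not adequately describe the data\n")
  }
  invisible(x)
}
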