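# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately written from first principles (grid integration,
# textbook formulas, brute-force sums) so they do not share code paths with
# the package implementation they check.

quick_mcmc <- function(iterations = 12000, burn_in = 3000, chains = 3,
                       seed = 1) {
  mcmc_config(iterations, burn_in, chains = chains, seed = seed)
}

stocked_fixture <- function() subset_samples(builtin_pond_study(), pond_id != 1)

best_model_spec <- function(priors = prior_spec()) {
  model_spec(c("middle", "density", "temperature"), priors = priors)
}

# tiny sample table with arbitrary valid design coordinates
tiny_table <- function(detection, density = 1, temperature = 25) {
  n <- length(detection)
  sample_table(data.frame(
    pond_id = 1L, day = 1L,
    transect = ((seq_len(n) - 1L) %% 9L) + 1L,
    section = section_of_transect(((seq_len(n) - 1L) %% 9L) + 1L),
    position = rep(c("surface", "middle", "bottom"), length.out = n),
    density_fish_per_m3 = density, temperature_c = temperature,
    detection = detection
  ), provenance = "test")
}

# Deterministic grid integration of the intercept-only log posterior:
# posterior over beta0 on a fine grid, for comparison with MCMC.
grid_intercept_posterior <- function(y, prior_sd = 10,
                                     grid = seq(-60, 60, by = 0.005)) {
  n <- length(y); s <- sum(y)
  loglik <- s * grid - n * (pmax(grid, 0) + log1p(exp(-abs(grid))))
  logpost <- loglik + dnorm(grid, 0, prior_sd, log = TRUE)
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(mean = sum(w * grid), sd = sqrt(sum(w * grid^2) - sum(w * grid)^2))
}

# Textbook potential-scale-reduction formula, written independently:
# chains as columns of a matrix.
naive_psrf <- function(mat) {
  m <- ncol(mat); n <- nrow(mat)
  chain_means <- colMeans(mat)
  B <- n / (m - 1) * sum((chain_means - mean(chain_means))^2)
  W <- mean(apply(mat, 2, var))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Brute-force Bernoulli log-likelihood + normal prior, independent of the
# package's incremental bookkeeping.
naive_log_posterior <- function(beta, X, y, prior_sd = 10) {
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  sum(dbinom(y, 1, p, log = TRUE)) + sum(dnorm(beta, 0, prior_sd, log = TRUE))
}

# Monte-Carlo standard error of a chain mean via non-overlapping batch means.
batch_mc_se <- function(x, batches = 30) {
  b <- floor(length(x) / batches)
  bm <- vapply(seq_len(batches), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(bm) / sqrt(batches)
}
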