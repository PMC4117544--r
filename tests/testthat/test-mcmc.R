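# mcmc_inference: log posterior, sampler correctness, diagnostics, summaries

test_that("mcmc_config validates its arguments", {
  cfg <- quick_mcmc()
  expect_identical(cfg$iterations, 12000L)
  expect_error(mcmc_config(1000, 1000), "burn_in < iterations")
  expect_error(mcmc_config(chains = 0), "chains")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("log_posterior matches an independent brute-force evaluation", {
  stocked <- stocked_fixture()
  dm <- build_design_matrix(stocked, best_model_spec())
  set.seed(5)
  for (i in 1:5) {
    beta <- rnorm(4)
    names(beta) <- colnames(dm$X)
    expect_equal(log_posterior(beta, dm),
                 naive_log_posterior(beta, dm$X, dm$response))
  }
  expect_error(log_posterior(c(a = 1), dm), "does not match")
})

test_that("log_posterior handles random-effect support boundaries", {
  tab <- tiny_table(c(1L, 0L, 0L, 1L, 0L, 0L))
  dm <- build_design_matrix(tab, model_spec(character(),
                                            random_structure = "section"))
  nm <- c("(Intercept)", "sigma_section",
          paste0("u_section[", levels(dm$section), "]"))
  params <- setNames(c(0, 1, rep(0.1, nlevels(dm$section))), nm)
  lp <- log_posterior(params, dm)
  expect_true(is.finite(lp))
  params["sigma_section"] <- -0.5
  expect_identical(log_posterior(params, dm), -Inf)
  params["sigma_section"] <- 11
  expect_identical(log_posterior(params, dm), -Inf)
})

test_that("likelihood depends only on aggregated counts (collapse exactness)", {
  stocked <- stocked_fixture()
  spec <- best_model_spec()
  dm <- build_design_matrix(stocked, spec)
  shuffled <- as.data.frame(stocked)[sample(nrow(stocked)), ]
  dm2 <- build_design_matrix(sample_table(shuffled), spec)
  beta <- setNames(c(-2.5, -0.8, 1.5, -0.5), colnames(dm$X))
  expect_equal(log_posterior(beta, dm), log_posterior(beta, dm2))
})

test_that("extreme linear predictors stay finite", {
  stocked <- stocked_fixture()
  dm <- build_design_matrix(stocked, best_model_spec())
  beta <- setNames(c(500, -500, 300, -300), colnames(dm$X))
  expect_true(is.finite(log_posterior(beta, dm)))
})

test_that("fits are reproducible from the seed", {
  tab <- tiny_table(c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L))
  spec <- model_spec(character())
  cfg <- mcmc_config(4000, 1000, chains = 2, seed = 9)
  f1 <- fit_detection_model(tab, spec, std = list(), config = cfg)
  f2 <- fit_detection_model(tab, spec, std = list(), config = cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_detection_model(tab, spec, std = list(),
                            config = mcmc_config(4000, 1000, chains = 2, seed = 10))
  expect_false(identical(f1$draws, f3$draws))
  # chains start over-dispersed and are distinct
  expect_false(identical(f1$draws[[1]], f1$draws[[2]]))
})

test_that("intercept-only posterior matches deterministic grid integration", {
  y <- c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)
  fit <- fit_detection_model(tiny_table(y), model_spec(character()),
                             std = list(), config = quick_mcmc(seed = 4))
  oracle <- grid_intercept_posterior(y, prior_sd = 10)
  draws <- do.call(rbind, fit$draws)[, "(Intercept)"]
  se <- batch_mc_se(draws)
  expect_lt(abs(mean(draws) - oracle$mean), 3 * se)
  expect_lt(abs(sd(draws) - oracle$sd), 0.1 * oracle$sd)
})

test_that("stored deviance equals -2 times the Bernoulli log-likelihood", {
  y <- c(1L, 0L, 0L, 1L, 0L, 0L)
  fit <- fit_detection_model(tiny_table(y), model_spec(character()),
                             std = list(),
                             config = mcmc_config(2000, 500, chains = 1, seed = 2))
  b <- fit$draws[[1]][, "(Intercept)"]
  expected <- -2 * (sum(y) * b - length(y) * (pmax(b, 0) + log1p(exp(-abs(b)))))
  expect_equal(fit$deviance[[1]], expected)
})

test_that("thinning and burn-in control the number of stored draws", {
  fit <- fit_detection_model(tiny_table(c(1L, 0L, 1L, 0L)),
                             model_spec(character()), std = list(),
                             config = mcmc_config(3000, 1000, chains = 2,
                                                  thin = 5, seed = 1))
  expect_identical(nrow(fit$draws[[1]]), 400L)
  expect_length(fit$deviance[[2]], 400L)
})

test_that("random-intercept models are sampled within prior support", {
  sim <- simulate_study(paper_design(),
                        true_params(-1, sigma_section = 1), seed = 21)
  spec <- model_spec(character(), random_structure = "section")
  fit <- fit_detection_model(sim, spec, std = list(),
                             config = mcmc_config(4000, 1000, chains = 2, seed = 3))
  d <- do.call(rbind, fit$draws)
  expect_true("sigma_section" %in% colnames(d))
  expect_true(all(d[, "sigma_section"] > 0 & d[, "sigma_section"] < 10))
  expect_identical(sum(grepl("^u_section\\[", colnames(d))), 12L) # 4 ponds x 3
})

test_that("gelman_rubin matches the textbook formula and flags divergence", {
  set.seed(8)
  base <- matrix(rnorm(3000), 1000, 3)
  fit <- posterior_fit(lapply(1:3, function(ch) {
    m <- base[, ch, drop = FALSE]; colnames(m) <- "theta"; m
  }))
  psrf <- gelman_rubin(fit)
  expect_equal(unname(psrf["theta"]), naive_psrf(base))
  expect_lt(psrf["theta"], 1.1)
  expect_length(attr(psrf, "flagged"), 0L)
  # shift one chain far away: flagged
  shifted <- base; shifted[, 3] <- shifted[, 3] + 10
  fit2 <- posterior_fit(lapply(1:3, function(ch) {
    m <- shifted[, ch, drop = FALSE]; colnames(m) <- "theta"; m
  }))
  expect_identical(attr(gelman_rubin(fit2), "flagged"), "theta")
  expect_gt(max(gelman_rubin(fit2)), 1.1)
})

test_that("gelman_rubin refuses single-chain fits", {
  m <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "theta"))
  expect_error(gelman_rubin(posterior_fit(list(m))), "at least 2 chains")
})

test_that("posterior_summary reports moments, intervals and odds ratios", {
  set.seed(1)
  m <- cbind("(Intercept)" = rnorm(5000, -2, 0.5), density = rnorm(5000, 1.5, 0.3))
  fit <- posterior_fit(list(m))
  s <- posterior_summary(fit)
  expect_identical(s$parameter, c("(Intercept)", "density"))
  expect_equal(s$mean, colMeans(m), ignore_attr = TRUE)
  expect_equal(s$lower95, apply(m, 2, quantile, 0.025), ignore_attr = TRUE)
  expect_equal(s$or, exp(colMeans(m)), ignore_attr = TRUE)
  expect_identical(posterior_summary(fit), summary(fit))
  expect_output(print(s), "parameter")
})

test_that("round_half_up follows the half-away-from-zero convention", {
  expect_identical(round_half_up(0.125, 2), 0.13)
  expect_identical(round_half_up(-0.125, 2), -0.13)
  expect_identical(round_half_up(0.39499, 2), 0.39)
  expect_identical(round_half_up(2.5, 0), 3)
})

test_that("draws export round-trips through CSV", {
  fit <- fit_detection_model(tiny_table(c(1L, 0L, 1L, 0L)),
                             model_spec(character()), std = list(),
                             config = mcmc_config(2000, 1000, chains = 2, seed = 6))
  df <- as.data.frame(fit)
  expect_identical(names(df), c("chain", "iteration", "(Intercept)"))
  expect_identical(nrow(df), 2000L)
  path <- tempfile(fileext = ".csv"); on.exit(unlink(path))
  write_draws(fit, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back[["(Intercept)"]], df[["(Intercept)"]])
  spath <- tempfile(fileext = ".csv"); on.exit(unlink(spath), add = TRUE)
  write_summary(fit, spath)
  expect_identical(names(utils::read.csv(spath))[1:3],
                   c("Parameter", "Mean", "SD"))
})
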