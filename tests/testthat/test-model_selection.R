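# model_selection: DIC, weights, comparison tables, confidence set, ratios

test_that("dic_weights reproduces the published confidence-set weights", {
  w <- dic_weights(c(0, 0.75, 1.74, 2.45, 3.32))
  expect_equal(round_half_up(w, 2), c(0.39, 0.27, 0.16, 0.11, 0.07))
  expect_equal(sum(w), 1)
  expect_error(dic_weights(numeric(0)), "non-empty")
  expect_error(dic_weights(c(1, NA)), "finite")
})

test_that("DIC weights are invariant to shifting every DIC by a constant", {
  set.seed(13)
  for (i in 1:10) {
    dics <- runif(6, 100, 140)
    shift <- runif(1, -1000, 1000)
    expect_equal(dic_weights(dics), dic_weights(dics + shift))
  }
})

test_that("dic decomposes as deviance_bar + pD with pD = dbar - D(theta_bar)", {
  stocked <- stocked_fixture()
  fit <- fit_detection_model(stocked, best_model_spec(),
                             config = quick_mcmc(seed = 2))
  v <- dic(fit)
  expect_named(v, c("deviance_bar", "pD", "DIC"))
  expect_equal(unname(v["deviance_bar"]), mean(unlist(fit$deviance)))
  expect_equal(unname(v["DIC"]), unname(v["deviance_bar"] + v["pD"]))
  # pD roughly the number of sampled fixed effects for this regular model
  expect_gt(v["pD"], 1)
  expect_lt(v["pD"], 8)
  # independent check of D(theta_bar) via the exported log posterior minus
  # the prior contribution
  theta_bar <- colMeans(do.call(rbind, fit$draws))
  lp <- log_posterior(theta_bar, fit$dm)
  prior <- sum(dnorm(theta_bar, 0, fit$spec$priors$fixed_sd, log = TRUE))
  dhat <- -2 * (lp - prior)
  expect_equal(unname(v["deviance_bar"] - v["pD"]), dhat)
})

test_that("compare_models ranks ascending DIC with weights and dDIC", {
  stocked <- stocked_fixture()
  fits <- list(
    fit_detection_model(stocked, model_spec(character()), config = quick_mcmc(seed = 5)),
    fit_detection_model(stocked, best_model_spec(), config = quick_mcmc(seed = 6))
  )
  cmp <- compare_models(fits)
  expect_s3_class(cmp, "model_comparison")
  expect_identical(cmp$model[1], "Intercept, middle, density, temperature")
  expect_identical(cmp$dDIC[1], 0)
  expect_true(all(diff(cmp$DIC) >= 0))
  expect_equal(sum(cmp$weight), 1)
  expect_true(all(is.na(cmp$p_value)))
  path <- tempfile(fileext = ".csv"); on.exit(unlink(path))
  write_comparison(cmp, path)
  expect_identical(names(utils::read.csv(path))[1:4],
                   c("model", "Deviance", "pd", "DIC"))
})

test_that("confidence_set keeps models within 10% of the best weight", {
  cmp <- structure(
    data.frame(model = letters[1:6], deviance_bar = 0, pD = 0,
               DIC = c(100, 100.75, 101.74, 102.45, 103.32, 110),
               dDIC = c(0, 0.75, 1.74, 2.45, 3.32, 10)),
    class = c("model_comparison", "data.frame"))
  cmp$weight <- dic_weights(cmp$DIC)
  cmp$p_value <- NA_real_
  cs <- confidence_set(cmp)
  expect_identical(cs$model, letters[1:5])  # exp(-10/2) < 0.10 * best
  expect_equal(sum(cs$weight_conf), 1)
  expect_equal(round_half_up(cs$weight_conf, 2), c(0.39, 0.27, 0.16, 0.11, 0.07))
  # idempotent on the retained set
  cs2 <- confidence_set(cs)
  expect_identical(cs2$model, cs$model)
  expect_equal(cs2$weight_conf, cs$weight_conf)
})

test_that("plausibility_ratios uses the rounded-weight convention", {
  w <- dic_weights(c(0, 0.75, 1.74, 2.45, 3.32))
  r <- plausibility_ratios(w)
  expect_equal(as.vector(r), c(1.44, 2.44, 3.55, 5.57))
  # unrounded ratios attached: exp(dDIC / 2)
  expect_equal(attr(r, "unrounded"),
               exp(c(0.75, 1.74, 2.45, 3.32) / 2))
  expect_error(plausibility_ratios(0.5), "at least two")
})

test_that("select_models fits an all-subsets set reproducibly", {
  stocked <- stocked_fixture()
  cfg <- mcmc_config(4000, 1000, chains = 2, seed = 30)
  cmp <- select_models(stocked, "density", config = cfg)
  expect_identical(nrow(cmp), 2L)
  expect_setequal(cmp$model, c("Intercept", "Intercept, density"))
  # the density model dominates on the stocked data
  expect_identical(cmp$model[1], "Intercept, density")
  cmp2 <- select_models(stocked, "density", config = cfg)
  expect_equal(as.data.frame(cmp), as.data.frame(cmp2))
})
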