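# model_spec: standardization, priors, candidate enumeration, design matrices

test_that("std_from_data reproduces the published density scales", {
  # distinct stocked-pond densities: SD 2.53 fish/m^3
  d <- std_from_data(c(0.32, 1.75, 5.24), "data-distinct-values")
  expect_equal(round_half_up(d$sd, 2), 2.53)
  # all-rows scale over the stocked fixture: SD 2.07 fish/m^3
  stocked <- stocked_fixture()
  a <- std_from_data(stocked$density_fish_per_m3, "data-all-rows")
  expect_equal(round_half_up(a$sd, 2), 2.07)
  expect_equal(a$mean, mean(stocked$density_fish_per_m3))
  expect_error(std_from_data(rep(2, 5)), "zero variance")
})

test_that("standardize centres and scales; round-trips", {
  s <- standardization(10, 2)
  x <- c(6, 10, 14)
  z <- standardize(x, s)
  expect_equal(z, c(-2, 0, 2))
  expect_equal(z * s$sd + s$mean, x)
  expect_error(standardization(0, 0), "sd must be > 0")
  expect_error(standardize(x, list(mean = 10, sd = 2)))
})

test_that("prior_spec validates families and bounds", {
  p <- prior_spec()
  expect_identical(p$fixed_sd, 10)
  expect_identical(p$fixed_family, "normal")
  expect_identical(p$random_sd_params, c(0, 10))
  expect_identical(prior_spec(fixed_family = "logistic")$fixed_family, "logistic")
  expect_error(prior_spec(fixed_sd = 0), "finite and positive")
  expect_error(prior_spec(random_sd_family = "half-cauchy"), "uniform")
  expect_error(prior_spec(random_sd_params = c(5, 2)))
})

test_that("model_spec builds labels and rejects bad terms", {
  m <- model_spec(c("middle", "density", "temperature"))
  expect_identical(m$label, "Intercept, middle, density, temperature")
  expect_identical(model_spec(character())$label, "Intercept")
  expect_error(model_spec("ph"), "unknown fixed term")
  expect_error(model_spec(c("density", "density")), "duplicated")
  expect_error(model_spec("density", random_structure = "pond"),
               "random_structure")
  expect_identical(variance_structures(),
                   c("none", "section", "transect", "section+transect"))
})

test_that("enumerate_candidates yields the full deterministic subset lattice", {
  cands <- enumerate_candidates(c("density", "temperature", "middle", "bottom"))
  expect_length(cands, 16L)
  labels <- vapply(cands, `[[`, "", "label")
  expect_identical(labels[1], "Intercept")
  expect_identical(anyDuplicated(labels), 0L)
  # ordered by subset size, then lexicographically in supplied order
  sizes <- lengths(lapply(cands, `[[`, "fixed_terms"))
  expect_identical(sizes, sort(sizes))
  expect_identical(labels[2], "Intercept, density")
  expect_identical(labels[16], "Intercept, density, temperature, middle, bottom")
  # deterministic across calls
  expect_identical(labels,
                   vapply(enumerate_candidates(c("density", "temperature",
                                                 "middle", "bottom")),
                          `[[`, "", "label"))
})

test_that("paper_standardization mixes data-derived and explicit constants", {
  std <- paper_standardization()
  expect_identical(std$density$source, "data-all-rows")
  expect_equal(round_half_up(std$density$sd, 2), 2.07)
  expect_identical(std$temperature$source, "explicit")
  expect_identical(std$temperature$sd, 1.02)
  expect_equal(round_half_up(std$temperature$mean, 2), 29.60)
})

test_that("build_design_matrix lays out the model as specified", {
  stocked <- stocked_fixture()
  std <- paper_standardization()
  dm <- build_design_matrix(stocked, best_model_spec(), std)
  expect_s3_class(dm, "edna_design")
  expect_identical(colnames(dm$X),
                   c("(Intercept)", "middle", "density", "temperature"))
  expect_identical(nrow(dm$X), 243L)
  expect_identical(dm$response, as.integer(stocked$detection))
  expect_equal(dm$X[, "middle"], as.numeric(stocked$position == "middle"))
  expect_equal(dm$X[, "density"],
               (stocked$density_fish_per_m3 - std$density$mean) / std$density$sd)
  # ponds stay distinct in the grouping factors
  expect_identical(nlevels(dm$section), 9L)   # 3 ponds x 3 sections
  expect_identical(nlevels(dm$transect), 27L) # 3 ponds x 9 transects
  expect_identical(nlevels(dm$cell), 27L)     # 3 ponds x 3 days x 3 positions
})

test_that("day enters unstandardized; missing standardizations error", {
  stocked <- stocked_fixture()
  dm <- build_design_matrix(stocked, model_spec("day"), std = list())
  expect_equal(dm$X[, "day"], as.numeric(stocked$day))
  expect_error(build_design_matrix(stocked, model_spec("density"), std = list()),
               "standardization")
  expect_error(build_design_matrix(subset_samples(stocked, pond_id == 99),
                                   model_spec(character())),
               "empty")
})
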