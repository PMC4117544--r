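# Stratified-design simulator: Bernoulli detections from a logistic model
# with optional section- and transect-level random intercepts, for
# parameter-recovery and pipeline tests.

#' Describe a stratified pond sampling design
#'
#' @param ponds data frame with columns `pond_id` and `density_fish_per_m3`.
#' @param temperatures data frame with columns `pond_id`, `day`,
#'   `temperature_c` giving one temperature per pond-day.
#' @param days integer vector of sampling days.
#' @param transects_per_pond number of transects per pond; must be divisible
#'   by 3 so transects group into the three pond sections (default 9).
#' @param samples_per_transect samples per transect per day (default 3; the
#'   three water-column positions are cycled across a transect's samples, so
#'   the default yields one surface, one middle and one bottom sample per
#'   transect and a balanced 1/3 split per pond-day).
#' @return a `study_design` object.
#' @export
study_design <- function(ponds, temperatures, days = c(1L, 5L, 10L),
                         transects_per_pond = 9L, samples_per_transect = 3L) {
  ponds <- as.data.frame(ponds)
  temperatures <- as.data.frame(temperatures)
  stopifnot(all(c("pond_id", "density_fish_per_m3") %in% names(ponds)),
            all(c("pond_id", "day", "temperature_c") %in% names(temperatures)),
            transects_per_pond >= 3L, samples_per_transect >= 1L)
  if (transects_per_pond %% 3L != 0L) {
    stop("transects_per_pond must be divisible by 3 (three sections)", call. = FALSE)
  }
  need <- expand.grid(pond_id = ponds$pond_id, day = days)
  key <- paste(temperatures$pond_id, temperatures$day)
  missing <- !paste(need$pond_id, need$day) %in% key
  if (any(missing)) {
    stop("missing temperature for pond-day(s): ",
         paste(paste(need$pond_id[missing], need$day[missing], sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  structure(list(ponds = ponds, temperatures = temperatures, days = as.integer(days),
                 transects_per_pond = as.integer(transects_per_pond),
                 samples_per_transect = as.integer(samples_per_transect)),
            class = "study_design")
}

#' The four-pond experimental design
#'
#' Four ponds at densities 0 (control), 0.32, 1.75 and 5.24 fish/m^3,
#' sampled on days 1, 5 and 10 with 9 transects x 3 samples per pond-day
#' (324 planned samples), using the recorded pond-day temperatures.
#'
#' @return a `study_design`.
#' @export
paper_design <- function() {
  cons <- pond_study_constants()
  ponds <- unique(cons[, c("pond_id", "density_fish_per_m3")])
  rownames(ponds) <- NULL
  study_design(ponds, cons[, c("pond_id", "day", "temperature_c")])
}

#' Number of samples a design plans
#' @param design a `study_design`.
#' @return integer count.
#' @export
design_size <- function(design) {
  stopifnot(inherits(design, "study_design"))
  nrow(design$ponds) * length(design$days) *
    design$transects_per_pond * design$samples_per_transect
}

#' True parameter values for the detection simulator
#'
#' Log-odds scale coefficients of the generating logistic model, the random
#' intercept SDs, and the standardization constants shared between
#' simulation and fitting (carrying them here keeps the covariate scale
#' fixed across parameter-recovery replicates instead of drifting with each
#' simulated dataset).
#'
#' @param beta0 intercept (log-odds of detection at covariate means,
#'   surface position).
#' @param beta_density,beta_temperature slopes per 1 SD of the standardized
#'   covariate.
#' @param beta_middle,beta_bottom log-odds offsets of the middle/bottom
#'   strata relative to surface.
#' @param sigma_section,sigma_transect non-negative SDs of the section- and
#'   transect-level random intercepts (0 disables the component).
#' @param standardization named list of `standardization` objects for
#'   `density` and `temperature` (default: the bundled pond analysis scale,
#'   [paper_standardization()]).
#' @return a `true_params` object.
#' @export
true_params <- function(beta0, beta_density = 0, beta_temperature = 0,
                        beta_middle = 0, beta_bottom = 0,
                        sigma_section = 0, sigma_transect = 0,
                        standardization = paper_standardization()) {
  stopifnot(sigma_section >= 0, sigma_transect >= 0,
            inherits(standardization$density, "standardization"),
            inherits(standardization$temperature, "standardization"))
  structure(list(beta0 = beta0, beta_density = beta_density,
                 beta_temperature = beta_temperature,
                 beta_middle = beta_middle, beta_bottom = beta_bottom,
                 sigma_section = sigma_section, sigma_transect = sigma_transect,
                 standardization = standardization),
            class = "true_params")
}

#' Posterior-mean parameters of the published best-approximating model
#'
#' Convenience set of generating values: intercept -2.78, density slope
#' 1.58, temperature slope -0.51, middle offset -0.81, no bottom offset and
#' no random intercepts, on the bundled analysis' covariate scale.
#'
#' @return a `true_params` object.
#' @export
paper_best_params <- function() {
  true_params(beta0 = -2.78, beta_density = 1.58, beta_temperature = -0.51,
              beta_middle = -0.81)
}

#' Simulate a detection/non-detection study
#'
#' Builds the full sample layout of `design`, draws one random intercept per
#' pond-section and one per pond-transect (N(0, sigma); shared across days,
#' as sections and transects are fixed physical locations), computes each
#' sample's detection probability as
#' `plogis(beta0 + beta_density*z_density + beta_temperature*z_temperature +
#' position offsets + u_section + u_transect)`
#' and draws independent Bernoulli detections.
#'
#' All randomness flows from a single seed in a fixed order (section
#' intercepts, then transect intercepts, then detections in row order), so
#' output is bit-reproducible.
#'
#' @param design a [study_design()].
#' @param params a [true_params()].
#' @param seed integer seed (required).
#' @return a `sample_table` with provenance `"simulated"`.
#' @export
simulate_study <- function(design, params, seed) {
  stopifnot(inherits(design, "study_design"), inherits(params, "true_params"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  layout <- expand.grid(
    sample = seq_len(design$samples_per_transect),
    transect = seq_len(design$transects_per_pond),
    day = design$days,
    pond_id = design$ponds$pond_id,
    KEEP.OUT.ATTRS = FALSE
  )
  layout$section <- section_of_transect(layout$transect)
  # cycle positions within each transect's samples
  layout$position <- POSITIONS[((layout$sample - 1L) %% 3L) + 1L]
  layout$density_fish_per_m3 <-
    design$ponds$density_fish_per_m3[match(layout$pond_id, design$ponds$pond_id)]
  tkey <- paste(design$temperatures$pond_id, design$temperatures$day)
  layout$temperature_c <-
    design$temperatures$temperature_c[match(paste(layout$pond_id, layout$day), tkey)]

  sec_groups <- unique(layout[, c("pond_id", "section")])
  sec_groups <- sec_groups[order(sec_groups$pond_id, sec_groups$section), ]
  u_sec <- stats::rnorm(nrow(sec_groups), 0, params$sigma_section)
  tr_groups <- unique(layout[, c("pond_id", "transect")])
  tr_groups <- tr_groups[order(tr_groups$pond_id, tr_groups$transect), ]
  u_tr <- stats::rnorm(nrow(tr_groups), 0, params$sigma_transect)

  zd <- standardize(layout$density_fish_per_m3, params$standardization$density)
  zt <- standardize(layout$temperature_c, params$standardization$temperature)
  eta <- params$beta0 +
    params$beta_density * zd +
    params$beta_temperature * zt +
    params$beta_middle * (layout$position == "middle") +
    params$beta_bottom * (layout$position == "bottom") +
    u_sec[match(paste(layout$pond_id, layout$section),
                paste(sec_groups$pond_id, sec_groups$section))] +
    u_tr[match(paste(layout$pond_id, layout$transect),
               paste(tr_groups$pond_id, tr_groups$transect))]
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  layout$detection <- stats::rbinom(nrow(layout), 1L, stats::plogis(eta))
  sample_table(layout[, SAMPLE_COLUMNS], provenance = "simulated")
}
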