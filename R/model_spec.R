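# Candidate model definitions: covariate standardization, priors, the
# random-intercept structures, design matrices, and enumeration of the
# all-subsets candidate set.

FIXED_TERMS <- c("middle", "bottom", "density", "temperature", "day")
RANDOM_STRUCTURES <- c("none", "section", "transect", "section+transect")

#' Standardization constants for a continuous covariate
#'
#' @param mean centre.
#' @param sd scale; must be strictly positive.
#' @param source how the constants were obtained: `"explicit"`,
#'   `"data-all-rows"` (mean/SD of the covariate column, n-1 denominator) or
#'   `"data-distinct-values"` (mean/SD over the distinct covariate values,
#'   e.g. the pond-level densities).
#' @return a `standardization` object.
#' @export
standardization <- function(mean, sd, source = "explicit") {
  if (!is.finite(sd) || sd <= 0) stop("standardization sd must be > 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, source = source),
            class = "standardization")
}

#' Derive standardization constants from data
#'
#' @param values numeric covariate values (one per record).
#' @param source `"data-all-rows"` uses all values; `"data-distinct-values"`
#'   uses each distinct value once (e.g. the three stocked-pond densities,
#'   whose SD is 2.53 fish/m^3). Both use the n-1 denominator.
#' @return a `standardization` object.
#' @examples
#' std_from_data(c(0.32, 1.75, 5.24), "data-distinct-values")$sd # 2.53
#' @export
std_from_data <- function(values, source = c("data-all-rows",
                                             "data-distinct-values")) {
  source <- match.arg(source)
  v <- if (source == "data-distinct-values") sort(unique(values)) else values
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("covariate has zero variance; cannot standardize", call. = FALSE)
  }
  standardization(mean(v), s, source)
}

#' Standardize a covariate vector
#'
#' @param values numeric vector.
#' @param how a `standardization` object.
#' @return `(values - mean) / sd`.
#' @export
standardize <- function(values, how) {
  stopifnot(inherits(how, "standardization"))
  (values - how$mean) / how$sd
}

#' Prior specification for logistic-regression parameters
#'
#' Fixed effects receive independent zero-mean priors on the log-odds scale;
#' random-intercept standard deviations receive a uniform prior. The
#' defaults are weakly informative: they keep the posterior proper even for
#' zero-detection (control pond) data, where the intercept is
#' prior-dominated — use [false_positive_report()]'s sensitivity output in
#' that case.
#'
#' @param fixed_sd SD of the normal prior on each fixed effect (default 10).
#' @param fixed_family `"normal"`, or `"logistic"` for a standard-logistic
#'   prior on the log-odds, which is equivalent to a flat Beta(1,1) prior on
#'   the probability scale for an intercept-only model.
#' @param random_sd_family family of the prior on random-intercept SDs;
#'   only `"uniform"` is implemented.
#' @param random_sd_params numeric lower/upper bounds of the uniform prior
#'   (default `c(0, 10)`).
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(fixed_sd = 10, fixed_family = c("normal", "logistic"),
                       random_sd_family = "uniform",
                       random_sd_params = c(0, 10)) {
  fixed_family <- match.arg(fixed_family)
  if (fixed_family == "normal" && (!is.finite(fixed_sd) || fixed_sd <= 0)) {
    stop("fixed_sd must be finite and positive", call. = FALSE)
  }
  if (!identical(random_sd_family, "uniform")) {
    stop("only a uniform random-SD prior is implemented", call. = FALSE)
  }
  if (length(random_sd_params) != 2L || any(!is.finite(random_sd_params)) ||
      random_sd_params[1] < 0 || diff(random_sd_params) <= 0) {
    stop("random_sd_params must be finite bounds 0 <= lower < upper", call. = FALSE)
  }
  structure(list(fixed_sd = fixed_sd, fixed_family = fixed_family,
                 random_sd_family = random_sd_family,
                 random_sd_params = random_sd_params),
            class = "prior_spec")
}

#' Specify a candidate detection model
#'
#' A model always contains an intercept; `middle` and `bottom` are 0/1
#' indicators with surface as baseline; `density` and `temperature` enter
#' standardized; `day` enters unstandardized (its slope is per study day).
#'
#' @param fixed_terms character subset of
#'   `c("middle", "bottom", "density", "temperature", "day")`.
#' @param random_structure one of [variance_structures()].
#' @param priors a [prior_spec()].
#' @return a `model_spec` object with a human-readable `label`.
#' @export
model_spec <- function(fixed_terms = character(),
                       random_structure = "none",
                       priors = prior_spec()) {
  fixed_terms <- as.character(fixed_terms)
  bad <- setdiff(fixed_terms, FIXED_TERMS)
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(fixed_terms)) stop("duplicated fixed terms", call. = FALSE)
  if (!random_structure %in% RANDOM_STRUCTURES) {
    stop("random_structure must be one of: ",
         paste(RANDOM_STRUCTURES, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(priors, "prior_spec"))
  label <- paste(c("Intercept", fixed_terms), collapse = ", ")
  structure(list(fixed_terms = fixed_terms, random_structure = random_structure,
                 priors = priors, label = label),
            class = "model_spec")
}

#' The four random-intercept structures considered
#'
#' In order: no random effects; a random intercept per pond section; per
#' pond transect; and both.
#' @return character vector of length 4.
#' @export
variance_structures <- function() RANDOM_STRUCTURES

#' Enumerate the all-subsets candidate model set
#'
#' Every subset of the supplied predictors (including the empty set, i.e.
#' the intercept-only model) becomes one candidate, in deterministic order:
#' by subset size, then lexicographically in the order the predictors were
#' supplied.
#'
#' @param predictors ordered character vector of fixed-effect terms.
#' @param priors a [prior_spec()] shared by all candidates.
#' @param random_structure random-intercept structure shared by all
#'   candidates (selected beforehand on the global model; see
#'   [variance_structures()]).
#' @return list of [model_spec()] objects (length `2^length(predictors)`).
#' @examples
#' length(enumerate_candidates(c("density", "temperature", "middle", "bottom")))
#' # 16
#' @export
enumerate_candidates <- function(predictors, priors = prior_spec(),
                                 random_structure = "none") {
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors)) stop("duplicated predictors", call. = FALSE)
  k <- length(predictors)
  subsets <- list(integer(0))
  if (k > 0L) {
    for (size in seq_len(k)) {
      subsets <- c(subsets, utils::combn(seq_len(k), size, simplify = FALSE))
    }
  }
  lapply(subsets, function(idx) {
    model_spec(predictors[idx], random_structure = random_structure,
               priors = priors)
  })
}

#' Default covariate standardizations for the bundled pond analysis
#'
#' Density is standardized by the mean and SD of the 243 stocked-pond
#' sample values (SD 2.07 fish/m^3); temperature by explicit constants —
#' the mean of the stocked pond-day temperatures (29.60 C) and an SD of
#' 1.02 C, the scale on which the published temperature odds ratio is
#' expressed (the per-stratum temperature measurements behind that
#' constant were not published, so it is carried as an explicit constant).
#'
#' @param table sample table the density constants are computed from
#'   (default: the stocked-pond subset of [builtin_pond_study()]).
#' @return named list of `standardization` objects for `density` and
#'   `temperature`.
#' @export
paper_standardization <- function(table = NULL) {
  if (is.null(table)) {
    table <- subset_samples(builtin_pond_study(), pond_id != 1)
  }
  list(
    density = std_from_data(table$density_fish_per_m3, "data-all-rows"),
    temperature = standardization(29.60111, 1.02, source = "explicit")
  )
}

#' Build a design matrix for a candidate model
#'
#' @param table a non-empty `sample_table`.
#' @param spec a [model_spec()].
#' @param std named list of `standardization` objects for any of the
#'   continuous terms in the model (`density`, `temperature`); `day`
#'   always enters unstandardized.
#' @return an `edna_design` object: binary response vector, fixed-effect
#'   matrix `X` (intercept first), section/transect grouping factors
#'   (ponds kept distinct), pond-day-position cell ids used by grouped
#'   posterior-predictive discrepancies, and the spec.
#' @export
build_design_matrix <- function(table, spec, std = paper_standardization()) {
  stopifnot(inherits(table, "sample_table"), inherits(spec, "model_spec"))
  if (nrow(table) == 0L) stop("empty sample table", call. = FALSE)
  n <- nrow(table)
  cols <- list("(Intercept)" = rep(1, n))
  for (term in spec$fixed_terms) {
    cols[[term]] <- switch(term,
      middle = as.numeric(table$position == "middle"),
      bottom = as.numeric(table$position == "bottom"),
      density = {
        if (is.null(std$density)) stop("no standardization supplied for density",
                                       call. = FALSE)
        standardize(table$density_fish_per_m3, std$density)
      },
      temperature = {
        if (is.null(std$temperature)) stop("no standardization supplied for temperature",
                                           call. = FALSE)
        standardize(table$temperature_c, std$temperature)
      },
      day = as.numeric(table$day)
    )
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(
    response = as.integer(table$detection),
    X = X,
    section = factor(paste(table$pond_id, table$section, sep = ":")),
    transect = factor(paste(table$pond_id, table$transect, sep = ":")),
    cell = factor(paste(table$pond_id, table$day, table$position, sep = ":")),
    spec = spec,
    std = std
  ), class = "edna_design")
}
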