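# Sample-level data model for stratified eDNA detection surveys.
#
# A sample table holds one row per 1-L water sample with its design
# coordinates (pond, day, section, transect, water-column position),
# pond-level covariates (fish density, water temperature) and the binary
# qPCR detection outcome.

#' Required columns of a sample table
#' @keywords internal
SAMPLE_COLUMNS <- c("pond_id", "day", "section", "transect", "position",
                    "density_fish_per_m3", "temperature_c", "detection")

#' Water-column positions (surface is the statistical baseline)
#' @keywords internal
POSITIONS <- c("surface", "middle", "bottom")

#' Construct a sample table
#'
#' Validates and classes a data frame of 1-L water-sample detection records.
#' Each record carries the stratified design coordinates (pond, study day,
#' pond section 1-3, transect 1-9, water-column position), the pond-level
#' covariates (fish density in fish per cubic metre, water temperature in
#' degrees Celsius) and a binary eDNA detection outcome.
#'
#' @param records data frame with columns `pond_id`, `day`, `section`,
#'   `transect`, `position`, `density_fish_per_m3`, `temperature_c`,
#'   `detection`.
#' @param provenance free-text tag recording where the records came from
#'   (`"fixture"`, `"file"` or `"simulated"`).
#' @return a `sample_table` (a validated data frame with a `provenance`
#'   attribute), row order preserved.
#' @seealso [builtin_pond_study()], [load_samples()], [simulate_study()]
#' @export
sample_table <- function(records, provenance = "unknown") {
  records <- validate_sample_table(records)
  structure(records, class = c("sample_table", "data.frame"),
            provenance = provenance)
}

#' Validate sample records
#'
#' Checks column presence, position labels, binary detections, non-negative
#' densities and section/transect consistency (transects 1-3 belong to
#' section 1, 4-6 to section 2, 7-9 to section 3). Errors name the offending
#' row and column.
#'
#' @param records data frame of candidate records.
#' @return the records, invisibly coerced to canonical column types.
#' @export
validate_sample_table <- function(records) {
  records <- as.data.frame(records)
  missing <- setdiff(SAMPLE_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("sample table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(col, rows, what) {
    stop(sprintf("invalid %s in column '%s' at row(s) %s", what, col,
                 paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
  }
  records$position <- tolower(as.character(records$position))
  bad <- which(!records$position %in% POSITIONS)
  if (length(bad)) fail("position", bad, "position label")
  det <- records$detection
  bad <- which(!(det %in% c(0, 1)) | is.na(det))
  if (length(bad)) fail("detection", bad, "non-binary detection value")
  records$detection <- as.integer(det)
  bad <- which(is.na(records$density_fish_per_m3) |
                 records$density_fish_per_m3 < 0)
  if (length(bad)) fail("density_fish_per_m3", bad, "negative or missing density")
  for (col in c("pond_id", "day", "section", "transect")) {
    v <- records[[col]]
    bad <- which(is.na(v) | v != as.integer(v))
    if (length(bad)) fail(col, bad, "non-integer value")
    records[[col]] <- as.integer(records[[col]])
  }
  bad <- which(records$section != section_of_transect(records$transect))
  if (length(bad)) fail("section", bad, "section/transect mismatch")
  invisible(records)
}

#' Section implied by a transect index
#'
#' Transects are numbered 1-9 within a pond; three consecutive transects
#' make up one of the pond's three sections.
#' @param transect integer transect index (1-based).
#' @return integer section index.
#' @export
section_of_transect <- function(transect) {
  as.integer(ceiling(transect / 3))
}

#' Read a sample table from CSV
#'
#' Expects an RFC-4180 style CSV with a header row naming the canonical
#' columns (see [sample_table()]); positions are matched case-insensitively.
#'
#' @param path path to a CSV file.
#' @param ... further options passed to [utils::read.csv()].
#' @return a validated `sample_table` with provenance `"file"`; row order
#'   is preserved.
#' @export
load_samples <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, ...)
  sample_table(df, provenance = "file")
}

#' Write a sample table to CSV
#'
#' Positions are serialised lowercase; the schema round-trips through
#' [load_samples()] with identical field values.
#'
#' @param table a `sample_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  utils::write.csv(as.data.frame(table)[SAMPLE_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pond-day constants of the four-pond African jewelfish experiment:
# densities in fish/m^3, one mean temperature per pond and day, and the
# per-stratum detection counts out of 9 samples.
pond_study_constants <- function() {
  data.frame(
    pond_id = rep(1:4, each = 3L),
    day = rep(c(1L, 5L, 10L), 4L),
    density_fish_per_m3 = rep(c(0, 0.32, 1.75, 5.24), each = 3L),
    n_fish = rep(c(0L, 60L, 330L, 990L), each = 3L),
    volume_m3 = 189,
    temperature_c = c(30.20, 30.17, 28.30,
                      30.77, 29.77, 28.23,
                      30.70, 29.87, 28.23,
                      30.77, 29.77, 28.30),
    surface = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 2L, 2L, 6L),
    middle  = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 2L, 0L, 2L),
    bottom  = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 3L, 1L, 7L)
  )
}

#' The bundled four-pond eDNA detection experiment
#'
#' Reconstructs the full 324-sample detection/non-detection dataset of the
#' African jewelfish pond experiment: 4 ponds (one fishless control, plus
#' stocked ponds at 0.32, 1.75 and 5.24 fish per cubic metre) sampled on
#' days 1, 5 and 10, with 27 one-litre samples per pond-day laid out over
#' 9 transects in 3 sections, each transect contributing one surface, one
#' middle and one bottom sample.
#'
#' Per-stratum detection counts and pond-day mean temperatures are those of
#' the published experiment. Which of the nine samples within a
#' pond-day-position cell were the detections was not recorded; detections
#' are assigned deterministically to the lowest transect indices. This
#' choice is inferentially neutral for models without section or transect
#' random effects, whose likelihood depends only on the per-cell counts.
#'
#' @return a `sample_table` with 324 records (28 detections) and provenance
#'   `"fixture"`.
#' @examples
#' ponds <- builtin_pond_study()
#' nrow(ponds)          # 324
#' sum(ponds$detection) # 28
#' @export
builtin_pond_study <- function() {
  cons <- pond_study_constants()
  rows <- lapply(seq_len(nrow(cons)), function(i) {
    r <- cons[i, ]
    rec <- data.frame(
      pond_id = r$pond_id,
      day = r$day,
      transect = rep(1:9, times = 3L),
      position = rep(POSITIONS, each = 9L),
      density_fish_per_m3 = r$density_fish_per_m3,
      temperature_c = r$temperature_c
    )
    counts <- c(surface = r$surface, middle = r$middle, bottom = r$bottom)
    rec$detection <- as.integer(rec$transect <= counts[rec$position])
    rec
  })
  out <- do.call(rbind, rows)
  out$section <- section_of_transect(out$transect)
  sample_table(out[SAMPLE_COLUMNS], provenance = "fixture")
}

#' Subset a sample table by a field-based predicate
#'
#' @param table a `sample_table`.
#' @param predicate an expression over the table's columns, e.g.
#'   `pond_id != 1`. Referencing an unknown field is an error. An empty
#'   match returns an empty table, not an error.
#' @return the matching records as a `sample_table` (provenance preserved).
#' @examples
#' stocked <- subset_samples(builtin_pond_study(), pond_id != 1)
#' nrow(stocked) # 243
#' @export
subset_samples <- function(table, predicate) {
  stopifnot(inherits(table, "sample_table"))
  expr <- substitute(predicate)
  vars <- all.vars(expr)
  unknown <- setdiff(vars, names(table))
  if (length(unknown) > 0L) {
    stop("predicate references unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- eval(expr, as.data.frame(table), parent.frame())
  if (!is.logical(keep)) stop("predicate must be logical", call. = FALSE)
  out <- as.data.frame(table)[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sample_table", "data.frame"),
            provenance = attr(table, "provenance"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d records, %d detections (provenance: %s)\n",
              nrow(x), sum(x$detection), attr(x, "provenance")))
  print(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
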