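# Domain tables and delimited-text readers/writers.
#
# All tables are plain data frames; dates are `Date` (whole days, no
# time-of-day) and every duration is an exact day difference.

EVENT_COLUMNS <- c("patient_id", "source", "event_date", "vocabulary", "code",
                   "gestation_weeks", "scan_weeks", "n_babies")

#' Construct a validated table of source events
#'
#' One row per dated, coded record from one of the four linked datasets
#' (`GP`, `HES_MAT`, `HES_APC`, `HES_OPCS`). Vocabularies are constrained
#' to their datasets (SNOMED CT only in GP, OPCS-4 only in HES Procedures)
#' and recorded gestation (whole weeks, the HES Maternity GESTAT field) is
#' only accepted on `HES_MAT` rows.
#'
#' @param patient_id character identifiers
#' @param source dataset label, one of `GP`, `HES_MAT`, `HES_APC`, `HES_OPCS`
#' @param event_date coercible to `Date`
#' @param vocabulary `SNOMED`, `ICD10` or `OPCS4`
#' @param code clinical code string
#' @param gestation_weeks optional whole weeks of gestation (HES_MAT only)
#' @param scan_weeks optional completed weeks at an antenatal scan
#' @param n_babies optional number of babies delivered
#' @return data frame of class `source_events`, canonically sorted
#' @export
source_events <- function(patient_id, source, event_date, vocabulary, code,
                          gestation_weeks = NA_integer_,
                          scan_weeks = NA_integer_,
                          n_babies = NA_integer_) {
  ev <- data.frame(
    patient_id = as.character(patient_id),
    source = as.character(source),
    event_date = as.Date(event_date),
    vocabulary = as.character(vocabulary),
    code = as.character(code),
    gestation_weeks = as.integer(gestation_weeks),
    scan_weeks = as.integer(scan_weeks),
    n_babies = as.integer(n_babies),
    stringsAsFactors = FALSE
  )
  validate_source_events(ev)
  canonical_sort(ev)
}

validate_source_events <- function(ev) {
  bad <- which(!ev$source %in% SOURCES)
  if (length(bad))
    stop("unknown source '", ev$source[bad[1]], "' at row ", bad[1])
  bad <- which(!ev$vocabulary %in% VOCABULARIES)
  if (length(bad))
    stop("unknown vocabulary '", ev$vocabulary[bad[1]], "' at row ", bad[1])
  bad <- which(ev$vocabulary == "SNOMED" & ev$source != "GP")
  if (length(bad))
    stop("SNOMED code outside GP records at row ", bad[1])
  bad <- which(ev$vocabulary == "OPCS4" & ev$source != "HES_OPCS")
  if (length(bad))
    stop("OPCS4 code outside HES_OPCS records at row ", bad[1])
  bad <- which(!is.na(ev$gestation_weeks) & ev$source != "HES_MAT")
  if (length(bad))
    stop("gestation_weeks recorded outside HES_MAT at row ", bad[1])
  bad <- which(!is.na(ev$gestation_weeks) & ev$gestation_weeks < 0L)
  if (length(bad))
    stop("negative gestation_weeks at row ", bad[1])
  bad <- which(!is.na(ev$n_babies) & ev$n_babies < 1L)
  if (length(bad))
    stop("n_babies must be positive at row ", bad[1])
  if (anyNA(ev$event_date))
    stop("missing event_date at row ", which(is.na(ev$event_date))[1])
  invisible(ev)
}

#' Canonical event ordering
#'
#' Sorts events by patient, date, source precedence (maternity spine
#' first), vocabulary and code. All downstream tie-breaking is defined
#' against this order, making the pipeline independent of input row order.
#'
#' @param ev event data frame
#' @return the same rows, canonically ordered
#' @export
canonical_sort <- function(ev) {
  o <- order(ev$patient_id, ev$event_date, source_rank(ev$source),
             ev$vocabulary, ev$code, method = "radix")
  out <- ev[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("source_events", class(out)))
  out
}

parse_date_column <- function(x, column, file) {
  x <- trimws(x)
  d <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonempty <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[nonempty], format = "%Y-%m-%d")
  # as.Date() is lenient about impossible components in some locales; insist
  # on exact round-trip.
  ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x[nonempty]
  if (any(!ok)) {
    row <- which(nonempty)[which(!ok)[1]]
    stop("malformed date '", x[nonempty][which(!ok)[1]], "' in column '",
         column, "' at data row ", row, if (!is.null(file)) paste0(" of ", file))
  }
  d[nonempty] <- parsed
  d
}

parse_int_column <- function(x, column, file) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  nonempty <- !is.na(x) & nzchar(x)
  v <- suppressWarnings(as.integer(x[nonempty]))
  if (anyNA(v)) {
    row <- which(nonempty)[which(is.na(v))[1]]
    stop("non-integer value '", x[nonempty][which(is.na(v))[1]],
         "' in column '", column, "' at data row ", row,
         if (!is.null(file)) paste0(" of ", file))
  }
  out[nonempty] <- v
  out
}

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Read an event table
#'
#' Reads one comma-delimited event table (columns
#' `patient_id,source,event_date,vocabulary,code,gestation_weeks,scan_weeks,n_babies`,
#' ISO-8601 dates, empty string for missing) and applies the source's
#' coverage window: events dated after a source's coverage end (or before
#' an optional coverage start) are dropped and counted in the attached load
#' report. GP data in the shipped defaults end on 2022-02-11 while HES
#' data run to 2022-09-30.
#'
#' @param path file path
#' @param params `register_params` supplying per-source coverage windows
#' @param source_label if given, all rows must carry this source
#' @param coverage_start optional lower bound applied to all rows
#' @return `source_events` data frame with attribute `load_report`
#'   (a list with `n_read` and `n_dropped`)
#' @export
read_event_table <- function(path, params = register_params(),
                             source_label = NULL, coverage_start = NULL) {
  df <- read_delim_checked(path, EVENT_COLUMNS)
  if (nrow(df) == 0) {
    ev <- empty_events()
    attr(ev, "load_report") <- list(n_read = 0L, n_dropped = 0L)
    return(ev)
  }
  if (!is.null(source_label) && any(df$source != source_label)) {
    bad <- which(df$source != source_label)[1]
    stop("schema error in ", path, ": row ", bad, " has source '",
         df$source[bad], "', expected '", source_label, "'")
  }
  ev <- data.frame(
    patient_id = df$patient_id,
    source = df$source,
    event_date = parse_date_column(df$event_date, "event_date", path),
    vocabulary = df$vocabulary,
    code = df$code,
    gestation_weeks = parse_int_column(df$gestation_weeks, "gestation_weeks", path),
    scan_weeks = parse_int_column(df$scan_weeks, "scan_weeks", path),
    n_babies = parse_int_column(df$n_babies, "n_babies", path),
    stringsAsFactors = FALSE
  )
  validate_source_events(ev)
  cov_end <- vapply(ev$source, function(s) {
    as.numeric(params$source_coverage_end[[s]])
  }, numeric(1))
  keep <- as.numeric(ev$event_date) <= cov_end
  if (!is.null(coverage_start))
    keep <- keep & ev$event_date >= as.Date(coverage_start)
  n_dropped <- sum(!keep)
  ev <- canonical_sort(ev[keep, , drop = FALSE])
  attr(ev, "load_report") <- list(n_read = nrow(df), n_dropped = n_dropped)
  ev
}

#' @rdname read_event_table
#' @param paths character vector of event-table paths (one per source or
#'   arbitrary split); tables are concatenated and re-sorted
#' @export
read_event_tables <- function(paths, params = register_params()) {
  parts <- lapply(paths, read_event_table, params = params)
  ev <- canonical_sort(do.call(rbind, parts))
  attr(ev, "load_report") <- list(
    n_read = sum(vapply(parts, function(p) attr(p, "load_report")$n_read, integer(1))),
    n_dropped = sum(vapply(parts, function(p) attr(p, "load_report")$n_dropped, integer(1)))
  )
  ev
}

empty_events <- function() {
  source_events(character(0), character(0), as.Date(character(0)),
                character(0), character(0))
}

#' Construct or read a clinical code map
#'
#' Maps each (vocabulary, code) pair to an outcome or auxiliary category.
#' The pair must be unique across the map; a duplicated code with
#' conflicting categories is an error.
#'
#' @param vocabulary,code,category equal-length character vectors
#' @return data frame of class `code_map`
#' @export
code_map <- function(vocabulary, code, category) {
  cm <- data.frame(vocabulary = as.character(vocabulary),
                   code = as.character(code),
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  bad <- which(!cm$vocabulary %in% VOCABULARIES)
  if (length(bad))
    stop("code map: unknown vocabulary '", cm$vocabulary[bad[1]], "' at row ", bad[1])
  bad <- which(!cm$category %in% outcome_categories())
  if (length(bad))
    stop("code map: unknown category label '", cm$category[bad[1]], "' at row ", bad[1])
  key <- paste(cm$vocabulary, cm$code, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    # exact duplicates are tolerated (collapsed); conflicting ones are fatal
    full <- paste(key, cm$category, sep = "\r")
    conflicting <- key[dup][!(full[dup] %in% full[!dup])]
    if (length(conflicting)) {
      parts <- strsplit(conflicting[1], "\r", fixed = TRUE)[[1]]
      stop("code map: code '", parts[2], "' (", parts[1],
           ") mapped to conflicting categories")
    }
    cm <- cm[!duplicated(key), , drop = FALSE]
  }
  rownames(cm) <- NULL
  class(cm) <- unique(c("code_map", class(cm)))
  cm
}

#' @rdname code_map
#' @param path comma-delimited file with columns `vocabulary,code,category`
#' @export
read_code_map <- function(path) {
  df <- read_delim_checked(path, c("vocabulary", "code", "category"))
  code_map(df$vocabulary, df$code, df$category)
}

#' Read a patient demographics table
#'
#' Columns `patient_id,year_of_birth,ethnicity_gp,ethnicity_hes,
#' townsend_quintile,region`; empty string means missing.
#'
#' @param path file path
#' @return data frame, one row per patient
#' @export
read_patient_table <- function(path) {
  df <- read_delim_checked(path, c("patient_id", "year_of_birth", "ethnicity_gp",
                                   "ethnicity_hes", "townsend_quintile", "region"))
  data.frame(
    patient_id = df$patient_id,
    year_of_birth = parse_int_column(df$year_of_birth, "year_of_birth", path),
    ethnicity_gp = ifelse(nzchar(trimws(df$ethnicity_gp)), df$ethnicity_gp, NA_character_),
    ethnicity_hes = ifelse(nzchar(trimws(df$ethnicity_hes)), df$ethnicity_hes, NA_character_),
    townsend_quintile = parse_int_column(df$townsend_quintile, "townsend_quintile", path),
    region = df$region,
    stringsAsFactors = FALSE
  )
}

#' Read a standard population table
#'
#' @param path comma-delimited file with columns `age_group,population`
#' @return data frame with `age_group` and `population`
#' @export
read_standard_population <- function(path) {
  df <- read_delim_checked(path, c("age_group", "population"))
  data.frame(age_group = df$age_group,
             population = as.numeric(parse_int_column(df$population, "population", path)),
             stringsAsFactors = FALSE)
}

REGISTER_COLUMNS <- c("patient_id", "episode_index", "outcome_class",
                      "outcome_subtype", "end_date", "conception_date",
                      "gestation_days", "dating_method", "source_dataset")

#' Write and re-read a pregnancy register
#'
#' The register is written as comma-delimited text with ISO-8601 dates.
#' Writing requires every episode to be dated (conception date, gestation
#' and dating method present): dating is mandatory before persisting.
#' A write followed by [read_register()] reproduces the records exactly.
#'
#' @param episodes dated register data frame (see [build_register()] and
#'   [date_register()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_register <- function(episodes, path) {
  missing_cols <- setdiff(REGISTER_COLUMNS, names(episodes))
  if (length(missing_cols))
    stop("register is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(episodes) > 0 &&
      (anyNA(episodes$conception_date) || anyNA(episodes$gestation_days) ||
       anyNA(episodes$dating_method)))
    stop("register has undated episodes; run date_register() before writing")
  out <- episodes[, REGISTER_COLUMNS, drop = FALSE]
  out$end_date <- format(out$end_date, "%Y-%m-%d")
  out$conception_date <- format(out$conception_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_register
#' @export
read_register <- function(path) {
  df <- read_delim_checked(path, REGISTER_COLUMNS)
  data.frame(
    patient_id = df$patient_id,
    episode_index = parse_int_column(df$episode_index, "episode_index", path),
    outcome_class = df$outcome_class,
    outcome_subtype = df$outcome_subtype,
    end_date = parse_date_column(df$end_date, "end_date", path),
    conception_date = parse_date_column(df$conception_date, "conception_date", path),
    gestation_days = parse_int_column(df$gestation_days, "gestation_days", path),
    dating_method = df$dating_method,
    source_dataset = df$source_dataset,
    stringsAsFactors = FALSE
  )
}

#' Write event tables produced by the synthetic generator
#'
#' @param events `source_events` data frame
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_event_table <- function(events, path) {
  out <- events[, EVENT_COLUMNS, drop = FALSE]
  out$event_date <- format(out$event_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Bundled code map fixture
#'
#' A stub code map shipping one or more synthetic codes per outcome and
#' auxiliary category in each applicable vocabulary (real SNOMED/ICD/OPCS
#' curation is out of scope; the ICD-10 stubs reuse the familiar O-chapter
#' stems, e.g. O06 for unspecified abortion).
#'
#' @return `code_map` data frame
#' @export
default_code_map <- function() {
  read_code_map(system.file("extdata", "code_map.csv", package = "pregreg",
                            mustWork = TRUE))
}
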