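# Register constants, outcome vocabulary, and priority hierarchies.

#' Outcome and auxiliary categories
#'
#' The register's closed vocabulary of event categories. Delivery outcomes
#' are livebirths (singleton/multiple) and stillbirths; pregnancy-loss
#' outcomes are miscarriage, termination, probable termination, ectopic
#' pregnancy, molar pregnancy, unspecified loss and blighted ovum.
#' Auxiliary categories never terminate an episode: they carry dating
#' evidence (estimated date of delivery, last menstrual period, antenatal
#' scans), postnatal care markers, and the pre-term delivery indicator used
#' when imputing gestation.
#'
#' @return Character vector of category labels.
#' @export
outcome_categories <- function() {
  c(delivery_categories(), loss_categories(), auxiliary_categories())
}

#' @rdname outcome_categories
#' @export
delivery_categories <- function() {
  c("stillbirth", "livebirth_multiple", "livebirth_singleton")
}

#' @rdname outcome_categories
#' @export
loss_categories <- function() {
  c("ectopic", "termination", "miscarriage", "probable_termination",
    "molar", "unspecified_loss", "blighted_ovum")
}

#' @rdname outcome_categories
#' @export
auxiliary_categories <- function() {
  c("edd", "lmp", "antenatal_scan", "postnatal", "preterm_indicator")
}

#' @rdname outcomes_helpers
#' @name outcomes_helpers
#' @title Category class helpers
#' @param category character vector of category labels
#' @return logical vector / character vector of the same length
#' @export
is_delivery_category <- function(category) category %in% delivery_categories()

#' @rdname outcomes_helpers
#' @export
is_loss_category <- function(category) category %in% loss_categories()

#' @rdname outcomes_helpers
#' @export
is_outcome_category <- function(category) {
  is_delivery_category(category) | is_loss_category(category)
}

#' @rdname outcomes_helpers
#' @export
outcome_class <- function(category) {
  ifelse(is_delivery_category(category), "delivery",
         ifelse(is_loss_category(category), "loss", NA_character_))
}

SOURCES <- c("GP", "HES_MAT", "HES_APC", "HES_OPCS")
VOCABULARIES <- c("SNOMED", "ICD10", "OPCS4")

# Source precedence for tie-breaking: the maternity spine first, then the
# canonical dataset order.
source_rank <- function(source) match(source, c("HES_MAT", "GP", "HES_APC", "HES_OPCS"))

#' Category priority rank
#'
#' Same-day and within-episode conflicts are resolved by a fixed hierarchy:
#' any delivery beats any loss; deliveries rank stillbirth, then multiple
#' livebirth, then singleton livebirth; losses rank ectopic, termination,
#' miscarriage, probable termination, molar, unspecified loss, blighted
#' ovum. Lower rank wins.
#'
#' @param category character vector of outcome categories
#' @return integer rank (1 = highest priority); NA for auxiliary categories
#' @export
category_priority <- function(category) {
  order_all <- c(delivery_categories(), loss_categories())
  match(category, order_all)
}

#' Loss-only priority rank
#'
#' @param category character vector of loss categories
#' @return integer rank within the loss hierarchy (1 = ectopic ... 7 =
#'   blighted ovum); NA for non-loss categories
#' @export
loss_priority <- function(category) match(category, loss_categories())

#' Register parameters
#'
#' All thresholds and imputation constants of the register algorithm in one
#' record. Defaults are the algorithm's published operating constants:
#' a new delivery episode needs at least 175 days since the previous
#' outcome record and a new loss 56 days; livebirths need a gestation of at
#' least 154 days and stillbirths 168; losses must have between 35 and 167
#' days of gestation; at least 21 days must separate the end of one
#' pregnancy and the conception of the next. Undated episodes are imputed
#' at 275 days (full-term delivery), 259 (pre-term or multiple), 83
#' (non-ectopic loss) or 63 (ectopic); an estimated date of delivery
#' implies conception 280 days earlier. The default study window is
#' 2020-12-30 to 2022-09-30 with GP coverage ending 2022-02-11 and HES
#' coverage running to the study end.
#'
#' @param study_start,study_end study window (coercible to `Date`)
#' @param source_coverage_end named list/vector of per-source coverage end
#'   dates (sources `GP`, `HES_MAT`, `HES_APC`, `HES_OPCS`)
#' @param delivery_gap_min,loss_gap_min minimum days since the previous
#'   outcome record for a new delivery / loss episode
#' @param livebirth_gestation_min,stillbirth_gestation_min viability floors
#'   in days
#' @param loss_gestation_min,loss_gestation_max legal gestation range for
#'   losses, days
#' @param inter_episode_gap minimum days between one episode's end and the
#'   next conception
#' @param fullterm_imputed_gestation,preterm_imputed_gestation,
#'   multiple_imputed_gestation,loss_imputed_gestation,
#'   ectopic_imputed_gestation imputation constants, days
#' @param edd_offset days between last menstrual period and the estimated
#'   date of delivery
#' @param postnatal_window days after delivery searched for postnatal GP
#'   records
#' @param ppv_windows day offsets used for cross-source linkage
#' @param suppression_threshold counts below this are suppressed in reports
#' @param stillbirth_below_floor what to do with stillbirths whose recorded
#'   gestation is under the 168-day floor: `"reclassify"` to miscarriage
#'   (default) or `"drop"`
#' @param unspecified_relabel when surviving unspecified-loss outcomes are
#'   relabelled as terminations: `"after_priority"` (default: they compete
#'   at rank 6 first) or `"before_priority"` (relabelled before conflict
#'   resolution, so they compete at termination's rank)
#' @return object of class `register_params`
#' @export
register_params <- function(study_start = "2020-12-30",
                            study_end = "2022-09-30",
                            source_coverage_end = list(
                              GP = "2022-02-11",
                              HES_MAT = "2022-09-30",
                              HES_APC = "2022-09-30",
                              HES_OPCS = "2022-09-30"),
                            delivery_gap_min = 175L,
                            loss_gap_min = 56L,
                            livebirth_gestation_min = 154L,
                            stillbirth_gestation_min = 168L,
                            loss_gestation_min = 35L,
                            loss_gestation_max = 167L,
                            inter_episode_gap = 21L,
                            fullterm_imputed_gestation = 275L,
                            preterm_imputed_gestation = 259L,
                            multiple_imputed_gestation = 259L,
                            loss_imputed_gestation = 83L,
                            ectopic_imputed_gestation = 63L,
                            edd_offset = 280L,
                            postnatal_window = 175L,
                            ppv_windows = c(0L, 2L, 7L),
                            suppression_threshold = 5L,
                            stillbirth_below_floor = c("reclassify", "drop"),
                            unspecified_relabel = c("after_priority", "before_priority")) {
  p <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    source_coverage_end = lapply(as.list(source_coverage_end), as.Date),
    delivery_gap_min = as.integer(delivery_gap_min),
    loss_gap_min = as.integer(loss_gap_min),
    livebirth_gestation_min = as.integer(livebirth_gestation_min),
    stillbirth_gestation_min = as.integer(stillbirth_gestation_min),
    loss_gestation_min = as.integer(loss_gestation_min),
    loss_gestation_max = as.integer(loss_gestation_max),
    inter_episode_gap = as.integer(inter_episode_gap),
    fullterm_imputed_gestation = as.integer(fullterm_imputed_gestation),
    preterm_imputed_gestation = as.integer(preterm_imputed_gestation),
    multiple_imputed_gestation = as.integer(multiple_imputed_gestation),
    loss_imputed_gestation = as.integer(loss_imputed_gestation),
    ectopic_imputed_gestation = as.integer(ectopic_imputed_gestation),
    edd_offset = as.integer(edd_offset),
    postnatal_window = as.integer(postnatal_window),
    ppv_windows = sort(as.integer(ppv_windows)),
    suppression_threshold = as.integer(suppression_threshold),
    stillbirth_below_floor = match.arg(stillbirth_below_floor),
    unspecified_relabel = match.arg(unspecified_relabel)
  )
  class(p) <- "register_params"
  validate_register_params(p)
  p
}

validate_register_params <- function(p) {
  stopifnot(inherits(p, "register_params"))
  durations <- c("delivery_gap_min", "loss_gap_min", "livebirth_gestation_min",
                 "stillbirth_gestation_min", "loss_gestation_min",
                 "loss_gestation_max", "inter_episode_gap",
                 "fullterm_imputed_gestation", "preterm_imputed_gestation",
                 "multiple_imputed_gestation", "loss_imputed_gestation",
                 "ectopic_imputed_gestation", "edd_offset", "postnatal_window")
  for (d in durations) {
    if (!is.finite(p[[d]]) || p[[d]] <= 0L)
      stop("register_params: '", d, "' must be a positive number of days")
  }
  if (p$study_end < p$study_start)
    stop("register_params: study_end precedes study_start")
  missing_src <- setdiff(SOURCES, names(p$source_coverage_end))
  if (length(missing_src))
    stop("register_params: source_coverage_end missing for: ",
         paste(missing_src, collapse = ", "))
  # Internal coherence of the shipped rule set.
  if (p$loss_gestation_min + p$inter_episode_gap != p$loss_gap_min)
    stop("register_params: loss_gestation_min + inter_episode_gap must equal loss_gap_min")
  if (p$loss_gestation_max >= p$stillbirth_gestation_min)
    stop("register_params: loss_gestation_max must be below stillbirth_gestation_min")
  invisible(p)
}

#' @export
print.register_params <- function(x, ...) {
  cat("Pregnancy register parameters\n")
  cat("  study window: ", format(x$study_start), " to ", format(x$study_end), "\n", sep = "")
  cov <- vapply(x$source_coverage_end[SOURCES], format, character(1))
  cat("  coverage end: ", paste(SOURCES, cov, sep = "=", collapse = "  "), "\n", sep = "")
  cat("  gaps: delivery >= ", x$delivery_gap_min, "d, loss >= ", x$loss_gap_min,
      "d, inter-episode >= ", x$inter_episode_gap, "d\n", sep = "")
  cat("  gestation bounds: livebirth >= ", x$livebirth_gestation_min,
      "d, stillbirth >= ", x$stillbirth_gestation_min,
      "d, loss in [", x$loss_gestation_min, ", ", x$loss_gestation_max, "]d\n", sep = "")
  cat("  imputation: full-term ", x$fullterm_imputed_gestation,
      "d, pre-term/multiple ", x$preterm_imputed_gestation,
      "d, loss ", x$loss_imputed_gestation,
      "d, ectopic ", x$ectopic_imputed_gestation,
      "d, EDD offset ", x$edd_offset, "d\n", sep = "")
  invisible(x)
}
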