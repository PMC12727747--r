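# Outcome classification: code-map lookup, deduplication, and same-day
# conflict resolution by the register's priority hierarchies.

#' Classify coded events against a code map
#'
#' Maps every source event to an outcome category (delivery or loss
#' subtype) or auxiliary category (EDD, LMP, antenatal scan, postnatal,
#' pre-term indicator) via its (vocabulary, code) pair. Events whose code
#' is absent from the map are excluded from episode building and returned
#' in the `unclassified` report. A livebirth event carrying `n_babies > 1`
#' is marked a multiple birth regardless of its code's category.
#'
#' @param events `source_events` data frame
#' @param map `code_map` data frame
#' @return list with `events` (classified events with a `category` column)
#'   and `unclassified` (unmapped input rows)
#' @export
classify_events <- function(events, map = default_code_map()) {
  key <- paste(events$vocabulary, events$code, sep = "\r")
  mkey <- paste(map$vocabulary, map$code, sep = "\r")
  idx <- match(key, mkey)
  out <- events
  out$category <- map$category[idx]
  unclassified <- events[is.na(idx), , drop = FALSE]
  out <- out[!is.na(idx), , drop = FALSE]
  multiple <- out$category == "livebirth_singleton" & !is.na(out$n_babies) & out$n_babies > 1L
  out$category[multiple] <- "livebirth_multiple"
  rownames(out) <- NULL
  rownames(unclassified) <- NULL
  list(events = out, unclassified = unclassified)
}

event_group_key <- function(ev, ...) {
  do.call(paste, c(lapply(list(...), function(col) as.character(ev[[col]])),
                   sep = "\r"))
}

#' Collapse exact same-day duplicates
#'
#' Events identical on (patient, date, source, category) are collapsed to
#' one row; recorded gestation, scan weeks and baby counts are filled from
#' the first non-missing value in the group (canonical order). Duplicates
#' recorded in *different* sources are deliberately kept: they are the
#' cross-source evidence the internal validation counts.
#'
#' @param events classified events
#' @return deduplicated events
#' @export
dedup_same_day <- function(events) {
  if (nrow(events) == 0) return(events)
  ev <- canonical_sort(events)
  key <- event_group_key(ev, "patient_id", "event_date", "source", "category")
  first_non_na <- function(x) {
    g <- !is.na(x)
    stats::ave(x, key, FUN = function(v) {
      nn <- v[!is.na(v)]
      if (length(nn)) nn[1] else v[1]
    })
  }
  ev$gestation_weeks <- first_non_na(ev$gestation_weeks)
  ev$scan_weeks <- first_non_na(ev$scan_weeks)
  ev$n_babies <- first_non_na(ev$n_babies)
  out <- ev[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolution_log_row <- function(patient_id, date, kept, dropped, rule) {
  data.frame(patient_id = patient_id, date = as.Date(date),
             kept_category = kept, dropped_category = dropped,
             rule = rule, stringsAsFactors = FALSE)
}

empty_resolution_log <- function() {
  resolution_log_row(character(0), as.Date(character(0)), character(0),
                     character(0), character(0))
}

#' Resolve same-day outcome conflicts
#'
#' For each (patient, date) with more than one outcome category recorded,
#' exactly one outcome survives: deliveries beat losses; within deliveries
#' the order is stillbirth, multiple livebirth, singleton livebirth; within
#' losses ectopic, termination, miscarriage, probable termination, molar,
#' unspecified loss, blighted ovum. When the surviving category is
#' recorded in several sources the HES Maternity record is kept, then the
#' canonical sort order decides. Auxiliary events pass through untouched.
#'
#' @param events deduplicated classified events
#' @return list with `events` (at most one outcome per patient-date, plus
#'   all auxiliary events) and `log` (dropped records with the rule that
#'   dropped them)
#' @export
resolve_same_day <- function(events) {
  ev <- canonical_sort(events)
  is_outcome <- is_outcome_category(ev$category)
  aux <- ev[!is_outcome, , drop = FALSE]
  out <- ev[is_outcome, , drop = FALSE]
  if (nrow(out) == 0)
    return(list(events = ev, log = empty_resolution_log()))
  key <- event_group_key(out, "patient_id", "event_date")
  prio <- category_priority(out$category)
  src <- source_rank(out$source)
  # canonical order within key is preserved by a stable sort on (key, prio, src)
  o <- order(key, prio, src, method = "radix")
  out <- out[o, , drop = FALSE]
  key <- key[o]
  keep <- !duplicated(key)
  dropped <- out[!keep, , drop = FALSE]
  kept_for_dropped <- out[keep, , drop = FALSE][match(key[!keep], key[keep]), , drop = FALSE]
  log <- if (nrow(dropped)) {
    rule <- ifelse(outcome_class(dropped$category) != outcome_class(kept_for_dropped$category),
                   "delivery_over_loss",
                   ifelse(dropped$category != kept_for_dropped$category,
                          "same_day_category_priority", "same_day_source_tiebreak"))
    resolution_log_row(dropped$patient_id, dropped$event_date,
                       kept_for_dropped$category, dropped$category, rule)
  } else empty_resolution_log()
  resolved <- canonical_sort(rbind(out[keep, , drop = FALSE], aux))
  list(events = resolved, log = log)
}

#' Relabel surviving unspecified losses as terminations
#'
#' Loss records without a clear outcome (e.g. an unspecified-abortion
#' code) are categorised as terminations once the prioritisation process
#' is complete. Under the default sequencing the unspecified-loss category
#' first competes in the loss hierarchy at rank 6 and is only relabelled
#' if it survives.
#'
#' @param x a data frame with a category column (`category` for events,
#'   `outcome_subtype` for register episodes)
#' @return `x` with surviving `unspecified_loss` entries relabelled
#'   `termination`
#' @export
finalise_unspecified <- function(x) {
  col <- if ("outcome_subtype" %in% names(x)) "outcome_subtype" else "category"
  x[[col]][x[[col]] == "unspecified_loss"] <- "termination"
  x
}
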