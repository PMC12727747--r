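# Internal validation (cross-source linkage, PPV, overlap cells, postnatal
# link) and directly age-standardised rates.

# events eligible as corroborating evidence for an episode: same patient,
# same outcome class, a different source from the one the episode was
# derived from, within +/- window days of the episode end, and not itself
# the terminating record of any of the patient's episodes
linkage_sources <- function(episodes, all_events, window_days) {
  ev <- all_events[is_outcome_category(all_events$category), , drop = FALSE]
  ev$cls <- outcome_class(ev$category)
  term_key <- paste(episodes$patient_id, episodes$end_date, episodes$source_dataset)
  ev_key <- paste(ev$patient_id, ev$event_date, ev$source)
  ev <- ev[!(ev_key %in% term_key), , drop = FALSE]
  ev_by_patient <- split(ev, ev$patient_id)
  lapply(seq_len(nrow(episodes)), function(k) {
    pev <- ev_by_patient[[episodes$patient_id[k]]]
    if (is.null(pev)) return(character(0))
    hit <- pev$cls == episodes$outcome_class[k] &
      pev$source != episodes$source_dataset[k] &
      abs(as.numeric(pev$event_date - episodes$end_date[k])) <= window_days
    unique(pev$source[hit])
  })
}

#' Internal validation: cross-source positive predictive value
#'
#' An episode is "linked" if at least one record of the same outcome class
#' exists in a dataset other than the one the episode was derived from,
#' within the given number of days either side of the episode end, that is
#' not itself the terminating record of one of the patient's episodes.
#' PPV = linked episodes / episodes in register x 100.
#'
#' @param episodes register (dated or undated)
#' @param all_events classified, deduplicated events from all sources
#'   (cross-source duplicates intact)
#' @param window_days non-negative day window (0, 2 and 7 in the shipped
#'   defaults)
#' @return list of class `validation_summary`: `window_days`,
#'   `n_episodes`, `n_linked`, `ppv_percent`
#' @export
internal_ppv <- function(episodes, all_events, window_days) {
  if (nrow(episodes) == 0) stop("internal_ppv: empty register, PPV undefined")
  linked <- vapply(linkage_sources(episodes, all_events, window_days),
                   function(s) length(s) > 0, logical(1))
  out <- list(window_days = window_days, n_episodes = nrow(episodes),
              n_linked = sum(linked),
              ppv_percent = 100 * sum(linked) / nrow(episodes))
  class(out) <- "validation_summary"
  out
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("PPV(+/-%dd) = %.1f%% (%d/%d episodes linked)\n",
              x$window_days, x$ppv_percent, x$n_linked, x$n_episodes))
  invisible(x)
}

#' Source-overlap (Venn) counts
#'
#' Assigns each episode to exactly one source-subset cell: its own deriving
#' source plus every source holding a linking record under the same
#' criteria as [internal_ppv()]. Cells partition the register.
#'
#' @inheritParams internal_ppv
#' @return data frame `sources` (sorted, `+`-joined subset label), `n`
#' @export
overlap_counts <- function(episodes, all_events, window_days) {
  srcs <- linkage_sources(episodes, all_events, window_days)
  cell <- vapply(seq_len(nrow(episodes)), function(k) {
    paste(intersect(SOURCES, union(episodes$source_dataset[k], srcs[[k]])),
          collapse = "+")
  }, character(1))
  tab <- as.data.frame(table(cell), stringsAsFactors = FALSE)
  names(tab) <- c("sources", "n")
  tab[order(-tab$n), , drop = FALSE]
}

#' Postnatal GP linkage for deliveries
#'
#' Share of delivery episodes with at least one postnatal-category GP
#' record in the 175 days after the delivery date (window half-open:
#' strictly after delivery, up to and including day 175).
#'
#' @param episodes register; only delivery episodes are considered
#' @param gp_events classified GP events
#' @param params `register_params` (postnatal window)
#' @return percent of delivery episodes with a postnatal link
#' @export
postnatal_link <- function(episodes, gp_events, params = register_params()) {
  del <- episodes[episodes$outcome_class == "delivery", , drop = FALSE]
  if (nrow(del) == 0) stop("postnatal_link: no delivery episodes")
  pn <- gp_events[gp_events$category == "postnatal" & gp_events$source == "GP",
                  , drop = FALSE]
  linked <- vapply(seq_len(nrow(del)), function(k) {
    any(pn$patient_id == del$patient_id[k] &
          pn$event_date > del$end_date[k] &
          pn$event_date <= del$end_date[k] + params$postnatal_window)
  }, logical(1))
  100 * mean(linked)
}

#' Run the full internal validation
#'
#' @inheritParams internal_ppv
#' @param params `register_params` (PPV windows and postnatal window)
#' @return list with one `validation_summary` per window, overlap tables,
#'   and the postnatal link percentage (NA if the register has no
#'   deliveries)
#' @export
validate_register <- function(episodes, all_events, params = register_params()) {
  ppv <- lapply(params$ppv_windows, function(w) internal_ppv(episodes, all_events, w))
  names(ppv) <- paste0("window_", params$ppv_windows)
  overlaps <- lapply(params$ppv_windows, function(w) overlap_counts(episodes, all_events, w))
  names(overlaps) <- names(ppv)
  pn <- if (any(episodes$outcome_class == "delivery"))
    postnatal_link(episodes, all_events, params) else NA_real_
  list(ppv = ppv, overlap = overlaps, postnatal_link_percent = pn)
}

#' Directly age-standardised rate
#'
#' Standardised rate = sum over strata of (standard-population weight x
#' stratum rate) x scale, with weights the standard population's share per
#' stratum. The 95% CI uses the gamma approximation (Fay-Feuer); the crude
#' rate CI uses the same gamma form with equal weights. When all stratum
#' rates are equal the standardised rate equals the crude rate.
#'
#' @param events_by_age named numeric vector of numerator counts per age
#'   stratum
#' @param denominator_by_age named numeric vector of person (or pregnancy)
#'   denominators per stratum; names must match
#' @param standard_pop data frame with `age_group` and `population`
#'   covering the same strata
#' @param scale rate multiplier (default per 1000)
#' @return list of class `rate_result`: `numerator`, `denominator`,
#'   `crude_rate`, `standardised_rate`, `ci_lower`, `ci_upper`, `scale`
#' @export
direct_standardised_rate <- function(events_by_age, denominator_by_age,
                                     standard_pop, scale = 1000) {
  strata <- names(events_by_age)
  if (is.null(strata) || !setequal(strata, names(denominator_by_age)) ||
      !all(strata %in% standard_pop$age_group))
    stop("age strata of numerator, denominator and standard population must align")
  x <- as.numeric(events_by_age[strata])
  n <- as.numeric(denominator_by_age[strata])
  w_raw <- standard_pop$population[match(strata, standard_pop$age_group)]
  w <- w_raw / sum(w_raw)
  if (any(n <= 0 & w > 0))
    stop("zero denominator in stratum with non-zero standard weight: ",
         paste(strata[n <= 0 & w > 0], collapse = ", "))
  rate_i <- x / n
  dsr <- sum(w * rate_i)
  v <- sum(w^2 * x / n^2)
  wM <- max(w / n)
  ci <- gamma_rate_ci(dsr, v, wM)
  out <- list(numerator = sum(x), denominator = sum(n),
              crude_rate = scale * sum(x) / sum(n),
              standardised_rate = scale * dsr,
              ci_lower = scale * ci[1], ci_upper = scale * ci[2],
              scale = scale)
  class(out) <- "rate_result"
  out
}

# Fay-Feuer gamma interval for a weighted sum of Poisson rates
gamma_rate_ci <- function(dsr, v, wM, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (dsr > 0 && v > 0) stats::qgamma(a, shape = dsr^2 / v) * v / dsr else 0
  upper <- stats::qgamma(1 - a, shape = (dsr + wM)^2 / (v + wM^2)) *
    (v + wM^2) / (dsr + wM)
  c(lower, upper)
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("crude %.1f, age-standardised %.1f (95%% CI %.1f-%.1f) per %g\n",
              x$crude_rate, x$standardised_rate, x$ci_lower, x$ci_upper, x$scale))
  invisible(x)
}

#' Wilson score interval for a proportion
#'
#' Used for the register's proportion-type summaries (e.g. PPV).
#'
#' @param k successes
#' @param n trials
#' @param level confidence level
#' @return two-element vector (lower, upper) on the proportion scale
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}
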