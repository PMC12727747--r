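# Estimated date of conception: five-level dating hierarchy with
# outcome-specific imputation.
#
# Order of priority: recorded length of gestation (HES GESTAT, weeks x 7;
# a GP-coded gestational age would rank next but the shipped schema only
# carries gestation on HES Maternity records, so the `gp_gestation` method
# is reserved), then the estimated date of delivery (EDD minus 280 days),
# then the first day of the last menstrual period (conception = LMP), then
# antenatal scans (scan date minus completed weeks, earlier scans first
# and HES over GP on ties), then simple imputation. A dating source whose
# implied gestation falls outside the outcome's legal range is skipped,
# not clamped.

legal_gestation_range <- function(subtype, params) {
  if (subtype %in% c("livebirth_singleton", "livebirth_multiple"))
    c(params$livebirth_gestation_min, Inf)
  else if (subtype == "stillbirth")
    c(params$stillbirth_gestation_min, Inf)
  else
    c(params$loss_gestation_min, params$loss_gestation_max)
}

gestation_floor <- function(subtype, params) {
  legal_gestation_range(subtype, params)[1]
}

#' Select the preferred antenatal scan
#'
#' Earliest scan date wins; on date ties a hospital-recorded scan beats a
#' GP one.
#'
#' @param scan_events events with category `antenatal_scan` and
#'   `scan_weeks` present
#' @return the scan events reordered by preference (first row = chosen)
#' @export
select_scan <- function(scan_events) {
  if (nrow(scan_events) == 0) return(scan_events)
  o <- order(scan_events$event_date, scan_events$source == "GP",
             source_rank(scan_events$source))
  out <- scan_events[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute gestation length
#'
#' Fallback constants when no dating record exists: 275 days for a
#' full-term delivery, 259 for a pre-term or multiple delivery, 83 for a
#' non-ectopic loss, 63 for an ectopic pregnancy. When the time since the
#' previous pregnancy event is shorter than the constant plus the 21-day
#' inter-episode minimum, gestation is the available time minus 21 days,
#' floored at the outcome's minimum (35 days for losses: conception can
#' never be less than 35 days before a loss, even if that breaches the
#' 21-day spacing).
#'
#' @param subtype outcome subtype
#' @param available_window_days days since the previous pregnancy event
#'   (`Inf` if none)
#' @param params `register_params`
#' @param preterm logical: a pre-term indicator code applies to this
#'   delivery
#' @return list with `gestation_days`, `method`, and `floor_exception`
#'   (logical: the subtype floor overrode the 21-day spacing)
#' @export
impute_gestation <- function(subtype, available_window_days,
                             params = register_params(), preterm = FALSE) {
  if (is.finite(available_window_days) && available_window_days <= 0)
    stop("impute_gestation: non-positive window; episode builder invariant broken")
  if (subtype == "ectopic") {
    default <- params$ectopic_imputed_gestation; method <- "imputed_ectopic"
  } else if (is_loss_category(subtype)) {
    default <- params$loss_imputed_gestation; method <- "imputed_loss"
  } else if (subtype == "livebirth_multiple") {
    default <- params$multiple_imputed_gestation; method <- "imputed_multiple"
  } else if (preterm) {
    default <- params$preterm_imputed_gestation; method <- "imputed_preterm"
  } else {
    default <- params$fullterm_imputed_gestation; method <- "imputed_fullterm"
  }
  floor_g <- gestation_floor(subtype, params)
  gest <- default
  floor_exception <- FALSE
  if (is.finite(available_window_days) &&
      available_window_days < default + params$inter_episode_gap) {
    gest <- as.integer(available_window_days) - params$inter_episode_gap
    method <- "imputed_window_capped"
    if (gest < floor_g) {
      gest <- as.integer(floor_g)
      floor_exception <- TRUE
    }
  }
  list(gestation_days = as.integer(gest), method = method,
       floor_exception = floor_exception)
}

# try a candidate conception date against the legal range and spacing;
# returns TRUE if it may be used
conception_legal <- function(conc, end, subtype, prior, params) {
  gest <- as.integer(end - conc)
  rng <- legal_gestation_range(subtype, params)
  if (gest < rng[1] || gest > rng[2]) return(FALSE)
  if (!is.na(prior) && conc < prior + params$inter_episode_gap) return(FALSE)
  TRUE
}

#' Estimate the conception date of one episode
#'
#' Applies the dating hierarchy to a single (undated) episode. A dating
#' source producing a gestation outside the outcome's legal range, or a
#' conception closer than 21 days to the previous pregnancy event, is
#' skipped and the next source consulted; imputation always succeeds.
#'
#' @param episode one-row undated register data frame
#' @param aux_events the patient's auxiliary events (EDD, LMP, scans,
#'   pre-term indicators)
#' @param prior_episode_end date of the previous pregnancy event, or `NA`
#' @param params `register_params`
#' @return the episode row with `conception_date`, `gestation_days` and
#'   `dating_method` filled in, plus a `floor_exception` logical column
#' @export
estimate_conception <- function(episode, aux_events = NULL,
                                prior_episode_end = as.Date(NA),
                                params = register_params()) {
  stopifnot(nrow(episode) == 1)
  aux <- if (is.null(aux_events)) NULL
         else aux_events[aux_events$patient_id == episode$patient_id, , drop = FALSE]
  res <- date_one(episode$end_date, episode$outcome_subtype,
                  episode$gestation_weeks, as.Date(prior_episode_end),
                  aux, params)
  episode$conception_date <- res$conception
  episode$gestation_days <- as.integer(episode$end_date - res$conception)
  episode$dating_method <- res$method
  episode$floor_exception <- res$floor_exception
  episode
}

# hierarchy core for a single episode; aux already restricted to the
# patient (or NULL)
date_one <- function(end, subtype, gestation_weeks, prior, aux, params) {
  lower <- if (is.na(prior)) as.Date("0001-01-01") else prior + params$inter_episode_gap

  set_result <- function(conc, method, floor_exception = FALSE) {
    list(conception = as.Date(conc), method = method,
         floor_exception = floor_exception)
  }

  # 1. recorded gestation (HES Maternity GESTAT, whole weeks x 7)
  if (!is.null(gestation_weeks) && !is.na(gestation_weeks)) {
    conc <- end - 7L * gestation_weeks
    if (conception_legal(conc, end, subtype, prior, params))
      return(set_result(conc, "hes_gestation"))
  }

  # 2. EDD: conception = EDD - 280; attributed when the implied conception
  # lies between the previous event + 21 days and the episode end
  if (!is.null(aux) && nrow(aux)) {
    edd <- aux[aux$category == "edd", , drop = FALSE]
    if (nrow(edd)) {
      conc_all <- edd$event_date - params$edd_offset
      keep <- conc_all >= lower & conc_all <= end
      for (conc in sort(conc_all[keep])) {
        conc <- as.Date(conc, origin = "1970-01-01")
        if (conception_legal(conc, end, subtype, prior, params))
          return(set_result(conc, "edd"))
      }
    }
    # 3. LMP: conception = first day of the last menstrual period
    lmp <- aux[aux$category == "lmp", , drop = FALSE]
    lmp <- lmp[lmp$event_date >= lower & lmp$event_date <= end, , drop = FALSE]
    if (nrow(lmp)) {
      for (conc in sort(lmp$event_date, decreasing = TRUE)) {
        conc <- as.Date(conc, origin = "1970-01-01")
        if (conception_legal(conc, end, subtype, prior, params))
          return(set_result(conc, "lmp"))
      }
    }
    # 4. antenatal scans: scan date - completed weeks
    scans <- aux[aux$category == "antenatal_scan" & !is.na(aux$scan_weeks), , drop = FALSE]
    scans <- scans[scans$event_date >= lower & scans$event_date <= end, , drop = FALSE]
    if (nrow(scans)) {
      scans <- select_scan(scans)
      for (k in seq_len(nrow(scans))) {
        conc <- scans$event_date[k] - 7L * scans$scan_weeks[k]
        if (conception_legal(conc, end, subtype, prior, params))
          return(set_result(conc, "scan"))
      }
    }
  }

  # 5. simple imputation
  preterm <- FALSE
  if (!is.null(aux) && !is_loss_category(subtype)) {
    pt <- aux[aux$category == "preterm_indicator" & aux$source == "HES_MAT", , drop = FALSE]
    preterm <- any(pt$event_date >= lower & pt$event_date <= end)
  }
  window <- if (is.na(prior)) Inf else as.numeric(end - prior)
  imp <- impute_gestation(subtype, window, params, preterm = preterm)
  set_result(end - imp$gestation_days, imp$method, imp$floor_exception)
}

#' Date every episode of a register
#'
#' Runs [estimate_conception()] over all episodes, patient by patient in
#' episode order, using each episode's recorded prior-event date (the most
#' recent retained outcome record before it, as established by the
#' builder) as the spacing reference.
#'
#' @param episodes undated register from [build_register()]
#' @param events classified events (auxiliary dating records are taken
#'   from here); may be `NULL` if no dating records exist
#' @param params `register_params`
#' @return dated register: adds `conception_date`, `gestation_days`,
#'   `dating_method`, `floor_exception`
#' @export
date_register <- function(episodes, events = NULL, params = register_params()) {
  if (nrow(episodes) == 0) {
    episodes$conception_date <- as.Date(character(0))
    episodes$gestation_days <- integer(0)
    episodes$dating_method <- character(0)
    episodes$floor_exception <- logical(0)
    return(episodes)
  }
  aux <- if (is.null(events)) NULL
         else events[events$category %in% auxiliary_categories(), , drop = FALSE]
  aux_by_patient <- if (!is.null(aux) && nrow(aux))
    split(aux, aux$patient_id) else list()
  n <- nrow(episodes)
  conception <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  method <- character(n)
  floor_ex <- logical(n)
  for (k in seq_len(n)) {
    res <- date_one(episodes$end_date[k], episodes$outcome_subtype[k],
                    episodes$gestation_weeks[k],
                    episodes$prior_event_date[k],
                    aux_by_patient[[episodes$patient_id[k]]], params)
    conception[k] <- res$conception
    method[k] <- res$method
    floor_ex[k] <- res$floor_exception
  }
  out <- episodes
  out$conception_date <- conception
  out$gestation_days <- as.integer(out$end_date - conception)
  out$dating_method <- method
  out$floor_exception <- floor_ex
  attr(out, "decision_log") <- attr(episodes, "decision_log")
  out
}
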