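# Seeded synthetic linked-EHR generator: true pregnancy histories and
# their noisy multi-source rendering, so every pipeline stage is testable
# without access-controlled data.

#' Synthetic cohort configuration
#'
#' Defaults emulate the register's study conditions: a 21-month study
#' window (2020-12-30 to 2022-09-30) with GP coverage ending 2022-02-11;
#' 83.4% of true episodes are deliveries (99.5% livebirths, of which 1.5%
#' multiples, and 0.5% stillbirths) and 16.6% losses, with the loss
#' subtype mix echoing the published register composition (42.4%
#' miscarriage, 48.9% termination including probable terminations, the
#' rest ectopic/molar/blighted ovum); 95.6% of patients have one
#' pregnancy, 4.2% two and the remainder three or four. Maternal age is
#' drawn around 30 (SD 5.7), truncated to 15-50 years.
#'
#' @param n_patients number of patients
#' @param params `register_params` (study window and gestation bounds)
#' @param episode_mix probabilities of 1-4 true episodes per patient
#' @param delivery_fraction probability a true episode is a delivery
#' @param delivery_mix named probabilities over delivery subtypes
#' @param loss_mix named probabilities over loss subtypes
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_patients = 1000L,
                         params = register_params(),
                         episode_mix = c(`1` = 0.956, `2` = 0.042,
                                         `3` = 0.0019, `4` = 0.0001),
                         delivery_fraction = 0.834,
                         delivery_mix = c(livebirth_singleton = 0.980,
                                          livebirth_multiple = 0.015,
                                          stillbirth = 0.005),
                         loss_mix = c(miscarriage = 0.424,
                                      termination = 0.450,
                                      probable_termination = 0.039,
                                      ectopic = 0.055,
                                      molar = 0.015,
                                      blighted_ovum = 0.017)) {
  stopifnot(n_patients >= 1,
            abs(sum(episode_mix) - 1) < 1e-8,
            delivery_fraction >= 0, delivery_fraction <= 1,
            abs(sum(delivery_mix) - 1) < 1e-8,
            abs(sum(loss_mix) - 1) < 1e-8)
  cfg <- list(n_patients = as.integer(n_patients), params = params,
              episode_mix = episode_mix, delivery_fraction = delivery_fraction,
              delivery_mix = delivery_mix, loss_mix = loss_mix)
  class(cfg) <- "synth_config"
  cfg
}

#' Recording model for rendering truth as source events
#'
#' Per-source recording probabilities by outcome class, bounded integer
#' date lags, gestation-field and auxiliary-record probabilities, and
#' duplicate/conflict injection rates. The defaults produce the
#' partial-overlap structure seen in linked data: deliveries are recorded
#' nearly everywhere (hospital maternity records dominant), losses mostly
#' in primary care, and a sizeable share of losses appear in a single
#' source only.
#'
#' @param p_record named list `delivery`/`loss`, each a named vector of
#'   per-source recording probabilities
#' @param lag named list of two-element integer vectors `c(min, max)` of
#'   uniform date lags per source
#' @param p_gestat probability a HES_MAT delivery record carries GESTAT
#' @param p_edd,p_lmp,p_scan probabilities of GP dating records per episode
#' @param p_postnatal probability of a postnatal GP record after delivery
#' @param p_duplicate probability a recorded event is duplicated same-day
#'   in its source
#' @param p_conflict probability a same-day conflicting loss code is
#'   injected alongside a recorded loss
#' @param p_unspecified_code probability a loss is rendered with an
#'   unspecified-loss code instead of its true subtype code
#' @return list of class `recording_model`
#' @export
recording_model <- function(p_record = list(
                              delivery = c(GP = 0.55, HES_MAT = 0.95,
                                           HES_APC = 0.30, HES_OPCS = 0.85),
                              loss = c(GP = 0.80, HES_MAT = 0.08,
                                       HES_APC = 0.20, HES_OPCS = 0.10)),
                            lag = list(GP = c(0L, 2L), HES_MAT = c(0L, 0L),
                                       HES_APC = c(0L, 1L), HES_OPCS = c(0L, 1L)),
                            p_gestat = 0.95,
                            p_edd = 0.30, p_lmp = 0.20, p_scan = 0.40,
                            p_postnatal = 0.22,
                            p_duplicate = 0.05,
                            p_conflict = 0.02,
                            p_unspecified_code = 0.05) {
  probs <- c(unlist(p_record), p_gestat, p_edd, p_lmp, p_scan, p_postnatal,
             p_duplicate, p_conflict, p_unspecified_code)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(vapply(lag, function(l) length(l) == 2 && all(is.finite(l)) &&
                         l[1] <= l[2], logical(1))))
  rm <- list(p_record = p_record, lag = lapply(lag, as.integer),
             p_gestat = p_gestat, p_edd = p_edd, p_lmp = p_lmp,
             p_scan = p_scan, p_postnatal = p_postnatal,
             p_duplicate = p_duplicate, p_conflict = p_conflict,
             p_unspecified_code = p_unspecified_code)
  class(rm) <- "recording_model"
  rm
}

#' @rdname recording_model
#' @export
noise_free_recording <- function() {
  recording_model(
    p_record = list(delivery = c(GP = 1, HES_MAT = 1, HES_APC = 1, HES_OPCS = 1),
                    loss = c(GP = 1, HES_MAT = 1, HES_APC = 1, HES_OPCS = 1)),
    lag = list(GP = c(0L, 0L), HES_MAT = c(0L, 0L),
               HES_APC = c(0L, 0L), HES_OPCS = c(0L, 0L)),
    p_gestat = 1, p_edd = 0, p_lmp = 0, p_scan = 0, p_postnatal = 1,
    p_duplicate = 0, p_conflict = 0, p_unspecified_code = 0)
}

truth_gestation_range <- function(subtype, params) {
  switch(subtype,
         livebirth_singleton = c(params$livebirth_gestation_min, 293L),
         livebirth_multiple = c(params$livebirth_gestation_min, 273L),
         stillbirth = c(params$stillbirth_gestation_min, 293L),
         ectopic = c(42L, 84L),
         c(params$loss_gestation_min, params$loss_gestation_max))
}

ETHNIC_GROUPS <- c("White", "Indian", "Pakistani", "Bangladeshi", "Other Asian",
                   "Caribbean", "Black African", "Chinese", "Other")
ETHNIC_PROBS <- c(0.736, 0.043, 0.041, 0.028, 0.023, 0.012, 0.044, 0.008, 0.065)
REGIONS <- c("East Midlands", "East of England", "London", "North East",
             "North West", "South Central", "South East", "South West",
             "West Midlands", "Yorkshire & Humber")
REGION_PROBS <- c(0.017, 0.037, 0.303, 0.021, 0.184, 0.112, 0.112, 0.081,
                  0.106, 0.027)

#' Generate ground-truth patients and pregnancy histories
#'
#' Reproducible for a fixed seed. True episodes respect every register
#' gestation bound by construction: gestations are drawn uniformly within
#' the outcome's legal range, consecutive episodes keep at least the
#' inter-episode 21 days between one end and the next conception, and end
#' dates keep the builder's minimum gaps (175 days before a delivery, 56
#' before a loss), so a noise-free rendering is recoverable exactly.
#' Episodes that no longer fit inside the study window are truncated from
#' the patient's history.
#'
#' @param config `synth_config`
#' @param seed integer seed (mandatory; no hidden global randomness)
#' @return list with `patients` and `truth` (one row per true episode:
#'   `patient_id, true_conception, true_end, true_outcome_subtype,
#'   n_babies`)
#' @export
generate_truth <- function(config = synth_config(), seed) {
  stopifnot(inherits(config, "synth_config"), is.numeric(seed))
  p <- config$params
  window_days <- as.numeric(p$study_end - p$study_start)
  if (window_days < 1) stop("infeasible config: empty study window")
  withr_seed <- .Random.seed_exists()
  on.exit(restore_seed(withr_seed), add = TRUE)
  set.seed(as.integer(seed))

  n <- config$n_patients
  age <- pmin(pmax(round(stats::rnorm(n, 30, 5.7)), 15), 50)
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    year_of_birth = as.integer(format(p$study_start, "%Y")) - as.integer(age),
    ethnicity_gp = ifelse(stats::runif(n) < 0.90,
                          sample(ETHNIC_GROUPS, n, TRUE, ETHNIC_PROBS), NA),
    ethnicity_hes = ifelse(stats::runif(n) < 0.70,
                           sample(ETHNIC_GROUPS, n, TRUE, ETHNIC_PROBS), NA),
    townsend_quintile = ifelse(stats::runif(n) < 0.97,
                               sample(1:5, n, TRUE, c(.163, .191, .209, .209, .197) / 0.969),
                               NA),
    region = sample(REGIONS, n, TRUE, REGION_PROBS),
    stringsAsFactors = FALSE
  )

  n_eps <- sample(as.integer(names(config$episode_mix)), n, TRUE, config$episode_mix)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_eps[i]
    is_del <- stats::runif(k) < config$delivery_fraction
    subtype <- ifelse(is_del,
                      sample(names(config$delivery_mix), k, TRUE, config$delivery_mix),
                      sample(names(config$loss_mix), k, TRUE, config$loss_mix))
    gest <- vapply(subtype, function(s) {
      r <- truth_gestation_range(s, p)
      as.integer(round(stats::runif(1, r[1], r[2])))
    }, integer(1))
    ends <- as.Date(rep(NA_real_, k), origin = "1970-01-01")
    prev_end <- as.Date(NA)
    kept <- logical(k)
    for (j in seq_len(k)) {
      gap_min <- gap_required(outcome_class(subtype[j]), p)
      min_end <- if (is.na(prev_end)) p$study_start
                 else prev_end + max(gap_min, gest[j] + p$inter_episode_gap)
      if (min_end > p$study_end) break  # history truncated at window edge
      span <- as.numeric(p$study_end - min_end)
      # leave head-room for later episodes where possible
      target <- if (j < k) min(span, 120) else span
      ends[j] <- min_end + as.integer(round(stats::runif(1, 0, target)))
      prev_end <- ends[j]
      kept[j] <- TRUE
    }
    if (!any(kept)) next
    rows[[i]] <- data.frame(
      patient_id = patients$patient_id[i],
      true_conception = ends[kept] - gest[kept],
      true_end = ends[kept],
      true_outcome_subtype = subtype[kept],
      n_babies = ifelse(subtype[kept] == "livebirth_multiple",
                        2L + (stats::runif(sum(kept)) < 0.03),
                        ifelse(is_delivery_category(subtype[kept]), 1L, NA_integer_)),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(truth) <- NULL
  list(patients = patients, truth = truth)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

category_code <- function(category, vocabulary) {
  # one stub code per (category, vocabulary) from the bundled map
  map <- default_code_map()
  hit <- map[map$category == category & map$vocabulary == vocabulary, , drop = FALSE]
  if (nrow(hit) == 0) stop("no stub code for ", category, " in ", vocabulary)
  hit$code[1]
}

source_vocabulary <- function(source) {
  c(GP = "SNOMED", HES_MAT = "ICD10", HES_APC = "ICD10", HES_OPCS = "OPCS4")[[source]]
}

#' Render ground truth as noisy multi-source events
#'
#' Every true episode is offered to each of the four sources with the
#' model's per-class recording probability; recorded events get an
#' independent bounded integer date lag per source. HES Maternity delivery
#' records carry GESTAT as the floor of true gestation / 7 (whole weeks).
#' GP dating records (EDD = conception + 280, LMP = conception, scans at
#' completed weeks) and postnatal records are added per the model, as are
#' same-day duplicates, injected conflicting loss codes, and unspecified
#' loss coding. With probability 1 and zero lag every true episode yields
#' a same-day, same-category record in every source.
#'
#' @param truth output of [generate_truth()]
#' @param model `recording_model`
#' @param seed integer seed
#' @return `source_events` data frame (unfiltered by coverage windows)
#' @export
render_source_events <- function(truth, model = recording_model(), seed) {
  stopifnot(inherits(model, "recording_model"), is.numeric(seed))
  tr <- if (is.list(truth) && !is.data.frame(truth)) truth$truth else truth
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))

  # cache stub codes once
  cats <- outcome_categories()
  map <- default_code_map()
  code_of <- list()
  for (v in VOCABULARIES) {
    code_of[[v]] <- vapply(cats, function(cc) {
      hit <- map$code[map$category == cc & map$vocabulary == v]
      if (length(hit)) hit[1] else NA_character_
    }, character(1))
  }

  nr <- nrow(tr)
  cls <- outcome_class(tr$true_outcome_subtype)
  gest <- as.integer(tr$true_end - tr$true_conception)
  parts <- list()
  emit <- function(pid, source, date, category, gw = NA_integer_,
                   sw = NA_integer_, nb = NA_integer_) {
    if (!length(pid)) return(invisible(NULL))
    k <- length(pid)
    source <- rep_len(source, k)
    category <- rep_len(category, k)
    v <- vapply(source, source_vocabulary, character(1))
    code <- mapply(function(vv, cc) code_of[[vv]][[cc]], v, category,
                   USE.NAMES = FALSE)
    keep <- !is.na(code)
    parts[[length(parts) + 1L]] <<- data.frame(
      patient_id = pid[keep], source = source[keep],
      event_date = date[keep], vocabulary = v[keep], code = code[keep],
      gestation_weeks = rep_len(gw, k)[keep], scan_weeks = rep_len(sw, k)[keep],
      n_babies = rep_len(nb, k)[keep], stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (s in SOURCES) {
    p_rec <- ifelse(cls == "delivery", model$p_record$delivery[[s]],
                    model$p_record$loss[[s]])
    rec <- stats::runif(nr) < p_rec
    if (!any(rec)) next
    lag <- model$lag[[s]]
    d <- tr$true_end[rec] + sample(lag[1]:lag[2], sum(rec), replace = TRUE)
    cat_r <- tr$true_outcome_subtype[rec]
    swap <- cls[rec] == "loss" & stats::runif(sum(rec)) < model$p_unspecified_code &
      !is.na(code_of[[source_vocabulary(s)]][["unspecified_loss"]])
    cat_r[swap] <- "unspecified_loss"
    gw <- if (s == "HES_MAT") {
      ifelse(cls[rec] == "delivery" & stats::runif(sum(rec)) < model$p_gestat,
             gest[rec] %/% 7L, NA_integer_)
    } else NA_integer_
    nb <- ifelse(cls[rec] == "delivery", tr$n_babies[rec], NA_integer_)
    emit(tr$patient_id[rec], s, d, cat_r, gw = gw, nb = nb)
    dup <- stats::runif(sum(rec)) < model$p_duplicate
    if (any(dup))
      emit(tr$patient_id[rec][dup], s, d[dup], cat_r[dup],
           gw = if (s == "HES_MAT") gw[dup] else NA_integer_, nb = nb[dup])
    confl <- cls[rec] == "loss" & stats::runif(sum(rec)) < model$p_conflict
    if (any(confl)) {
      other <- vapply(cat_r[confl], function(cc)
        sample(setdiff(loss_categories(), cc), 1L), character(1))
      emit(tr$patient_id[rec][confl], s, d[confl], other)
    }
  }
  # GP dating and postnatal auxiliaries
  edd <- stats::runif(nr) < model$p_edd
  emit(tr$patient_id[edd], "GP", tr$true_conception[edd] + 280L,
       rep("edd", sum(edd)))
  lmp <- stats::runif(nr) < model$p_lmp
  emit(tr$patient_id[lmp], "GP", tr$true_conception[lmp],
       rep("lmp", sum(lmp)))
  scan <- stats::runif(nr) < model$p_scan & gest > 90L
  if (any(scan)) {
    w <- sample(8:13, sum(scan), replace = TRUE)
    emit(tr$patient_id[scan], "GP", tr$true_conception[scan] + 7L * w,
         rep("antenatal_scan", sum(scan)), sw = w)
  }
  pn <- cls == "delivery" & stats::runif(nr) < model$p_postnatal
  if (any(pn))
    emit(tr$patient_id[pn], "GP",
         tr$true_end[pn] + sample(10:120, sum(pn), replace = TRUE),
         rep("postnatal", sum(pn)))

  if (!length(parts)) return(empty_events())
  ev <- do.call(rbind, parts)
  # auxiliary events are written with their category's stub code; the
  # returned table is plain source events (category re-derived by classify)
  canonical_sort(source_events(ev$patient_id, ev$source, ev$event_date,
                               ev$vocabulary, ev$code, ev$gestation_weeks,
                               ev$scan_weeks, ev$n_babies))
}

#' One-call synthetic cohort
#'
#' Generates truth and renders events with seeds derived from one master
#' seed.
#'
#' @param config `synth_config`
#' @param model `recording_model`
#' @param seed master integer seed
#' @return list with `patients`, `truth`, `events`
#' @export
simulate_cohort <- function(config = synth_config(), model = recording_model(),
                            seed) {
  gt <- generate_truth(config, seed = seed)
  ev <- render_source_events(gt, model, seed = as.integer(seed) + 1L)
  list(patients = gt$patients, truth = gt$truth, events = ev)
}
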