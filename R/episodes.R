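# Three-phase pregnancy episode identification.
#
# Patients with any HES Maternity outcome record are processed by phase 1
# (the maternity "spine"), remaining patients with any delivery record by
# phase 2, and patients with losses only by phase 3. Episode boundaries
# follow minimum-gap rules measured from the most recent retained outcome
# record (a loss within 56 days of *any* previous outcome record belongs to
# the same episode, a delivery within 175 days likewise), recorded
# gestations must be consistent with inter-episode spacing, and conflicting
# losses inside one episode are resolved by the loss priority hierarchy.

EPISODE_COLUMNS <- c("patient_id", "episode_index", "outcome_class",
                     "outcome_subtype", "end_date", "source_dataset", "phase",
                     "gestation_weeks", "n_babies", "prior_event_date")

empty_episodes <- function() {
  data.frame(patient_id = character(0), episode_index = integer(0),
             outcome_class = character(0), outcome_subtype = character(0),
             end_date = as.Date(character(0)), source_dataset = character(0),
             phase = integer(0), gestation_weeks = integer(0),
             n_babies = integer(0),
             prior_event_date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

# decision-log rows are accumulated as plain lists and materialised once
decision_row <- function(patient_id, date, source, category, action, episode_index = NA_integer_) {
  list(patient_id = patient_id, date = as.numeric(date), source = source,
       category = category, action = action,
       episode_index = as.integer(episode_index))
}

empty_decision_log <- function() {
  data.frame(patient_id = character(0), date = as.Date(character(0)),
             source = character(0), category = character(0),
             action = character(0), episode_index = integer(0),
             stringsAsFactors = FALSE)
}

log_from_rows <- function(rows) {
  if (!length(rows)) return(empty_decision_log())
  data.frame(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    date = as.Date(vapply(rows, `[[`, numeric(1), "date"), origin = "1970-01-01"),
    source = vapply(rows, `[[`, character(1), "source"),
    category = vapply(rows, `[[`, character(1), "category"),
    action = vapply(rows, `[[`, character(1), "action"),
    episode_index = vapply(rows, `[[`, integer(1), "episode_index"),
    stringsAsFactors = FALSE
  )
}

gap_required <- function(cls, params) {
  ifelse(cls == "delivery", params$delivery_gap_min, params$loss_gap_min)
}

# Spine pass: HES Maternity outcome records become episodes when gap
# thresholds hold, recorded gestations do not conflict with inter-episode
# spacing, and viability floors are met. Returns candidate episodes plus
# clock-updating (retained but non-terminating) rows and a log.
spine_pass <- function(ev, sidx, params) {
  eps <- list(); log <- list(); clockers <- list(); absorbed <- list()
  clock <- as.Date(NA); prev_end <- as.Date(NA)
  for (i in sidx) {
    cat <- ev$category[i]; d <- ev$event_date[i]
    weeks <- ev$gestation_weeks[i]
    gest <- if (!is.na(weeks)) 7L * weeks else NA_integer_
    cls <- outcome_class(cat)
    if (cat %in% c("livebirth_singleton", "livebirth_multiple") &&
        !is.na(gest) && gest < params$livebirth_gestation_min) {
      log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                              cat, "dropped_gestation_below_viability")
      next
    }
    if (cat == "stillbirth" && !is.na(gest) && gest < params$stillbirth_gestation_min) {
      if (params$stillbirth_below_floor == "reclassify") {
        log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                                cat, "stillbirth_reclassified_miscarriage")
        cat <- "miscarriage"; cls <- "loss"
      } else {
        log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                                cat, "dropped_stillbirth_below_floor")
        next
      }
    }
    req <- gap_required(cls, params)
    if (!is.na(clock) && as.integer(d - clock) < req) {
      absorbed[[length(absorbed) + 1L]] <- list(i = i, cat = cat,
                                                to = length(eps))
      log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                              cat, "absorbed_within_gap")
      clock <- d
      next
    }
    if (!is.na(gest) && !is.na(prev_end) &&
        (d - gest) < prev_end + params$inter_episode_gap) {
      log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                              cat, "rejected_gestation_conflict")
      next
    }
    if (d < params$study_start) {
      clock <- d; prev_end <- d
      clockers[[length(clockers) + 1L]] <- d
      log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                              cat, "pre_study_anchor")
      next
    }
    if (d > params$study_end) {
      log[[length(log) + 1L]] <- decision_row(ev$patient_id[i], d, ev$source[i],
                                              cat, "dropped_post_study")
      next
    }
    eps[[length(eps) + 1L]] <- list(i = i, category = cat, class = cls,
                                    end = d, gest_rec = gest)
    clock <- d; prev_end <- d
  }
  # dates of records retained by the spine but not terminating anything:
  # anchors and absorbed HES_MAT rows also advance the merged clock
  abs_dates <- if (length(absorbed)) as.Date(vapply(absorbed, function(a) as.numeric(ev$event_date[a$i]), numeric(1)), origin = "1970-01-01") else as.Date(character(0))
  anchor_dates <- if (length(clockers)) as.Date(vapply(clockers, as.numeric, numeric(1)), origin = "1970-01-01") else as.Date(character(0))
  list(episodes = eps, log = log, absorbed = absorbed,
       clock_dates = sort(c(abs_dates, anchor_dates)))
}

# Merge pass: fixed spine episodes plus the patient's remaining outcome
# records, processed in date order. A non-spine record starts a new
# episode only when it respects the gap rule from the most recent retained
# record AND does not conflict (gap or recorded-gestation spacing) with the
# next spine episode.
build_patient_episodes <- function(ev, phase, params) {
  stopifnot(!is.unsorted(ev$event_date))
  pid <- ev$patient_id[1]
  sidx <- if (phase == 1L) which(ev$source == "HES_MAT") else integer(0)
  sp <- spine_pass(ev, sidx, params)
  log <- sp$log
  spine_eps <- sp$episodes
  spine_ends <- as.Date(vapply(spine_eps, function(e) as.numeric(e$end), numeric(1)),
                        origin = "1970-01-01")
  other_idx <- setdiff(seq_len(nrow(ev)), sidx)

  # merged timeline: spine episodes, loose clock dates, other records
  it_date <- c(as.numeric(spine_ends), as.numeric(sp$clock_dates),
               as.numeric(ev$event_date[other_idx]))
  it_kind <- c(rep("spine", length(spine_eps)),
               rep("clock", length(sp$clock_dates)),
               rep("rec", length(other_idx)))
  it_ref <- c(seq_along(spine_eps), rep(NA_integer_, length(sp$clock_dates)),
              other_idx)
  o <- order(it_date, match(it_kind, c("clock", "spine", "rec")))
  it_date <- it_date[o]; it_kind <- it_kind[o]; it_ref <- it_ref[o]

  episodes <- list()       # final episodes in date order
  absorbed <- list()       # list(i = event row, to = episode slot or NA)
  clock <- as.Date(NA)
  spine_slot <- rep(NA_integer_, length(spine_eps))  # final slot of each spine ep
  remaining_spine <- seq_along(spine_eps)

  for (k in seq_along(it_date)) {
    if (it_kind[k] == "clock") {
      clock <- as.Date(it_date[k], origin = "1970-01-01")
      next
    }
    if (it_kind[k] == "spine") {
      e <- spine_eps[[it_ref[k]]]
      episodes[[length(episodes) + 1L]] <- list(
        i = e$i, category = e$category, class = e$class, end = e$end,
        source = "HES_MAT", prior_event_date = clock)
      spine_slot[it_ref[k]] <- length(episodes)
      remaining_spine <- setdiff(remaining_spine, it_ref[k])
      clock <- e$end
      next
    }
    i <- it_ref[k]
    cat <- ev$category[i]; d <- ev$event_date[i]
    cls <- outcome_class(cat)
    req <- gap_required(cls, params)
    if (!is.na(clock) && as.integer(d - clock) < req) {
      absorbed[[length(absorbed) + 1L]] <- list(i = i, to = length(episodes))
      log[[length(log) + 1L]] <- decision_row(pid, d, ev$source[i], cat,
                                              "absorbed_within_gap", length(episodes))
      clock <- d
      next
    }
    if (length(remaining_spine)) {
      s <- spine_eps[[remaining_spine[1]]]
      req_s <- gap_required(s$class, params)
      conflict <- as.integer(s$end - d) < req_s ||
        (!is.na(s$gest_rec) &&
           (s$end - s$gest_rec) < d + params$inter_episode_gap)
      if (conflict) {
        absorbed[[length(absorbed) + 1L]] <- list(i = i, to = -remaining_spine[1])
        log[[length(log) + 1L]] <- decision_row(pid, d, ev$source[i], cat,
                                                "absorbed_conflicts_with_spine")
        clock <- d
        next
      }
    }
    if (d < params$study_start) {
      clock <- d
      log[[length(log) + 1L]] <- decision_row(pid, d, ev$source[i], cat,
                                              "pre_study_anchor")
      next
    }
    if (d > params$study_end) {
      log[[length(log) + 1L]] <- decision_row(pid, d, ev$source[i], cat,
                                              "dropped_post_study")
      next
    }
    episodes[[length(episodes) + 1L]] <- list(
      i = i, category = cat, class = cls, end = d,
      source = ev$source[i], prior_event_date = clock)
    clock <- d
  }

  # resolve forward references (-j means "absorbed into spine episode j")
  for (a in seq_along(absorbed)) {
    to <- absorbed[[a]]$to
    if (!is.na(to) && to < 0L) absorbed[[a]]$to <- spine_slot[-to]
    else if (!is.na(to) && to == 0L) absorbed[[a]]$to <- NA_integer_
  }
  # HES_MAT rows absorbed during the spine pass are evidence for (and loss
  # candidates of) the spine episode that absorbed them
  for (a in sp$absorbed) {
    absorbed[[length(absorbed) + 1L]] <- list(
      i = a$i, to = if (a$to == 0L) NA_integer_ else spine_slot[a$to])
  }

  # within-episode loss prioritisation: the highest-priority loss among the
  # terminator and the losses it absorbed (at or after the terminator date)
  # represents the episode; the other loss codes are dropped
  for (j in seq_along(episodes)) {
    e <- episodes[[j]]
    if (e$class != "loss") next
    cand_rows <- vapply(absorbed, function(a) {
      !is.na(a$to) && a$to == j && is_loss_category(ev$category[a$i]) &&
        ev$event_date[a$i] >= e$end
    }, logical(1))
    cand <- c(e$i, vapply(absorbed[cand_rows], function(a) a$i, integer(1)))
    if (length(cand) <= 1L) next
    pr <- loss_priority(ev$category[cand])
    best <- cand[order(pr, ev$event_date[cand], source_rank(ev$source[cand]))][1]
    if (best != e$i) {
      log[[length(log) + 1L]] <- decision_row(pid, e$end, e$source, e$category,
                                              "dropped_within_episode_loss_priority", j)
      episodes[[j]] <- list(i = best, category = ev$category[best], class = "loss",
                            end = ev$event_date[best], source = ev$source[best],
                            prior_event_date = e$prior_event_date)
    }
    for (b in setdiff(cand, episodes[[j]]$i)) {
      if (b == e$i) next  # original terminator already logged above
      log[[length(log) + 1L]] <- decision_row(pid, ev$event_date[b], ev$source[b],
                                              ev$category[b],
                                              "dropped_within_episode_loss_priority", j)
    }
  }

  # plain vectors; the register data frame is assembled once by the caller
  list(
    pid = pid, n = length(episodes), phase = phase,
    class = vapply(episodes, function(e) e$class, character(1)),
    subtype = vapply(episodes, function(e) e$category, character(1)),
    end = vapply(episodes, function(e) as.numeric(e$end), numeric(1)),
    source = vapply(episodes, function(e) e$source, character(1)),
    gw = vapply(episodes, function(e) {
      if (e$source == "HES_MAT") ev$gestation_weeks[e$i] else NA_integer_
    }, integer(1)),
    nb = vapply(episodes, function(e) ev$n_babies[e$i], integer(1)),
    prior = vapply(episodes, function(e) as.numeric(e$prior_event_date), numeric(1)),
    log = log
  )
}

assemble_register <- function(parts) {
  n <- vapply(parts, `[[`, integer(1), "n")
  episodes <- data.frame(
    patient_id = rep(vapply(parts, `[[`, character(1), "pid"), n),
    episode_index = unlist(lapply(n, seq_len), use.names = FALSE),
    outcome_class = unlist(lapply(parts, `[[`, "class"), use.names = FALSE),
    outcome_subtype = unlist(lapply(parts, `[[`, "subtype"), use.names = FALSE),
    end_date = as.Date(unlist(lapply(parts, `[[`, "end"), use.names = FALSE),
                       origin = "1970-01-01"),
    source_dataset = unlist(lapply(parts, `[[`, "source"), use.names = FALSE),
    phase = rep(vapply(parts, `[[`, integer(1), "phase"), n),
    gestation_weeks = unlist(lapply(parts, `[[`, "gw"), use.names = FALSE),
    n_babies = unlist(lapply(parts, `[[`, "nb"), use.names = FALSE),
    prior_event_date = as.Date(unlist(lapply(parts, `[[`, "prior"), use.names = FALSE),
                               origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  if (nrow(episodes) == 0) episodes <- empty_episodes()
  log <- log_from_rows(do.call(c, lapply(parts, `[[`, "log")))
  attr(episodes, "decision_log") <- log
  episodes
}

patient_phase <- function(ev) {
  if (any(ev$source == "HES_MAT")) 1L
  else if (any(is_delivery_category(ev$category))) 2L
  else 3L
}

#' Identify pregnancy episodes
#'
#' Runs the three-phase episode identification over classified,
#' conflict-resolved outcome events (at most one outcome per patient-date;
#' see [resolve_same_day()]). Each patient is processed by exactly one
#' phase: phase 1 if they have any HES Maternity outcome record (the
#' maternity spine, prioritised over the other datasets), phase 2 if they
#' have a delivery record elsewhere, phase 3 if they have losses only.
#' Every emitted episode is terminated by a record inside the study
#' window; earlier records are retained as anchors for gap checking only.
#' Surviving unspecified-loss episodes are relabelled terminations.
#'
#' @param events classified, conflict-resolved events (auxiliary rows are
#'   ignored here and may be present)
#' @param params `register_params`
#' @return register data frame (one row per episode, undated) with a
#'   `decision_log` attribute recording every dropped, absorbed, rejected
#'   or reclassified record
#' @export
build_register <- function(events, params = register_params()) {
  ev <- events[is_outcome_category(events$category), , drop = FALSE]
  ev <- canonical_sort(ev)
  if (params$unspecified_relabel == "before_priority")
    ev <- finalise_unspecified(ev)
  if (nrow(ev) == 0) {
    out <- empty_episodes()
    attr(out, "decision_log") <- empty_decision_log()
    return(out)
  }
  dup <- duplicated(paste(ev$patient_id, ev$event_date))
  if (any(dup))
    stop("build_register: more than one outcome per patient-date; ",
         "run resolve_same_day() first")
  parts <- lapply(split(seq_len(nrow(ev)), ev$patient_id), function(rows) {
    pev <- ev[rows, , drop = FALSE]
    build_patient_episodes(pev, patient_phase(pev), params)
  })
  episodes <- assemble_register(parts)
  if (params$unspecified_relabel == "after_priority")
    episodes <- finalise_unspecified(episodes)
  episodes
}

#' Single-phase entry points
#'
#' Direct access to the three identification phases. Each expects events
#' from patients eligible for that phase: phase 1 requires at least one
#' HES Maternity outcome record per patient, phase 2 no HES Maternity
#' record but at least one delivery record, phase 3 losses only.
#'
#' @param events classified, conflict-resolved events for eligible patients
#' @param params `register_params`
#' @return undated register data frame with a `decision_log` attribute
#' @name phases
NULL

run_phase <- function(events, params, phase, check) {
  ev <- canonical_sort(events[is_outcome_category(events$category), , drop = FALSE])
  if (params$unspecified_relabel == "before_priority")
    ev <- finalise_unspecified(ev)
  parts <- lapply(split(seq_len(nrow(ev)), ev$patient_id), function(rows) {
    pev <- ev[rows, , drop = FALSE]
    check(pev)
    build_patient_episodes(pev, phase, params)
  })
  episodes <- assemble_register(parts)
  if (params$unspecified_relabel == "after_priority")
    episodes <- finalise_unspecified(episodes)
  episodes
}

#' @rdname phases
#' @export
phase1_maternity_spine <- function(events, params = register_params()) {
  run_phase(events, params, 1L, function(pev) {
    if (!any(pev$source == "HES_MAT"))
      stop("phase 1 requires at least one HES_MAT outcome record per patient")
  })
}

#' @rdname phases
#' @export
phase2_other_deliveries <- function(events, params = register_params()) {
  run_phase(events, params, 2L, function(pev) {
    if (any(pev$source == "HES_MAT"))
      stop("phase 2 patients must have no HES_MAT outcome record")
    if (!any(is_delivery_category(pev$category)))
      stop("phase 2 requires at least one delivery record per patient")
  })
}

#' @rdname phases
#' @export
phase3_losses_only <- function(events, params = register_params()) {
  run_phase(events, params, 3L, function(pev) {
    if (any(is_delivery_category(pev$category)) || any(pev$source == "HES_MAT"))
      stop("phase 3 patients must have loss records only, outside HES_MAT")
  })
}
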