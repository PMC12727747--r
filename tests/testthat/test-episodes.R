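build_outcomes <- function(categories, dates, sources = "GP", ...) {
  build_register(mk_outcome_events(categories, dates, sources, ...))
}

test_that("minimum gaps separate episodes: 175 days for deliveries, 56 for losses", {
  one <- build_outcomes("livebirth_singleton", D0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$outcome_class, "delivery")

  expect_equal(nrow(build_outcomes(c("livebirth_singleton", "livebirth_singleton"),
                                   c(D0, D0 + 175))), 2L)
  expect_equal(nrow(build_outcomes(c("livebirth_singleton", "livebirth_singleton"),
                                   c(D0, D0 + 174))), 1L)
  expect_equal(nrow(build_outcomes(c("miscarriage", "miscarriage"),
                                   c(D0, D0 + 56))), 2L)
  expect_equal(nrow(build_outcomes(c("miscarriage", "miscarriage"),
                                   c(D0, D0 + 55))), 1L)
})

test_that("gap chaining measures from the most recent retained record", {
  # three losses, each 40 days apart: all one episode even though the
  # third is 80 days after the first
  reg <- build_outcomes(rep("miscarriage", 3), D0 + c(0, 40, 80))
  expect_equal(nrow(reg), 1L)
})

test_that("phase 1 drops non-viable livebirths and converts GESTAT weeks to days", {
  # 12 weeks = 84 days < 154: dropped from the cohort
  reg <- build_register(mk_outcome_events("livebirth_singleton", D0, "HES_MAT",
                                          gestation_weeks = 12))
  expect_equal(nrow(reg), 0L)
  log <- attr(reg, "decision_log")
  expect_equal(log$action, "dropped_gestation_below_viability")

  dated <- date_register(build_register(
    mk_outcome_events("livebirth_singleton", D0, "HES_MAT", gestation_weeks = 40)))
  expect_equal(dated$gestation_days, 280L)
  expect_equal(dated$dating_method, "hes_gestation")
})

test_that("phase 1 rejects records whose recorded gestation conflicts with spacing", {
  # prior episode ends day 0; second HES_MAT delivery day 200 with GESTAT 30
  # (210 days) implies conception 10 days before the prior end: rejected
  ev <- mk_outcome_events(c("livebirth_singleton", "livebirth_singleton"),
                          c(D0, D0 + 200), "HES_MAT",
                          gestation_weeks = c(NA, 30))
  reg <- build_register(ev)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end_date, D0)
  expect_true("rejected_gestation_conflict" %in% attr(reg, "decision_log")$action)
  # same spacing with a consistent gestation (25 weeks -> conception day 25)
  ev2 <- mk_outcome_events(c("livebirth_singleton", "livebirth_singleton"),
                           c(D0, D0 + 200), "HES_MAT",
                           gestation_weeks = c(NA, 25))
  expect_equal(nrow(build_register(ev2)), 2L)
})

test_that("sub-threshold stillbirths are reclassified as miscarriages by default", {
  ev <- mk_outcome_events("stillbirth", D0, "HES_MAT", gestation_weeks = 23)
  reg <- build_register(ev)
  expect_equal(reg$outcome_subtype, "miscarriage")
  expect_equal(reg$outcome_class, "loss")
  drop_params <- register_params(stillbirth_below_floor = "drop")
  expect_equal(nrow(build_register(ev, drop_params)), 0L)
  # at the floor (24 weeks = 168 days) the stillbirth is retained
  ev2 <- mk_outcome_events("stillbirth", D0, "HES_MAT", gestation_weeks = 24)
  expect_equal(build_register(ev2)$outcome_subtype, "stillbirth")
})

test_that("the maternity spine absorbs conflicting records from other sources", {
  # GP delivery 100 days before a HES_MAT delivery cannot open an episode
  ev <- rbind(mk_outcome_events("livebirth_singleton", D0, "GP"),
              mk_outcome_events("livebirth_singleton", D0 + 100, "HES_MAT"))
  reg <- build_register(ev)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$source_dataset, "HES_MAT")
  expect_equal(reg$end_date, D0 + 100)
  expect_true("absorbed_conflicts_with_spine" %in% attr(reg, "decision_log")$action)
  # far enough apart, the GP record is its own episode
  ev2 <- rbind(mk_outcome_events("livebirth_singleton", D0, "GP"),
               mk_outcome_events("livebirth_singleton", D0 + 200, "HES_MAT"))
  expect_equal(nrow(build_register(ev2)), 2L)
})

test_that("phase 2 builds episodes from GP/APC/OPCS with the same gap logic", {
  reg <- build_outcomes("livebirth_singleton", D0, "GP")
  expect_equal(reg$source_dataset, "GP")
  expect_equal(reg$phase, 2L)

  reg2 <- build_outcomes(c("livebirth_singleton", "miscarriage"),
                         c(D0, D0 + 30), "GP")
  expect_equal(nrow(reg2), 1L)   # loss 30 days after delivery: absorbed

  reg3 <- build_outcomes(c("livebirth_singleton", "livebirth_singleton"),
                         c(D0, D0 + 200), c("GP", "HES_OPCS"))
  expect_equal(nrow(reg3), 2L)
  expect_equal(reg3$source_dataset, c("GP", "HES_OPCS"))
})

test_that("phase 3 resolves within-episode loss conflicts by the loss hierarchy", {
  reg <- build_outcomes(c("ectopic", "miscarriage"), c(D0, D0 + 10),
                        c("GP", "HES_APC"))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$outcome_subtype, "ectopic")
  expect_equal(reg$phase, 3L)

  reg2 <- build_outcomes(c("molar", "blighted_ovum"), c(D0, D0 + 20), "GP")
  expect_equal(reg2$outcome_subtype, "molar")

  # the higher-priority loss may arrive later and re-represent the episode
  reg3 <- build_outcomes(c("miscarriage", "ectopic"), c(D0, D0 + 10),
                         c("GP", "HES_APC"))
  expect_equal(reg3$outcome_subtype, "ectopic")
  expect_equal(reg3$end_date, D0 + 10)

  expect_equal(nrow(build_outcomes(c("miscarriage", "miscarriage"),
                                   c(D0, D0 + 56), "GP")), 2L)
})

test_that("dedicated phase entry points enforce their cohort preconditions", {
  gp_loss <- mk_outcome_events("miscarriage", D0, "GP")
  mat_del <- mk_outcome_events("livebirth_singleton", D0, "HES_MAT")
  expect_error(phase1_maternity_spine(gp_loss), "HES_MAT")
  expect_error(phase2_other_deliveries(gp_loss), "delivery")
  expect_error(phase3_losses_only(mat_del), "loss")
  expect_equal(nrow(phase3_losses_only(gp_loss)), 1L)
  expect_equal(phase1_maternity_spine(mat_del)$phase, 1L)
})

test_that("events before the study window anchor gaps but never terminate episodes", {
  start <- register_params()$study_start
  ev <- mk_outcome_events(c("livebirth_singleton", "livebirth_singleton"),
                          c(start - 30, start + 200), "GP")
  reg <- build_register(ev)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end_date, start + 200)
  expect_equal(reg$prior_event_date, start - 30)
  # too close to the pre-study anchor: nothing terminates
  ev2 <- mk_outcome_events(c("livebirth_singleton", "livebirth_singleton"),
                           c(start - 30, start + 100), "GP")
  expect_equal(nrow(build_register(ev2)), 0L)
  expect_true("pre_study_anchor" %in%
                attr(build_register(ev2), "decision_log")$action)
})

test_that("builder output is invariant to input row order", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    ev <- mk_outcome_events(
      sample(c(delivery_categories(), loss_categories()), n, replace = TRUE),
      D0 + sort(sample(0:400, n)),
      sources = sample(c("GP", "HES_APC", "HES_MAT", "HES_OPCS"), n, replace = TRUE))
    ref <- build_register(ev)
    perm <- build_register(ev[sample(nrow(ev)), , drop = FALSE])
    attr(ref, "decision_log") <- NULL; attr(perm, "decision_log") <- NULL
    expect_equal(perm, ref)
  }
})

test_that("adding a later event never removes earlier episode end dates", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    dates <- D0 + sort(sample(0:350, n))
    cats <- sample(c(delivery_categories(), loss_categories()), n, replace = TRUE)
    base <- build_register(mk_outcome_events(cats[-n], dates[-n], "GP"))
    grown <- build_register(mk_outcome_events(cats, dates, "GP"))
    # the new event is either absorbed (possibly re-representing the last
    # loss episode at a later date) or a new episode: existing episodes
    # persist and their end dates can only move forward
    expect_gte(nrow(grown), nrow(base))
    expect_true(all(grown$end_date[seq_len(nrow(base))] >= base$end_date))
  }
})

test_that("segmentation matches the brute-force oracle on random small layouts", {
  set.seed(17)
  cats <- c("livebirth_singleton", "stillbirth", "miscarriage", "termination",
            "ectopic", "unspecified_loss")
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    dates <- D0 + sort(sample(seq(0, 399, by = 7), n))
    categories <- sample(cats, n, replace = TRUE)
    sources <- sample(c("GP", "HES_APC", "HES_MAT"), n, replace = TRUE)
    reg <- build_register(mk_outcome_events(categories, dates, sources))
    oracle <- oracle_segment(dates, categories, sources)
    oracle$subtype[oracle$subtype == "unspecified_loss"] <- "termination"
    expect_equal(reg$end_date, oracle$end_date)
    expect_equal(reg$outcome_subtype, oracle$subtype)
  }
})
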