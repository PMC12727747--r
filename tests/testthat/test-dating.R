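date_one_patient <- function(ev, params = register_params()) {
  cls <- classify_events(ev, CODE_MAP)$events
  res <- resolve_same_day(dedup_same_day(cls))
  date_register(build_register(res$events, params), res$events, params)
}

test_that("the dating hierarchy fires in order: gestation, EDD, LMP, scan, imputation", {
  del <- D0 + 100
  # all sources present: recorded gestation wins
  ev <- rbind(mk_events("livebirth_singleton", del, "HES_MAT", gestation_weeks = 39),
              mk_events("edd", del + 5, "GP"),
              mk_events("lmp", del - 270, "GP"),
              mk_events("antenatal_scan", del - 200, "GP", scan_weeks = 10))
  d <- date_one_patient(ev)
  expect_equal(d$dating_method, "hes_gestation")
  expect_equal(d$conception_date, del - 273)
  expect_equal(d$gestation_days, 273L)

  # no gestation: EDD - 280
  d2 <- date_one_patient(ev[ev$code != stub_code("livebirth_singleton", "ICD10"), ] |>
                           (\(x) rbind(mk_events("livebirth_singleton", del, "GP"), x))())
  expect_equal(d2$dating_method, "edd")
  expect_equal(d2$conception_date, del + 5 - 280)

  # no gestation/EDD: conception = LMP
  ev3 <- rbind(mk_events("livebirth_singleton", del, "GP"),
               mk_events("lmp", del - 270, "GP"))
  d3 <- date_one_patient(ev3)
  expect_equal(d3$dating_method, "lmp")
  expect_equal(d3$gestation_days, 270L)

  # scan only: scan date minus completed weeks
  ev4 <- rbind(mk_events("livebirth_singleton", del, "GP"),
               mk_events("antenatal_scan", del - 189, "GP", scan_weeks = 12))
  d4 <- date_one_patient(ev4)
  expect_equal(d4$dating_method, "scan")
  expect_equal(d4$conception_date, del - 189 - 84)
})

test_that("a dating source with an illegal gestation falls through, not clamps", {
  # LMP 168 days before a miscarriage exceeds the 167-day loss maximum
  ev <- rbind(mk_events("miscarriage", D0, "GP"),
              mk_events("lmp", D0 - 168, "GP"))
  d <- date_one_patient(ev)
  expect_equal(d$dating_method, "imputed_loss")
  expect_equal(d$gestation_days, 83L)
  # at 167 days the LMP is legal and used
  ev2 <- rbind(mk_events("miscarriage", D0, "GP"),
               mk_events("lmp", D0 - 167, "GP"))
  expect_equal(date_one_patient(ev2)$gestation_days, 167L)
  expect_equal(date_one_patient(ev2)$dating_method, "lmp")
})

test_that("scan selection prefers earlier scans and hospital records on ties", {
  scans <- classify_events(rbind(
    mk_events("antenatal_scan", D0 + 30, "HES_APC", scan_weeks = 12),
    mk_events("antenatal_scan", D0 + 20, "GP", scan_weeks = 10)), CODE_MAP)$events
  expect_equal(select_scan(scans)$source[1], "GP")      # earlier wins
  expect_equal(select_scan(scans)$event_date[1], D0 + 20)
  tied <- classify_events(rbind(
    mk_events("antenatal_scan", D0 + 30, "HES_APC", scan_weeks = 12),
    mk_events("antenatal_scan", D0 + 30, "GP", scan_weeks = 12)), CODE_MAP)$events
  expect_equal(select_scan(tied)$source[1], "HES_APC")  # HES beats GP on a tie
  single <- scans[1, , drop = FALSE]
  expect_equal(select_scan(single), single)
})

test_that("imputation uses outcome constants, window caps, and the 35-day floor", {
  p <- register_params()
  expect_equal(impute_gestation("miscarriage", Inf, p),
               list(gestation_days = 83L, method = "imputed_loss",
                    floor_exception = FALSE))
  expect_equal(impute_gestation("ectopic", Inf, p)$gestation_days, 63L)
  expect_equal(impute_gestation("livebirth_singleton", Inf, p)$gestation_days, 275L)
  expect_equal(impute_gestation("livebirth_multiple", Inf, p)$gestation_days, 259L)
  expect_equal(impute_gestation("livebirth_singleton", Inf, p, preterm = TRUE)$gestation_days,
               259L)
  # window shorter than constant + 21: available time minus 21
  cap <- impute_gestation("miscarriage", 90, p)
  expect_equal(cap$gestation_days, 69L)
  expect_equal(cap$method, "imputed_window_capped")
  expect_false(cap$floor_exception)
  # floored at 35 days even though that breaches the 21-day spacing
  fl <- impute_gestation("miscarriage", 40, p)
  expect_equal(fl$gestation_days, 35L)
  expect_true(fl$floor_exception)
  expect_error(impute_gestation("miscarriage", 0, p), "invariant")
})

test_that("pre-term indicator codes from HES Maternity select the 259-day constant", {
  del <- D0 + 100
  ev <- rbind(mk_events("livebirth_singleton", del, "GP"),
              source_events("P1", "HES_MAT", del, "ICD10", "O601"))
  d <- date_one_patient(ev)
  expect_equal(d$dating_method, "imputed_preterm")
  expect_equal(d$gestation_days, 259L)
  # the same code outside HES Maternity does not qualify
  ev2 <- rbind(mk_events("livebirth_singleton", del, "GP"),
               source_events("P1", "HES_APC", del, "ICD10", "O603"))
  expect_equal(date_one_patient(ev2)$dating_method, "imputed_fullterm")
})

test_that("gestation always equals end date minus conception date and stays legal", {
  sim <- simulate_cohort(synth_config(n_patients = 150), recording_model(),
                         seed = 23)
  reg <- pregnancy_register(sim$events)$episodes
  expect_true(all(reg$gestation_days ==
                    as.integer(reg$end_date - reg$conception_date)))
  p <- register_params()
  loss <- reg$outcome_class == "loss"
  expect_true(all(reg$gestation_days[loss] >= p$loss_gestation_min))
  expect_true(all(reg$gestation_days[loss] <= p$loss_gestation_max))
  lb <- reg$outcome_subtype %in% c("livebirth_singleton", "livebirth_multiple")
  expect_true(all(reg$gestation_days[lb] >= p$livebirth_gestation_min))
  expect_true(all(reg$gestation_days[reg$outcome_subtype == "stillbirth"] >=
                    p$stillbirth_gestation_min))
  # spacing: conception at least 21 days after the prior event, unless the
  # 35-day floor exception fired (which is flagged)
  has_prior <- !is.na(reg$prior_event_date)
  ok <- reg$conception_date >= reg$prior_event_date + p$inter_episode_gap
  expect_true(all(ok[has_prior] | reg$floor_exception[has_prior]))
})

test_that("the second of two undated deliveries conceives 21 days after the first", {
  d <- date_one_patient(mk_events(c("livebirth_singleton", "livebirth_singleton"),
                                  c(D0, D0 + 200), "GP"))
  expect_equal(nrow(d), 2L)
  expect_equal(as.integer(d$conception_date[2] - d$end_date[1]), 21L)
  expect_equal(d$dating_method[2], "imputed_window_capped")
  expect_equal(d$gestation_days[2], 179L)
})
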