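test_that("PPV counts linked episodes per the cross-source definition", {
  # 4 single-episode patients; 3 have a same-day corroborating record in
  # another source, 1 only has its own record
  ev <- rbind(
    mk_events("livebirth_singleton", D0, "GP", patient = "A"),
    mk_events("livebirth_singleton", D0, "HES_APC", patient = "A"),
    mk_events("miscarriage", D0, "GP", patient = "B"),
    mk_events("miscarriage", D0 + 1, "HES_APC", patient = "B"),
    mk_events("livebirth_singleton", D0, "HES_MAT", patient = "C"),
    mk_events("livebirth_singleton", D0 + 2, "HES_OPCS", patient = "C"),
    mk_events("termination", D0, "GP", patient = "D"))
  reg <- pregnancy_register(ev)
  v <- internal_ppv(reg$episodes, reg$events, 2)
  expect_equal(v$n_episodes, 4L)
  expect_equal(v$n_linked, 3L)
  expect_equal(v$ppv_percent, 75)
})

test_that("corroboration in the episode's own source does not count", {
  ev <- rbind(mk_events("miscarriage", D0, "GP"),
              mk_events("termination", D0 + 1, "GP"))
  reg <- pregnancy_register(ev)
  expect_equal(nrow(reg$episodes), 1L)
  expect_equal(internal_ppv(reg$episodes, reg$events, 2)$n_linked, 0L)
})

test_that("a record terminating another episode of the patient cannot corroborate", {
  # two loss episodes 60 days apart, both GP-derived, plus one HES_APC
  # record coinciding with the second: only the second links at +/-7
  ev <- rbind(mk_events(c("miscarriage", "miscarriage"), c(D0, D0 + 60), "GP"),
              mk_events("miscarriage", D0 + 60, "HES_APC"))
  reg <- pregnancy_register(ev)
  expect_equal(nrow(reg$episodes), 2L)
  v <- internal_ppv(reg$episodes, reg$events, 7)
  expect_equal(v$n_linked, 1L)
})

test_that("PPV is monotone in the window and undefined on an empty register", {
  sim <- simulate_cohort(synth_config(n_patients = 120), recording_model(),
                         seed = 19)
  reg <- pregnancy_register(sim$events)
  ppv <- vapply(c(0, 2, 7),
                function(w) internal_ppv(reg$episodes, reg$events, w)$ppv_percent,
                numeric(1))
  expect_true(ppv[1] <= ppv[2] && ppv[2] <= ppv[3])
  expect_error(internal_ppv(reg$episodes[0, ], reg$events, 2), "empty")
})

test_that("overlap cells partition the register and match a brute-force recount", {
  sim <- simulate_cohort(synth_config(n_patients = 150), recording_model(),
                         seed = 21)
  reg <- pregnancy_register(sim$events)
  tab <- overlap_counts(reg$episodes, reg$events, 2)
  expect_equal(sum(tab$n), nrow(reg$episodes))

  # independent recount straight from the definition
  ev <- reg$events[is_outcome_category(reg$events$category), ]
  term <- paste(reg$episodes$patient_id, reg$episodes$end_date,
                reg$episodes$source_dataset)
  recount <- table(vapply(seq_len(nrow(reg$episodes)), function(k) {
    e <- reg$episodes[k, ]
    hits <- ev[ev$patient_id == e$patient_id &
                 outcome_class(ev$category) == e$outcome_class &
                 ev$source != e$source_dataset &
                 abs(as.numeric(ev$event_date - e$end_date)) <= 2 &
                 !(paste(ev$patient_id, ev$event_date, ev$source) %in% term), ]
    paste(intersect(c("GP", "HES_MAT", "HES_APC", "HES_OPCS"),
                    union(e$source_dataset, unique(hits$source))), collapse = "+")
  }, character(1)))
  expect_equal(tab$n[match(names(recount), tab$sources)],
               as.integer(recount))

  # noise-free: every delivery episode sits in the all-four cell
  simnf <- simulate_cohort(synth_config(n_patients = 60), noise_free_recording(),
                           seed = 22)
  regnf <- pregnancy_register(simnf$events)
  tabnf <- overlap_counts(regnf$episodes[regnf$episodes$outcome_class == "delivery", ],
                          regnf$events, 2)
  expect_equal(tabnf$sources, "GP+HES_MAT+HES_APC+HES_OPCS")
})

test_that("postnatal linkage uses a half-open 175-day window after delivery", {
  mk_case <- function(offset) {
    ev <- rbind(mk_events("livebirth_singleton", D0, "GP"),
                mk_events("postnatal", D0 + offset, "GP"))
    reg <- pregnancy_register(ev)
    postnatal_link(reg$episodes, reg$events)
  }
  expect_equal(mk_case(100), 100)
  expect_equal(mk_case(175), 100)
  expect_equal(mk_case(176), 0)
  expect_equal(mk_case(0), 0)   # same-day record is not postnatal follow-up
  loss_reg <- pregnancy_register(mk_events("miscarriage", D0, "GP"))
  expect_error(postnatal_link(loss_reg$episodes, loss_reg$events),
               "no delivery")
})

test_that("direct standardisation reduces to the crude rate under equal stratum rates", {
  sp <- data.frame(age_group = c("a", "b", "c"),
                   population = c(100, 300, 600))
  r <- direct_standardised_rate(c(a = 5, b = 10, c = 20),
                                c(a = 500, b = 1000, c = 2000), sp)
  expect_equal(r$standardised_rate, r$crude_rate)
  expect_equal(r$crude_rate, 10)
  expect_true(r$ci_lower <= r$standardised_rate &&
                r$standardised_rate <= r$ci_upper)
})

test_that("the two-stratum hand example gives 25.0 per 1000", {
  sp <- data.frame(age_group = c("young", "old"), population = c(25, 75))
  r <- direct_standardised_rate(c(young = 10, old = 30),
                                c(young = 1000, old = 1000), sp)
  expect_equal(r$standardised_rate, 25)
})

test_that("standardisation matches an independent weighted-sum recomputation", {
  set.seed(14)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    sp <- data.frame(age_group = letters[1:k],
                     population = sample(1000:9999, k))
    x <- stats::setNames(sample(0:50, k), letters[1:k])
    n <- stats::setNames(sample(500:5000, k), letters[1:k])
    r <- direct_standardised_rate(x, n, sp, scale = 1000)
    w <- sp$population / sum(sp$population)
    expect_equal(r$standardised_rate, 1000 * sum(w * x / n))
  }
  sp <- data.frame(age_group = c("a", "b"), population = c(1, 1))
  expect_error(direct_standardised_rate(c(a = 1, b = 1), c(a = 0, b = 10), sp),
               "zero denominator")
  expect_error(direct_standardised_rate(c(a = 1, b = 1), c(a = 5, b = 10),
                                        sp[1, , drop = FALSE]), "align")
})
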