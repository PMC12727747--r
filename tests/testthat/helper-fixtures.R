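# Shared fixture builders: all test data is constructed in code.

CODE_MAP <- pregreg::default_code_map()
D0 <- as.Date("2021-03-01")

stub_code <- local({
  cache <- new.env()
  function(category, vocabulary) {
    key <- paste0(vocabulary, ":", category)
    if (is.null(cache[[key]])) {
      hit <- CODE_MAP$code[CODE_MAP$category == category &
                             CODE_MAP$vocabulary == vocabulary]
      if (!length(hit)) stop("no stub code for ", category, " in ", vocabulary)
      cache[[key]] <- hit[1]
    }
    cache[[key]]
  }
})

vocab_for <- function(source) {
  c(GP = "SNOMED", HES_MAT = "ICD10", HES_APC = "ICD10", HES_OPCS = "OPCS4")[[source]]
}

# raw (uncategorised) events for the classification entry point
mk_events <- function(categories, dates, sources = "GP", patient = "P1",
                      gestation_weeks = NA, scan_weeks = NA, n_babies = NA) {
  n <- length(dates)
  sources <- rep_len(sources, n)
  categories <- rep_len(categories, n)
  voc <- vapply(sources, vocab_for, character(1))
  codes <- mapply(stub_code, categories, voc)
  source_events(rep_len(patient, n), sources, dates, voc, codes,
                gestation_weeks = rep_len(gestation_weeks, n),
                scan_weeks = rep_len(scan_weeks, n),
                n_babies = rep_len(n_babies, n))
}

# classified events ready for the episode builder (skips the code map)
mk_outcome_events <- function(categories, dates, sources = "GP", patient = "P1",
                              gestation_weeks = NA, n_babies = NA) {
  ev <- mk_events(categories, dates, sources, patient,
                  gestation_weeks = gestation_weeks, n_babies = n_babies)
  classify_events(ev, CODE_MAP)$events
}

# single-patient convenience: raw events -> dated register
quick_register <- function(ev, params = register_params()) {
  pregnancy_register(ev, CODE_MAP, params)$episodes
}
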