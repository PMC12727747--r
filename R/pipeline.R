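# End-to-end register construction.

#' Build and date a pregnancy register from raw events
#'
#' Chains the full pipeline: code-map classification, same-day
#' deduplication, same-day conflict resolution, three-phase episode
#' identification, and conception dating.
#'
#' @param events `source_events` from [read_event_table()] or
#'   [render_source_events()]
#' @param map `code_map`
#' @param params `register_params`
#' @return list with `episodes` (dated register), `events` (classified,
#'   deduplicated events across all sources, the evidence base for
#'   validation), `resolution_log`, `decision_log`, `unclassified`
#' @export
pregnancy_register <- function(events, map = default_code_map(),
                               params = register_params()) {
  cls <- classify_events(events, map)
  ded <- dedup_same_day(cls$events)
  res <- resolve_same_day(ded)
  eps <- build_register(res$events, params)
  dated <- date_register(eps, res$events, params)
  list(episodes = dated,
       events = ded,
       resolution_log = res$log,
       decision_log = attr(eps, "decision_log"),
       unclassified = cls$unclassified)
}
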