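# Brute-force oracles, independent of the builder's sequential machinery.

# Declarative segmentation oracle: enumerates all 2^n terminator/absorbed
# labelings of a patient's outcome records and keeps those satisfying the
# register's rules stated declaratively:
#   * a HES Maternity record terminates an episode iff it is the first
#     HES_MAT record or lies at least the class gap after the previous
#     HES_MAT record (chaining within the spine);
#   * any other record terminates iff it lies at least the class gap after
#     the immediately preceding record of any kind AND does not conflict
#     with the next terminating HES_MAT record (which must itself sit at
#     least its own class gap later);
#   * an absorbed record belongs to the previous episode when its own gap
#     failed, otherwise (spine conflict) to the next spine episode;
#   * a loss episode is represented by the highest-priority loss among its
#     own record and the losses absorbed into it at or after its date
#     (ties: earlier date, then maternity-first source order).
# Exactly one labeling must be legal; the oracle fails otherwise.
# Scope: records without recorded gestation, all inside the study window.
oracle_segment <- function(dates, categories, sources, params = register_params()) {
  stopifnot(!is.unsorted(dates), !anyDuplicated(dates))
  n <- length(dates)
  cls <- outcome_class(categories)
  req <- ifelse(cls == "delivery", params$delivery_gap_min, params$loss_gap_min)
  is_spine <- sources == "HES_MAT"

  legal_labelings <- list()
  for (mask in 0:(2^n - 1)) {
    term <- as.logical(bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) > 0)
    ok <- TRUE
    for (j in seq_len(n)) {
      if (is_spine[j]) {
        prev_sp <- which(is_spine[seq_len(j - 1L)])
        can <- if (!length(prev_sp)) TRUE
               else as.numeric(dates[j] - dates[max(prev_sp)]) >= req[j]
      } else {
        gap_ok <- if (j == 1L) TRUE
                  else as.numeric(dates[j] - dates[j - 1L]) >= req[j]
        next_sp <- which(is_spine & term & seq_len(n) > j)
        spine_ok <- TRUE
        if (length(next_sp)) {
          s <- next_sp[1]
          spine_ok <- as.numeric(dates[s] - dates[j]) >= req[s]
        }
        can <- gap_ok && spine_ok
      }
      if (term[j] != can) { ok <- FALSE; break }
    }
    if (ok) legal_labelings[[length(legal_labelings) + 1L]] <- term
  }
  if (length(legal_labelings) != 1L)
    stop("oracle: ", length(legal_labelings), " legal labelings (expected 1)")
  term <- legal_labelings[[1]]

  # assignment of absorbed records
  assign_to <- rep(NA_integer_, n)     # index of owning terminator record
  for (j in seq_len(n)) {
    if (term[j]) { assign_to[j] <- j; next }
    gap_ok <- if (j == 1L) TRUE
              else as.numeric(dates[j] - dates[j - 1L]) >= req[j]
    if (!gap_ok) {
      prev_t <- which(term & seq_len(n) < j)
      if (length(prev_t)) assign_to[j] <- max(prev_t)
    } else {
      next_sp <- which(is_spine & term & seq_len(n) > j)
      if (length(next_sp)) assign_to[j] <- next_sp[1]
    }
  }

  idx <- which(term)
  end <- dates[idx]
  subtype <- categories[idx]
  for (q in seq_along(idx)) {
    j <- idx[q]
    if (cls[j] != "loss") next
    members <- which(assign_to == j & is_loss_category(categories) &
                       dates >= dates[j])
    pr <- pregreg::loss_priority(categories[members])
    best <- members[order(pr, dates[members],
                          match(sources[members],
                                c("HES_MAT", "GP", "HES_APC", "HES_OPCS")))][1]
    end[q] <- dates[best]
    subtype[q] <- categories[best]
  }
  list(end_date = end, subtype = subtype)
}

# brute-force conflict resolution: survivor of a same-day category set
oracle_resolve <- function(categories) {
  categories[which.min(category_priority(categories))]
}
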