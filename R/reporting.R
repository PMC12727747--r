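# Demographic tabulations with ethnicity coalescing and small-count
# suppression.

#' Coalesce ethnicity from GP and HES records
#'
#' GP-recorded ethnicity takes precedence; HES ethnicity fills gaps; both
#' missing yields "Not recorded".
#'
#' @param gp_value,hes_value character vectors (NA = missing)
#' @return character vector
#' @export
resolve_ethnicity <- function(gp_value, hes_value) {
  out <- ifelse(!is.na(gp_value) & nzchar(gp_value), gp_value,
                ifelse(!is.na(hes_value) & nzchar(hes_value), hes_value,
                       "Not recorded"))
  out
}

#' Age band specifications
#'
#' `patient_bands()` follows the patient-level presentation (<20, 20-29,
#' 30-34, 35-39, >=40); `five_year_bands()` the pregnancy-level 5-year
#' bands 15-19 ... 45-50. Both are plain data frames (`label`, `min`,
#' `max`) so alternative band definitions can be supplied.
#'
#' @return data frame with columns `label`, `min`, `max`
#' @export
patient_bands <- function() {
  data.frame(label = c("<20", "20-29", "30-34", "35-39", ">=40"),
             min = c(-Inf, 20, 30, 35, 40),
             max = c(19, 29, 34, 39, Inf), stringsAsFactors = FALSE)
}

#' @rdname patient_bands
#' @export
five_year_bands <- function() {
  data.frame(label = c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-50"),
             min = c(15, 20, 25, 30, 35, 40, 45),
             max = c(19, 24, 29, 34, 39, 44, 50), stringsAsFactors = FALSE)
}

#' Assign ages to bands
#'
#' @param age integer ages
#' @param bands band specification data frame
#' @return character band labels (NA outside all bands)
#' @export
age_band <- function(age, bands = patient_bands()) {
  out <- rep(NA_character_, length(age))
  for (b in seq_len(nrow(bands)))
    out[!is.na(age) & age >= bands$min[b] & age <= bands$max[b]] <- bands$label[b]
  out
}

age_at <- function(year_of_birth, date) {
  as.integer(format(as.Date(date), "%Y")) - year_of_birth
}

loss_group <- function(subtype) {
  ifelse(subtype == "miscarriage", "Miscarriage",
         ifelse(subtype %in% c("termination", "probable_termination"), "Termination",
                "Other pregnancy losses"))
}

crosstab <- function(row_block, row_value, col_value, col_levels) {
  lv <- unique(row_value)
  tab <- table(factor(row_value, levels = lv),
               factor(col_value, levels = col_levels))
  df <- as.data.frame.matrix(tab)
  out <- data.frame(block = rep(row_block, nrow(df)), stratum = rownames(df), df,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$Total <- rowSums(df)
  rownames(out) <- NULL
  out
}

demographic_blocks <- function(patients, age, bands) {
  band <- age_band(age, bands)
  # ages drift past the top band between cohort entry and outcome date;
  # keep those rows visible rather than dropping them from the table
  band[is.na(band)] <- "Out of band"
  list(
    `Age group` = band,
    `Ethnic group` = resolve_ethnicity(patients$ethnicity_gp, patients$ethnicity_hes),
    `Quintile of Townsend` = ifelse(is.na(patients$townsend_quintile),
                                    "Not recorded",
                                    as.character(patients$townsend_quintile)),
    Region = patients$region
  )
}

stack_blocks <- function(blocks, col_value, col_levels) {
  do.call(rbind, lapply(names(blocks), function(b) {
    crosstab(b, blocks[[b]], col_value, col_levels)
  }))
}

#' Demographic tables for a dated register
#'
#' Produces the standard report set: a patient-level summary (each woman
#' counted once, age taken at study start), and pregnancy-level summaries
#' using age at the outcome date - by number of pregnancies (1 / 2 / 3 or
#' more), by outcome class (delivery vs loss), deliveries by outcome
#' (livebirth vs stillbirth), and losses grouped as miscarriage /
#' termination (including probable terminations) / other pregnancy losses
#' (ectopic, molar, blighted ovum). Counts come with row or column
#' percentages; small-count suppression is applied separately via
#' [suppress_small_counts()].
#'
#' @param patients patient demographics table
#' @param episodes dated register
#' @param params `register_params` (study window)
#' @param patient_band_spec,pregnancy_band_spec age band specifications
#' @return named list of data frames: `patients`, `by_parity`,
#'   `by_outcome`, `by_delivery_outcome`, `by_loss_type`
#' @export
pregnancy_tables <- function(patients, episodes, params = register_params(),
                             patient_band_spec = patient_bands(),
                             pregnancy_band_spec = five_year_bands()) {
  in_reg <- patients[patients$patient_id %in% episodes$patient_id, , drop = FALSE]
  age_start <- age_at(in_reg$year_of_birth, params$study_start)
  pat_blocks <- demographic_blocks(in_reg, age_start, patient_band_spec)
  pat_tab <- stack_blocks(pat_blocks, rep("Women", nrow(in_reg)), "Women")
  pat_tab$Total <- NULL

  ep <- merge(episodes, patients, by = "patient_id", sort = FALSE)
  age_out <- age_at(ep$year_of_birth, ep$end_date)
  ep_blocks <- demographic_blocks(ep, age_out, pregnancy_band_spec)

  n_preg <- table(episodes$patient_id)
  parity <- as.character(pmin(as.integer(n_preg[ep$patient_id]), 3L))
  parity[parity == "3"] <- "3 or more"

  list(
    patients = pat_tab,
    by_parity = stack_blocks(ep_blocks, parity, c("1", "2", "3 or more")),
    by_outcome = stack_blocks(ep_blocks,
                              ifelse(ep$outcome_class == "delivery", "Delivery", "Loss"),
                              c("Delivery", "Loss")),
    by_delivery_outcome = {
      del <- ep$outcome_class == "delivery"
      del_blocks <- demographic_blocks(ep[del, , drop = FALSE], age_out[del],
                                       pregnancy_band_spec)
      stack_blocks(del_blocks,
                   ifelse(ep$outcome_subtype[del] == "stillbirth",
                          "Stillbirth", "Livebirth"),
                   c("Stillbirth", "Livebirth"))
    },
    by_loss_type = {
      lo <- ep$outcome_class == "loss"
      loss_blocks <- demographic_blocks(ep[lo, , drop = FALSE], age_out[lo],
                                        pregnancy_band_spec)
      stack_blocks(loss_blocks, loss_group(ep$outcome_subtype[lo]),
                   c("Miscarriage", "Termination", "Other pregnancy losses"))
    }
  )
}

#' Row percentages for a stratified table
#'
#' @param table stratified count table (from [pregnancy_tables()])
#' @param digits decimal places (default 1, the report convention)
#' @return data frame of formatted "count (pct%)" strings
#' @export
row_percentages <- function(table, digits = 1) {
  count_cols <- setdiff(names(table), c("block", "stratum", "Total"))
  tot <- if ("Total" %in% names(table)) table$Total
         else rowSums(table[count_cols])
  out <- table
  for (cc in count_cols) {
    pct <- ifelse(tot > 0, 100 * table[[cc]] / tot, 0)
    out[[cc]] <- sprintf(paste0("%d (%.", digits, "f%%)"), table[[cc]], pct)
  }
  out
}

#' Small-count suppression
#'
#' Counts of 1 to threshold-1 are replaced by `"<threshold"` (zero cells
#' are shown as 0: censoring does not include 0). Within each row, if
#' exactly one cell was suppressed and the row total is displayed, the
#' smallest remaining cell is obscured to a range `[a-b]` so the censored
#' count cannot be back-calculated from the total. Stated totals are
#' never changed.
#'
#' @param table stratified count table with numeric count columns and an
#'   optional `Total` column
#' @param threshold suppression threshold (default 5)
#' @return data frame with count columns as character, suppressed cells
#'   marked; attribute `n_suppressed` records the number of censored cells
#' @export
suppress_small_counts <- function(table, threshold = 5L) {
  count_cols <- setdiff(names(table), c("block", "stratum", "Total"))
  out <- table
  for (cc in count_cols) out[[cc]] <- as.character(table[[cc]])
  n_sup <- 0L
  for (r in seq_len(nrow(table))) {
    vals <- as.numeric(table[r, count_cols])
    sup <- vals >= 1 & vals < threshold
    n_sup <- n_sup + sum(sup)
    for (j in which(sup)) out[r, count_cols[j]] <- paste0("<", threshold)
    if (sum(sup) == 1 && "Total" %in% names(table)) {
      # one censored cell is recoverable from the total: obscure the
      # smallest unsuppressed companion cell to a range
      open <- which(!sup & vals > 0)
      if (length(open)) {
        j <- open[which.min(vals[open])]
        s <- vals[sup]
        lo <- vals[j] + s - (threshold - 1)
        hi <- vals[j] + s - 1
        out[r, count_cols[j]] <- paste0("[", lo, "-", hi, "]")
        n_sup <- n_sup + 1L
      }
    }
  }
  attr(out, "n_suppressed") <- n_sup
  out
}

#' Reference rates for report footnotes
#'
#' Published national and register-based comparison values (ONS, CPRD)
#' shipped as a static reference table; these are context for report
#' footnotes and are never recomputed.
#'
#' @return data frame with `metric`, `group`, `value`, `units`, `source`
#' @export
external_reference_rates <- function() {
  utils::read.csv(system.file("extdata", "external_reference_rates.csv",
                              package = "pregreg", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
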