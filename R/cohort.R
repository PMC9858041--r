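#' Impute the diabetes diagnosis date (DDD)
#'
#' The trajectory time origin is the diabetes diagnosis date. When the first
#' recorded HbA1c specimen falls in the diagnosis year, the specimen date is
#' taken as the DDD. When the first specimen falls in a later year, the DDD is
#' drawn uniformly over the integer day offsets \{0, ..., 364\} from January 1
#' of the diagnosis year. (The draw is on 365 values: day 365 would fall
#' outside non-leap years.) The draw is deterministic given `rng_seed` and
#' `subject_id`, independent of call order, so re-imputation with the same
#' seed reproduces the same dates subject by subject.
#'
#' @param diagnosis_year calendar year of diagnosis.
#' @param first_specimen_date `Date` of the first HbA1c specimen.
#' @param rng_seed integer seed controlling the imputation stream.
#' @param subject_id subject identifier (mixed into the per-subject stream).
#' @return a `Date`.
#' @export
impute_ddd <- function(diagnosis_year, first_specimen_date, rng_seed, subject_id = "") {
  first_specimen_date <- as.Date(first_specimen_date)
  spec_year <- as.integer(format(first_specimen_date, "%Y"))
  if (diagnosis_year > spec_year) {
    ht_stop(sprintf(
      "impute_ddd: diagnosis_year %d is after the first specimen year %d (subject '%s')",
      diagnosis_year, spec_year, subject_id), "hba1ctraj_data_error")
  }
  if (spec_year == diagnosis_year) {
    return(first_specimen_date)
  }
  mix <- (as.numeric(rng_seed) * 48271 + stable_id_hash(subject_id)) %% 2147483647
  offset <- local({
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(mix))
    sample.int(365L, 1L) - 1L
  })
  as.Date(sprintf("%d-01-01", diagnosis_year)) + offset
}

#' Apply the eligibility filter
#'
#' A subject is eligible when it has at least `min_samples` HbA1c measurements
#' and its specimen dates span at least `min_span_days` days (3 years,
#' leap-year neutral at 365.25 days/year). Subjects failing the count rule are
#' reported with reason `"too_few_samples"`, then the span rule with
#' `"span_too_short"`.
#'
#' @param measurements data frame with `subject_id`, `specimen_date`.
#' @param subjects data frame with `subject_id`; every measured subject must
#'   appear here.
#' @param min_samples minimum measurement count (default 5).
#' @param min_span_days minimum first-to-last specimen span in days
#'   (default 1095.75).
#' @return list with `kept` (character vector of ids) and `excluded`
#'   (data frame `subject_id`, `reason`).
#' @export
filter_eligible <- function(measurements, subjects,
                            min_samples = 5L, min_span_days = 1095.75) {
  orphan <- setdiff(unique(measurements$subject_id), subjects$subject_id)
  if (length(orphan)) {
    ht_stop(paste0("filter_eligible: subjects present in measurements but missing ",
                   "from the subjects table: ", paste(orphan, collapse = ", ")),
            "hba1ctraj_data_error")
  }
  d <- as.numeric(as.Date(measurements$specimen_date))
  counts <- tapply(d, measurements$subject_id, length)
  spans <- tapply(d, measurements$subject_id, function(x) max(x) - min(x))
  ids <- names(counts)
  too_few <- counts < min_samples
  too_short <- !too_few & spans < min_span_days
  excluded <- data.frame(
    subject_id = c(ids[too_few], ids[too_short]),
    reason = c(rep("too_few_samples", sum(too_few)),
               rep("span_too_short", sum(too_short))),
    stringsAsFactors = FALSE
  )
  list(kept = ids[!(too_few | too_short)], excluded = excluded)
}

#' Build an analysis cohort from raw registry tables
#'
#' Applies the eligibility filter, imputes each subject's diabetes diagnosis
#' date ([impute_ddd()]), converts specimen dates to weeks from the DDD
#' (days/7, fractional), drops any measurement dated before the DDD (possible
#' under imputation) and re-checks eligibility after the drop, and resolves
#' the event outcome: the first HHF strictly after the DDD counts as an event
#' at its week offset; otherwise the subject is censored, by default at the
#' last observed measurement (`censor_at = "events_table"` instead carries the
#' events table's censoring time forward).
#'
#' `event_weeks` in the events table is interpreted as weeks relative to the
#' subject's first specimen date, the observable anchor shared by generator
#' and registry extracts.
#'
#' @param tables a `registry_tables` list (see [generate_cohort()] /
#'   [read_registry()]).
#' @param rng_seed seed for DDD imputation.
#' @param censor_at `"last_measurement"` (default) or `"events_table"`.
#' @param min_samples,min_span_days eligibility thresholds, see
#'   [filter_eligible()].
#' @return object of class `hba1c_cohort`: list with `subjects` (one row per
#'   subject: ddd, covariates, `event_weeks`, `event_indicator`, and the
#'   oracle-only `true_class` when present in the input), `measurements`
#'   (`subject_id`, `weeks`, `hba1c`, sorted by subject then time) and
#'   `provenance` (raw/excluded/final counts, per-reason exclusions, seed).
#' @export
build_cohort <- function(tables, rng_seed = 1L,
                         censor_at = c("last_measurement", "events_table"),
                         min_samples = 5L, min_span_days = 1095.75) {
  censor_at <- match.arg(censor_at)
  meas <- tables$measurements
  subj <- tables$subjects
  ev <- tables$events
  for (col in c("subject_id", "specimen_date", "hba1c_pct")) {
    if (is.null(meas[[col]])) {
      ht_stop(sprintf("build_cohort: measurements table lacks column '%s'", col),
              "hba1ctraj_data_error")
    }
  }
  meas$specimen_date <- as.Date(meas$specimen_date)
  n_raw <- length(unique(meas$subject_id))

  flt <- filter_eligible(meas, subj, min_samples, min_span_days)
  meas <- meas[meas$subject_id %in% flt$kept, , drop = FALSE]

  # per-subject first specimen, DDD imputation, rebasing
  meas <- meas[order(meas$subject_id, meas$specimen_date), , drop = FALSE]
  by_subj <- split(seq_len(nrow(meas)), meas$subject_id)
  ids <- names(by_subj)
  srow <- subj[match(ids, subj$subject_id), , drop = FALSE]
  ev <- ev[match(ids, ev$subject_id), , drop = FALSE]

  dropped_pre_ddd <- 0L
  post_excl <- character(0)
  out_meas <- vector("list", length(ids))
  ddd <- as.Date(rep(NA, length(ids)))
  event_weeks <- numeric(length(ids)); event_ind <- integer(length(ids))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    rows <- by_subj[[i]]
    dates <- meas$specimen_date[rows]
    first_spec <- dates[1L]
    ddd_i <- impute_ddd(srow$diagnosis_year[i], first_spec, rng_seed, ids[i])
    weeks <- as.numeric(dates - ddd_i) / 7
    ok <- weeks >= 0
    dropped_pre_ddd <- dropped_pre_ddd + sum(!ok)
    weeks <- weeks[ok]; y <- meas$hba1c_pct[rows][ok]; dates <- dates[ok]
    if (length(weeks) < min_samples ||
        (max(weeks) - min(weeks)) * 7 < min_span_days) {
      post_excl <- c(post_excl, ids[i])
      next
    }
    keep[i] <- TRUE
    ddd[i] <- ddd_i
    out_meas[[i]] <- data.frame(subject_id = ids[i], weeks = weeks, hba1c = y,
                                stringsAsFactors = FALSE)
    # events table times are weeks from the first specimen date
    ev_date <- first_spec + ev$event_weeks[i] * 7
    ev_weeks_ddd <- as.numeric(ev_date - ddd_i) / 7
    if (!is.na(ev$event_indicator[i]) && ev$event_indicator[i] == 1L &&
        ev_weeks_ddd > 0) {
      event_weeks[i] <- ev_weeks_ddd
      event_ind[i] <- 1L
    } else {
      event_ind[i] <- 0L
      event_weeks[i] <- if (censor_at == "events_table" && ev_weeks_ddd > 0) {
        max(ev_weeks_ddd, max(weeks))
      } else {
        max(weeks)
      }
      if (event_weeks[i] <= 0) event_weeks[i] <- max(weeks)
    }
  }
  if (!any(keep)) {
    ht_stop("build_cohort: all subjects excluded by the eligibility filter",
            "hba1ctraj_data_error")
  }

  subjects_out <- srow[keep, setdiff(names(srow), "subject_id"), drop = FALSE]
  subjects_out <- cbind(
    data.frame(subject_id = ids[keep], stringsAsFactors = FALSE),
    subjects_out
  )
  subjects_out$ddd <- ddd[keep]
  subjects_out$event_weeks <- event_weeks[keep]
  subjects_out$event_indicator <- event_ind[keep]
  rownames(subjects_out) <- NULL
  measurements_out <- do.call(rbind, out_meas[keep])
  rownames(measurements_out) <- NULL

  excl <- flt$excluded
  if (length(post_excl)) {
    excl <- rbind(excl, data.frame(subject_id = post_excl,
                                   reason = "ineligible_after_ddd_rebase",
                                   stringsAsFactors = FALSE))
  }
  structure(
    list(
      subjects = subjects_out,
      measurements = measurements_out,
      provenance = list(
        n_raw = n_raw,
        n_excluded = n_raw - nrow(subjects_out),
        n_final = nrow(subjects_out),
        exclusions = excl,
        dropped_pre_ddd_measurements = dropped_pre_ddd,
        ddd_seed = rng_seed,
        censor_at = censor_at
      )
    ),
    class = "hba1c_cohort"
  )
}

#' @export
print.hba1c_cohort <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<hba1c_cohort> %d subjects (%d raw, %d excluded), %d measurements\n",
              p$n_final, p$n_raw, p$n_excluded, nrow(x$measurements)))
  cat(sprintf("  events: %d (%.2f%%); DDD seed %s\n",
              sum(x$subjects$event_indicator),
              100 * mean(x$subjects$event_indicator), p$ddd_seed))
  invisible(x)
}

#' Re-serialize a cohort as raw registry tables
#'
#' Inverts the rebasing done by [build_cohort()]: specimen dates are
#' reconstructed as `ddd + weeks * 7` days, the diagnosis year is the DDD's
#' calendar year, and the events table carries times relative to the first
#' specimen date. Rebuilding the result with [build_cohort()] under the same
#' imputation seed reproduces the cohort (the per-subject imputation stream
#' redraws identical dates).
#'
#' @param cohort an `hba1c_cohort`.
#' @return a `registry_tables` list.
#' @export
cohort_as_tables <- function(cohort) {
  s <- cohort$subjects
  m <- cohort$measurements
  ddd <- s$ddd[match(m$subject_id, s$subject_id)]
  measurements <- data.frame(
    subject_id = m$subject_id,
    specimen_date = ddd + m$weeks * 7,
    hba1c_pct = m$hba1c,
    stringsAsFactors = FALSE
  )
  first_w <- tapply(m$weeks, m$subject_id, min)[s$subject_id]
  events <- data.frame(
    subject_id = s$subject_id,
    event_weeks = s$event_weeks - as.numeric(first_w),
    event_indicator = s$event_indicator
  )
  subjects <- s[, setdiff(names(s), c("ddd", "event_weeks", "event_indicator")),
                drop = FALSE]
  subjects$diagnosis_year <- as.integer(format(s$ddd, "%Y"))
  structure(list(measurements = measurements, subjects = subjects,
                 events = events),
            class = "registry_tables")
}

#' Write a cohort to disk (long CSV + provenance JSON)
#'
#' @param cohort an `hba1c_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$measurements, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "cohort_subjects.csv"),
                   row.names = FALSE)
  prov <- cohort$provenance
  prov$exclusions <- NULL
  jsonlite::write_json(prov, file.path(dir, "cohort_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
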