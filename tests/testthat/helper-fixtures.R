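# Shared fixture builders. Everything is generated in code; no stored data.

# Long-format trajectory data with known class structure on a log-time basis.
make_traj_data <- function(n, intercepts, slopes, sd = 0.4, n_obs = 6,
                           t_max = 250, seed = 1, prefix = "T") {
  set.seed(seed)
  k <- length(intercepts)
  cls <- rep(seq_len(k), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    tt <- c(0, sort(runif(n_obs - 1, 0, t_max)))
    y <- intercepts[cls[i]] + slopes[cls[i]] * log(tt + 1) + rnorm(n_obs, 0, sd)
    data.frame(subject_id = sprintf("%s%04d", prefix, i), weeks = tt, hba1c = y)
  })
  structure(list(data = do.call(rbind, rows), class = cls),
            class = "list")
}

# Minimal hand-built registry tables (explicit dates) for cohort-stage tests.
make_mini_tables <- function() {
  mk_dates <- function(start, offsets_days) as.Date(start) + offsets_days
  meas <- rbind(
    # A: same-year first specimen, 5 samples over >3 years
    data.frame(subject_id = "A",
               specimen_date = mk_dates("2014-03-10", c(0, 14, 400, 800, 1200)),
               hba1c_pct = c(7.0, 7.1, 6.9, 7.0, 7.2)),
    # B: mismatch (diagnosed 2013, first specimen 2015)
    data.frame(subject_id = "B",
               specimen_date = mk_dates("2015-06-01", c(0, 100, 500, 900, 1300)),
               hba1c_pct = c(8.0, 7.9, 7.8, 7.7, 7.6)),
    # C: too few samples
    data.frame(subject_id = "C",
               specimen_date = mk_dates("2014-01-01", c(0, 400, 900, 1800)),
               hba1c_pct = c(6.5, 6.6, 6.4, 6.5)),
    # D: span too short
    data.frame(subject_id = "D",
               specimen_date = mk_dates("2014-01-01", c(0, 100, 300, 600, 1000)),
               hba1c_pct = c(9.0, 8.8, 8.6, 8.4, 8.2)),
    # E: eligible, same-year first specimen, recorded HHF predates the DDD
    data.frame(subject_id = "E",
               specimen_date = mk_dates("2015-02-01", c(0, 200, 500, 900, 1300)),
               hba1c_pct = c(7.5, 7.4, 7.3, 7.2, 7.1))
  )
  subjects <- data.frame(
    subject_id = c("A", "B", "C", "D", "E"),
    diagnosis_year = c(2014L, 2013L, 2014L, 2014L, 2015L),
    sex = c("male", "female", "male", "female", "male"),
    ethnicity = c("chinese", "malay", "indian", "other", "chinese"),
    age_at_diagnosis = c(60, 55, 50, 65, 58),
    prior_cvd = c(0L, 1L, 0L, NA, 0L),
    prior_hf = c(0L, 0L, 0L, NA, 1L)
  )
  events <- data.frame(
    subject_id = c("A", "B", "C", "D", "E"),
    # B: event between diagnosis and first specimen (before the first specimen,
    #    after any DDD imputed in 2013); E: event strictly before its DDD
    event_weeks = c(100, -10, 50, 30, -2),
    event_indicator = c(1L, 1L, 0L, 0L, 1L)
  )
  list(measurements = meas, subjects = subjects, events = events)
}

# Small survival fixture with ties and interleaved censoring (hand-checked).
km_fixture <- function() {
  data.frame(
    time = c(2, 2, 2, 4, 5, 6, 6, 6, 8, 9),
    event = c(1, 1, 0, 1, 0, 1, 1, 0, 0, 1)
  )
}

# Default-condition synthetic cohort, memoised so several tests can share it.
default_cohort_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 2000L, gen_seed = 7L, ddd_seed = 3L) {
    key <- sprintf("c_%d_%d_%d", n, gen_seed, ddd_seed)
    if (is.null(cache[[key]])) {
      tb <- generate_cohort(default_registry_config(n_subjects = n, seed = gen_seed))
      cache[[key]] <- list(tables = tb, cohort = build_cohort(tb, rng_seed = ddd_seed))
    }
    cache[[key]]
  }
})
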