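#' Specification of one true latent trajectory class
#'
#' Describes a latent class of the synthetic registry: its population share,
#' mean HbA1c curve on the generating basis, within-subject measurement
#' scatter, constant weekly hazard of first hospitalization for heart failure
#' (HHF), and baseline covariate distributions.
#'
#' @param label 1-based class index.
#' @param proportion fraction of the cohort in this class, in (0, 1).
#' @param curve_coefficients coefficients of the class mean curve on the
#'   generating basis (HbA1c % per basis term; first entry is the intercept,
#'   i.e. mean HbA1c at diagnosis).
#' @param residual_sd within-subject measurement SD (HbA1c %), > 0 (0 allowed
#'   for noiseless checks).
#' @param event_rate constant hazard of HHF per week, >= 0.
#' @param age_mean,age_sd age at diagnosis distribution (years).
#' @param ethnicity_probs length-4 probability vector
#'   (Chinese, Malay, Indian, Other), summing to 1.
#' @param male_prob probability of male sex.
#' @param prior_complication_probs named numeric vector of per-complication
#'   prevalences at baseline (fractions).
#' @return object of class `true_class_spec`.
#' @export
true_class_spec <- function(label, proportion, curve_coefficients, residual_sd,
                            event_rate, age_mean, age_sd,
                            ethnicity_probs, male_prob,
                            prior_complication_probs) {
  chk <- function(ok, field) {
    if (!ok) ht_stop(sprintf("true_class_spec: invalid field '%s'", field),
                     "hba1ctraj_config_error")
  }
  chk(is.numeric(proportion) && proportion > 0 && proportion < 1, "proportion")
  chk(is.numeric(residual_sd) && residual_sd >= 0, "residual_sd")
  chk(is.numeric(event_rate) && event_rate >= 0, "event_rate")
  chk(is.numeric(age_sd) && age_sd > 0, "age_sd")
  chk(length(ethnicity_probs) == 4 && abs(sum(ethnicity_probs) - 1) < 1e-9 &&
        all(ethnicity_probs >= 0), "ethnicity_probs")
  chk(is.numeric(male_prob) && male_prob >= 0 && male_prob <= 1, "male_prob")
  chk(all(prior_complication_probs >= 0 & prior_complication_probs <= 1) &&
        !is.null(names(prior_complication_probs)), "prior_complication_probs")
  structure(
    list(label = as.integer(label), proportion = proportion,
         curve_coefficients = curve_coefficients, residual_sd = residual_sd,
         event_rate = event_rate, age_mean = age_mean, age_sd = age_sd,
         ethnicity_probs = ethnicity_probs, male_prob = male_prob,
         prior_complication_probs = prior_complication_probs),
    class = "true_class_spec"
  )
}

#' Configuration of the synthetic registry generator
#'
#' @param n_subjects number of subjects to generate.
#' @param class_specs list of [true_class_spec()]; proportions must sum to 1
#'   (within 1e-9; see [default_registry_config()] for rescaling of printed
#'   rounded shares).
#' @param generating_shape time-link shape of the generating curves.
#' @param visits_mean,visits_sd HbA1c measurement count distribution.
#' @param followup_mean_weeks,followup_sd_weeks follow-up length distribution
#'   (weeks).
#' @param ddd_mismatch_fraction fraction of subjects whose first specimen
#'   falls in the calendar year after their diagnosis year (their diagnosis
#'   date will require random imputation downstream).
#' @param admin_censor_weeks administrative censoring horizon (weeks from
#'   diagnosis).
#' @param seed integer seed; generation is fully deterministic given it.
#' @param missing_complication_fraction fraction of subjects with all
#'   prior-complication flags missing (recorded as NA).
#' @param covariate_log_hr optional named list of log hazard-ratio effects
#'   applied on top of the class hazard (supported names:
#'   `age_per_year`, `male`, and any `prior_*` flag); default `NULL` means the
#'   event hazard depends on the latent class only, keeping recovery
#'   experiments interpretable.
#' @param diagnosis_years calendar years diagnoses are drawn from.
#' @param eligibility_floor_prob probability a subject's visit count and
#'   follow-up are floored (>= 5 visits, >= 160 weeks) so that the downstream
#'   eligibility filter keeps ~90-95% of subjects but is not vacuous.
#' @param time_scale,exp_timescale_weeks passed to [basis_spec()] for the
#'   generating curves.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects, class_specs,
                             generating_shape = "logarithmic",
                             visits_mean = 15, visits_sd = 5.5,
                             followup_mean_weeks = 245, followup_sd_weeks = 68,
                             ddd_mismatch_fraction = 0.19,
                             admin_censor_weeks = 364,
                             seed = 1L,
                             missing_complication_fraction = 0.13,
                             covariate_log_hr = NULL,
                             diagnosis_years = 2013:2016,
                             eligibility_floor_prob = 0.95,
                             time_scale = 100, exp_timescale_weeks = 26) {
  bad <- function(field) ht_stop(
    sprintf("generator_config: invalid field '%s'", field), "hba1ctraj_config_error")
  if (!is.numeric(n_subjects) || n_subjects < 1) bad("n_subjects")
  if (!length(class_specs) || !all(vapply(class_specs, inherits, TRUE, "true_class_spec"))) {
    bad("class_specs")
  }
  props <- vapply(class_specs, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-9) bad("class_specs (proportions must sum to 1)")
  if (!is.numeric(visits_mean) || visits_mean < 5) bad("visits_mean")
  if (ddd_mismatch_fraction < 0 || ddd_mismatch_fraction > 1) bad("ddd_mismatch_fraction")
  if (missing_complication_fraction < 0 || missing_complication_fraction > 1) {
    bad("missing_complication_fraction")
  }
  if (!is.numeric(admin_censor_weeks) || admin_censor_weeks <= 0) bad("admin_censor_weeks")
  basis <- basis_spec(generating_shape, time_scale = time_scale,
                      exp_timescale_weeks = exp_timescale_weeks)
  d <- basis_dim(basis)
  for (cs in class_specs) {
    if (length(cs$curve_coefficients) != d) {
      bad(sprintf("class_specs (class %d curve_coefficients: expected %d terms for %s shape)",
                  cs$label, d, generating_shape))
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), class_specs = class_specs,
         generating_shape = generating_shape,
         visits_mean = visits_mean, visits_sd = visits_sd,
         followup_mean_weeks = followup_mean_weeks,
         followup_sd_weeks = followup_sd_weeks,
         ddd_mismatch_fraction = ddd_mismatch_fraction,
         admin_censor_weeks = admin_censor_weeks,
         seed = as.integer(seed),
         missing_complication_fraction = missing_complication_fraction,
         covariate_log_hr = covariate_log_hr,
         diagnosis_years = as.integer(diagnosis_years),
         eligibility_floor_prob = eligibility_floor_prob,
         time_scale = time_scale, exp_timescale_weeks = exp_timescale_weeks),
    class = "generator_config"
  )
}

#' Default five-class registry configuration
#'
#' Returns the study conditions the generator emulates: five latent HbA1c
#' trajectory classes with population shares 35.5/41.1/3.4/10.7/9.2% (printed
#' rounded shares rescaled to sum to 1), logarithmic mean curves anchored at
#' baseline HbA1c 6.23/7.16/10.6/7.69/8.73%, class-wise constant HHF hazards
#' calibrated so cumulative incidence over each class's mean follow-up equals
#' 1.43/1.05/3.37/2.89/3.55%, ~15 HbA1c measurements over ~245 weeks of
#' follow-up, and a 19% diagnosis-year / first-specimen-year mismatch rate.
#'
#' Log-time slopes are free parameters of the generator (the emulated registry
#' reports only baseline means): Classes 1-2 are near-flat ("low stable",
#' "moderate low stable"), Class 3 declines from the highest baseline, Class 4
#' declines steeply and crosses the stable Class 2 curve within the first
#' weeks, Class 5 declines moderately.
#'
#' @param n_subjects cohort size (the emulated registry has 17,389 subjects;
#'   smaller synthetic cohorts keep experiments fast).
#' @param seed generator seed.
#' @param residual_sd common within-subject measurement SD (HbA1c %).
#' @return a [generator_config()].
#' @examples
#' cfg <- default_registry_config(n_subjects = 200)
#' cfg$class_specs[[3]]$proportion   # ~0.034
#' @export
default_registry_config <- function(n_subjects = 17389, seed = 1L, residual_sd = 0.55) {
  shares <- c(0.355, 0.411, 0.034, 0.107, 0.092)
  props <- shares / sum(shares)
  intercepts <- c(6.23, 7.16, 10.6, 7.69, 8.73)
  slopes <- c(-0.02, -0.01, -0.30, -0.20, -0.22)   # per log(weeks + 1)
  cum_hhf <- c(0.0143, 0.0105, 0.0337, 0.0289, 0.0355)
  mean_fu <- c(239.9, 252.5, 244.6, 233.9, 252.8)
  rates <- -log(1 - cum_hhf) / mean_fu
  age_mean <- c(61.6, 57.8, 49.2, 55.4, 53.2)
  age_sd <- c(10.9, 10.7, 11.7, 10.5, 12.1)
  male <- c(0.490, 0.517, 0.542, 0.576, 0.535)
  eth <- list(
    c(0.770, 0.137, 0.061, 0.032),
    c(0.714, 0.162, 0.087, 0.037),
    c(0.417, 0.341, 0.168, 0.074),
    c(0.641, 0.226, 0.096, 0.037),
    c(0.524, 0.275, 0.133, 0.068)
  )
  prior <- list(
    c(cvd = 0.1610, ihd = 0.0961, pad = 0.0037, hstroke = 0.0057, istroke = 0.0520,
      tia = 0.0134, af = 0.0138, neuropathy = 0.0034, dpa = 0.00292, hf = 0.00437),
    c(cvd = 0.1336, ihd = 0.0824, pad = 0.0032, hstroke = 0.0035, istroke = 0.0327,
      tia = 0.0089, af = 0.0099, neuropathy = 0.00364, dpa = 0.00238, hf = 0.00504),
    c(cvd = 0.0774, ihd = 0.0505, pad = 0.0084, hstroke = 0.0000, istroke = 0.0101,
      tia = 0.0067, af = 0.0051, neuropathy = 0.0135, dpa = 0.0135, hf = 0.00673),
    c(cvd = 0.1005, ihd = 0.0594, pad = 0.00695, hstroke = 0.00268, istroke = 0.0268,
      tia = 0.0043, af = 0.0107, neuropathy = 0.0102, dpa = 0.0150, hf = 0.0059),
    c(cvd = 0.1196, ihd = 0.0803, pad = 0.0031, hstroke = 0.0044, istroke = 0.0199,
      tia = 0.0081, af = 0.00934, neuropathy = 0.00498, dpa = 0.0056, hf = 0.0118)
  )
  specs <- lapply(1:5, function(k) {
    true_class_spec(
      label = k, proportion = props[k],
      curve_coefficients = c(intercepts[k], slopes[k]),
      residual_sd = residual_sd, event_rate = rates[k],
      age_mean = age_mean[k], age_sd = age_sd[k],
      ethnicity_probs = eth[[k]] / sum(eth[[k]]),
      male_prob = male[k],
      prior_complication_probs = prior[[k]]
    )
  })
  generator_config(n_subjects = n_subjects, class_specs = specs, seed = seed)
}

ETHNICITY_LEVELS <- c("chinese", "malay", "indian", "other")
PRIOR_FLAGS <- c("cvd", "ihd", "pad", "hstroke", "istroke",
                 "tia", "af", "neuropathy", "dpa", "hf")

#' Generate a synthetic registry
#'
#' Draws a cohort from a [generator_config()]: one latent class per subject,
#' an irregular visit schedule (a mandatory baseline visit plus uniformly
#' scattered visits over follow-up), HbA1c values on the class mean curve plus
#' Gaussian noise, class-dependent exponential HHF event times censored at the
#' earlier of follow-up end and the administrative horizon, and baseline
#' covariates drawn from the class-wise distributions. A configurable fraction
#' of subjects has its whole visit schedule delayed so the first specimen
#' falls in the calendar year after diagnosis (these subjects need diagnosis-
#' date imputation downstream).
#'
#' @param config a [generator_config()].
#' @return object of class `registry_tables`: a list with data frames
#'   `measurements` (subject_id, specimen_date, hba1c_pct), `subjects`
#'   (demographics, prior-complication flags and the oracle-only `true_class`
#'   column, which pipeline stages must never read), and `events`
#'   (subject_id, event_weeks relative to the first specimen date,
#'   event_indicator). Deterministic given `config$seed`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    ht_stop("generate_cohort: config must be a generator_config", "hba1ctraj_config_error")
  }
  set.seed(config$seed)
  n <- config$n_subjects
  K <- length(config$class_specs)
  props <- vapply(config$class_specs, `[[`, 0, "proportion")
  basis <- basis_spec(config$generating_shape, time_scale = config$time_scale,
                      exp_timescale_weeks = config$exp_timescale_weeks)

  ids <- sprintf("S%06d", seq_len(n))
  z <- sample.int(K, n, replace = TRUE, prob = props)
  diagnosis_year <- sample(config$diagnosis_years, n, replace = TRUE)
  ddd_true <- as.Date(sprintf("%d-01-01", diagnosis_year)) +
    sample.int(365, n, replace = TRUE) - 1L

  followup <- rnorm(n, config$followup_mean_weeks, config$followup_sd_weeks)
  visits <- round(rnorm(n, config$visits_mean, config$visits_sd))
  floored <- runif(n) < config$eligibility_floor_prob
  followup <- ifelse(floored, pmax(followup, 160), pmax(followup, 26))
  visits <- as.integer(ifelse(floored, pmax(visits, 5L), pmax(visits, 2L)))

  mismatch <- runif(n) < config$ddd_mismatch_fraction
  # delay (weeks) from true diagnosis date to the first specimen: 0 unless the
  # first specimen is pushed to a uniform date in the following calendar year
  next_jan1 <- as.Date(sprintf("%d-01-01", diagnosis_year + 1L))
  delayed_first <- next_jan1 + sample.int(365, n, replace = TRUE) - 1L
  delay_weeks <- ifelse(mismatch, as.numeric(delayed_first - ddd_true) / 7, 0)

  missing_prior <- runif(n) < config$missing_complication_fraction

  # covariates
  age <- numeric(n); sex <- character(n); ethnicity <- character(n)
  prior <- matrix(NA_integer_, n, length(PRIOR_FLAGS),
                  dimnames = list(NULL, paste0("prior_", PRIOR_FLAGS)))
  for (k in seq_len(K)) {
    cs <- config$class_specs[[k]]
    idx <- which(z == k); nk <- length(idx)
    if (!nk) next
    age[idx] <- rnorm(nk, cs$age_mean, cs$age_sd)
    sex[idx] <- ifelse(runif(nk) < cs$male_prob, "male", "female")
    ethnicity[idx] <- ETHNICITY_LEVELS[
      sample.int(4L, nk, replace = TRUE, prob = cs$ethnicity_probs)]
    for (f in PRIOR_FLAGS) {
      p <- unname(cs$prior_complication_probs[f])
      if (is.na(p)) p <- 0
      prior[idx, paste0("prior_", f)] <- as.integer(runif(nk) < p)
    }
  }
  prior[missing_prior, ] <- NA_integer_

  # visit schedules and HbA1c values
  meas <- vector("list", n)
  event_weeks <- numeric(n); event_ind <- integer(n)
  rates <- vapply(config$class_specs, `[[`, 0, "event_rate")
  loghr <- config$covariate_log_hr
  for (i in seq_len(n)) {
    cs <- config$class_specs[[z[i]]]
    v <- visits[i]
    # floored subjects observe the full follow-up (last visit at its end), so
    # the >=5 samples / >=3 years eligibility filter keeps them by design
    t_obs <- if (floored[i]) {
      delay_weeks[i] + c(0, sort(runif(v - 2L, 0, followup[i])), followup[i])
    } else {
      delay_weeks[i] + c(0, sort(runif(v - 1L, 0, followup[i])))
    }
    t_obs <- round(t_obs * 7) / 7   # visits live on the calendar-day grid
    mu <- drop(basis_matrix(t_obs, basis) %*% cs$curve_coefficients)
    y <- mu + rnorm(v, 0, cs$residual_sd)
    dates <- ddd_true[i] + round(t_obs * 7)
    meas[[i]] <- data.frame(subject_id = ids[i],
                            specimen_date = dates,
                            hba1c_pct = round(y, 3))
    rate <- rates[z[i]]
    if (!is.null(loghr)) {
      lp <- 0
      if (!is.null(loghr$age_per_year)) lp <- lp + loghr$age_per_year * (age[i] - 57)
      if (!is.null(loghr$male)) lp <- lp + loghr$male * (sex[i] == "male")
      for (f in names(loghr)) {
        if (startsWith(f, "prior_") && !is.na(prior[i, f])) {
          lp <- lp + loghr[[f]] * prior[i, f]
        }
      }
      rate <- rate * exp(lp)
    }
    t_event <- if (rate > 0) rexp(1, rate) else Inf
    t_cens <- min(delay_weeks[i] + followup[i], config$admin_censor_weeks)
    if (t_event <= t_cens) {
      event_weeks[i] <- t_event; event_ind[i] <- 1L
    } else {
      event_weeks[i] <- t_cens; event_ind[i] <- 0L
    }
  }

  measurements <- do.call(rbind, meas)
  measurements$specimen_date <- as.Date(measurements$specimen_date,
                                        origin = "1970-01-01")
  subjects <- data.frame(
    subject_id = ids,
    diagnosis_year = diagnosis_year,
    sex = sex,
    ethnicity = ethnicity,
    age_at_diagnosis = round(age, 1),
    stringsAsFactors = FALSE
  )
  subjects <- cbind(subjects, as.data.frame(prior))
  subjects$true_class <- z   # oracle-only: never read by pipeline stages

  # event_weeks in the emitted table is measured from the first specimen date
  first_spec <- vapply(meas, function(m) min(as.numeric(m$specimen_date)), 0)
  spec_offset_weeks <- (first_spec - as.numeric(ddd_true)) / 7
  events <- data.frame(
    subject_id = ids,
    event_weeks = round(event_weeks - spec_offset_weeks, 4),
    event_indicator = event_ind
  )

  structure(
    list(measurements = measurements, subjects = subjects, events = events,
         config = config),
    class = "registry_tables"
  )
}

#' Write / read registry tables as CSV
#'
#' @param tables a `registry_tables` object (or any list with the three data
#'   frames).
#' @param dir output directory; created if needed.
#' @return `write_registry` returns `dir` invisibly; `read_registry` returns a
#'   `registry_tables` list.
#' @export
write_registry <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  m <- utils::read.csv(file.path(dir, "measurements.csv"), stringsAsFactors = FALSE)
  m$specimen_date <- as.Date(m$specimen_date)
  s <- utils::read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  e <- utils::read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  structure(list(measurements = m, subjects = s, events = e),
            class = "registry_tables")
}

#' Serialize a generator configuration to JSON
#' @param config a [generator_config()].
#' @param path optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
generator_config_to_json <- function(config, path = NULL) {
  x <- unclass(config)
  x$class_specs <- lapply(x$class_specs, function(cs) {
    cs <- unclass(cs)
    cs$prior_complication_probs <- as.list(cs$prior_complication_probs)
    cs
  })
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname generator_config_to_json
#' @param json JSON string or path to a JSON file.
#' @export
generator_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(x$class_specs)), function(i) {
    row <- lapply(x$class_specs, function(col) {
      if (is.data.frame(col)) unlist(col[i, ]) else if (is.list(col)) col[[i]] else col[i]
    })
    true_class_spec(
      label = row$label, proportion = row$proportion,
      curve_coefficients = unlist(row$curve_coefficients),
      residual_sd = row$residual_sd, event_rate = row$event_rate,
      age_mean = row$age_mean, age_sd = row$age_sd,
      ethnicity_probs = unlist(row$ethnicity_probs), male_prob = row$male_prob,
      prior_complication_probs = unlist(row$prior_complication_probs)
    )
  })
  generator_config(
    n_subjects = x$n_subjects, class_specs = specs,
    generating_shape = x$generating_shape,
    visits_mean = x$visits_mean, visits_sd = x$visits_sd,
    followup_mean_weeks = x$followup_mean_weeks,
    followup_sd_weeks = x$followup_sd_weeks,
    ddd_mismatch_fraction = x$ddd_mismatch_fraction,
    admin_censor_weeks = x$admin_censor_weeks, seed = x$seed,
    missing_complication_fraction = x$missing_complication_fraction,
    covariate_log_hr = x$covariate_log_hr,
    diagnosis_years = x$diagnosis_years,
    eligibility_floor_prob = x$eligibility_floor_prob,
    time_scale = x$time_scale, exp_timescale_weeks = x$exp_timescale_weeks
  )
}
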