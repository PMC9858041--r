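test_that("invalid generator configurations name the offending field", {
  cfg <- default_registry_config(n_subjects = 10)
  specs <- cfg$class_specs
  expect_error(generator_config(10, specs, visits_mean = 3),
               "visits_mean", class = "hba1ctraj_config_error")
  expect_error(generator_config(10, specs, ddd_mismatch_fraction = 1.5),
               "ddd_mismatch_fraction", class = "hba1ctraj_config_error")
  bad <- specs
  bad[[1]]$proportion <- 0.5
  expect_error(generator_config(10, bad), "proportions",
               class = "hba1ctraj_config_error")
  expect_error(
    true_class_spec(1, 0.5, c(7, 0), residual_sd = -1, event_rate = 0,
                    age_mean = 60, age_sd = 10,
                    ethnicity_probs = c(0.7, 0.1, 0.1, 0.1), male_prob = 0.5,
                    prior_complication_probs = c(hf = 0.01)),
    "residual_sd", class = "hba1ctraj_config_error")
})

test_that("default configuration carries the registry's anchor values", {
  cfg <- default_registry_config(n_subjects = 100)
  props <- vapply(cfg$class_specs, `[[`, 0, "proportion")
  expect_equal(sum(props), 1, tolerance = 1e-12)
  expect_equal(cfg$class_specs[[3]]$proportion, 0.034, tolerance = 2e-3)
  expect_equal(vapply(cfg$class_specs, function(s) s$curve_coefficients[1], 0),
               c(6.23, 7.16, 10.6, 7.69, 8.73))
  # constant hazard inverts to the target cumulative incidence in closed form
  expect_equal(1 - exp(-cfg$class_specs[[1]]$event_rate * 239.9), 0.0143,
               tolerance = 1e-6)
  expect_equal(1 - exp(-cfg$class_specs[[5]]$event_rate * 252.8), 0.0355,
               tolerance = 1e-6)
})

test_that("same seed reproduces byte-identical tables; class draws track proportions", {
  cfg <- default_registry_config(n_subjects = 5000, seed = 31)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1$measurements, t2$measurements)
  expect_identical(t1$subjects, t2$subjects)
  expect_identical(t1$events, t2$events)

  props <- vapply(cfg$class_specs, `[[`, 0, "proportion")
  emp <- tabulate(t1$subjects$true_class, 5) / nrow(t1$subjects)
  expect_true(all(abs(emp - props) < 0.02))
})

test_that("class frequencies are consistent across seeds (MAD < 0.01 at n = 5000)", {
  props <- vapply(default_registry_config(10)$class_specs, `[[`, 0, "proportion")
  devs <- sapply(1:10, function(s) {
    tb <- generate_cohort(default_registry_config(n_subjects = 5000, seed = s))
    emp <- tabulate(tb$subjects$true_class, 5) / nrow(tb$subjects)
    abs(emp - props)
  })
  expect_lt(mean(devs), 0.01)
})

test_that("zero residual SD puts every measurement exactly on the class curve", {
  spec <- true_class_spec(1, 0.999999999, c(8, -0.3), residual_sd = 0,
                          event_rate = 1e-4, age_mean = 55, age_sd = 10,
                          ethnicity_probs = c(0.7, 0.15, 0.1, 0.05),
                          male_prob = 0.5,
                          prior_complication_probs = c(hf = 0.01))
  spec$proportion <- 1
  cfg <- generator_config(50, list(spec), ddd_mismatch_fraction = 0, seed = 4)
  tb <- generate_cohort(cfg)
  first <- tapply(as.numeric(tb$measurements$specimen_date),
                  tb$measurements$subject_id, min)
  w <- (as.numeric(tb$measurements$specimen_date) -
          first[tb$measurements$subject_id]) / 7
  mu <- 8 - 0.3 * log(w + 1)
  # exact up to the 3-decimal formatting of the written values
  expect_lt(max(abs(tb$measurements$hba1c_pct - mu)), 5.01e-4)
})

test_that("residual noise is calibrated within 5% at n = 5000", {
  cfg <- default_registry_config(n_subjects = 5000, seed = 12)
  cfg$ddd_mismatch_fraction <- 0   # first specimen = diagnosis date exactly
  tb <- generate_cohort(cfg)
  m <- tb$measurements
  first <- tapply(as.numeric(m$specimen_date), m$subject_id, min)
  w <- (as.numeric(m$specimen_date) - first[m$subject_id]) / 7
  cls <- tb$subjects$true_class[match(m$subject_id, tb$subjects$subject_id)]
  for (k in 1:5) {
    co <- cfg$class_specs[[k]]$curve_coefficients
    res <- m$hba1c_pct[cls == k] - (co[1] + co[2] * log(w[cls == k] + 1))
    expect_equal(stats::sd(res), 0.55, tolerance = 0.05)
  }
})

test_that("event incidence matches the closed-form exponential calibration", {
  cfg <- default_registry_config(n_subjects = 5000, seed = 17)
  cfg$ddd_mismatch_fraction <- 0
  tb <- generate_cohort(cfg)
  mean_fu <- c(239.9, 252.5, 244.6, 233.9, 252.8)
  for (k in 1:5) {
    idx <- tb$subjects$true_class == k
    ev <- tb$events[match(tb$subjects$subject_id[idx], tb$events$subject_id), ]
    km <- km_curve(ev$event_weeks, ev$event_indicator)
    s_t <- km_survival_at(km, mean_fu[k])
    # Greenwood standard error at the evaluation time
    inc <- km$time <= mean_fu[k]
    se <- s_t * sqrt(sum(km$n_event[inc] /
                           (km$n_risk[inc] * (km$n_risk[inc] - km$n_event[inc]))))
    target <- exp(-cfg$class_specs[[k]]$event_rate * mean_fu[k])
    expect_lt(abs(s_t - target), 3 * se + 1e-12)
  }
})

test_that("diagnosis-year mismatch is injected at the configured rate", {
  tb <- generate_cohort(default_registry_config(n_subjects = 4000, seed = 9))
  first_year <- as.integer(format(
    as.Date(tapply(tb$measurements$specimen_date, tb$measurements$subject_id,
                   min), origin = "1970-01-01"), "%Y"))
  diag_year <- tb$subjects$diagnosis_year[
    match(names(tapply(tb$measurements$specimen_date,
                       tb$measurements$subject_id, min)),
          tb$subjects$subject_id)]
  expect_lt(abs(mean(first_year != diag_year) - 0.19), 0.02)
})

test_that("generator configs survive a JSON round trip", {
  cfg <- default_registry_config(n_subjects = 123, seed = 5)
  js <- generator_config_to_json(cfg)
  cfg2 <- generator_config_from_json(js)
  expect_equal(cfg2$n_subjects, cfg$n_subjects)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(length(cfg2$class_specs), 5L)
  for (k in 1:5) {
    expect_equal(cfg2$class_specs[[k]]$curve_coefficients,
                 cfg$class_specs[[k]]$curve_coefficients)
    expect_equal(cfg2$class_specs[[k]]$proportion, cfg$class_specs[[k]]$proportion)
    expect_equal(unname(cfg2$class_specs[[k]]$prior_complication_probs),
                 unname(cfg$class_specs[[k]]$prior_complication_probs))
  }
  expect_identical(generate_cohort(cfg2)$measurements,
                   generate_cohort(cfg)$measurements)
})

test_that("registry tables round-trip through CSV files", {
  tb <- generate_cohort(default_registry_config(n_subjects = 30, seed = 2))
  dir <- withr::local_tempdir()
  write_registry(tb, dir)
  tb2 <- read_registry(dir)
  expect_equal(tb2$subjects$true_class, tb$subjects$true_class)
  expect_equal(tb2$measurements$hba1c_pct, tb$measurements$hba1c_pct)
  expect_equal(as.Date(tb2$measurements$specimen_date),
               tb$measurements$specimen_date)
  expect_equal(tb2$events$event_weeks, tb$events$event_weeks)
})

test_that("optional covariate effects scale the event hazard", {
  base <- default_registry_config(n_subjects = 3000, seed = 44)
  cfg <- generator_config(3000, base$class_specs, seed = 44,
                          covariate_log_hr = list(age_per_year = 0.2))
  tb0 <- generate_cohort(base)
  tb1 <- generate_cohort(cfg)
  # a strong positive age effect must raise overall incidence among the old
  old1 <- tb1$subjects$age_at_diagnosis > 65
  ev1 <- tb1$events$event_indicator[match(tb1$subjects$subject_id,
                                          tb1$events$subject_id)]
  expect_gt(mean(ev1[old1]), mean(ev1[!old1]))
  expect_gt(mean(ev1), mean(tb0$events$event_indicator))
})
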