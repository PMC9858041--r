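# End-to-end analyses: primary trajectory + association analysis,
# baseline-shift and DDD-seed sensitivity, and split-sample predictive
# validation.

#' Analysis configuration
#'
#' Collects every knob of the end-to-end pipeline. Either `generator` (a
#' [generator_config()] for synthetic runs) or `input_dir` (a directory of
#' registry CSVs) supplies the raw tables.
#'
#' @param generator optional [generator_config()].
#' @param input_dir optional directory with measurements/subjects/events CSVs.
#' @param shape,k fixed time-link shape and class count; when both are given
#'   the model-selection grid is skipped.
#' @param k_max,shapes,min_prop,cv_folds model-selection settings (see
#'   [select_lcga_model()]).
#' @param n_starts,burn_in_iters,tol,max_iters EM settings (see [fit_lcga()]).
#' @param split_fraction training fraction for predictive validation.
#' @param window_width_weeks,n_windows cumulative concordance windows.
#' @param baseline_shift_weeks baseline shift for the sensitivity analysis.
#' @param ddd_seed,lcga_seed,split_seed seeds for the three random stages.
#' @param censor_at see [build_cohort()].
#' @param reference_class `"lowest"` (default: the lowest mean trajectory is
#'   the Cox base class) or an explicit class index.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(generator = NULL, input_dir = NULL,
                            shape = NULL, k = NULL,
                            k_max = 10L,
                            shapes = c("linear", "quadratic", "cubic",
                                       "logarithmic", "exponential"),
                            min_prop = 0.03, cv_folds = 10L,
                            n_starts = 20L, burn_in_iters = 30L,
                            tol = 1e-6, max_iters = 500L,
                            split_fraction = 0.8,
                            window_width_weeks = 50, n_windows = 7L,
                            baseline_shift_weeks = 50,
                            ddd_seed = 1L, lcga_seed = 1L, split_seed = 1L,
                            censor_at = "last_measurement",
                            reference_class = "lowest") {
  if (split_fraction <= 0 || split_fraction >= 1) {
    ht_stop("analysis_config: split_fraction must be in (0, 1)",
            "hba1ctraj_config_error")
  }
  if (window_width_weeks <= 0) {
    ht_stop("analysis_config: window_width_weeks must be > 0",
            "hba1ctraj_config_error")
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Subset a cohort to a set of subjects
#' @param cohort an `hba1c_cohort`.
#' @param ids subject ids to keep.
#' @export
subset_cohort <- function(cohort, ids) {
  cohort$subjects <- cohort$subjects[cohort$subjects$subject_id %in% ids, ,
                                     drop = FALSE]
  cohort$measurements <- cohort$measurements[
    cohort$measurements$subject_id %in% ids, , drop = FALSE]
  cohort$provenance$n_final <- nrow(cohort$subjects)
  cohort
}

#' Match classes between two fits by mean-curve distance
#'
#' Optimal one-to-one assignment (exhaustive over permutations, k <= 8)
#' minimizing the summed squared distance between class mean curves over a
#' common time grid. Used to compare refits (baseline shift, re-seeded DDD,
#' training subsets) whose class labels need not align.
#'
#' @param fit_a,fit_b `lcga_fit`s (or [lcga_params()]) with equal k.
#' @param t_grid evaluation grid in each fit's own time coordinates; `t_grid_b`
#'   defaults to `t_grid`.
#' @param t_grid_b optional separate grid for `fit_b` (e.g. shifted times).
#' @return integer vector `map` with `map[j]` = class of `fit_a` matched to
#'   class `j` of `fit_b`.
#' @export
match_classes <- function(fit_a, fit_b, t_grid = seq(0, 250, by = 10),
                          t_grid_b = NULL) {
  ca <- class_curves(fit_a, t_grid)
  cb <- class_curves(fit_b, t_grid_b %||% t_grid)
  k <- ncol(ca)
  stopifnot(ncol(cb) == k)
  cost <- matrix(0, k, k)  # cost[i, j] = distance between a-class i, b-class j
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cost[i, j] <- mean((ca[, i] - cb[, j])^2)
  }
  perms <- all_permutations(k)
  best <- which.min(apply(perms, 1L, function(p) {
    sum(cost[cbind(p, seq_len(k))])
  }))
  perms[best, ]
}

# ---- Cox design ------------------------------------------------------------

#' Covariate design matrix for the association Cox model
#'
#' Class indicators (base class = `reference_class`), male sex, ethnicity
#' indicators with Chinese as reference, age at diagnosis, prior-complication
#' indicators, and an explicit "missing prior complications" indicator for
#' subjects whose complication flags are all NA (those subjects' flags enter
#' as 0).
#'
#' @param cohort an `hba1c_cohort`.
#' @param class_assign integer class per subject (cohort order), or `NULL` to
#'   omit class indicators.
#' @param k number of classes (needed when `class_assign` is given).
#' @param reference_class base class index.
#' @return list with `time`, `event`, `x` (design matrix), `ids`.
#' @export
cox_design <- function(cohort, class_assign = NULL, k = NULL,
                       reference_class = NULL) {
  s <- cohort$subjects
  cols <- list()
  if (!is.null(class_assign)) {
    stopifnot(length(class_assign) == nrow(s), !is.null(k))
    if (is.null(reference_class)) reference_class <- k
    for (cl in setdiff(seq_len(k), reference_class)) {
      cols[[sprintf("class_%d", cl)]] <- as.numeric(class_assign == cl)
    }
  }
  cols$sex_male <- as.numeric(s$sex == "male")
  for (e in c("malay", "indian", "other")) {
    cols[[paste0("eth_", e)]] <- as.numeric(s$ethnicity == e)
  }
  cols$age_at_diagnosis <- s$age_at_diagnosis
  prior_cols <- grep("^prior_", names(s), value = TRUE)
  missing_prior <- if (length(prior_cols)) {
    apply(is.na(s[, prior_cols, drop = FALSE]), 1L, all)
  } else rep(FALSE, nrow(s))
  cols$prior_missing <- as.numeric(missing_prior)
  for (pc in prior_cols) {
    v <- s[[pc]]
    v[is.na(v)] <- 0
    cols[[pc]] <- as.numeric(v)
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(time = s$event_weeks, event = s$event_indicator, x = x,
       ids = s$subject_id)
}

# ---- primary analysis ------------------------------------------------------

#' Primary trajectory + association analysis
#'
#' Builds the cohort, selects (or fits the fixed) latent class growth model,
#' and quantifies the trajectory-HHF association: Kaplan-Meier curves per
#' class, omnibus and pairwise log-rank tests, and a multivariate Cox model
#' with class indicators plus demographics and prior complications.
#'
#' @param config an [analysis_config()].
#' @param tables optional pre-generated `registry_tables` (overrides the
#'   config's generator / input_dir).
#' @return object of class `hba1c_analysis_report`: `cohort`, `selection`
#'   (NULL when shape/k fixed), `fit`, `km_by_class`, `logrank_omnibus`,
#'   `logrank_pairwise`, `cox`, `cox_table`, `reference_class`, `log` (stage
#'   seeds and counts).
#' @export
run_primary_analysis <- function(config, tables = NULL) {
  t0 <- Sys.time()
  if (is.null(tables)) {
    tables <- if (!is.null(config$generator)) {
      generate_cohort(config$generator)
    } else if (!is.null(config$input_dir)) {
      read_registry(config$input_dir)
    } else {
      ht_stop("run_primary_analysis: no generator or input_dir in config",
              "hba1ctraj_config_error")
    }
  }
  cohort <- build_cohort(tables, rng_seed = config$ddd_seed,
                         censor_at = config$censor_at)

  selection <- NULL
  if (!is.null(config$shape) && !is.null(config$k)) {
    fit <- fit_lcga(cohort, basis_spec(config$shape), config$k,
                    n_starts = config$n_starts,
                    burn_in_iters = config$burn_in_iters,
                    tol = config$tol, max_iters = config$max_iters,
                    seed = config$lcga_seed)
  } else {
    selection <- select_lcga_model(
      cohort, k_max = config$k_max, shapes = config$shapes,
      min_prop = config$min_prop, cv_folds = config$cv_folds,
      n_starts = config$n_starts, burn_in_iters = config$burn_in_iters,
      tol = config$tol, max_iters = config$max_iters, seed = config$lcga_seed)
    fit <- selection$chosen_fit
  }
  k <- fit$params$k
  ref <- if (identical(config$reference_class, "lowest")) k
         else as.integer(config$reference_class)

  s <- cohort$subjects
  km_by_class <- lapply(seq_len(k), function(cl) {
    idx <- fit$modal_class == cl
    if (!any(idx)) return(NULL)
    km_curve(s$event_weeks[idx], s$event_indicator[idx])
  })
  names(km_by_class) <- paste0("class_", seq_len(k))

  lr_omnibus <- tryCatch(
    logrank_test(s$event_weeks, s$event_indicator, fit$modal_class),
    hba1ctraj_config_error = function(e) NULL)
  pairs <- utils::combn(seq_len(k), 2L)
  lr_pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    idx <- fit$modal_class %in% c(a, b)
    lr <- tryCatch(
      logrank_test(s$event_weeks[idx], s$event_indicator[idx],
                   fit$modal_class[idx]),
      hba1ctraj_config_error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    # observed/expected hazard-ratio approximation for the pair
    oe <- (lr$observed + 1e-12) / (lr$expected + 1e-12)
    data.frame(class_a = a, class_b = b, statistic = lr$statistic,
               p_value = lr$p_value, hr_oe = oe[1] / oe[2])
  }))

  design <- cox_design(cohort, class_assign = fit$modal_class, k = k,
                       reference_class = ref)
  cox <- cox_fit(design$time, design$event, design$x)
  cox_table <- data.frame(
    term = names(cox$coef), hazard_ratio = unname(cox$hr),
    ci_lower = unname(cox$ci95[, "lower"]), ci_upper = unname(cox$ci95[, "upper"]),
    p_value = unname(cox$wald_p)
  )

  structure(list(
    cohort = cohort, selection = selection, fit = fit,
    km_by_class = km_by_class, logrank_omnibus = lr_omnibus,
    logrank_pairwise = lr_pairwise, cox = cox, cox_table = cox_table,
    reference_class = ref,
    log = list(ddd_seed = config$ddd_seed, lcga_seed = config$lcga_seed,
               n_raw = cohort$provenance$n_raw,
               n_final = cohort$provenance$n_final,
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), class = "hba1c_analysis_report")
}

#' @export
print.hba1c_analysis_report <- function(x, ...) {
  cat(sprintf("<hba1c_analysis_report> n = %d subjects, %s basis, k = %d\n",
              x$cohort$provenance$n_final, x$fit$basis$shape, x$fit$params$k))
  if (!is.null(x$selection)) cat(" ", x$selection$rationale, "\n")
  if (!is.null(x$logrank_omnibus)) {
    cat(sprintf("  omnibus log-rank: chi2 = %.2f (df %d), p = %.3g\n",
                x$logrank_omnibus$statistic, x$logrank_omnibus$df,
                x$logrank_omnibus$p_value))
  }
  cat(sprintf("  Cox concordance: %.3f\n", x$cox$concordance))
  invisible(x)
}

# ---- baseline-shift sensitivity --------------------------------------------

#' Baseline-shift sensitivity analysis
#'
#' Drops measurements before `shift_weeks`, re-zeros time to the new baseline,
#' refits the same (shape, k) model on the shifted cohort, matches new classes
#' to the original ones by mean-curve distance (the shifted curve at t is
#' compared with the original curve at t + shift), and tabulates
#' original-class x new-class membership flows. A Cox model then compares HHF
#' risk of subjects newly grouped into the target class against subjects
#' originally in it (time measured from the DDD in both arms), adjusted for
#' demographics and prior complications.
#'
#' @param cohort an `hba1c_cohort`.
#' @param fit the original `lcga_fit`.
#' @param shift_weeks new baseline, weeks after the DDD.
#' @param config an [analysis_config()] (EM settings reused for the refit).
#' @param target_class original-class index whose inflow is analysed; default
#'   picks the new class receiving the largest inflow from other classes.
#' @return list: `retention_matrix` (original x new, counts),
#'   `retention_fraction` (per original class), `excluded_n` (subjects with
#'   < 2 measurements after the shift), `class_map`, `target_class`,
#'   `cox_regrouped` (adjusted), `logrank_regrouped` (unadjusted),
#'   `shifted_fit`.
#' @export
baseline_shift_analysis <- function(cohort, fit, shift_weeks = 50,
                                    config = analysis_config(),
                                    target_class = NULL) {
  k <- fit$params$k
  m <- cohort$measurements
  if (shift_weeks > 0) {
    m <- m[m$weeks >= shift_weeks, , drop = FALSE]
    m$weeks <- m$weeks - shift_weeks
  }
  counts <- table(m$subject_id)
  keep_ids <- names(counts)[counts >= 2L]
  excluded_n <- nrow(cohort$subjects) - length(keep_ids)
  m <- m[m$subject_id %in% keep_ids, , drop = FALSE]

  refit <- fit_lcga(m, fit$basis, k, n_starts = config$n_starts,
                    burn_in_iters = config$burn_in_iters, tol = config$tol,
                    max_iters = config$max_iters, seed = config$lcga_seed)

  grid_new <- seq(0, max(m$weeks), length.out = 26)
  map <- match_classes(fit, refit, t_grid = grid_new + shift_weeks,
                       t_grid_b = grid_new)  # map[j]: original class for new j

  orig <- fit$modal_class[match(refit$subject_ids, fit$subject_ids)]
  new_in_orig_labels <- map[refit$modal_class]
  retention_matrix <- matrix(0L, k, k,
                             dimnames = list(original = paste0("class_", seq_len(k)),
                                             new = paste0("class_", seq_len(k))))
  for (i in seq_along(orig)) {
    retention_matrix[orig[i], new_in_orig_labels[i]] <-
      retention_matrix[orig[i], new_in_orig_labels[i]] + 1L
  }
  retention_fraction <- diag(retention_matrix) / pmax(rowSums(retention_matrix), 1L)

  if (is.null(target_class)) {
    inflow <- retention_matrix
    diag(inflow) <- 0L
    target_class <- unname(which.max(colSums(inflow)))
  }
  in_orig <- orig == target_class
  regrouped <- new_in_orig_labels == target_class & orig != target_class
  sel <- in_orig | regrouped
  cox_regrouped <- NULL; lr <- NULL
  sub <- subset_cohort(cohort, refit$subject_ids[sel])
  ord <- match(sub$subjects$subject_id, refit$subject_ids)
  flag <- as.numeric(regrouped[ord])
  if (sum(sub$subjects$event_indicator) >= 2 && length(unique(flag)) == 2L) {
    base <- cox_design(sub)
    x <- cbind(regrouped = flag, base$x)
    cox_regrouped <- tryCatch(
      suppressWarnings(cox_fit(base$time, base$event, x)),
      hba1ctraj_error = function(e) NULL)
    lr <- tryCatch(
      logrank_test(base$time, base$event, flag),
      hba1ctraj_config_error = function(e) NULL)
  }

  list(retention_matrix = retention_matrix,
       retention_fraction = retention_fraction,
       excluded_n = excluded_n, class_map = map,
       target_class = target_class,
       n_regrouped = sum(regrouped), n_original = sum(in_orig),
       cox_regrouped = cox_regrouped, logrank_regrouped = lr,
       shifted_fit = refit)
}

# ---- DDD seed sensitivity --------------------------------------------------

#' Diagnosis-date re-seeding sensitivity analysis
#'
#' Rebuilds the cohort under two different DDD-imputation seeds, refits the
#' fixed (shape, k) model under identical settings, matches classes by
#' mean-curve distance, and reports the fraction of common subjects keeping
#' their (matched) modal class plus a per-class log-rank comparing the
#' survival composition of each class across the two baselines.
#'
#' @param tables raw `registry_tables`.
#' @param config an [analysis_config()] with fixed `shape` and `k`.
#' @param seed_a,seed_b the two imputation seeds.
#' @return list: `retention` (fraction), `n_common`, `per_class_logrank`
#'   (data frame), `fit_a`, `fit_b`, `class_map`.
#' @export
seed_sensitivity_analysis <- function(tables, config, seed_a, seed_b) {
  if (is.null(config$shape) || is.null(config$k)) {
    ht_stop("seed_sensitivity_analysis: config must fix shape and k",
            "hba1ctraj_config_error")
  }
  fit_one <- function(seed) {
    cohort <- build_cohort(tables, rng_seed = seed, censor_at = config$censor_at)
    fit <- fit_lcga(cohort, basis_spec(config$shape), config$k,
                    n_starts = config$n_starts,
                    burn_in_iters = config$burn_in_iters,
                    tol = config$tol, max_iters = config$max_iters,
                    seed = config$lcga_seed)
    list(cohort = cohort, fit = fit)
  }
  a <- fit_one(seed_a)
  b <- fit_one(seed_b)
  map <- match_classes(a$fit, b$fit)
  common <- intersect(a$fit$subject_ids, b$fit$subject_ids)
  cls_a <- a$fit$modal_class[match(common, a$fit$subject_ids)]
  cls_b <- map[b$fit$modal_class[match(common, b$fit$subject_ids)]]
  retention <- mean(cls_a == cls_b)

  k <- config$k
  per_class <- do.call(rbind, lapply(seq_len(k), function(cl) {
    ids_a <- a$fit$subject_ids[a$fit$modal_class == cl]
    ids_b <- b$fit$subject_ids[map[b$fit$modal_class] == cl]
    sa <- a$cohort$subjects[a$cohort$subjects$subject_id %in% ids_a, ]
    sb <- b$cohort$subjects[b$cohort$subjects$subject_id %in% ids_b, ]
    time <- c(sa$event_weeks, sb$event_weeks)
    event <- c(sa$event_indicator, sb$event_indicator)
    grp <- rep(c("a", "b"), c(nrow(sa), nrow(sb)))
    identical_groups <- nrow(sa) == nrow(sb) &&
      isTRUE(all.equal(sort(paste(sa$event_weeks, sa$event_indicator)),
                       sort(paste(sb$event_weeks, sb$event_indicator))))
    if (identical_groups) {
      return(data.frame(class = cl, statistic = 0, p_value = 1,
                        n_a = nrow(sa), n_b = nrow(sb)))
    }
    lr <- tryCatch(logrank_test(time, event, grp),
                   hba1ctraj_config_error = function(e) NULL)
    data.frame(class = cl,
               statistic = if (is.null(lr)) NA_real_ else lr$statistic,
               p_value = if (is.null(lr)) NA_real_ else lr$p_value,
               n_a = nrow(sa), n_b = nrow(sb))
  }))

  list(retention = retention, n_common = length(common),
       per_class_logrank = per_class, fit_a = a$fit, fit_b = b$fit,
       class_map = map)
}

# ---- predictive validation -------------------------------------------------

#' Split-sample predictive validation
#'
#' Splits subjects into training and validation sets, fits the latent class
#' model and the multivariate Cox model on training data only, then (i)
#' reports the fraction of validation subjects whose posterior-predicted
#' class (full trajectories, frozen training parameters) matches their class
#' under a full-data fit, and (ii) computes Harrell's concordance of the
#' training Cox risk score on the validation set when trajectories are
#' restricted to cumulative windows of increasing length — only the class
#' assignment is recomputed per window; the Cox fit stays fixed. A Cox model
#' without class covariates provides the reference concordance.
#'
#' Validation subjects with no measurement inside the first window are
#' excluded once (a baseline must exist at time 0 of every window).
#'
#' @param cohort an `hba1c_cohort`.
#' @param config an [analysis_config()] with fixed `shape` and `k`.
#' @param full_fit optional pre-computed full-data `lcga_fit` (refit when
#'   omitted).
#' @return list: `retention`, `windows` (data frame `week`, `concordance`,
#'   `n_events`), `concordance_no_class`, `concordance_full_trajectory`,
#'   `cox_train`, `cox_noclass`, `train_fit`, `n_train`, `n_valid`,
#'   `excluded_n`.
#' @export
predictive_validation <- function(cohort, config, full_fit = NULL) {
  if (is.null(config$shape) || is.null(config$k)) {
    ht_stop("predictive_validation: config must fix shape and k",
            "hba1ctraj_config_error")
  }
  basis <- basis_spec(config$shape)
  k <- config$k
  ids <- cohort$subjects$subject_id
  set.seed(config$split_seed)
  train_ids <- sample(ids, round(config$split_fraction * length(ids)))
  valid_ids <- setdiff(ids, train_ids)

  if (is.null(full_fit)) {
    full_fit <- fit_lcga(cohort, basis, k, n_starts = config$n_starts,
                         burn_in_iters = config$burn_in_iters,
                         tol = config$tol, max_iters = config$max_iters,
                         seed = config$lcga_seed)
  }
  train_cohort <- subset_cohort(cohort, train_ids)
  valid_cohort <- subset_cohort(cohort, valid_ids)
  train_fit <- fit_lcga(train_cohort, basis, k, n_starts = config$n_starts,
                        burn_in_iters = config$burn_in_iters,
                        tol = config$tol, max_iters = config$max_iters,
                        seed = config$lcga_seed)
  map <- match_classes(full_fit, train_fit)   # map[j]: full class for train j

  pred_full <- posterior_predict_lcga(valid_cohort, train_fit$params)
  full_cls <- full_fit$modal_class[match(names(pred_full$modal_class),
                                         full_fit$subject_ids)]
  retention <- mean(map[pred_full$modal_class] == full_cls)

  ref <- if (identical(config$reference_class, "lowest")) k
         else as.integer(config$reference_class)
  dtr <- cox_design(train_cohort, class_assign = train_fit$modal_class, k = k,
                    reference_class = ref)
  cox_train <- suppressWarnings(cox_fit(dtr$time, dtr$event, dtr$x))
  dtr0 <- cox_design(train_cohort)
  cox_noclass <- suppressWarnings(cox_fit(dtr0$time, dtr0$event, dtr0$x))

  # validation subjects need a baseline measurement in the first window
  w1 <- config$window_width_weeks
  mv <- valid_cohort$measurements
  has_base <- unique(mv$subject_id[mv$weeks <= w1])
  excluded_n <- length(valid_ids) - length(has_base)
  vc <- subset_cohort(valid_cohort, has_base)

  dval0 <- cox_design(vc)
  risk_nc <- cox_predict_risk(cox_noclass, dval0$x)
  concordance_no_class <- concordance_index(dval0$time, dval0$event, risk_nc)

  windows <- do.call(rbind, lapply(seq_len(config$n_windows), function(wi) {
    w <- wi * w1
    mw <- vc$measurements[vc$measurements$weeks <= w, , drop = FALSE]
    pred <- posterior_predict_lcga(mw, train_fit$params,
                                   subject_ids = vc$subjects$subject_id)
    cls <- pred$modal_class[vc$subjects$subject_id]
    dv <- cox_design(vc, class_assign = as.integer(cls), k = k,
                     reference_class = ref)
    risk <- cox_predict_risk(cox_train, dv$x)
    n_ev <- sum(dv$event)
    conc <- if (n_ev == 0) NA_real_ else {
      concordance_index(dv$time, dv$event, risk)
    }
    data.frame(week = w, concordance = conc, n_events = n_ev)
  }))

  pred_all <- posterior_predict_lcga(vc, train_fit$params)
  dva <- cox_design(vc, class_assign = as.integer(pred_all$modal_class), k = k,
                    reference_class = ref)
  conc_full <- concordance_index(dva$time, dva$event,
                                 cox_predict_risk(cox_train, dva$x))

  list(retention = retention, windows = windows,
       concordance_no_class = concordance_no_class,
       concordance_full_trajectory = conc_full,
       cox_train = cox_train, cox_noclass = cox_noclass,
       train_fit = train_fit, full_fit = full_fit, class_map = map,
       n_train = length(train_ids), n_valid = length(valid_ids),
       excluded_n = excluded_n)
}
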