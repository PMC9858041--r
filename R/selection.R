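#' Model selection over time-link shapes and class counts
#'
#' Fits every combination of shape and `k = 1..k_max` by [fit_lcga()] and
#' applies a two-part rule: a grid cell is *admissible* when its smallest
#' modal class proportion is at least `min_prop` (3% by default — with
#' registry-scale cohorts, smaller classes are unstable); the chosen `k` is
#' the largest `k` at which **all** shapes are still admissible while some
#' shape drops below the floor at `k + 1` (or `k = k_max` if the floor is
#' never hit); the chosen shape then minimizes BIC at that `k`. Subject-level
#' k-fold cross-validated held-out log-likelihood is recorded per grid cell as
#' corroboration; it never overrides the BIC + proportion rule.
#'
#' Cross-validation refits warm-start from the full-data parameters of each
#' cell, which keeps the procedure affordable on the full grid.
#'
#' @param cohort an `hba1c_cohort`.
#' @param k_max largest class count to try.
#' @param shapes character vector of time-link shapes to scan.
#' @param min_prop minimum admissible modal class proportion.
#' @param cv_folds folds for the corroborating cross-validation
#'   (0 disables it).
#' @param n_starts,burn_in_iters,tol,max_iters passed to [fit_lcga()].
#' @param seed RNG seed (start perturbations and fold assignment).
#' @param time_scale,exp_timescale_weeks basis settings, see [basis_spec()].
#' @param use_modal_proportions if `FALSE`, the admissibility rule uses the
#'   estimated mixing proportions instead of modal-assignment fractions.
#' @param keep_fits keep every fitted grid cell in the report (needed to reuse
#'   the chosen fit without refitting).
#' @return object of class `lcga_selection`: `grid` (data frame over
#'   shape x k with loglik, bic, min proportion, cv held-out log-likelihood,
#'   admissible flag), `chosen` (list with `shape`, `k`), `chosen_fit`,
#'   `rationale`, and (optionally) `fits`.
#' @export
select_lcga_model <- function(cohort, k_max = 10L,
                              shapes = c("linear", "quadratic", "cubic",
                                         "logarithmic", "exponential"),
                              min_prop = 0.03, cv_folds = 10L,
                              n_starts = 20L, burn_in_iters = 30L,
                              tol = 1e-6, max_iters = 500L, seed = 1L,
                              time_scale = 100, exp_timescale_weeks = 26,
                              use_modal_proportions = TRUE,
                              keep_fits = TRUE) {
  k_max <- as.integer(k_max)
  if (k_max < 1L) ht_stop("select_lcga_model: k_max must be >= 1",
                          "hba1ctraj_config_error")
  n <- nrow(cohort$subjects)
  folds <- NULL
  if (cv_folds > 0L) {
    set.seed(seed + 10000L)
    folds <- sample(rep(seq_len(cv_folds), length.out = n))
  }

  grid <- expand.grid(shape = shapes, k = seq_len(k_max),
                      stringsAsFactors = FALSE)
  grid$loglik <- grid$bic <- grid$min_class_proportion <- NA_real_
  grid$cv_mean_heldout_loglik <- NA_real_
  grid$admissible <- NA
  fits <- vector("list", nrow(grid))

  for (r in seq_len(nrow(grid))) {
    basis <- basis_spec(grid$shape[r], time_scale = time_scale,
                        exp_timescale_weeks = exp_timescale_weeks)
    fit <- fit_lcga(cohort, basis, grid$k[r], n_starts = n_starts,
                    burn_in_iters = burn_in_iters, tol = tol,
                    max_iters = max_iters, seed = seed)
    grid$loglik[r] <- fit$loglik
    grid$bic[r] <- fit$bic
    grid$min_class_proportion[r] <- if (use_modal_proportions) {
      min(fit$class_proportions)
    } else {
      min(mixing_props(fit$params))
    }
    grid$admissible[r] <- grid$min_class_proportion[r] >= min_prop
    if (cv_folds > 0L) {
      grid$cv_mean_heldout_loglik[r] <-
        .cv_heldout_loglik(cohort, fit, folds, tol, max_iters)
    }
    fits[[r]] <- fit
  }

  all_adm <- vapply(seq_len(k_max), function(kk) {
    all(grid$admissible[grid$k == kk])
  }, TRUE)
  candidates <- which(all_adm &
                        (seq_len(k_max) == k_max | !c(all_adm[-1], TRUE)))
  if (!length(candidates)) {
    if (!any(all_adm)) {
      ht_stop("select_lcga_model: no admissible model on the grid",
              "hba1ctraj_selection_error")
    }
    candidates <- which(all_adm)
  }
  chosen_k <- max(candidates)
  at_k <- grid[grid$k == chosen_k, ]
  chosen_shape <- at_k$shape[which.min(at_k$bic)]
  chosen_row <- which(grid$k == chosen_k & grid$shape == chosen_shape)

  rationale <- sprintf(paste0(
    "All shapes keep every class above %.0f%% up to k = %d%s; at k = %d the ",
    "%s shape has the lowest BIC (%.1f)."),
    100 * min_prop, chosen_k,
    if (chosen_k < k_max) sprintf(" but not at k = %d", chosen_k + 1L) else "",
    chosen_k, chosen_shape, grid$bic[chosen_row])

  structure(list(
    grid = grid,
    chosen = list(shape = chosen_shape, k = chosen_k),
    chosen_fit = fits[[chosen_row]],
    rationale = rationale,
    min_prop = min_prop,
    fits = if (keep_fits) fits else NULL
  ), class = "lcga_selection")
}

# warm-start k-fold CV: mean per-subject held-out log-likelihood
.cv_heldout_loglik <- function(cohort, fit, folds, tol, max_iters) {
  prep <- lcga_prepare(cohort, fit$basis)
  ids <- cohort$subjects$subject_id
  tot <- 0; nh <- 0L
  for (f in sort(unique(folds))) {
    train <- prep_subset(prep, ids[folds != f])
    test <- prep_subset(prep, ids[folds == f])
    run <- tryCatch(.em_run(train, fit$params, min(max_iters, 100L), tol),
                    hba1ctraj_rank_error = function(e) NULL)
    params <- if (is.null(run)) fit$params else run$params
    tot <- tot + .e_step(test, params)$ll
    nh <- nh + test$n
  }
  tot / nh
}

#' @export
print.lcga_selection <- function(x, ...) {
  cat(sprintf("<lcga_selection> chosen: %s shape, k = %d\n",
              x$chosen$shape, x$chosen$k))
  cat(" ", x$rationale, "\n")
  invisible(x)
}

#' Serialize a selection report to JSON
#' @param selection an `lcga_selection`.
#' @param path output file.
#' @export
write_selection_report <- function(selection, path) {
  jsonlite::write_json(
    list(grid = selection$grid, chosen = selection$chosen,
         rationale = selection$rationale, min_prop = selection$min_prop),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
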