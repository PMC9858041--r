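# Latent class growth analysis: a finite mixture of fixed-effect growth
# curves over a chosen time basis, with a shared residual SD, estimated by
# multi-start EM. Subjects are the mixing unit: all measurements of a subject
# share one latent class.

#' Parameter set of a latent class growth model
#'
#' @param basis a [basis_spec()].
#' @param k number of latent classes (>= 1).
#' @param beta `k x d` matrix of curve coefficients (d = [basis_dim()]).
#' @param theta length `k-1` vector of multinomial-logit mixing intercepts
#'   (last class is the reference); class proportions are
#'   `softmax(c(theta, 0))`.
#' @param sigma shared residual SD (HbA1c %), > 0.
#' @return object of class `lcga_params`.
#' @export
lcga_params <- function(basis, k, beta, theta, sigma) {
  if (!inherits(basis, "basis_spec")) {
    ht_stop("lcga_params: basis must be a basis_spec", "hba1ctraj_config_error")
  }
  k <- as.integer(k)
  beta <- rbind(beta)
  if (k < 1L || nrow(beta) != k || ncol(beta) != basis_dim(basis)) {
    ht_stop(sprintf("lcga_params: beta must be %d x %d", k, basis_dim(basis)),
            "hba1ctraj_config_error")
  }
  if (length(theta) != k - 1L) {
    ht_stop("lcga_params: theta must have length k - 1", "hba1ctraj_config_error")
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    ht_stop("lcga_params: sigma must be > 0", "hba1ctraj_domain_error")
  }
  structure(list(basis = basis, k = k, beta = beta, theta = as.numeric(theta),
                 sigma = sigma),
            class = "lcga_params")
}

#' Mixing proportions implied by the logit intercepts
#' @param params an [lcga_params()].
#' @return length-`k` probability vector.
#' @export
mixing_props <- function(params) softmax_ref(params$theta)

# ---- internal measurement-level representation -----------------------------

# Flattens a cohort (or a long measurements data frame) for one basis:
# X (N x d), y (N), gi (subject index per measurement), m (counts), ids.
lcga_prepare <- function(cohort, basis, ids = NULL) {
  m <- if (inherits(cohort, "hba1c_cohort")) cohort$measurements else cohort
  if (is.null(ids)) {
    ids <- if (inherits(cohort, "hba1c_cohort")) cohort$subjects$subject_id
           else unique(m$subject_id)
  }
  m <- m[m$subject_id %in% ids, , drop = FALSE]
  gi <- match(m$subject_id, ids)
  ord <- order(gi, m$weeks)
  m <- m[ord, , drop = FALSE]
  gi <- gi[ord]
  present <- sort(unique(gi))
  X <- basis_matrix(m$weeks, basis)
  list(X = X, y = m$hba1c, gi = gi, n = length(present),
       m = tabulate(gi, length(ids))[present],
       gi_dense = match(gi, present),
       ids = ids[present], basis = basis, d = ncol(X), N = nrow(X))
}

prep_subset <- function(prep, keep_ids) {
  rows <- prep$ids[prep$gi_dense] %in% keep_ids
  gi <- prep$gi_dense[rows]
  present <- sort(unique(gi))
  list(X = prep$X[rows, , drop = FALSE], y = prep$y[rows],
       gi = gi, gi_dense = match(gi, present),
       n = length(present), m = tabulate(gi, max(gi))[present],
       ids = prep$ids[present], basis = prep$basis, d = prep$d,
       N = sum(rows))
}

# per-subject log joint density matrix (n x k): log pi_k + sum_j log phi
.log_joint <- function(prep, params) {
  mu <- prep$X %*% t(params$beta)              # N x k
  ss <- rowsum((prep$y - mu)^2, prep$gi_dense) # n x k
  s2 <- params$sigma^2
  A <- -ss / (2 * s2) - 0.5 * prep$m * log(2 * pi * s2)
  sweep(A, 2L, log(mixing_props(params)), `+`)
}

.e_step <- function(prep, params) {
  L <- .log_joint(prep, params)
  ll_i <- logsumexp_rows(L)
  list(post = exp(L - ll_i), ll = sum(ll_i))
}

.m_step <- function(prep, post, params) {
  k <- ncol(post)
  pik <- colMeans(post)
  pik <- pmax(pik, 1e-12); pik <- pik / sum(pik)
  beta <- matrix(0, k, prep$d)
  ssr <- 0
  for (cl in seq_len(k)) {
    w <- post[prep$gi_dense, cl]
    XtWX <- crossprod(prep$X, prep$X * w)
    XtWy <- crossprod(prep$X, prep$y * w)
    b <- tryCatch(solve(XtWX, XtWy), error = function(e) {
      ht_stop(sprintf("m_step: weighted design is rank deficient in class %d", cl),
              "hba1ctraj_rank_error")
    })
    beta[cl, ] <- b
    ssr <- ssr + sum(w * (prep$y - drop(prep$X %*% b))^2)
  }
  sigma <- sqrt(max(ssr / prep$N, 1e-12))
  theta <- if (k > 1L) log(pik[-k] / pik[k]) else numeric(0)
  lcga_params(params$basis, k, beta, theta, sigma)
}

# EM loop from given params; returns params, loglik, trace, converged
.em_run <- function(prep, params, max_iters, tol) {
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    es <- .e_step(prep, params)
    trace[it] <- es$ll
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) <= tol * (abs(trace[it - 1L]) + 1e-3)) {
      converged <- TRUE
      break
    }
    params <- .m_step(prep, es$post, params)
  }
  es <- .e_step(prep, params)
  list(params = params, loglik = es$ll, post = es$post,
       trace = trace, converged = converged)
}

# ---- exported operations ---------------------------------------------------

#' Mixture log-likelihood of a cohort under a parameter set
#'
#' `sum_i log sum_k pi_k prod_j phi(y_ij; x_ij' beta_k, sigma^2)`, evaluated
#' with per-subject log-sum-exp so long measurement series do not underflow.
#'
#' @param cohort an `hba1c_cohort` (or long measurements data frame with
#'   columns `subject_id`, `weeks`, `hba1c`).
#' @param params an [lcga_params()].
#' @return scalar log-likelihood.
#' @export
lcga_loglik <- function(cohort, params) {
  prep <- lcga_prepare(cohort, params$basis)
  .e_step(prep, params)$ll
}

#' E-step: posterior class-membership probabilities
#'
#' @inheritParams lcga_loglik
#' @return `n x k` matrix of posterior probabilities; rows (subjects, in
#'   cohort order) sum to 1.
#' @export
lcga_e_step <- function(cohort, params) {
  prep <- lcga_prepare(cohort, params$basis)
  post <- .e_step(prep, params)$post
  rownames(post) <- prep$ids
  post
}

#' M-step: update curve coefficients, mixing logits and residual SD
#'
#' Given posterior weights, each class's coefficients solve the
#' posterior-weighted least-squares problem pooling all measurements; the
#' residual variance is the pooled weighted mean squared residual; the mixing
#' proportions are posterior column means. One E+M sweep never decreases the
#' mixture log-likelihood.
#'
#' @inheritParams lcga_loglik
#' @param posterior `n x k` matrix, rows summing to 1 (subjects in cohort
#'   order).
#' @param basis a [basis_spec()].
#' @return an [lcga_params()].
#' @export
lcga_m_step <- function(cohort, posterior, basis) {
  prep <- lcga_prepare(cohort, basis)
  if (nrow(posterior) != prep$n) {
    ht_stop("lcga_m_step: posterior rows must match cohort subjects",
            "hba1ctraj_config_error")
  }
  dummy <- lcga_params(basis, ncol(posterior),
                       matrix(0, ncol(posterior), prep$d),
                       rep(0, ncol(posterior) - 1L), 1)
  .m_step(prep, posterior, dummy)
}

#' Bayesian Information Criterion for a subject-level mixture
#'
#' `-2 loglik + n_params log(n_subjects)`. The sample-size term counts
#' subjects (the independent units of the mixture), not measurements.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params free parameter count (`k*d + (k-1) + 1` for this model).
#' @param n_subjects number of subjects.
#' @export
bic_value <- function(loglik, n_params, n_subjects) {
  stopifnot(n_subjects >= 1)
  -2 * loglik + n_params * log(n_subjects)
}

#' Average posterior probability of assignment (APPA)
#'
#' For each class k, the mean posterior probability of class k among subjects
#' modally assigned to k. Values near 1 indicate well-separated classes;
#' 0.7 is the usual adequacy floor.
#'
#' @param posterior `n x k` posterior matrix.
#' @param modal_class integer vector of modal assignments.
#' @return length-`k` vector; `NA` (with a warning) for classes with no modal
#'   members.
#' @export
appa <- function(posterior, modal_class) {
  k <- ncol(posterior)
  out <- rep(NA_real_, k)
  for (cl in seq_len(k)) {
    members <- modal_class == cl
    if (any(members)) out[cl] <- mean(posterior[members, cl])
  }
  if (anyNA(out)) {
    warning(sprintf("appa: class(es) %s have no modal members; APPA undefined",
                    paste(which(is.na(out)), collapse = ", ")))
  }
  out
}

#' Scaled entropy of a posterior matrix
#'
#' `1 - sum_ik (-p_ik log p_ik) / (n log k)`, with `0 log 0 := 0`; 1 for
#' perfectly separated (one-hot) posteriors, 0 for uninformative uniform ones.
#' Undefined (`NA`) for k = 1.
#'
#' @param posterior `n x k` posterior matrix.
#' @export
scaled_entropy <- function(posterior) {
  k <- ncol(posterior)
  if (k < 2L) return(NA_real_)
  p <- posterior
  h <- -p * log(p)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(p) * log(k))
}

#' Fit a latent class growth model by multi-start EM
#'
#' Start 1 is deterministic: the single-curve least-squares fit replicated
#' `k` times with ordered intercept offsets (normal quantiles scaled by the
#' residual SD). Starts 2..`n_starts` add Gaussian perturbations. Every start
#' runs `burn_in_iters` EM iterations; the start with the best burn-in
#' log-likelihood is refined until the relative log-likelihood change drops
#' below `tol` or `max_iters` is reached. Classes are then relabelled in
#' descending order of mean fitted HbA1c over the cohort's observed times, so
#' class 1 is always the highest trajectory (label-switching
#' canonicalization). Deterministic given `seed`.
#'
#' @param cohort an `hba1c_cohort` (or long measurements data frame).
#' @param basis a [basis_spec()].
#' @param k number of classes.
#' @param n_starts number of EM starts (1 deterministic + `n_starts - 1`
#'   perturbed).
#' @param burn_in_iters EM iterations per start before the best is refined.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iters iteration cap for the refinement run.
#' @param seed RNG seed for the perturbed starts.
#' @return object of class `lcga_fit`: `params`, `loglik`, `bic`, `posterior`
#'   (rows named by subject id), `modal_class`, `class_proportions` (modal
#'   fractions), `appa`, `scaled_entropy`, `n_subjects`, `converged`,
#'   `n_starts_used`, `trace` (log-likelihood per refinement iteration),
#'   `burn_trace` (per-start burn-in traces).
#' @export
fit_lcga <- function(cohort, basis, k, n_starts = 20L, burn_in_iters = 30L,
                     tol = 1e-6, max_iters = 500L, seed = 1L) {
  k <- as.integer(k)
  prep <- lcga_prepare(cohort, basis)
  if (k < 1L) ht_stop("fit_lcga: k must be >= 1", "hba1ctraj_config_error")
  if (prep$n < k) ht_stop("fit_lcga: fewer subjects than classes",
                          "hba1ctraj_config_error")

  # single-curve least squares anchor
  b0 <- tryCatch(solve(crossprod(prep$X), crossprod(prep$X, prep$y)),
                 error = function(e) ht_stop(
                   "fit_lcga: design is rank deficient for this basis",
                   "hba1ctraj_rank_error"))
  res0 <- prep$y - drop(prep$X %*% b0)
  sig0 <- sqrt(max(mean(res0^2), 1e-8))

  if (k == 1L) {
    params <- lcga_params(basis, 1L, matrix(b0, 1L), numeric(0), sig0)
    es <- .e_step(prep, params)
    post <- es$post; rownames(post) <- prep$ids
    fit <- structure(list(
      params = params, loglik = es$ll,
      bic = bic_value(es$ll, prep$d + 1L, prep$n),
      posterior = post, modal_class = rep(1L, prep$n),
      class_proportions = 1, appa = 1, scaled_entropy = NA_real_,
      n_subjects = prep$n, converged = TRUE, n_starts_used = 1L,
      trace = es$ll, burn_trace = list(es$ll),
      subject_ids = prep$ids, basis = basis, seed = seed
    ), class = "lcga_fit")
    return(fit)
  }

  offsets <- stats::qnorm(seq(k, 1L) / (k + 1)) * sig0
  make_start1 <- function() {
    beta <- matrix(rep(drop(b0), each = k), k, prep$d)
    beta[, 1L] <- beta[, 1L] + offsets
    lcga_params(basis, k, beta, rep(0, k - 1L), sig0)
  }
  csd <- apply(prep$X, 2L, stats::sd)
  noise_scale <- ifelse(csd < 1e-10, sig0, sig0 / pmax(csd, 0.05))

  set.seed(seed)
  burns <- vector("list", n_starts)
  burn_ll <- rep(-Inf, n_starts)
  for (s in seq_len(n_starts)) {
    start <- make_start1()
    if (s > 1L) {
      start$beta <- start$beta +
        sweep(matrix(stats::rnorm(k * prep$d), k, prep$d), 2L, noise_scale, `*`)
      start$theta <- stats::rnorm(k - 1L, 0, 0.3)
      start$sigma <- sig0 * exp(stats::rnorm(1, 0, 0.1))
    }
    run <- tryCatch(.em_run(prep, start, burn_in_iters, tol),
                    hba1ctraj_rank_error = function(e) NULL)
    if (!is.null(run) && is.finite(run$loglik)) {
      burns[[s]] <- run
      burn_ll[s] <- run$loglik
    }
  }
  if (all(!is.finite(burn_ll))) {
    ht_stop("fit_lcga: no start achieved a finite likelihood", "hba1ctraj_fit_error")
  }
  best <- which.max(burn_ll)
  refined <- .em_run(prep, burns[[best]]$params, max_iters, tol)

  # canonical order: descending mean fitted level over observed times
  g <- colMeans(prep$X %*% t(refined$params$beta))
  perm <- order(-g)
  pik <- mixing_props(refined$params)[perm]
  params <- lcga_params(basis, k, refined$params$beta[perm, , drop = FALSE],
                        log(pik[-k] / pik[k]), refined$params$sigma)
  post <- refined$post[, perm, drop = FALSE]
  rownames(post) <- prep$ids
  modal <- max.col(post, ties.method = "first")
  props <- tabulate(modal, k) / prep$n
  structure(list(
    params = params, loglik = refined$loglik,
    bic = bic_value(refined$loglik, k * prep$d + (k - 1L) + 1L, prep$n),
    posterior = post, modal_class = modal, class_proportions = props,
    appa = suppressWarnings(appa(post, modal)),
    scaled_entropy = scaled_entropy(post),
    n_subjects = prep$n, converged = refined$converged,
    n_starts_used = sum(is.finite(burn_ll)),
    trace = refined$trace,
    burn_trace = lapply(burns[is.finite(burn_ll)], `[[`, "trace"),
    subject_ids = prep$ids, basis = basis, seed = seed
  ), class = "lcga_fit")
}

#' @export
print.lcga_fit <- function(x, ...) {
  cat(sprintf("<lcga_fit> %s basis, k = %d, n = %d subjects\n",
              x$basis$shape, x$params$k, x$n_subjects))
  cat(sprintf("  loglik %.2f | BIC %.2f | entropy %s | converged: %s\n",
              x$loglik, x$bic,
              ifelse(is.na(x$scaled_entropy), "NA", sprintf("%.3f", x$scaled_entropy)),
              x$converged))
  cat("  modal proportions:", paste(sprintf("%.3f", x$class_proportions),
                                    collapse = " "), "\n")
  invisible(x)
}

#' Class mean curves on a time grid
#' @param fit an `lcga_fit` (or [lcga_params()]).
#' @param t_weeks evaluation grid (weeks).
#' @return `length(t_weeks) x k` matrix of fitted mean HbA1c.
#' @export
class_curves <- function(fit, t_weeks) {
  params <- if (inherits(fit, "lcga_fit")) fit$params else fit
  basis_matrix(t_weeks, params$basis) %*% t(params$beta)
}

#' Posterior class prediction for new subjects
#'
#' Applies the E-step with frozen parameters; no refitting. Subjects present
#' in `subject_ids` but with zero usable measurements are reported in
#' `excluded`, not silently dropped.
#'
#' @param new_data an `hba1c_cohort` or long data frame (`subject_id`,
#'   `weeks`, `hba1c`).
#' @param params an [lcga_params()] (or an `lcga_fit`, whose params are used).
#' @param subject_ids optional id vector defining the prediction set (defaults
#'   to the ids present in `new_data`).
#' @return list with `posterior` (rows named by id), `modal_class` (named),
#'   and `excluded` (ids with no measurements).
#' @export
posterior_predict_lcga <- function(new_data, params, subject_ids = NULL) {
  if (inherits(params, "lcga_fit")) params <- params$params
  m <- if (inherits(new_data, "hba1c_cohort")) new_data$measurements else new_data
  if (is.null(subject_ids)) {
    subject_ids <- if (inherits(new_data, "hba1c_cohort")) {
      new_data$subjects$subject_id
    } else unique(m$subject_id)
  }
  prep <- lcga_prepare(m, params$basis, ids = subject_ids)
  excluded <- setdiff(subject_ids, prep$ids)
  post <- .e_step(prep, params)$post
  rownames(post) <- prep$ids
  modal <- max.col(post, ties.method = "first")
  names(modal) <- prep$ids
  list(posterior = post, modal_class = modal, excluded = excluded)
}

#' Serialize a fitted model to JSON + CSV
#'
#' @param fit an `lcga_fit`.
#' @param dir output directory; writes `lcga_fit.json` (parameters and
#'   diagnostics) and `posterior.csv` (subject_id, p_1..p_k, modal_class).
#' @return `dir`, invisibly.
#' @export
write_lcga_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    shape = fit$basis$shape, time_scale = fit$basis$time_scale,
    exp_timescale_weeks = fit$basis$exp_timescale_weeks,
    k = fit$params$k, beta = fit$params$beta, theta = fit$params$theta,
    sigma = fit$params$sigma, loglik = fit$loglik, bic = fit$bic,
    appa = fit$appa, scaled_entropy = fit$scaled_entropy,
    class_proportions = fit$class_proportions,
    n_subjects = fit$n_subjects, converged = fit$converged,
    n_starts_used = fit$n_starts_used, seed = fit$seed
  )
  jsonlite::write_json(meta, file.path(dir, "lcga_fit.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  post <- as.data.frame(fit$posterior)
  names(post) <- paste0("p_", seq_len(ncol(post)))
  post <- cbind(data.frame(subject_id = rownames(fit$posterior)), post,
                modal_class = fit$modal_class)
  utils::write.csv(post, file.path(dir, "posterior.csv"), row.names = FALSE)
  invisible(dir)
}
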