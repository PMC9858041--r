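# From-scratch survival estimators: product-limit curves, the log-rank test,
# Cox proportional hazards with Efron tie handling, and Harrell's concordance.
# The estimators are self-contained; established survival software is used
# only as an independent cross-check in the test suite.

#' Kaplan-Meier product-limit curve
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators.
#' @return object of class `km_curve`: data frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `survival`); `survival` is the
#'   product-limit estimate just after that time. Censored subjects leave the
#'   risk set immediately after their time.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time <= 0)) ht_stop("km_curve: times must be > 0", "hba1ctraj_domain_error")
  et <- sort(unique(time[event == 1]))
  if (!length(et)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0))
    return(structure(out, class = c("km_curve", "data.frame")))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), 0L)
  n_event <- vapply(et, function(t) sum(time == t & event == 1), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param curve a [km_curve()].
#' @param t times at which to evaluate S(t).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    below <- curve$time <= tt
    if (!any(below)) 1 else curve$survival[max(which(below))]
  }, 0)
}

#' Log-rank test for k groups
#'
#' Observed minus expected events per group accumulated over distinct event
#' times, with the hypergeometric covariance; the statistic is
#' `(O-E)' V^- (O-E)` over the first `k-1` groups and is referred to a
#' chi-square distribution with `k-1` degrees of freedom. Groups with
#' identical time/event composition yield a statistic of exactly 0 (p = 1).
#'
#' @param time positive times.
#' @param event 0/1 indicators.
#' @param group group labels (>= 2 distinct values; each group non-empty).
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`
#'   (per group, in `sort(unique(group))` order).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  levels <- sort(unique(group))
  if (length(levels) < 2L) {
    ht_stop("logrank_test: need at least two groups", "hba1ctraj_config_error")
  }
  for (g in levels) {
    if (!sum(group == g)) ht_stop(sprintf("logrank_test: group '%s' is empty", g),
                                  "hba1ctraj_config_error")
  }
  if (!sum(event)) ht_stop("logrank_test: no events", "hba1ctraj_config_error")
  k <- length(levels)
  gi <- match(group, levels)
  et <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(seq_len(k), function(g) sum(at_risk & gi == g), 0)
    dg <- vapply(seq_len(k), function(g) sum(event == 1 & time == t & gi == g), 0)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(ng / n, k) - tcrossprod(ng / n))
    }
  }
  u <- O - E
  if (max(abs(u)) < 1e-12) {
    stat <- 0
  } else {
    idx <- seq_len(k - 1L)
    Vi <- V[idx, idx, drop = FALSE]
    sol <- tryCatch(solve(Vi, u[idx]), error = function(e) MASS::ginv(Vi) %*% u[idx])
    stat <- drop(u[idx] %*% sol)
  }
  df <- k - 1L
  list(statistic = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E, groups = levels)
}

#' Cox proportional hazards fit (Efron ties, Newton-Raphson)
#'
#' Maximizes the Efron-approximation partial log-likelihood by Newton-Raphson
#' with step-halving. The covariance is the inverse observed information; 95%
#' confidence intervals and p-values are Wald-based. Constant covariate
#' columns carry no information and are dropped with a warning. Harrell's
#' concordance on the fitted linear predictor is included.
#'
#' @param time positive times.
#' @param event 0/1 indicators (>= 1 event required).
#' @param x covariate matrix (or data frame of numeric columns).
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the log-likelihood change.
#' @return object of class `cox_fit`: `coef`, `covariance`, `se`, `hr`,
#'   `ci95` (matrix lower/upper on the HR scale), `wald_p`, `loglik`,
#'   `loglik_null`, `concordance`, `n`, `n_event`, `iterations`, `dropped`
#'   (names of removed constant columns).
#' @export
cox_fit <- function(time, event, x, max_iter = 50L, tol = 1e-9) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(time) == nrow(x), length(event) == nrow(x))
  if (sum(event) < 1) ht_stop("cox_fit: no events", "hba1ctraj_config_error")

  const <- apply(x, 2L, function(col) max(col) - min(col) < 1e-12)
  dropped <- colnames(x)[const]
  if (any(const)) {
    warning(sprintf("cox_fit: dropping constant covariate(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  if (!ncol(x)) ht_stop("cox_fit: no informative covariates", "hba1ctraj_rank_error")
  p <- ncol(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)   # centering improves conditioning; coef unchanged

  et <- sort(unique(time[event == 1]))
  risk_idx <- lapply(et, function(t) which(time >= t))
  death_idx <- lapply(et, function(t) which(time == t & event == 1))

  efron <- function(beta) {
    eta <- drop(xc %*% beta)
    w <- exp(eta)
    ll <- 0
    grad <- numeric(p)
    info <- matrix(0, p, p)
    for (j in seq_along(et)) {
      R <- risk_idx[[j]]; D <- death_idx[[j]]
      d <- length(D)
      sr <- sum(w[R]); sd <- sum(w[D])
      wr <- colSums(xc[R, , drop = FALSE] * w[R])
      wd <- colSums(xc[D, , drop = FALSE] * w[D])
      Qr <- crossprod(xc[R, , drop = FALSE], xc[R, , drop = FALSE] * w[R])
      Qd <- crossprod(xc[D, , drop = FALSE], xc[D, , drop = FALSE] * w[D])
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1L) {
        a <- l / d
        denom <- sr - a * sd
        num <- wr - a * wd
        ll <- ll - log(denom)
        grad <- grad - num / denom
        info <- info + (Qr - a * Qd) / denom - tcrossprod(num / denom)
      }
    }
    grad <- grad + colSums(xc[event == 1, , drop = FALSE])
    list(ll = ll, grad = grad, info = info)
  }

  beta <- numeric(p)
  ev <- efron(beta)
  ll0 <- ev$ll
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) {
      ht_stop("cox_fit: singular information matrix (collinear covariates?)",
              "hba1ctraj_rank_error")
    })
    halves <- 0L
    repeat {
      cand <- beta + step
      evc <- efron(cand)
      if (is.finite(evc$ll) && evc$ll >= ev$ll - 1e-12) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 30L) break
    }
    improved <- evc$ll - ev$ll
    if (halves > 30L && improved < 0) break  # no ascent direction left
    beta <- cand
    ev <- evc
    if (abs(improved) < tol || iter >= max_iter) break
  }
  if (iter >= max_iter && abs(improved) >= tol) {
    worst <- colnames(x)[which.max(abs(beta))]
    if (max(abs(beta)) > 10) {
      ht_stop(sprintf(
        "cox_fit: likelihood appears monotone (possible perfect separation in '%s')",
        worst), "hba1ctraj_fit_error")
    }
    warning("cox_fit: Newton-Raphson did not converge within max_iter")
  }

  cov <- tryCatch(solve(ev$info), error = function(e) {
    ht_stop("cox_fit: singular information at the optimum", "hba1ctraj_rank_error")
  })
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  lp <- drop(x %*% beta)   # uncentered linear predictor (ranking only)
  names(beta) <- colnames(x)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- colnames(x)
  structure(list(
    coef = beta, covariance = cov, se = stats::setNames(se, colnames(x)),
    hr = exp(beta), ci95 = ci,
    wald_p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(x)),
    loglik = ev$ll, loglik_null = ll0,
    concordance = concordance_index(time, event, lp),
    n = nrow(x), n_event = sum(event), iterations = iter,
    dropped = dropped, center = ctr, xnames = colnames(x)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, loglik = %.3f, concordance = %.3f\n",
              x$n, x$n_event, x$loglik, x$concordance))
  tab <- data.frame(coef = x$coef, HR = x$hr,
                    lower95 = x$ci95[, "lower"], upper95 = x$ci95[, "upper"],
                    p = x$wald_p)
  print(round(tab, 4))
  invisible(x)
}

#' Linear risk score from a Cox fit
#'
#' The linear predictor `x' coef`; monotone in the hazard, so sufficient for
#' ranking and concordance (no baseline hazard needed).
#'
#' @param fit a [cox_fit()].
#' @param x covariate matrix with the fit's columns.
#' @export
cox_predict_risk <- function(fit, x) {
  x <- as.matrix(x)
  if (length(fit$dropped)) {
    keep <- !(colnames(x) %in% fit$dropped)
    if (any(!keep)) x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) != length(fit$coef)) {
    ht_stop(sprintf("cox_predict_risk: expected %d covariates, got %d",
                    length(fit$coef), ncol(x)), "hba1ctraj_config_error")
  }
  drop(x %*% fit$coef)
}

#' Harrell's concordance index
#'
#' Over pairs (i, j) with `t_i < t_j` and subject i experiencing the event:
#' concordant when `risk_i > risk_j`, 0.5 credit for tied risks.
#'
#' @param time positive times.
#' @param event 0/1 indicators.
#' @param risk risk scores (higher = riskier).
#' @return C in [0, 1]; `NA` (with a warning) when no comparable pair exists.
#' @export
concordance_index <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  conc <- 0; pairs <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    np <- sum(later)
    if (!np) next
    pairs <- pairs + np
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (!pairs) {
    warning("concordance_index: no comparable pairs; C undefined")
    return(NA_real_)
  }
  conc / pairs
}

#' Serialize a Cox fit to JSON
#' @param fit a [cox_fit()].
#' @param path output file.
#' @export
write_cox_fit <- function(fit, path) {
  jsonlite::write_json(list(
    coef = as.list(fit$coef), hr = as.list(fit$hr),
    ci95_lower = as.list(fit$ci95[, "lower"]),
    ci95_upper = as.list(fit$ci95[, "upper"]),
    p = as.list(fit$wald_p), loglik = fit$loglik,
    concordance = fit$concordance, n = fit$n, n_event = fit$n_event
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
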