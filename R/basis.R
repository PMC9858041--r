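#' Time-link basis for growth curves
#'
#' The class-specific mean HbA1c curves are linear in a small set of basis
#' functions of time since baseline (weeks). Five shapes are supported:
#' polynomial links of degree 1-3 in scaled weeks, a logarithmic link
#' `log(weeks + 1)` (defined at the baseline visit), and an exponential-decay
#' link `exp(-weeks / exp_timescale_weeks)` capturing a fast early decline
#' that levels off.
#'
#' @param shape one of `"linear"`, `"quadratic"`, `"cubic"`, `"logarithmic"`,
#'   `"exponential"`.
#' @param time_scale divisor applied to weeks before polynomial evaluation;
#'   keeps the design well-conditioned over multi-year follow-up. Default 100.
#' @param exp_timescale_weeks decay constant (weeks) of the exponential link.
#'   Default 26, i.e. most of the decline happens within the first ~30 weeks.
#' @return an object of class `basis_spec`.
#' @examples
#' b <- basis_spec("logarithmic")
#' design_row(0, b)   # c(1, 0)
#' @export
basis_spec <- function(shape = c("linear", "quadratic", "cubic", "logarithmic", "exponential"),
                       time_scale = 100, exp_timescale_weeks = 26) {
  shape <- match.arg(shape)
  if (!is.numeric(time_scale) || time_scale <= 0) {
    ht_stop("basis_spec: time_scale must be > 0", "hba1ctraj_config_error")
  }
  if (!is.numeric(exp_timescale_weeks) || exp_timescale_weeks <= 0) {
    ht_stop("basis_spec: exp_timescale_weeks must be > 0", "hba1ctraj_config_error")
  }
  structure(
    list(shape = shape, time_scale = time_scale,
         exp_timescale_weeks = exp_timescale_weeks),
    class = "basis_spec"
  )
}

#' Dimension of a basis (number of curve coefficients per class)
#' @param basis a [basis_spec()].
#' @export
basis_dim <- function(basis) {
  switch(basis$shape,
    linear = 2L, quadratic = 3L, cubic = 4L,
    logarithmic = 2L, exponential = 2L
  )
}

#' Design matrix of the time basis
#'
#' @param t_weeks numeric vector of non-negative times (weeks from baseline).
#' @param basis a [basis_spec()].
#' @return numeric matrix with `length(t_weeks)` rows and [basis_dim()] columns;
#'   the first column is the intercept.
#' @export
basis_matrix <- function(t_weeks, basis) {
  if (any(t_weeks < 0)) {
    ht_stop("basis_matrix: negative times are outside the basis domain",
            "hba1ctraj_domain_error")
  }
  s <- t_weeks / basis$time_scale
  one <- rep(1, length(t_weeks))
  switch(basis$shape,
    linear      = cbind(1, s, deparse.level = 0),
    quadratic   = cbind(1, s, s^2, deparse.level = 0),
    cubic       = cbind(1, s, s^2, s^3, deparse.level = 0),
    logarithmic = cbind(1, log(t_weeks + 1), deparse.level = 0),
    exponential = cbind(1, exp(-t_weeks / basis$exp_timescale_weeks), deparse.level = 0)
  )
}

#' Single design row
#' @param t_weeks a single non-negative time in weeks.
#' @param basis a [basis_spec()].
#' @return numeric vector of length [basis_dim()].
#' @export
design_row <- function(t_weeks, basis) {
  stopifnot(length(t_weeks) == 1L)
  drop(basis_matrix(t_weeks, basis))
}
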