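# QALYs over a 12-month horizon from utilities at protocol visits
# 0, 6 and 12 months (0, 0.5, 1.0 years).

#' QALYs by trapezoidal area under the utility curve
#'
#' Computes 12-month quality-adjusted life years from utilities at the three
#' protocol visits by the trapezoid rule:
#' \deqn{QALY = 0.5 (u_0 + u_6)/2 + 0.5 (u_6 + u_{12})/2}
#' i.e. weights (0.25, 0.5, 0.25). Any missing utility propagates to a
#' missing QALY; in the base-case pipeline imputation happens upstream of
#' this call. Baseline-utility adjustment is handled downstream as a
#' regression covariate (see [fit_sur()]), not by subtracting here.
#'
#' @param u0,u6,u12 numeric utility vectors at 0, 6 and 12 months.
#' @param visit_times visit times in years; must be strictly increasing and
#'   span exactly one year. Default `c(0, 0.5, 1)`.
#' @return numeric QALY vector.
#' @examples
#' qaly_auc(0.6, 0.7, 0.8)  # 0.70
#' @export
qaly_auc <- function(u0, u6, u12, visit_times = c(0, 0.5, 1)) {
  if (length(visit_times) != 3L || any(diff(visit_times) <= 0) ||
      abs(visit_times[3L] - visit_times[1L] - 1) > 1e-12) {
    stop("visit_times must be 3 strictly increasing times spanning 1 year",
         call. = FALSE)
  }
  w1 <- diff(visit_times)[1L]
  w2 <- diff(visit_times)[2L]
  w1 * (u0 + u6) / 2 + w2 * (u6 + u12) / 2
}

#' Change in hand pain on the numerical rating scale
#'
#' Difference between 6-month and baseline hand pain NRS (0 = no pain,
#' 10 = worst pain). Negative values denote pain reduction; positive values
#' denote worsening.
#'
#' @param nrs6,nrs0 scores in 0..10 (`NA` allowed and propagated).
#' @return `nrs6 - nrs0`.
#' @export
pain_change <- function(nrs6, nrs0) {
  check_nrs <- function(x, what) {
    bad <- !is.na(x) & (x < 0 | x > 10)
    if (any(bad)) {
      stop(what, " outside 0..10: ",
           paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
    }
  }
  check_nrs(nrs0, "baseline NRS")
  check_nrs(nrs6, "6-month NRS")
  nrs6 - nrs0
}
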