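# Adjusted incremental costs and effects by seemingly unrelated regression
# (SUR), uncertainty by stratified nonparametric bootstrap with
# bias-corrected and accelerated (BCa) intervals, and the exchangeable-
# covariance mixed model for repeated pain scores.

#' Specification of the cost/QALY regression system
#'
#' Two equations (total cost; QALY) over the same participants, each
#' adjusted for baseline utility, baseline cost and the clinical-model
#' covariates, with the randomised-arm indicator whose coefficients are the
#' incremental cost and incremental QALYs.
#'
#' @param cost_outcome,qaly_outcome outcome column names.
#' @param covariates adjustment covariate column names.
#' @param arm arm column name (must have levels `control`, `intervention`).
#' @return list of class `sur_spec`.
#' @export
sur_spec <- function(cost_outcome = "total_cost", qaly_outcome = "qaly",
                     covariates = c("baseline_utility", "baseline_cost",
                                    "pain_nrs_0", "analgesic",
                                    "grip_strength", "bmi", "age", "gender"),
                     arm = "arm") {
  structure(list(cost_outcome = cost_outcome, qaly_outcome = qaly_outcome,
                 covariates = covariates, arm = arm), class = "sur_spec")
}

sur_design <- function(data, spec) {
  fml <- stats::reformulate(c(spec$arm, spec$covariates))
  mf <- stats::model.frame(fml, data = data, na.action = stats::na.fail)
  stats::model.matrix(fml, mf)
}

#' Fit the cost/QALY system by seemingly unrelated regression
#'
#' Feasible GLS: each equation is first fit by least squares, the 2 x 2
#' cross-equation residual covariance is estimated, and the stacked system
#' is re-estimated by GLS. With identical regressor sets in both equations
#' the FGLS estimates coincide with equation-by-equation least squares (the
#' classical Kruskal identity), but the joint covariance still reflects the
#' residual correlation between cost and QALY equations.
#'
#' @param data completed (no missing modelled fields) analysis data frame.
#' @param spec a [sur_spec()].
#' @return list of class `sur_fit`: `delta_cost`, `delta_qaly` (arm
#'   coefficients), `se_cost`, `se_qaly`, per-equation `coefficients`,
#'   residual covariance `sigma`, full `vcov`, `n`, and `df_residual`.
#' @export
fit_sur <- function(data, spec = sur_spec()) {
  stopifnot(inherits(spec, "sur_spec"))
  used <- c(spec$cost_outcome, spec$qaly_outcome, spec$covariates, spec$arm)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[, used])) {
    stop("missing values among modelled fields; impute or drop first",
         call. = FALSE)
  }
  X <- sur_design(data, spec)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  y <- cbind(cost = data[[spec$cost_outcome]], qaly = data[[spec$qaly_outcome]])

  ols <- qr.coef(qrX, y)                       # p x 2
  resid <- y - X %*% ols
  sigma <- crossprod(resid) / n                # MLE scaling, as usual for FGLS
  sinv <- solve(sigma)

  # stacked GLS, solved as whitened least squares for numerical stability:
  # with Sigma^-1 = U'U (Cholesky), GLS equals OLS of (U x I) y on
  # (U x I) blockdiag(X, X)
  U <- chol(sinv)
  Xstar <- rbind(cbind(U[1, 1] * X, U[1, 2] * X),
                 cbind(matrix(0, n, p), U[2, 2] * X))
  ystar <- c(U[1, 1] * y[, 1] + U[1, 2] * y[, 2], U[2, 2] * y[, 2])
  qs <- qr(Xstar)
  beta <- qr.coef(qs, ystar)
  vc <- matrix(0, 2L * p, 2L * p)
  vc[qs$pivot, qs$pivot] <- chol2inv(qr.R(qs))
  coefs <- matrix(beta, ncol = 2L,
                  dimnames = list(colnames(X), c("cost", "qaly")))

  arm_col <- grep(paste0("^", spec$arm), colnames(X), value = TRUE)
  arm_col <- setdiff(arm_col, "(Intercept)")[1L]
  ai <- match(arm_col, colnames(X))
  structure(list(delta_cost = coefs[ai, "cost"],
                 delta_qaly = coefs[ai, "qaly"],
                 se_cost = sqrt(vc[ai, ai]),
                 se_qaly = sqrt(vc[p + ai, p + ai]),
                 coefficients = coefs, sigma = sigma, vcov = vc,
                 arm_term = arm_col, n = n, df_residual = n - p),
            class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat("SUR fit (n =", x$n, "):\n")
  cat(sprintf("  incremental cost: %.4f (SE %.4f)\n", x$delta_cost, x$se_cost))
  cat(sprintf("  incremental QALY: %.6f (SE %.6f)\n", x$delta_qaly,
              x$se_qaly))
  invisible(x)
}

#' Bootstrap cloud of incremental costs and effects
#'
#' Resamples participants (whole rows) with replacement, stratified by arm
#' so the per-arm sample sizes are preserved, and evaluates a
#' pipeline statistic on each replicate. Replicates on which the statistic
#' fails are recorded; the run aborts if more than 1% fail.
#'
#' @param data analysis data frame (one row per participant).
#' @param statistic function `data -> named numeric vector` (typically
#'   `c(delta_cost=, delta_qaly=)`).
#' @param B number of replicates (>= 1); 5000 in the analyses this package
#'   reproduces.
#' @param seed integer seed; identical seeds give identical clouds.
#' @param strata column name used for stratified resampling, or `NULL` for
#'   simple resampling.
#' @return object of class `bootstrap_cloud`: `replicates` (B x p matrix),
#'   `B`, `seed`, `n_failed`.
#' @export
bootstrap_cloud <- function(data, statistic, B = 5000L, seed = 1L,
                            strata = "arm") {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be >= 1", call. = FALSE)
  set.seed(seed)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(nrow(data)))
                    else split(seq_len(nrow(data)), data[[strata]])
  reps <- vector("list", B)
  failed <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_stratum, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    val <- tryCatch(statistic(data[take, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val) || anyNA(val)) {
      failed <- failed + 1L
      reps[[b]] <- NULL
    } else {
      reps[[b]] <- val
    }
  }
  if (failed > 0.01 * B) {
    stop("bootstrap aborted: ", failed, " of ", B,
         " replicates failed (> 1%)", call. = FALSE)
  }
  ok <- !vapply(reps, is.null, logical(1))
  mat <- do.call(rbind, reps[ok])
  structure(list(replicates = mat, B = sum(ok), seed = seed,
                 n_failed = failed), class = "bootstrap_cloud")
}

#' @export
print.bootstrap_cloud <- function(x, ...) {
  cat("Bootstrap cloud:", x$B, "replicates of",
      paste(colnames(x$replicates), collapse = ", "),
      if (x$n_failed) paste0("(", x$n_failed, " failed)"), "\n")
  invisible(x)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' The bias constant \eqn{z_0} is the normal quantile of the fraction of
#' replicates below the point estimate; the acceleration \eqn{a} is the
#' jackknife skewness
#' \eqn{a = \sum (\bar\theta - \theta_i)^3 / (6 [\sum (\bar\theta -
#' \theta_i)^2]^{3/2})}. Adjusted percentile levels
#' \eqn{\alpha_j^* = \Phi(z_0 + (z_0+z_j)/(1 - a(z_0+z_j)))} are applied to
#' the empirical replicate distribution; endpoints are order statistics of
#' the cloud. With \eqn{z_0 = 0} and \eqn{a = 0} the interval reduces to
#' the percentile interval.
#'
#' @param cloud numeric vector of bootstrap replicates.
#' @param point point estimate on the original data.
#' @param jackknife leave-one-out estimates for the acceleration; `NULL`
#'   sets `a = 0`.
#' @param level confidence level (default 0.95; needs >= 100 replicates).
#' @param z0,a optional forced values overriding the computed constants.
#' @return numeric `c(lower, upper)` with attributes `z0` and `a`.
#' @export
bca_interval <- function(cloud, point, jackknife = NULL, level = 0.95,
                         z0 = NULL, a = NULL) {
  cloud <- cloud[is.finite(cloud)]
  B <- length(cloud)
  if (B < 100L && is.null(z0)) {
    stop("need >= 100 replicates for a BCa interval", call. = FALSE)
  }
  if (max(cloud) - min(cloud) < .Machine$double.eps * max(1, abs(point))) {
    v <- cloud[1L]
    return(structure(c(lower = v, upper = v), z0 = 0, a = 0))
  }
  if (is.null(z0)) {
    frac <- mean(cloud < point)
    if (frac <= 0 || frac >= 1) {
      warning("point estimate outside the bootstrap distribution; ",
              "bias constant clamped")
      frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
    }
    z0 <- stats::qnorm(frac)
  }
  if (is.null(a)) {
    a <- if (is.null(jackknife)) 0 else {
      d <- mean(jackknife) - jackknife
      denom <- sum(d^2)^1.5
      if (denom <= 0) 0 else sum(d^3) / (6 * denom)
    }
  }
  zq <- stats::qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  s <- sort(cloud)
  # inverse-ECDF rank; round before ceiling to absorb pnorm/qnorm float noise
  pick <- function(alpha) s[min(max(1L, ceiling(round(alpha * B, 9))), B)]
  structure(c(lower = pick(adj[1L]), upper = pick(adj[2L])), z0 = z0, a = a)
}

#' Percentile bootstrap interval
#'
#' Order-statistic (inverse-ECDF) percentile endpoints; equivalent to
#' [bca_interval()] with `z0 = 0`, `a = 0`.
#'
#' @inheritParams bca_interval
#' @export
percentile_interval <- function(cloud, level = 0.95) {
  bca_interval(cloud, point = stats::median(cloud), level = level,
               z0 = 0, a = 0)
}

#' Leave-one-out estimates for the BCa acceleration
#'
#' Jackknife is by participant (whole rows), matching the bootstrap
#' resampling unit.
#'
#' @param data analysis data frame.
#' @param statistic function `data -> named numeric vector`.
#' @return matrix n x p of leave-one-out statistics.
#' @export
jackknife_estimates <- function(data, statistic) {
  n <- nrow(data)
  template <- statistic(data)
  res <- vapply(seq_len(n),
                function(i) statistic(data[-i, , drop = FALSE]), template)
  if (length(template) == 1L) matrix(res, ncol = 1L,
                                     dimnames = list(NULL, names(template)))
  else t(res)
}

#' Mixed model for repeated pain scores (exchangeable covariance)
#'
#' GLS with compound-symmetry covariance (common variance, common
#' within-person correlation rho) for follow-up pain NRS, adjusted for
#' baseline covariates, with a separate arm effect at each visit. Estimated
#' by REML via [nlme::gls()]; a rho estimate outside the feasible range is
#' clipped by the optimiser's parameterisation.
#'
#' @param long data frame in long format: one row per participant-visit
#'   with columns `id`, `visit` (factor), `pain`, `arm`, plus covariates.
#' @param covariates baseline adjustment covariates (default: the clinical
#'   model list).
#' @return list of class `pain_model`: `arm_effects` (data frame
#'   visit/estimate/se), `rho`, and the underlying `gls` fit.
#' @export
fit_pain_mixed_model <- function(long,
                                 covariates = c("pain_nrs_0", "analgesic",
                                                "grip_strength", "bmi",
                                                "age", "gender")) {
  need <- c("id", "visit", "pain", "arm", covariates)
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  long <- long[stats::complete.cases(long[, need]), , drop = FALSE]
  long$visit <- factor(long$visit)
  long$arm <- factor(long$arm, levels = c("control", "intervention"))
  fml <- stats::as.formula(paste(
    "pain ~ visit +", paste(covariates, collapse = " + "), "+ visit:arm"))
  fit <- nlme::gls(fml, data = long,
                   correlation = nlme::corCompSymm(form = ~ 1 | id),
                   method = "REML")
  rho <- as.numeric(stats::coef(fit$modelStruct$corStruct,
                                unconstrained = FALSE))
  co <- stats::coef(fit)
  vc <- stats::vcov(fit)
  visits <- levels(long$visit)
  terms <- paste0("visit", visits, ":armintervention")
  found <- terms %in% names(co)
  arm_effects <- data.frame(visit = visits[found],
                            estimate = co[terms[found]],
                            se = sqrt(diag(vc)[terms[found]]),
                            row.names = NULL)
  structure(list(arm_effects = arm_effects, rho = rho, fit = fit),
            class = "pain_model")
}

#' Reshape wide trial data to long pain format
#'
#' @param data canonical wide data frame with `pain_nrs_6`, `pain_nrs_12`.
#' @return long data frame for [fit_pain_mixed_model()].
#' @export
pain_long <- function(data) {
  base <- data[, intersect(c("id", "arm", "pain_nrs_0", "analgesic",
                             "grip_strength", "bmi", "age", "gender"),
                           names(data))]
  out <- rbind(cbind(base, visit = "6", pain = data$pain_nrs_6),
               cbind(base, visit = "12", pain = data$pain_nrs_12))
  out$visit <- factor(out$visit, levels = c("6", "12"))
  out
}
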