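# Synthetic two-arm trial generator. Emulates the statistical structure the
# downstream analysis assumes -- balanced 1:1 randomisation, EQ-5D-5L
# profiles whose scored utilities follow a bounded right-tailed distribution
# (mean ~0.61, SD ~0.18 at baseline), right-skewed resource-use counts
# (SD > mean), category-coded medication use, study-drug exposure, and
# missingness rising from ~1% at baseline to ~25% at 12 months -- so the
# whole pipeline is testable without any patient-level trial data.
#
# Arm effects are calibrated analytically: the intervention arm's follow-up
# utility means are shifted by delta_qaly / 0.75 (the AUC weight of the two
# follow-up visits) and its follow-up resource-count means are scaled by a
# single multiplier chosen so that the expected NHS/PSS total-cost contrast
# (including expected study-drug cost and the configured medication-cost
# contrast) equals `true_delta_cost` exactly.

#' Configuration for the synthetic trial generator
#'
#' Defaults reproduce the study conditions the package targets: 124
#' participants per arm, baseline utility mean 0.613 (SD 0.178) in both
#' arms, follow-up utility gain ~0.026, a true incremental cost of -11.80
#' pounds and true incremental QALYs of -0.0052 (intervention minus
#' control), per-visit resource-count means taken from the control-arm
#' descriptives of the emulated trial, medication-cost means of 282.16
#' (intervention) and 300.17 (control) pounds, study-drug dosing 200/300/400
#' mg in proportions 7/85/32 of 124 with 90/124 completing 365 days, and
#' visit-level questionnaire missingness of roughly 1%/16%/24% at 0/6/12
#' months made weakly monotone over visits.
#'
#' @param n_per_arm participants per arm (>= 2).
#' @param true_delta_cost target expected NHS/PSS cost contrast, pounds.
#' @param true_delta_qaly target expected QALY contrast.
#' @param baseline_utility_mean,baseline_utility_sd scored-utility moments
#'   at baseline (both arms).
#' @param followup_utility_gain mean utility change from baseline to both
#'   follow-up visits (both arms; the arm shift is added on top).
#' @param utility_floor lower bound of the scaled-beta utility scale; should
#'   not exceed the tariff floor.
#' @param utility_autocorr latent (Gaussian-copula) correlation between a
#'   participant's utilities at different visits.
#' @param utility_pain_coef latent loading of standardised baseline pain on
#'   utility (negative: more pain, lower utility). Its square must not
#'   exceed `utility_autocorr`.
#' @param pd_marginal length-5 probability vector for the pain/discomfort
#'   dimension level (applied at every visit); the default places ~99% of
#'   participants above level 1.
#' @param pd_utility_cor rank correlation between pain/discomfort severity
#'   and (negated) utility.
#' @param tariff `eq5d_tariff` used to invert utilities into level profiles
#'   (default: the packaged synthetic decrement tariff).
#' @param unit_costs,medication_costs costing tables used to calibrate the
#'   intervention cost multiplier (defaults: packaged tables).
#' @param count_means 13 x 3 matrix of control-arm mean counts per resource
#'   item (rows, in [resource_items()] order) and visit (0/6/12 months).
#' @param count_dispersion negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param frailty_sd,frailty_pain_coef log-scale SD of the mean-one
#'   person-level use multiplier and the share of it loading on baseline
#'   pain.
#' @param med_use_rates per-interval Poisson rates of category use (names
#'   must exist in `medication_costs`).
#' @param med_cost_mean named vector `c(intervention=, control=)` of target
#'   expected 12-month medication costs, pounds.
#' @param hcq_dose_probs probabilities of daily dose 200/300/400 mg.
#' @param hcq_full_duration_prob probability of 365 days on drug; otherwise
#'   duration is uniform on `hcq_partial_range`.
#' @param hcq_partial_range days range for early stoppers.
#' @param expense_params list per personal-expense component (`otc`,
#'   `childcare`, `travel`) of `c(p_nonzero, mean_nonzero, shape)` for the
#'   per-visit zero-inflated gamma.
#' @param pain_delta intervention effect on follow-up pain NRS (positive =
#'   worse pain).
#' @param pain_trend mean drift of follow-up pain relative to its
#'   baseline-driven prediction.
#' @param pain_resid_sd residual SD of follow-up pain before rounding.
#' @param missing_rates list: `eq5d` and `resource` are length-3 per-visit
#'   masking probabilities (0/6/12 months); `other_item_soft` /
#'   `other_item_hard` are person-level blank-proneness probabilities for
#'   the free-text "other" resource items; `coupling` (between 0 and 1) is the
#'   probability that the resource-block mask copies the EQ-5D-block mask
#'   at a visit (the joint pattern across instruments is not identified by
#'   published marginals, so it is a knob); `monotone_boost` is the
#'   log-odds increase at a visit when the previous visit was missing.
#' @param mar_coefficients named log-odds-per-SD weights linking masking to
#'   always-observed baseline fields (allowed names: `age`, `bmi`, `pain`,
#'   `grip`, `gender`, `analgesic`).
#' @param covariate_params list of baseline covariate parameters (see
#'   defaults in the function signature).
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    n_per_arm = 124L,
    true_delta_cost = -11.80,
    true_delta_qaly = -0.0052,
    baseline_utility_mean = 0.613,
    baseline_utility_sd = 0.178,
    followup_utility_gain = 0.026,
    utility_floor = -0.59,
    utility_autocorr = 0.60,
    utility_pain_coef = -0.25,
    pd_marginal = c(0.012, 0.113, 0.617, 0.234, 0.024),
    pd_utility_cor = 0.5,
    tariff = NULL,
    unit_costs = NULL,
    medication_costs = NULL,
    count_means = NULL,
    count_dispersion = 0.6,
    frailty_sd = 0.5,
    frailty_pain_coef = 0.4,
    med_use_rates = c(oral_opioid = 0.5, oral_nsaid = 0.8,
                      topical_nsaid = 0.9, antidepressant_neuropathic = 0.35,
                      simple_analgesic = 1.2, other_medication = 0.45),
    med_cost_mean = c(intervention = 282.16, control = 300.17),
    hcq_dose_probs = c(`200` = 7, `300` = 85, `400` = 32) / 124,
    hcq_full_duration_prob = 90 / 124,
    hcq_partial_range = c(15, 308),
    expense_params = list(otc = c(p_nonzero = 0.50, mean_nonzero = 24.3,
                                  shape = 1.0),
                          childcare = c(p_nonzero = 0.03, mean_nonzero = 50,
                                        shape = 1.0),
                          travel = c(p_nonzero = 0.45, mean_nonzero = 16.5,
                                     shape = 1.0)),
    pain_delta = 0.16,
    pain_trend = -0.3,
    pain_resid_sd = 1.8,
    missing_rates = list(eq5d = c(0.012, 0.157, 0.238),
                         resource = c(0.015, 0.165, 0.245),
                         other_item_soft = 0.07,
                         other_item_hard = 0.35,
                         coupling = 0.5,
                         monotone_boost = 1.0),
    mar_coefficients = c(age = 0.3, pain = 0.4),
    covariate_params = list(age_mean = 62.7, age_sd = 10,
                            age_range = c(40, 88), prop_female = 0.819,
                            bmi_mean = 28, bmi_sd = 5,
                            grip_mean = 20, grip_sd = 8,
                            analgesic_prob = 0.7,
                            pain_mean = 6.9, pain_sd = 1.6,
                            pain_range = c(4, 10)),
    seed = 1L) {
  if (is.null(tariff)) tariff <- load_tariff(
    system.file("extdata", "tariff_synthetic_decrements.csv",
                package = "trialcea"), name = "synthetic-decrements")
  if (is.null(unit_costs)) unit_costs <- load_unit_costs()
  if (is.null(medication_costs)) medication_costs <- load_medication_costs()
  if (is.null(count_means)) count_means <- default_count_means()

  n_per_arm <- as.integer(n_per_arm)
  if (is.na(n_per_arm) || n_per_arm < 2L) {
    stop("n_per_arm must be an integer >= 2", call. = FALSE)
  }
  if (baseline_utility_sd < 0) stop("baseline_utility_sd must be >= 0",
                                    call. = FALSE)
  probs <- c(pd_marginal, hcq_dose_probs, hcq_full_duration_prob,
             missing_rates$eq5d, missing_rates$resource,
             missing_rates$other_item_soft, missing_rates$other_item_hard,
             missing_rates$coupling,
             vapply(expense_params, `[[`, numeric(1), "p_nonzero"),
             covariate_params$prop_female, covariate_params$analgesic_prob)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(pd_marginal) - 1) > 1e-8) {
    stop("pd_marginal must sum to 1", call. = FALSE)
  }
  if (length(missing_rates$eq5d) != 3L || length(missing_rates$resource) != 3L) {
    stop("missing_rates$eq5d and $resource must have one rate per visit",
         call. = FALSE)
  }
  if (utility_pain_coef^2 > utility_autocorr) {
    stop("utility_pain_coef^2 must not exceed utility_autocorr",
         call. = FALSE)
  }
  check_mar_coefficients(mar_coefficients)
  stopifnot(inherits(tariff, "eq5d_tariff"),
            all(resource_items() %in% rownames(count_means)),
            ncol(count_means) == 3L, all(count_means >= 0),
            count_dispersion > 0, frailty_sd >= 0,
            all(med_use_rates >= 0),
            all(names(med_use_rates) %in% names(medication_costs)),
            all(med_cost_mean >= 0),
            all(c("intervention", "control") %in% names(med_cost_mean)))
  structure(as.list(environment()), class = "generator_config")
}

# Control-arm mean counts per resource item (rows) and visit 0/6/12 months
# (columns), shaped like the emulated trial's available-case descriptives.
default_count_means <- function() {
  m <- rbind(
    hospital_outpatient    = c(1.51, 1.08, 1.29),
    a_and_e                = c(0.06, 0.09, 0.03),
    other_outpatient_1     = c(0.71, 0.33, 0.40),
    other_outpatient_2     = c(0.11, 0.13, 0.25),
    gp_practice            = c(1.95, 1.28, 1.67),
    gp_home                = c(0.02, 0.01, 0.02),
    nurse_practice         = c(0.42, 0.48, 0.64),
    other_primary_1        = c(0.15, 0.09, 0.07),
    other_primary_2        = c(0.01, 0.01, 0.005),
    physiotherapist        = c(0.69, 0.30, 0.32),
    occupational_therapist = c(0.12, 0.08, 0.03),
    other_community_1      = c(0.40, 0.08, 0.05),
    other_community_2      = c(0.01, 0.01, 0.01))
  colnames(m) <- c("0", "6", "12")
  m
}

MAR_FIELDS <- c("age", "bmi", "pain", "grip", "gender", "analgesic")

check_mar_coefficients <- function(coefs) {
  if (length(coefs) == 0L) return(invisible(TRUE))
  if (is.null(names(coefs)) || any(!nzchar(names(coefs)))) {
    stop("mar_coefficients must be named", call. = FALSE)
  }
  bad <- setdiff(names(coefs), MAR_FIELDS)
  if (length(bad)) {
    stop("mar_coefficients may only reference always-observed baseline ",
         "fields (", paste(MAR_FIELDS, collapse = ", "), "); masking driven ",
         "by maskable fields would make the data missing not at random: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Beta parameters on [floor, 1] from a target mean and SD.
beta_shapes <- function(mean, sd, floor) {
  m <- (mean - floor) / (1 - floor)
  s <- sd / (1 - floor)
  if (m <= 0 || m >= 1) stop("utility mean outside the (floor, 1) interval",
                             call. = FALSE)
  nu <- m * (1 - m) / s^2 - 1
  if (nu <= 0) stop("utility SD too large for a beta on [floor, 1]",
                    call. = FALSE)
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

# For each pain/discomfort level, the 625 states sharing it, ordered by
# tariff utility, with runs of tied utilities for random tie-breaking.
build_pd_lookup <- function(tariff) {
  states <- eq5d_all_states()
  lapply(1:5, function(p) {
    idx <- which(states[, "PD"] == p)
    u <- tariff$utilities[idx]
    o <- order(u)
    su <- u[o]
    uv <- unique(su)
    run_start <- match(uv, su)
    run_len <- c(diff(run_start), length(su) - run_start[length(uv)] + 1L)
    list(state_idx = idx[o], sorted_u = su, unique_u = uv,
         mids = (uv[-1] + uv[-length(uv)]) / 2,
         run_start = run_start, run_len = run_len)
  })
}

# Map target utilities + pain/discomfort levels to full EQ-5D profiles:
# nearest tariff value among states with that PD level, ties broken
# uniformly at random. Returns an n x 5 integer matrix.
nearest_profile <- function(u, pd_level, lookup) {
  n <- length(u)
  out <- integer(n)
  for (p in 1:5) {
    sel <- which(pd_level == p)
    if (!length(sel)) next
    lk <- lookup[[p]]
    k <- findInterval(u[sel], lk$mids) + 1L
    pick <- lk$run_start[k] + floor(stats::runif(length(sel)) * lk$run_len[k])
    out[sel] <- lk$state_idx[pick]
  }
  eq5d_all_states()[out, , drop = FALSE]
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws `2 * n_per_arm` participant records with the column conventions the
#' pipeline consumes (one wide row per participant; see Details), applies
#' missing-at-random masking via [apply_mar_missingness()] after all
#' outcomes are generated, and retains the complete (pre-masking) data for
#' recovery tests.
#'
#' @details Columns: `id`, `arm`, baseline covariates (`age`, `gender`,
#' `bmi`, `pain_nrs_0`, `grip_strength`, `analgesic`), EQ-5D-5L levels
#' `eq5d_<dim>_<t>` for dim `mo`,`sc`,`ua`,`pd`,`ad` and t `0`,`6`,`12`,
#' `vas_<t>`, resource counts `rc_<item>_<t>`, follow-up pain `pain_nrs_6`,
#' `pain_nrs_12`, study-drug `hcq_dose_mg`/`hcq_days` (`NA`/0 in control),
#' medication interval counts `med_<category>`, and per-visit personal
#' expenses `exp_otc_<t>`, `exp_childcare_<t>`, `exp_travel_<t>`.
#'
#' @param config a [generator_config()].
#' @return list of class `trial_data`: `data` (masked), `complete`
#'   (pre-masking), `config`, and `truth` (generating parameters including
#'   the calibrated utility shift and cost multiplier).
#' @export
generate_trial <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_arm <- config$n_per_arm
  n <- 2L * n_arm
  arm <- rep(c("intervention", "control"), each = n_arm)
  cp <- config$covariate_params

  age <- pmin(pmax(stats::rnorm(n, cp$age_mean, cp$age_sd),
                   cp$age_range[1]), cp$age_range[2])
  gender <- ifelse(stats::runif(n) < cp$prop_female, "F", "M")
  bmi <- pmax(stats::rnorm(n, cp$bmi_mean, cp$bmi_sd), 15)
  grip <- pmax(stats::rnorm(n, cp$grip_mean, cp$grip_sd), 1)
  analgesic <- stats::runif(n) < cp$analgesic_prob
  pain0 <- pmin(pmax(round(stats::rnorm(n, cp$pain_mean, cp$pain_sd)),
                     cp$pain_range[1]), cp$pain_range[2])
  pain_std <- as.numeric(scale(pain0))
  if (any(!is.finite(pain_std))) pain_std <- rep(0, n)

  ## --- utilities via a Gaussian copula over scaled betas -----------------
  delta_u <- config$true_delta_qaly / 0.75  # AUC weight of follow-up visits
  b <- config$utility_pain_coef
  a <- sqrt(config$utility_autocorr - b^2)
  c_res <- sqrt(1 - config$utility_autocorr)
  w <- stats::rnorm(n)
  z <- sapply(1:3, function(v) b * pain_std + a * w + c_res * stats::rnorm(n))
  fl <- config$utility_floor
  mean_fu <- config$baseline_utility_mean + config$followup_utility_gain
  u_target <- matrix(NA_real_, n, 3L)
  for (v in 1:3) {
    mu <- if (v == 1L) rep(config$baseline_utility_mean, n)
          else mean_fu + delta_u * (arm == "intervention")
    # two beta laws per follow-up visit (one per arm): exact mean shift
    for (m_val in unique(mu)) {
      sh <- beta_shapes(m_val, config$baseline_utility_sd, fl)
      sel <- mu == m_val
      u_target[sel, v] <- fl + (1 - fl) *
        stats::qbeta(stats::pnorm(z[sel, v]), sh[1L], sh[2L])
    }
  }

  ## --- EQ-5D profiles: PD level by copula, other dims by tariff match ---
  lookup <- build_pd_lookup(config$tariff)
  cum_pd <- cumsum(config$pd_marginal)
  rho <- config$pd_utility_cor
  eq5d <- vector("list", 3L)
  for (v in 1:3) {
    v_pd <- stats::pnorm(rho * (-z[, v]) +
                           sqrt(1 - rho^2) * stats::rnorm(n))
    pd_level <- findInterval(v_pd, cum_pd, rightmost.closed = TRUE) + 1L
    pd_level <- pmin(pd_level, 5L)
    eq5d[[v]] <- nearest_profile(u_target[, v], pd_level, lookup)
  }

  vas <- sapply(1:3, function(v) {
    pmin(pmax(round(72 + 40 * (u_target[, v] - 0.61) + stats::rnorm(n, 0, 9)),
              0), 100)
  })

  ## --- study drug --------------------------------------------------------
  hcq_dose <- rep(NA_real_, n)
  hcq_days <- rep(NA_real_, n)
  int_idx <- which(arm == "intervention")
  hcq_dose[int_idx] <- sample(c(200, 300, 400), length(int_idx),
                              replace = TRUE, prob = config$hcq_dose_probs)
  full <- stats::runif(length(int_idx)) < config$hcq_full_duration_prob
  pr <- config$hcq_partial_range
  hcq_days[int_idx] <- ifelse(full, 365,
                              round(stats::runif(length(int_idx),
                                                 pr[1], pr[2])))
  dcfg <- drug_cost_config()
  e_tablets <- sum(config$hcq_dose_probs * c(200, 300, 400)) /
    dcfg$tablet_strength_mg  # expected tablets per day
  e_days <- config$hcq_full_duration_prob * 365 +
    (1 - config$hcq_full_duration_prob) * mean(pr)
  e_drug <- e_days * e_tablets * dcfg$pack_price / dcfg$tablets_per_pack

  ## --- resource counts ---------------------------------------------------
  items <- resource_items()
  cm <- config$count_means[items, , drop = FALSE]
  uc <- as.numeric(config$unit_costs)[match(items, names(config$unit_costs))]
  e_hc_control <- sum((cm[, "6"] + cm[, "12"]) * uc)
  delta_med <- config$med_cost_mean[["intervention"]] -
    config$med_cost_mean[["control"]]
  hc_mult <- 1 + (config$true_delta_cost - e_drug - delta_med) / e_hc_control
  if (hc_mult < 0) {
    stop("true_delta_cost unattainable: implied healthcare multiplier < 0",
         call. = FALSE)
  }
  kf <- config$frailty_pain_coef
  g <- kf * pain_std + sqrt(1 - kf^2) * stats::rnorm(n)
  frailty <- exp(config$frailty_sd * g - config$frailty_sd^2 / 2)
  counts <- list()
  for (v in c("0", "6", "12")) {
    amul <- if (v == "0") rep(1, n)
            else ifelse(arm == "intervention", hc_mult, 1)
    for (it in items) {
      mu <- cm[it, v] * amul * frailty
      counts[[paste0("rc_", it, "_", v)]] <-
        stats::rnbinom(n, size = config$count_dispersion, mu = mu)
    }
  }

  ## --- medications -------------------------------------------------------
  rates <- config$med_use_rates
  cat_cost <- config$medication_costs[names(rates)]
  e_interval_cost <- sum(rates * cat_cost)
  med <- list()
  scale_arm <- config$med_cost_mean[match(arm, names(config$med_cost_mean))] /
    (4 * e_interval_cost)
  for (cat in names(rates)) {
    med[[paste0("med_", cat)]] <-
      stats::rpois(n, 4 * rates[[cat]] * scale_arm * frailty)
  }

  ## --- personal expenses (zero-inflated gamma, equal arms) ---------------
  expenses <- list()
  for (comp in names(config$expense_params)) {
    pp <- config$expense_params[[comp]]
    for (v in c("0", "6", "12")) {
      nz <- stats::runif(n) < pp[["p_nonzero"]]
      val <- ifelse(nz,
                    stats::rgamma(n, shape = pp[["shape"]],
                                  scale = pp[["mean_nonzero"]] / pp[["shape"]]),
                    0)
      expenses[[paste0("exp_", comp, "_", v)]] <- round(val, 2)
    }
  }

  ## --- follow-up pain ----------------------------------------------------
  pain_fu <- function() {
    raw <- 0.6 * pain0 + 0.4 * cp$pain_mean + config$pain_trend +
      config$pain_delta * (arm == "intervention") +
      stats::rnorm(n, 0, config$pain_resid_sd)
    pmin(pmax(round(raw), 0), 10)
  }
  pain6 <- pain_fu()
  pain12 <- pain_fu()

  dims <- c("mo", "sc", "ua", "pd", "ad")
  eq_cols <- list()
  for (v in 1:3) {
    t_lab <- c("0", "6", "12")[v]
    for (d in 1:5) {
      eq_cols[[paste0("eq5d_", dims[d], "_", t_lab)]] <- eq5d[[v]][, d]
    }
    eq_cols[[paste0("vas_", t_lab)]] <- vas[, v]
  }

  complete <- data.frame(
    id = sprintf("P%04d", seq_len(n)), arm = arm, age = round(age, 1),
    gender = gender, bmi = round(bmi, 1), pain_nrs_0 = pain0,
    grip_strength = round(grip, 1), analgesic = analgesic,
    eq_cols, pain_nrs_6 = pain6, pain_nrs_12 = pain12, counts,
    hcq_dose_mg = hcq_dose, hcq_days = hcq_days, med, expenses,
    stringsAsFactors = FALSE, check.names = FALSE)

  masked <- apply_mar_missingness(complete, config$missing_rates,
                                  config$mar_coefficients,
                                  seed = config$seed + 1L)

  truth <- list(true_delta_cost = config$true_delta_cost,
                true_delta_qaly = config$true_delta_qaly,
                utility_shift = delta_u, hc_multiplier = hc_mult,
                expected_drug_cost = e_drug,
                expected_control_healthcare_cost = e_hc_control,
                pain_delta = config$pain_delta, seed = config$seed)
  structure(list(data = masked, complete = complete, config = config,
                 truth = truth),
            class = "trial_data")
}

#' Apply missing-at-random masking to complete trial records
#'
#' Masks whole questionnaire blocks per visit: the EQ-5D block (five
#' dimensions, VAS, and follow-up pain NRS) and the resource block (resource
#' counts and personal expenses). Masking probability at each visit depends
#' only on always-observed baseline fields through `mar_coefficients`
#' (missing-at-random by construction) plus, optionally, on the previous
#' visit's missingness (weak monotonicity). Logistic intercepts are
#' calibrated numerically so the marginal per-visit rate matches the
#' configured rate despite covariate and carry-over terms. Person-level
#' blank-proneness additionally masks the free-text "other" resource items
#' across all visits. Baseline covariates (including baseline pain) are
#' never masked.
#'
#' @param data complete canonical wide data frame.
#' @param missing_rates,mar_coefficients see [generator_config()].
#' @param seed RNG seed (masking only).
#' @return the data frame with masked cells set to `NA`.
#' @export
apply_mar_missingness <- function(data,
                                  missing_rates = generator_config()$missing_rates,
                                  mar_coefficients = c(age = 0.3, pain = 0.4),
                                  seed = 1L) {
  check_mar_coefficients(mar_coefficients)
  rates_all <- c(missing_rates$eq5d, missing_rates$resource,
                 missing_rates$other_item_soft, missing_rates$other_item_hard)
  if (any(rates_all < 0 | rates_all > 1)) {
    stop("missing rates must lie in [0, 1]", call. = FALSE)
  }
  if (all(rates_all == 0)) return(data)
  set.seed(seed)
  n <- nrow(data)

  std <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  covs <- cbind(age = std(data$age), bmi = std(data$bmi),
                pain = std(data$pain_nrs_0), grip = std(data$grip_strength),
                gender = std(data$gender == "F"),
                analgesic = std(as.numeric(data$analgesic)))
  lp_mar <- if (length(mar_coefficients)) {
    as.numeric(covs[, names(mar_coefficients), drop = FALSE] %*%
                 mar_coefficients)
  } else rep(0, n)

  # intercept calibrated so mean masking probability equals the target rate
  draw_mask <- function(rate, extra_lp) {
    if (rate <= 0) return(rep(FALSE, n))
    if (rate >= 1) return(rep(TRUE, n))
    lp <- lp_mar + extra_lp
    f <- function(o) mean(stats::plogis(o + lp)) - rate
    o <- stats::uniroot(f, c(stats::qlogis(rate) - 10,
                             stats::qlogis(rate) + 10))$root
    stats::runif(n) < stats::plogis(o + lp)
  }

  boost <- missing_rates$monotone_boost %||% 0
  coupling <- missing_rates$coupling %||% 0
  dims <- c("mo", "sc", "ua", "pd", "ad")
  prev_eq <- rep(FALSE, n)
  prev_rc <- rep(FALSE, n)
  for (v in seq_along(c("0", "6", "12"))) {
    t_lab <- c("0", "6", "12")[v]
    m_eq <- draw_mask(missing_rates$eq5d[v], boost * prev_eq)
    copy <- stats::runif(n) < coupling
    m_rc_own <- draw_mask(missing_rates$resource[v], boost * prev_rc)
    m_rc <- ifelse(copy, m_eq, m_rc_own)
    eq_cols <- c(paste0("eq5d_", dims, "_", t_lab), paste0("vas_", t_lab))
    if (t_lab != "0") eq_cols <- c(eq_cols, paste0("pain_nrs_", t_lab))
    rc_cols <- c(grep(paste0("^rc_.*_", t_lab, "$"), names(data),
                      value = TRUE),
                 grep(paste0("^exp_.*_", t_lab, "$"), names(data),
                      value = TRUE))
    data[m_eq, intersect(eq_cols, names(data))] <- NA
    data[m_rc, intersect(rc_cols, names(data))] <- NA
    prev_eq <- m_eq
    prev_rc <- m_rc
  }

  # person-level blank-proneness on free-text "other" items, all visits
  soft <- stats::runif(n) < (missing_rates$other_item_soft %||% 0)
  hard <- stats::runif(n) < (missing_rates$other_item_hard %||% 0)
  soft_items <- c("other_outpatient_1", "other_primary_1", "other_community_1")
  hard_items <- c("other_outpatient_2", "other_primary_2", "other_community_2")
  for (t_lab in c("0", "6", "12")) {
    data[soft, intersect(paste0("rc_", soft_items, "_", t_lab),
                         names(data))] <- NA
    data[hard, intersect(paste0("rc_", hard_items, "_", t_lab),
                         names(data))] <- NA
  }
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the canonical participant CSV
#'
#' One wide row per participant; missing values are empty fields. For a
#' `trial_data` object the true generating parameters are written next to
#' the CSV as `<path>.truth.json` so recovery tests can reload them.
#'
#' @param x a `trial_data` object or canonical data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  df <- if (inherits(x, "trial_data")) x$data else x
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (inherits(x, "trial_data")) {
    jsonlite::write_json(x$truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("analgesic" %in% names(df)) df$analgesic <- as.logical(df$analgesic)
  df
}

#' @export
print.trial_data <- function(x, ...) {
  n <- nrow(x$data)
  cat("Synthetic trial dataset:", n, "participants (",
      sum(x$data$arm == "intervention"), "intervention /",
      sum(x$data$arm == "control"), "control ), seed", x$truth$seed, "\n")
  cat("  target contrasts: cost", x$truth$true_delta_cost,
      "GBP, QALY", x$truth$true_delta_qaly, "\n")
  invisible(x)
}
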