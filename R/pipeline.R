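# End-to-end orchestration: scoring -> costing -> (imputation) ->
# SUR estimation -> bootstrap uncertainty -> decision outputs, for the
# base-case intention-to-treat analysis with multiple imputation, the
# societal-perspective secondary analysis, and the complete-case
# sensitivity analysis.

ANALYSIS_IMPUTABLE <- c("u0", "u6", "u12", "hc0", "hc6", "hc12",
                        "ext0", "ext6", "ext12",
                        "pain_nrs_6", "pain_nrs_12")

#' Build the participant-level analysis dataset
#'
#' Scores EQ-5D-5L responses at each visit against the tariff, costs
#' resource use per visit, study drug and medications, and assembles one
#' row per participant with utilities (`u0`, `u6`, `u12`), per-visit
#' healthcare costs (`hc0`, `hc6`, `hc12`), per-visit personal expenses
#' (`ext0`, `ext6`, `ext12`), medication and drug costs, pain scores and
#' baseline covariates. Aggregates (QALY, total cost) are NOT computed
#' here: the base case imputes these components first and aggregates after
#' (see [finalize_analysis_data()]).
#'
#' @param data canonical wide trial data frame.
#' @param tariff an `eq5d_tariff`.
#' @param unit_costs,medication_costs,drug_config costing inputs.
#' @return analysis data frame, one row per participant.
#' @export
build_analysis_data <- function(data,
                                tariff = load_tariff(system.file(
                                  "extdata", "tariff_synthetic_decrements.csv",
                                  package = "trialcea")),
                                unit_costs = load_unit_costs(),
                                medication_costs = load_medication_costs(),
                                drug_config = drug_cost_config()) {
  dims <- c("mo", "sc", "ua", "pd", "ad")
  util_at <- function(t) {
    cols <- paste0("eq5d_", dims, "_", t)
    score_eq5d(data[, cols], tariff)
  }
  bd <- cost_breakdown(data, unit_costs, medication_costs, drug_config)
  ext_at <- function(t) {
    cols <- intersect(paste0("exp_", c("otc", "childcare", "travel"), "_", t),
                      names(data))
    if (!length(cols)) return(rep(0, nrow(data)))
    rowSums(data[, cols, drop = FALSE])
  }
  data.frame(id = data$id, arm = factor(data$arm,
                                        levels = c("control", "intervention")),
             age = data$age, gender = data$gender, bmi = data$bmi,
             pain_nrs_0 = data$pain_nrs_0,
             grip_strength = data$grip_strength,
             analgesic = data$analgesic,
             u0 = util_at("0"), u6 = util_at("6"), u12 = util_at("12"),
             hc0 = bd$baseline_healthcare, hc6 = bd$healthcare_6m,
             hc12 = bd$healthcare_12m,
             ext0 = ext_at("0"), ext6 = ext_at("6"), ext12 = ext_at("12"),
             med_cost = bd$medications, drug_cost = bd$drug,
             pain_nrs_6 = data$pain_nrs_6,
             pain_nrs_12 = if ("pain_nrs_12" %in% names(data))
               data$pain_nrs_12 else NA_real_,
             stringsAsFactors = FALSE)
}

#' Aggregate a (completed) analysis dataset for regression
#'
#' Adds `qaly` (trapezoid AUC), `total_cost` for the requested perspective,
#' `baseline_utility` and `baseline_cost` (baseline healthcare cost, plus
#' baseline personal expenses under the societal perspective).
#'
#' @param adata analysis data frame from [build_analysis_data()].
#' @param perspective `"nhs_pss"` or `"societal"`.
#' @return the data frame with aggregate columns added.
#' @export
finalize_analysis_data <- function(adata,
                                   perspective = c("nhs_pss", "societal")) {
  perspective <- match.arg(perspective)
  adata$qaly <- qaly_auc(adata$u0, adata$u6, adata$u12)
  hc_total <- adata$hc6 + adata$hc12
  nhs <- hc_total + adata$drug_cost + adata$med_cost
  adata$total_cost <- if (perspective == "societal")
    nhs + adata$ext6 + adata$ext12 else nhs
  adata$baseline_utility <- adata$u0
  adata$baseline_cost <- if (perspective == "societal")
    adata$hc0 + adata$ext0 else adata$hc0
  adata
}

#' Analysis run configuration
#'
#' @param data canonical wide data frame, or path to a participant CSV.
#' @param perspective `"nhs_pss"` (health-system) or `"societal"` (adds
#'   participant out-of-pocket expenses).
#' @param analysis_population `"itt_mi"` (all randomised, multiple
#'   imputation; the base case), `"complete_case"` (participants with fully
#'   observed economic profiles only), or `"available_case"` (item-wise
#'   descriptives, no inference).
#' @param B bootstrap replicates (default 5000).
#' @param m imputations; `NULL` uses 20 for `itt_mi` and is forbidden
#'   (non-`NULL`) for `complete_case`.
#' @param iterations,pmm_donors chained-equation settings.
#' @param thresholds willingness-to-pay thresholds for net benefit.
#' @param lambda_grid CEAC threshold grid.
#' @param bootstrap_strategy `"boot_then_impute"` (resample participants,
#'   then one stochastic imputation inside each replicate, so imputation
#'   uncertainty propagates into the cloud) or `"impute_then_boot"`
#'   (bootstrap each completed dataset and pool the clouds).
#' @param tariff,unit_costs,medication_costs,drug_config pipeline inputs
#'   (objects or, for the first three, file paths).
#' @param seed master seed; stage seeds (imputation, bootstrap, jackknife)
#'   are derived from it and logged.
#' @param output_dir optional directory for result files (`summary.json`,
#'   `ceac.csv`, `ce_plane.csv`, `cloud.csv`, `availability.csv`,
#'   `log.txt`); nothing is written when `NULL`.
#' @return list of class `run_config`.
#' @export
run_config <- function(data,
                       perspective = c("nhs_pss", "societal"),
                       analysis_population = c("itt_mi", "complete_case",
                                               "available_case"),
                       B = 5000L, m = NULL, iterations = 10L, pmm_donors = 5L,
                       thresholds = c(20000, 30000),
                       lambda_grid = seq(0, 50000, by = 500),
                       bootstrap_strategy = c("boot_then_impute",
                                              "impute_then_boot"),
                       tariff = NULL, unit_costs = NULL,
                       medication_costs = NULL,
                       drug_config = drug_cost_config(),
                       seed = 1L, output_dir = NULL) {
  perspective <- match.arg(perspective)
  analysis_population <- match.arg(analysis_population)
  bootstrap_strategy <- match.arg(bootstrap_strategy)
  if (analysis_population == "complete_case" && !is.null(m)) {
    stop("complete_case analysis forbids imputation settings (m)",
         call. = FALSE)
  }
  if (is.null(m)) m <- 20L
  if (is.character(data)) {
    if (!file.exists(data)) stop("input file not found: ", data,
                                 call. = FALSE)
    data <- read_trial_csv(data)
  }
  load_maybe <- function(x, loader) {
    if (is.null(x)) loader()
    else if (is.character(x)) loader(x)
    else x
  }
  tariff <- if (is.null(tariff)) {
    load_tariff(system.file("extdata", "tariff_synthetic_decrements.csv",
                            package = "trialcea"))
  } else if (is.character(tariff)) load_tariff(tariff) else tariff
  unit_costs <- load_maybe(unit_costs, load_unit_costs)
  medication_costs <- load_maybe(medication_costs, load_medication_costs)
  structure(list(data = data, perspective = perspective,
                 analysis_population = analysis_population,
                 B = as.integer(B), m = as.integer(m),
                 iterations = as.integer(iterations),
                 pmm_donors = as.integer(pmm_donors),
                 thresholds = thresholds, lambda_grid = lambda_grid,
                 bootstrap_strategy = bootstrap_strategy,
                 tariff = tariff, unit_costs = unit_costs,
                 medication_costs = medication_costs,
                 drug_config = drug_config, seed = as.integer(seed),
                 seeds = list(impute = as.integer(seed) + 1000L,
                              boot = as.integer(seed) + 2000L,
                              jack = as.integer(seed) + 3000L),
                 output_dir = output_dir),
            class = "run_config")
}

# One stochastic chained-equation fill using the ambient RNG stream
# (no re-seeding: callers control the stream).
single_imputation <- function(adata, ispec) {
  targets <- intersect(ANALYSIS_IMPUTABLE, names(adata))
  targets <- targets[vapply(adata[, targets, drop = FALSE], anyNA,
                            logical(1))]
  if (!length(targets)) return(adata)
  filled <- adata
  miss_idx <- lapply(adata[, targets, drop = FALSE], is.na)
  for (v in targets) {
    mi <- miss_idx[[v]]
    obs_vals <- filled[[v]][!mi]
    if (!length(obs_vals)) stop("no observed donors for ", v, call. = FALSE)
    filled[[v]][mi] <- sample(obs_vals, sum(mi), replace = TRUE)
  }
  for (it in seq_len(ispec$iterations)) {
    for (v in targets) {
      mi <- miss_idx[[v]]
      X <- impute_design(filled, ispec$model_covariates,
                         setdiff(targets, v))
      filled[[v]][mi] <- pmm_draw(ifelse(mi, NA, as.numeric(adata[[v]])),
                                  X, mi, ispec$pmm_donors)
    }
  }
  filled
}

#' Run the full cost-utility analysis
#'
#' Executes scoring, costing, imputation (for the base case), SUR
#' estimation, bootstrap uncertainty and decision analysis according to the
#' configuration, and optionally writes the result bundle to disk. Point
#' estimates under `itt_mi` pool `m` SUR fits by Rubin's rules; interval
#' estimates are BCa over a participant-resampled bootstrap cloud (with a
#' fresh stochastic imputation inside each replicate under the default
#' strategy). Under `complete_case`, participants with any missing modelled
#' field are excluded and no imputation runs. `available_case` returns
#' item-wise descriptives only.
#'
#' @param config a [run_config()].
#' @return list of class `cea_result` (see Details in the package
#'   vignette): point estimates, intervals, ICER, net-benefit table, CEAC,
#'   CE-plane summary, bootstrap cloud, pain-model arm effects, and the
#'   availability table.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  adata <- build_analysis_data(config$data, config$tariff, config$unit_costs,
                               config$medication_costs, config$drug_config)
  availability <- describe_availability(config$data)

  if (config$analysis_population == "available_case") {
    res <- structure(list(analysis_population = "available_case",
                          perspective = config$perspective,
                          availability = availability,
                          n = nrow(adata),
                          utility_means = available_case_utility_means(adata)),
                     class = "cea_result")
    write_result_bundle(res, config)
    return(res)
  }

  ispec <- imputation_spec(m = max(2L, config$m),
                           iterations = config$iterations,
                           pmm_donors = config$pmm_donors,
                           seed = config$seeds$impute)
  modelled <- c(ANALYSIS_IMPUTABLE, "med_cost", "drug_cost")
  modelled <- intersect(modelled, names(adata))

  sur_stat <- function(d) {
    fit <- fit_sur(finalize_analysis_data(d, config$perspective))
    c(delta_cost = fit$delta_cost, delta_qaly = fit$delta_qaly)
  }

  if (config$analysis_population == "complete_case") {
    cc <- adata[stats::complete.cases(adata[, modelled]), , drop = FALSE]
    n_analysis <- nrow(cc)
    fit <- fit_sur(finalize_analysis_data(cc, config$perspective))
    point <- c(delta_cost = fit$delta_cost, delta_qaly = fit$delta_qaly)
    pooled <- NULL
    cloud <- bootstrap_cloud(cc, sur_stat, B = config$B,
                             seed = config$seeds$boot, strata = "arm")
    jack <- jackknife_estimates(cc, sur_stat)
  } else {
    # base case: all randomised, multiple imputation
    n_analysis <- nrow(adata)
    mi <- mice_pmm(adata, ispec)
    fits <- lapply(mi$imputations, function(d)
      fit_sur(finalize_analysis_data(d, config$perspective)))
    est <- t(vapply(fits, function(f)
      c(delta_cost = f$delta_cost, delta_qaly = f$delta_qaly), numeric(2)))
    va <- t(vapply(fits, function(f)
      c(delta_cost = f$se_cost^2, delta_qaly = f$se_qaly^2), numeric(2)))
    pooled <- pool_rubin(est, va, dfcom = fits[[1L]]$df_residual)
    point <- stats::setNames(pooled$estimate, rownames(pooled))

    imp_stat <- function(d) {
      fit <- fit_sur(finalize_analysis_data(single_imputation(d, ispec),
                                            config$perspective))
      c(delta_cost = fit$delta_cost, delta_qaly = fit$delta_qaly)
    }
    if (config$bootstrap_strategy == "boot_then_impute") {
      cloud <- bootstrap_cloud(adata, imp_stat, B = config$B,
                               seed = config$seeds$boot, strata = "arm")
    } else {
      per_imp <- max(1L, config$B %/% length(mi$imputations))
      clouds <- lapply(seq_along(mi$imputations), function(i)
        bootstrap_cloud(mi$imputations[[i]], sur_stat, B = per_imp,
                        seed = config$seeds$boot + i, strata = "arm"))
      cloud <- structure(list(replicates = do.call(
        rbind, lapply(clouds, `[[`, "replicates")),
        B = sum(vapply(clouds, `[[`, integer(1), "B")),
        seed = config$seeds$boot,
        n_failed = sum(vapply(clouds, `[[`, integer(1), "n_failed"))),
        class = "bootstrap_cloud")
    }
    # deterministic jackknife: fixed-seed single imputation per leave-out
    jack_stat <- function(d) {
      set.seed(config$seeds$jack)
      imp_stat(d)
    }
    jack <- jackknife_estimates(adata, jack_stat)
  }

  reps <- cloud$replicates
  ci_cost <- bca_interval(reps[, "delta_cost"], point[["delta_cost"]],
                          jack[, "delta_cost"])
  ci_qaly <- bca_interval(reps[, "delta_qaly"], point[["delta_qaly"]],
                          jack[, "delta_qaly"])

  icer_res <- icer(point[["delta_cost"]], point[["delta_qaly"]])
  nb_rows <- lapply(config$thresholds, function(l) {
    nb_cloud <- net_benefit(reps[, "delta_cost"], reps[, "delta_qaly"], l)
    nb_jack <- net_benefit(jack[, "delta_cost"], jack[, "delta_qaly"], l)
    nb_point <- net_benefit(point[["delta_cost"]], point[["delta_qaly"]], l)
    ci <- bca_interval(nb_cloud, nb_point, nb_jack)
    data.frame(lambda = l, estimate = nb_point, lower = ci[["lower"]],
               upper = ci[["upper"]],
               probability_ce = mean(nb_cloud > 0))
  })
  nb_table <- do.call(rbind, nb_rows)
  ceac_curve <- ceac(cloud, config$lambda_grid)
  plane <- ce_plane_summary(cloud)

  pain <- pain_arm_effects(adata)

  res <- structure(list(
    analysis_population = config$analysis_population,
    perspective = config$perspective,
    n = n_analysis, n_randomised = nrow(adata),
    delta_cost = point[["delta_cost"]], delta_qaly = point[["delta_qaly"]],
    ci_cost = ci_cost, ci_qaly = ci_qaly, icer = icer_res,
    net_benefit = nb_table, ceac = ceac_curve, ce_plane = plane,
    cloud = cloud, pooled = pooled, pain = pain,
    availability = availability,
    seeds = config$seeds, B = cloud$B, m = config$m),
    class = "cea_result")
  write_result_bundle(res, config)
  res
}

# Pain mixed-model arm effects on the rows with observed follow-up pain,
# with the decision-rule flag for a non-reduction.
pain_arm_effects <- function(adata) {
  long <- pain_long(adata)
  long <- long[!is.na(long$pain), , drop = FALSE]
  if (!nrow(long) || length(unique(long$arm[!is.na(long$pain)])) < 2L) {
    return(NULL)
  }
  pm <- tryCatch(fit_pain_mixed_model(long), error = function(e) NULL)
  if (is.null(pm)) return(NULL)
  eff6 <- pm$arm_effects$estimate[pm$arm_effects$visit == "6"]
  flag <- if (length(eff6) && eff6 >= 0) {
    "no pain reduction at 6 months - cost per unit of pain reduction not meaningful"
  } else NA_character_
  list(arm_effects = pm$arm_effects, rho = pm$rho, flag = flag)
}

available_case_utility_means <- function(adata) {
  do.call(rbind, lapply(c("u0", "u6", "u12"), function(v) {
    do.call(rbind, lapply(split(adata[[v]], adata$arm), function(x) {
      data.frame(variable = v, n = sum(!is.na(x)),
                 mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
    }))
  }))
}

#' Item-wise availability table
#'
#' Per variable and timepoint: number missing, percentage missing (one
#' decimal place) and available-case mean and SD, computed item-wise
#' (pairwise deletion), split by arm.
#'
#' @param data canonical wide data frame.
#' @return data frame with columns `variable`, `timepoint`, `arm`, `n`,
#'   `n_missing`, `pct_missing`, `mean`, `sd`.
#' @export
describe_availability <- function(data) {
  cols <- grep("^(rc|eq5d|vas|exp)_.*_(0|6|12)$|^pain_nrs_(6|12)$",
               names(data), value = TRUE)
  arms <- sort(unique(as.character(data$arm)))
  rows <- lapply(cols, function(cn) {
    tp <- sub(".*_(0|6|12)$", "\\1", cn)
    var <- sub("_(0|6|12)$", "", cn)
    do.call(rbind, lapply(arms, function(a) {
      x <- data[[cn]][data$arm == a]
      nm <- sum(is.na(x))
      data.frame(variable = var, timepoint = tp, arm = a, n = length(x),
                 n_missing = nm,
                 pct_missing = round(100 * nm / length(x), 1),
                 mean = if (nm < length(x)) mean(x, na.rm = TRUE) else NA_real_,
                 sd = if (nm < length(x)) stats::sd(x, na.rm = TRUE)
                      else NA_real_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-utility analysis (", x$analysis_population, ", ",
      x$perspective, " perspective), n = ", x$n, "\n", sep = "")
  if (!is.null(x$delta_cost)) {
    cat(sprintf("  incremental cost: %.2f GBP (95%% BCa %.2f to %.2f)\n",
                x$delta_cost, x$ci_cost[["lower"]], x$ci_cost[["upper"]]))
    cat(sprintf("  incremental QALYs: %.4f (95%% BCa %.4f to %.4f)\n",
                x$delta_qaly, x$ci_qaly[["lower"]], x$ci_qaly[["upper"]]))
    print(x$icer)
    for (i in seq_len(nrow(x$net_benefit))) {
      cat(sprintf("  net benefit at %.0f GBP/QALY: %.2f (%.2f to %.2f); P(CE) = %.2f\n",
                  x$net_benefit$lambda[i], x$net_benefit$estimate[i],
                  x$net_benefit$lower[i], x$net_benefit$upper[i],
                  x$net_benefit$probability_ce[i]))
    }
  }
  invisible(x)
}

# Serialise the result bundle; numbers only, fixed key order, no
# timestamps, so identical runs are byte-identical.
result_summary_list <- function(res) {
  if (res$analysis_population == "available_case") {
    return(list(analysis_population = res$analysis_population,
                perspective = res$perspective, n = res$n))
  }
  list(analysis_population = res$analysis_population,
       perspective = res$perspective,
       n = res$n, n_randomised = res$n_randomised,
       delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
       ci_cost = as.list(res$ci_cost), ci_qaly = as.list(res$ci_qaly),
       icer = list(value = res$icer$value, quadrant = res$icer$quadrant,
                   interpretation = res$icer$interpretation),
       net_benefit = res$net_benefit,
       quadrant_shares = as.list(res$ce_plane$quadrant_shares),
       B = res$B, m = res$m, seeds = res$seeds)
}

write_result_bundle <- function(res, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  # stage in a temporary directory so partial outputs are never left behind
  stage <- tempfile("trialcea_out_")
  dir.create(stage)
  jsonlite::write_json(result_summary_list(res),
                       file.path(stage, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$availability, file.path(stage, "availability.csv"),
                   row.names = FALSE)
  if (!is.null(res$ceac)) {
    utils::write.csv(res$ceac, file.path(stage, "ceac.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ce_plane$points, file.path(stage, "ce_plane.csv"),
                     row.names = FALSE)
    cl <- data.frame(replicate = seq_len(nrow(res$cloud$replicates)),
                     res$cloud$replicates)
    utils::write.csv(cl, file.path(stage, "cloud.csv"), row.names = FALSE)
  }
  log_lines <- c(paste("trialcea", as.character(utils::packageVersion("trialcea"))),
                 paste("R", paste(R.version$major, R.version$minor, sep = ".")),
                 paste("run at", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
                 paste("analysis_population", res$analysis_population),
                 paste("perspective", res$perspective),
                 if (!is.null(res$seeds))
                   paste("seed", names(res$seeds),
                         unlist(res$seeds)))
  writeLines(log_lines, file.path(stage, "log.txt"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(dir, f), overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  invisible(dir)
}
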