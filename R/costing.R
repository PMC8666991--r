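# Costing: resource-use counts x unit costs, study-drug exposure,
# category-averaged medications and personal expenses. Prices are UK
# pounds sterling at 2015 levels; with a 12-month horizon no discounting
# is applied.

#' Canonical resource-use items
#'
#' Item identifiers for the healthcare resource-use questionnaire: primary
#' care (GP at practice/home, nurse, two free-text "other" slots), community
#' care (physiotherapist, occupational therapist, two "other" slots) and
#' hospital care (outpatient clinic, A&E, two "other" outpatient slots).
#'
#' @return character vector of item ids.
#' @export
resource_items <- function() {
  c("hospital_outpatient", "a_and_e", "other_outpatient_1",
    "other_outpatient_2", "gp_practice", "gp_home", "nurse_practice",
    "other_primary_1", "other_primary_2", "physiotherapist",
    "occupational_therapist", "other_community_1", "other_community_2")
}

#' Load a unit-cost table from CSV
#'
#' Expects columns `item,unit_cost` (optional `unit_description`), one row
#' per resource item. The packaged default (`load_unit_costs()` with no
#' argument) carries national reference costs per clinic visit / attendance /
#' appointment hour for every item in [resource_items()].
#'
#' @param path CSV path; default is the table shipped with the package.
#' @return object of class `unit_cost_table`: named numeric vector of unit
#'   costs (pounds) with a `description` attribute.
#' @export
load_unit_costs <- function(path = system.file("extdata", "unit_costs.csv",
                                               package = "trialcea")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("unit-cost file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         fileEncoding = "UTF-8")
  if (!all(c("item", "unit_cost") %in% names(tab))) {
    stop("unit-cost table needs columns item,unit_cost", call. = FALSE)
  }
  costs <- stats::setNames(as.numeric(tab$unit_cost), as.character(tab$item))
  if (anyDuplicated(names(costs))) {
    stop("duplicate items in unit-cost table: ",
         paste(names(costs)[duplicated(names(costs))], collapse = ", "),
         call. = FALSE)
  }
  if (any(costs < 0, na.rm = TRUE)) stop("unit costs must be >= 0",
                                         call. = FALSE)
  structure(costs, class = "unit_cost_table",
            description = if ("unit_description" %in% names(tab))
              stats::setNames(as.character(tab$unit_description),
                              names(costs)) else NULL)
}

#' Cost resource-use counts
#'
#' Multiplies each item count by its unit cost. A missing count gives a
#' missing item cost (missing is not zero: blank questionnaire fields stay
#' missing for complete-case determination; the imputation module decides
#' fill-in for the base case).
#'
#' @param counts named numeric vector of nonnegative integer counts (names
#'   are item ids), or an n x items matrix/data frame with item columns.
#' @param unit_costs a `unit_cost_table` (named numeric also accepted).
#' @return per-item costs (vector or matrix matching the input shape).
#' @examples
#' uc <- c(gp_practice = 44.00, nurse_practice = 11.11)
#' cost_resources(c(gp_practice = 2, nurse_practice = 1), uc)  # 88.00 11.11
#' @export
cost_resources <- function(counts, unit_costs) {
  uc <- as.numeric(unit_costs)
  names(uc) <- names(unit_costs)
  single <- is.null(dim(counts))
  m <- if (single) matrix(as.numeric(counts), nrow = 1L,
                          dimnames = list(NULL, names(counts)))
       else as.matrix(counts)
  if (is.null(colnames(m))) stop("counts must be named by item", call. = FALSE)
  unknown <- setdiff(colnames(m), names(uc))
  if (length(unknown)) {
    stop("no unit cost for item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(m) & (m < 0 | m != round(m))
  if (any(bad)) {
    stop("resource counts must be nonnegative integers (item ",
         colnames(m)[which(bad, arr.ind = TRUE)[1L, 2L]], ")", call. = FALSE)
  }
  res <- sweep(m, 2L, uc[colnames(m)], `*`)
  if (single) res[1L, ] else res
}

#' Study-drug (hydroxychloroquine) costing configuration
#'
#' Costing is anchored on the net price of a 60-tablet pack of 200 mg
#' tablets. Daily doses of 200/300/400 mg correspond to 1 / 1.5 / 2 tablets
#' per day (300 mg is taken as alternating 200 mg and 400 mg days, i.e.
#' 1.5 tablets per day on average).
#'
#' @param pack_price pounds per pack (default 5.15).
#' @param tablets_per_pack tablets per pack (default 60).
#' @param tablet_strength_mg milligrams per tablet (default 200).
#' @return list of class `drug_cost_config`.
#' @export
drug_cost_config <- function(pack_price = 5.15, tablets_per_pack = 60,
                             tablet_strength_mg = 200) {
  stopifnot(pack_price > 0, tablets_per_pack > 0, tablet_strength_mg > 0)
  structure(list(pack_price = pack_price,
                 tablets_per_pack = tablets_per_pack,
                 tablet_strength_mg = tablet_strength_mg),
            class = "drug_cost_config")
}

#' Cost study-drug exposure
#'
#' `cost = days * (dose_mg / tablet_strength) * pack_price / tablets_per_pack`.
#' Participants are assumed to stay on their allocated dose; exposure is
#' truncated at the recorded stop/withdrawal day. A missing dose (control
#' arm: no active-drug exposure; placebo tablets are a research cost and
#' contribute nothing) costs zero.
#'
#' @param dose_mg daily dose, one of 200, 300, 400 (or `NA` for none).
#' @param days days on drug, 0..365.
#' @param config a [drug_cost_config()].
#' @return cost in pounds (vectorised).
#' @examples
#' cost_hcq(200, 365)  # 365 * 5.15 / 60 = 31.33
#' @export
cost_hcq <- function(dose_mg, days, config = drug_cost_config()) {
  stopifnot(inherits(config, "drug_cost_config"))
  n <- max(length(dose_mg), length(days))
  dose_mg <- rep_len(dose_mg, n)
  days <- rep_len(days, n)
  bad_dose <- !is.na(dose_mg) & !(dose_mg %in% c(200, 300, 400))
  if (any(bad_dose)) {
    stop("daily dose must be 200, 300 or 400 mg, got ",
         paste(utils::head(unique(dose_mg[bad_dose]), 3L), collapse = ", "),
         call. = FALSE)
  }
  bad_days <- !is.na(days) & (days < 0 | days > 365)
  if (any(bad_days)) stop("days on drug must be in 0..365", call. = FALSE)
  daily <- (dose_mg / config$tablet_strength_mg) *
    config$pack_price / config$tablets_per_pack
  out <- ifelse(is.na(dose_mg), 0, daily * ifelse(is.na(days), 0, days))
  as.numeric(out)
}

#' Load medication category average costs from CSV
#'
#' Medications recorded on investigator forms (at 3, 6, 9 and 12 months) are
#' costed by category (e.g. oral opioid, topical NSAID,
#' antidepressant/neuropathic therapy) using the average cost of the most
#' commonly occurring medications within the category, rather than
#' micro-costing each product. Expects columns `category,avg_cost` (pounds
#' per recorded use-interval).
#'
#' @param path CSV path; default is the table shipped with the package
#'   (placeholder averages: the source analysis does not publish them).
#' @return named numeric vector of per-interval category costs.
#' @export
load_medication_costs <- function(path = system.file(
    "extdata", "medication_category_costs.csv", package = "trialcea")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("medication-cost file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         fileEncoding = "UTF-8")
  if (!all(c("category", "avg_cost") %in% names(tab))) {
    stop("medication-cost table needs columns category,avg_cost",
         call. = FALSE)
  }
  costs <- stats::setNames(as.numeric(tab$avg_cost), as.character(tab$category))
  if (any(costs < 0, na.rm = TRUE)) stop("category costs must be >= 0",
                                         call. = FALSE)
  costs
}

#' Cost recorded medication use
#'
#' Sums the per-interval category average cost over all recorded
#' use-intervals.
#'
#' @param uses either a character vector of category labels (one per
#'   recorded use-interval) or a named numeric vector of interval counts per
#'   category.
#' @param category_costs named numeric vector, pounds per use-interval.
#' @return total medication cost in pounds.
#' @examples
#' cost_medications(c(oral_opioid = 4), c(oral_opioid = 10))  # 40
#' @export
cost_medications <- function(uses, category_costs) {
  if (is.character(uses)) uses <- table_to_counts(uses)
  if (length(uses) == 0L) return(0)
  if (is.null(names(uses))) stop("uses must be named by category",
                                 call. = FALSE)
  unknown <- setdiff(names(uses), names(category_costs))
  if (length(unknown)) {
    stop("unknown medication category label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(uses < 0, na.rm = TRUE)) stop("interval counts must be >= 0",
                                        call. = FALSE)
  sum(as.numeric(uses) * category_costs[names(uses)])
}

table_to_counts <- function(labels) {
  tb <- table(labels)
  stats::setNames(as.numeric(tb), names(tb))
}

#' Per-participant cost breakdown
#'
#' Turns a canonical wide participant table (see [generate_trial()] for the
#' column conventions) into per-participant cost components over the
#' 12-month trial period: `healthcare` (6- plus 12-month resource use x unit
#' costs; missing if any contributing count is missing), `drug` (study-drug
#' exposure), `medications` (category-costed investigator-form records) and
#' `societal_extras` (participant-reported out-of-pocket spend:
#' over-the-counter medication, childcare, travel). Baseline-visit resource
#' costs and expenses are returned separately as covariates
#' (`baseline_healthcare`, `baseline_extras`), not counted in trial-period
#' totals.
#'
#' @param data canonical wide data frame.
#' @param unit_costs a `unit_cost_table`.
#' @param medication_costs named per-interval category costs.
#' @param drug_config a [drug_cost_config()].
#' @return data frame of class `cost_breakdown` keyed by `id`, with
#'   component columns and totals `total_nhs_pss` (healthcare + drug +
#'   medications) and `total_societal` (+ societal extras).
#' @export
cost_breakdown <- function(data,
                           unit_costs = load_unit_costs(),
                           medication_costs = load_medication_costs(),
                           drug_config = drug_cost_config()) {
  items <- resource_items()
  per_visit_cost <- function(t) {
    cols <- paste0("rc_", items, "_", t)
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols)) {
      stop("missing resource columns: ",
           paste(utils::head(missing_cols, 3L), collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(data[, cols, drop = FALSE])
    colnames(m) <- items
    rowSums(cost_resources(m, unit_costs))  # NA if any item missing
  }
  hc0 <- per_visit_cost(0)
  hc6 <- per_visit_cost(6)
  hc12 <- per_visit_cost(12)

  ctrl <- data$arm == "control"
  exposed <- (!is.na(data$hcq_dose_mg)) |
    (!is.na(data$hcq_days) & data$hcq_days > 0)
  if (any(ctrl & exposed)) {
    stop("control-arm participant(s) with study-drug exposure: ",
         paste(utils::head(data$id[ctrl & exposed], 3L), collapse = ", "),
         " (placebo must carry zero drug cost)", call. = FALSE)
  }
  drug <- cost_hcq(data$hcq_dose_mg, data$hcq_days, drug_config)

  med_cols <- grep("^med_", names(data), value = TRUE)
  med <- if (length(med_cols)) {
    cats <- sub("^med_", "", med_cols)
    unknown <- setdiff(cats, names(medication_costs))
    if (length(unknown)) {
      stop("unknown medication category label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    as.numeric(as.matrix(data[, med_cols, drop = FALSE]) %*%
                 medication_costs[cats])
  } else rep(0, nrow(data))

  extras_visit <- function(t) {
    cols <- paste0("exp_", c("otc", "childcare", "travel"), "_", t)
    cols <- intersect(cols, names(data))
    if (!length(cols)) return(rep(0, nrow(data)))
    rowSums(data[, cols, drop = FALSE])
  }
  ext0 <- extras_visit(0)
  extras <- extras_visit(6) + extras_visit(12)

  out <- data.frame(id = data$id, arm = data$arm,
                    healthcare = hc6 + hc12, drug = drug, medications = med,
                    societal_extras = extras,
                    baseline_healthcare = hc0, baseline_extras = ext0,
                    healthcare_6m = hc6, healthcare_12m = hc12,
                    stringsAsFactors = FALSE)
  out$total_nhs_pss <- out$healthcare + out$drug + out$medications
  out$total_societal <- out$total_nhs_pss + out$societal_extras
  class(out) <- c("cost_breakdown", class(out))
  out
}

#' Total cost under an analysis perspective
#'
#' NHS/PSS totals comprise healthcare resource use, study drug and
#' medications; the societal perspective adds participant out-of-pocket
#' extras. Totals are recomputed from components (never read from cached
#' columns), so additivity holds by construction.
#'
#' @param breakdown a [cost_breakdown()] data frame.
#' @param perspective `"nhs_pss"` or `"societal"`.
#' @return numeric vector of per-participant totals in pounds.
#' @export
total_cost <- function(breakdown, perspective = c("nhs_pss", "societal")) {
  perspective <- match.arg(perspective)
  base <- breakdown$healthcare + breakdown$drug + breakdown$medications
  if (perspective == "societal") base + breakdown$societal_extras else base
}
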