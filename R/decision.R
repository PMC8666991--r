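# Decision outputs: incremental cost-effectiveness ratios with
# cost-effectiveness-plane quadrant semantics, net monetary benefit, the
# acceptability curve, and CE-plane exports.
#
# Boundary convention (deterministic, conservative): replicates with
# delta_e = 0 count as a gain and delta_c = 0 as a cost increase when
# assigning quadrants (closed lower boundary), and a net benefit of exactly
# zero counts as NOT cost-effective.

#' Incremental cost-effectiveness ratio with quadrant semantics
#'
#' `value = delta_cost / delta_qaly`, interpreted by cost-effectiveness-
#' plane quadrant (effect on the x axis, cost on the y axis): NE = cost per
#' QALY gained; SE (cheaper, more effective) = dominant, no ratio needed;
#' NW (dearer, less effective) = dominated; SW = cost saved per QALY lost,
#' reported as a positive saving per QALY. A zero effect difference gives
#' no ratio, flagged `"undefined (zero effect)"`. Degenerate cases are
#' flagged states, not errors.
#'
#' @param delta_cost incremental cost (pounds), intervention minus control.
#' @param delta_qaly incremental QALYs.
#' @return list of class `icer_result`: `value` (pounds per QALY, `NA` when
#'   no ratio applies), `quadrant` (`NE`/`SE`/`SW`/`NW`), `interpretation`.
#' @examples
#' icer(-11.80, -0.0052)  # SW: ~2269 pounds saved per QALY lost
#' @export
icer <- function(delta_cost, delta_qaly) {
  quadrant <- if (delta_qaly >= 0) {
    if (delta_cost >= 0) "NE" else "SE"
  } else {
    if (delta_cost >= 0) "NW" else "SW"
  }
  if (delta_qaly == 0) {
    value <- NA_real_
    interpretation <- "undefined (zero effect)"
  } else if (quadrant == "SE") {
    value <- NA_real_
    interpretation <- "dominant"
  } else if (quadrant == "NW") {
    value <- NA_real_
    interpretation <- "dominated"
  } else if (quadrant == "SW") {
    value <- delta_cost / delta_qaly   # both negative: positive saving ratio
    interpretation <- "cost saved per QALY lost"
  } else {
    value <- delta_cost / delta_qaly
    interpretation <- "cost per QALY gained"
  }
  structure(list(value = value, quadrant = quadrant,
                 interpretation = interpretation,
                 delta_cost = delta_cost, delta_qaly = delta_qaly),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("ICER:", if (is.na(x$value)) x$interpretation
      else sprintf("%.0f GBP/QALY (%s, %s quadrant)", x$value,
                   x$interpretation, x$quadrant), "\n")
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `lambda * delta_qaly - delta_cost`, in pounds; positive values indicate
#' the intervention is cost-effective at threshold `lambda`. (The emulated
#' analysis labels this quantity "net health benefit" but prints it in
#' pounds; the QALY-denominated variant is [net_health_benefit_qaly()].)
#'
#' @param delta_cost incremental cost (pounds).
#' @param delta_qaly incremental QALYs.
#' @param lambda threshold, pounds per QALY (> 0); UK decision thresholds
#'   of 20,000 and 30,000 are the conventional anchors.
#' @return net benefit in pounds (vectorised over all arguments).
#' @examples
#' net_benefit(-11.80, -0.0052, 20000)  # -92.20
#' @export
net_benefit <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  lambda * delta_qaly - delta_cost
}

#' Net health benefit in QALY units
#'
#' `delta_qaly - delta_cost / lambda`.
#'
#' @inheritParams net_benefit
#' @export
net_health_benefit_qaly <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  delta_qaly - delta_cost / lambda
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold in `lambda_grid`, the probability that the
#' intervention is cost-effective: the fraction of bootstrap replicates
#' with strictly positive net benefit (ties at exactly zero count as not
#' cost-effective).
#'
#' @param cloud a [bootstrap_cloud()] (columns `delta_cost`, `delta_qaly`)
#'   or a two-column matrix/data frame.
#' @param lambda_grid thresholds in pounds per QALY; the default spans
#'   0-50,000 in steps of 500, covering both UK decision anchors.
#' @return data frame of class `ceac_curve`: `lambda`, `probability`.
#' @export
ceac <- function(cloud, lambda_grid = seq(0, 50000, by = 500)) {
  if (!length(lambda_grid)) stop("lambda grid must be non-empty",
                                 call. = FALSE)
  m <- cloud_matrix(cloud)
  if (!nrow(m)) stop("empty bootstrap cloud", call. = FALSE)
  lambda_grid <- sort(unique(lambda_grid))
  prob <- vapply(lambda_grid, function(l) {
    mean(l * m[, "delta_qaly"] - m[, "delta_cost"] > 0)
  }, numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

cloud_matrix <- function(cloud) {
  m <- if (inherits(cloud, "bootstrap_cloud")) cloud$replicates
       else as.matrix(cloud)
  if (is.null(colnames(m)) && ncol(m) == 2L) {
    colnames(m) <- c("delta_cost", "delta_qaly")
  }
  if (!all(c("delta_cost", "delta_qaly") %in% colnames(m))) {
    stop("cloud must have columns delta_cost and delta_qaly", call. = FALSE)
  }
  m[, c("delta_cost", "delta_qaly"), drop = FALSE]
}

#' Cost-effectiveness plane export
#'
#' Per-replicate coordinates plus the fraction of the cloud in each
#' quadrant (closed lower boundary: `delta_qaly >= 0` counts as a gain,
#' `delta_cost >= 0` as a cost increase; shares always sum to one).
#'
#' @param cloud a [bootstrap_cloud()] or two-column matrix/data frame.
#' @return list of class `ce_plane`: `points` (data frame `replicate`,
#'   `delta_cost`, `delta_qaly`, `quadrant`) and `quadrant_shares` (named
#'   numeric, NE/SE/SW/NW).
#' @export
ce_plane_summary <- function(cloud) {
  m <- cloud_matrix(cloud)
  if (!nrow(m)) stop("empty bootstrap cloud", call. = FALSE)
  q <- ifelse(m[, "delta_qaly"] >= 0,
              ifelse(m[, "delta_cost"] >= 0, "NE", "SE"),
              ifelse(m[, "delta_cost"] >= 0, "NW", "SW"))
  shares <- vapply(c(NE = "NE", SE = "SE", SW = "SW", NW = "NW"),
                   function(k) mean(q == k), numeric(1))
  structure(list(points = data.frame(replicate = seq_len(nrow(m)),
                                     delta_cost = m[, "delta_cost"],
                                     delta_qaly = m[, "delta_qaly"],
                                     quadrant = q),
                 quadrant_shares = shares),
            class = "ce_plane")
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of bootstrap (incremental QALY, incremental cost) pairs with the
#' origin axes and an optional threshold line.
#'
#' @param cloud a [bootstrap_cloud()] or two-column matrix.
#' @param lambda optional threshold to draw as a line through the origin.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(cloud, lambda = 20000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  pts <- as.data.frame(cloud_matrix(cloud))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_qaly,
                                         y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)")
  if (!is.null(lambda)) {
    p <- p + ggplot2::geom_abline(slope = lambda, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve a [ceac()] result.
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lambda,
                                      y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective")
}
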