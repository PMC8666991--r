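#' @keywords internal
"_PACKAGE"

# EQ-5D-5L dimensions, in instrument order.
EQ5D_DIMS <- c("MO", "SC", "UA", "PD", "AD")

# All 3125 five-level profiles as a 3125 x 5 integer matrix, ordered so that
# row index == eq5d_state_index(profile).
eq5d_all_states <- function() {
  g <- expand.grid(AD = 1:5, PD = 1:5, UA = 1:5, SC = 1:5, MO = 1:5,
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, EQ5D_DIMS])
}

# Row index of a profile in eq5d_all_states(): base-5 positional code + 1.
eq5d_state_index <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  as.integer((levels[, 1L] - 1L) * 625L + (levels[, 2L] - 1L) * 125L +
             (levels[, 3L] - 1L) * 25L + (levels[, 4L] - 1L) * 5L +
             levels[, 5L])
}

eq5d_state_string <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  apply(levels, 1L, paste0, collapse = "")
}

new_tariff <- function(utilities, name, form) {
  stopifnot(length(utilities) == 3125L)
  if (abs(utilities[1L] - 1) > 1e-12) {
    stop("tariff '", name, "': state 11111 must have utility exactly 1.0, got ",
         utilities[1L], call. = FALSE)
  }
  if (any(utilities > 1 + 1e-12)) {
    bad <- which(utilities > 1 + 1e-12)[1L]
    stop("tariff '", name, "': state ",
         eq5d_state_string(eq5d_all_states()[bad, , drop = FALSE]),
         " has utility > 1", call. = FALSE)
  }
  structure(list(name = name, form = form, utilities = as.numeric(utilities)),
            class = "eq5d_tariff")
}

#' Build a tariff from additive decrement coefficients
#'
#' Constructs an EQ-5D-5L value set of the common additive form
#' \deqn{U(s) = 1 - \sum_{d} c_{d,\ell_d} - c_{any} 1\{s \neq 11111\}}
#' where \eqn{c_{d,\ell}} is the decrement for dimension \eqn{d}
#' (`MO`, `SC`, `UA`, `PD`, `AD`) at level \eqn{\ell \in 2..5} and
#' `any_problem` is an optional constant decrement applied to every state
#' other than full health. Level-1 decrements are implicitly zero. The table
#' is expanded to all 3125 states at construction, so scoring is a lookup.
#'
#' @param coefficients named numeric vector or two-column data frame
#'   (`term`, `value`). Terms are `"MO2"` ... `"AD5"`, optionally
#'   `"any_problem"`; an optional `"anchor"` term must equal 1.
#' @param name label for the value set.
#' @return An object of class `eq5d_tariff`.
#' @examples
#' # a linear toy tariff: utility = 1 - 0.05 * sum(level - 1)
#' co <- setNames(rep(0.05 * (1:4), 5),
#'                paste0(rep(c("MO","SC","UA","PD","AD"), each = 4), 2:5))
#' tar <- tariff_from_coefficients(co, "linear-0.05")
#' score_eq5d(c(3, 3, 3, 3, 3), tar)  # 0.50
#' @export
tariff_from_coefficients <- function(coefficients, name = "coefficients") {
  if (is.data.frame(coefficients)) {
    if (!all(c("term", "value") %in% names(coefficients))) {
      stop("coefficient table needs columns 'term' and 'value'", call. = FALSE)
    }
    co <- stats::setNames(as.numeric(coefficients$value),
                          as.character(coefficients$term))
  } else {
    co <- coefficients
  }
  if (is.null(names(co)) || any(!nzchar(names(co)))) {
    stop("coefficients must be named", call. = FALSE)
  }
  if (anyDuplicated(names(co))) {
    stop("duplicate coefficient terms: ",
         paste(unique(names(co)[duplicated(names(co))]), collapse = ", "),
         call. = FALSE)
  }
  if ("anchor" %in% names(co) && abs(co[["anchor"]] - 1) > 1e-12) {
    stop("anchor term must equal 1.0 (utility of full health)", call. = FALSE)
  }
  valid <- c(paste0(rep(EQ5D_DIMS, each = 4L), rep(2:5, 5L)),
             "any_problem", "anchor")
  unknown <- setdiff(names(co), valid)
  if (length(unknown)) {
    stop("unknown coefficient terms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dec <- matrix(0, nrow = 5L, ncol = 5L, dimnames = list(NULL, EQ5D_DIMS))
  for (d in EQ5D_DIMS) for (l in 2:5) {
    term <- paste0(d, l)
    if (term %in% names(co)) dec[l, d] <- co[[term]]
  }
  anyp <- if ("any_problem" %in% names(co)) co[["any_problem"]] else 0
  states <- eq5d_all_states()
  u <- 1 - (dec[cbind(states[, "MO"], 1L)] + dec[cbind(states[, "SC"], 2L)] +
            dec[cbind(states[, "UA"], 3L)] + dec[cbind(states[, "PD"], 4L)] +
            dec[cbind(states[, "AD"], 5L)])
  u <- u - anyp * (rowSums(states) > 5L)
  new_tariff(u, name, form = "coefficients")
}

#' Build a tariff from an exhaustive state-utility table
#'
#' @param table data frame with columns `state` (5-character string of digits
#'   1-5) and `utility`. All 3125 states must appear exactly once.
#' @param name label for the value set.
#' @return An object of class `eq5d_tariff`.
#' @export
tariff_from_states <- function(table, name = "exhaustive") {
  if (!all(c("state", "utility") %in% names(table))) {
    stop("state table needs columns 'state' and 'utility'", call. = FALSE)
  }
  st <- as.character(table$state)
  bad <- which(!grepl("^[1-5]{5}$", st))
  if (length(bad)) {
    stop("invalid state string(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(st))
  if (length(dup)) {
    stop("duplicate state(s) at row(s) ",
         paste(utils::head(dup, 5L), collapse = ", "),
         ": ", paste(utils::head(st[dup], 5L), collapse = ", "), call. = FALSE)
  }
  lv <- matrix(as.integer(unlist(strsplit(st, ""), use.names = FALSE)),
               ncol = 5L, byrow = TRUE)
  idx <- eq5d_state_index(lv)
  if (length(idx) < 3125L) {
    missing_idx <- setdiff(seq_len(3125L), idx)
    miss <- eq5d_state_string(eq5d_all_states()[utils::head(missing_idx, 5L), ,
                                                drop = FALSE])
    stop(3125L - length(idx), " state(s) missing from table, e.g. ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  u <- numeric(3125L)
  u[idx] <- as.numeric(table$utility)
  new_tariff(u, name, form = "exhaustive")
}

#' Load a tariff (value set) from CSV
#'
#' Two dialects are accepted, detected from the header: an exhaustive table
#' (`state,utility`; 3125 rows, `state` a 5-digit string with digits 1-5) or
#' an additive coefficient table (`term,value`; see
#' [tariff_from_coefficients()]). Files are UTF-8 with a header row; lines
#' starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @param name label; defaults to the file name.
#' @return An object of class `eq5d_tariff`.
#' @export
load_tariff <- function(path, name = NULL) {
  if (!file.exists(path)) stop("tariff file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  if (is.null(name)) name <- basename(path)
  if (all(c("state", "utility") %in% names(tab))) {
    tab$utility <- as.numeric(tab$utility)
    tariff_from_states(tab, name = name)
  } else if (all(c("term", "value") %in% names(tab))) {
    tab$value <- as.numeric(tab$value)
    tariff_from_coefficients(tab, name = name)
  } else {
    stop("unrecognised tariff dialect: header must be state,utility or ",
         "term,value (got: ", paste(names(tab), collapse = ","), ")",
         call. = FALSE)
  }
}

#' Score EQ-5D-5L responses against a tariff
#'
#' Maps five-dimension response profiles to utilities. A profile with any
#' missing dimension scores `NA` (no partial scoring). Utilities may be
#' negative: states valued worse than dead are not floored.
#'
#' @param levels integer vector of length 5 (order `MO`, `SC`, `UA`, `PD`,
#'   `AD`) or an n x 5 matrix / data frame of profiles. `NA` allowed.
#' @param tariff an `eq5d_tariff`.
#' @return numeric utility vector (length 1 for a single profile).
#' @export
score_eq5d <- function(levels, tariff) {
  stopifnot(inherits(tariff, "eq5d_tariff"))
  single <- is.null(dim(levels))
  if (single) {
    if (length(levels) != 5L) stop("a profile has exactly 5 levels",
                                   call. = FALSE)
    levels <- matrix(as.numeric(levels), nrow = 1L)
  } else {
    levels <- as.matrix(levels)
    if (ncol(levels) != 5L) stop("profile matrix must have 5 columns",
                                 call. = FALSE)
    storage.mode(levels) <- "numeric"
  }
  for (j in seq_len(5L)) {
    v <- levels[, j]
    ok <- is.na(v) | (v %in% 1:5)
    if (!all(ok)) {
      stop("invalid level for dimension ", EQ5D_DIMS[j], ": ",
           paste(utils::head(unique(v[!ok]), 3L), collapse = ", "),
           " (levels must be integers 1-5 or NA)", call. = FALSE)
    }
  }
  out <- rep(NA_real_, nrow(levels))
  complete <- stats::complete.cases(levels)
  if (any(complete)) {
    idx <- eq5d_state_index(levels[complete, , drop = FALSE])
    out[complete] <- tariff$utilities[idx]
  }
  out
}

#' Expand a tariff to its full state-utility table
#'
#' @param tariff an `eq5d_tariff`.
#' @return data frame with columns `state` and `utility`, 3125 rows.
#' @export
expand_tariff <- function(tariff) {
  stopifnot(inherits(tariff, "eq5d_tariff"))
  data.frame(state = eq5d_state_string(eq5d_all_states()),
             utility = tariff$utilities)
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("EQ-5D-5L tariff '", x$name, "' (", x$form, " form)\n", sep = "")
  cat("  utility range: [", round(min(x$utilities), 4), ", ",
      round(max(x$utilities), 4), "]\n", sep = "")
  invisible(x)
}
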