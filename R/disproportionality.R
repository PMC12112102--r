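# Disproportionality analysis: per-PT 2x2 contingency tables, PRR, ROR with
# Woolf confidence intervals, chi-square, Evans-criteria classification and
# bubble-plot coordinates.
#
# Table layout (report-level counts; one report counts once per PT):
#             event   no event
#   drug        a        b        a + b = target-drug reports
#   other       c        d        a + b + c + d = database reports

#' Build a 2x2 contingency table
#'
#' @param a Reports with the target drug and the target event.
#' @param b Reports with the target drug, without the event.
#' @param c Reports with other drugs and the event.
#' @param d Reports with other drugs, without the event.
#' @return A `contingency2x2` (named list with fields `a`, `b`, `c`, `d`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  structure(as.list(cells), class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  cat("<contingency2x2> N =", x$a + x$b + x$c + x$d, "\n")
  print(m)
  invisible(x)
}

# Haldane-Anscombe: +0.5 on every cell, applied only when some cell is zero.
# `strict` errors instead, for callers that refuse corrected estimates.
apply_zero_policy <- function(a, b, c, d, zero_cells = c("haldane", "strict")) {
  zero_cells <- match.arg(zero_cells)
  has_zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_cells == "strict" && any(has_zero)) {
    stop("zero cell in contingency table; use zero_cells = \"haldane\" ",
         "to apply the +0.5 Haldane-Anscombe correction", call. = FALSE)
  }
  k <- ifelse(has_zero, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = has_zero)
}

#' Contingency table for one drug-event pair
#'
#' Counts reports, not occurrences: a report counts once towards each PT it
#' carries. The "target drug" rows are the reports in which the drug appears
#' with the configured role.
#'
#' @param db A deduplicated `report_db`.
#' @param drug Target drug name.
#' @param pt Target preferred term.
#' @param role Role the drug must carry (default `"PRIMARY_SUSPECT"`).
#' @return A `contingency2x2`.
#' @export
contingency <- function(db, drug, pt, role = "PRIMARY_SUSPECT") {
  stopifnot(inherits(db, "report_db"))
  if (!role %in% ROLE_CODES) {
    stop("unknown role '", role, "'; accepted roles: ",
         paste(ROLE_CODES, collapse = ", "), call. = FALSE)
  }
  drug <- normalize_term(drug)
  pt <- normalize_term(pt)
  if (!drug %in% db$drugs$drug_name) {
    stop("drug '", drug, "' absent from database", call. = FALSE)
  }
  target_vids <- db$drugs |>
    dplyr::filter(.data$drug_name == drug, !is.na(.data$role_code),
                  .data$role_code == role) |>
    dplyr::pull(.data$.vid) |>
    unique()
  pt_vids <- unique(db$events$.vid[db$events$pt == pt])
  N <- n_reports(db)
  a <- sum(target_vids %in% pt_vids)
  b <- length(target_vids) - a
  c <- length(pt_vids) - a
  d <- N - a - b - c
  contingency_table(a, b, c, d)
}

# vectorized kernels shared by the scalar wrappers and signal_scan ----------

.prr_vec <- function(a, b, c, d) {
  num <- a / (a + b)
  den <- c / (c + d)
  ifelse(den > 0, num / den, NA_real_)
}

.ror_ci_vec <- function(a, b, c, d, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ror <- (a * d) / (b * c)
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, low = exp(log(ror) - z * se), high = exp(log(ror) + z * se))
}

.chi2_vec <- function(a, b, c, d, corrected = TRUE) {
  # double arithmetic: products of report counts overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (corrected) dev <- pmax(dev - N / 2, 0)
  N * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Proportional reporting ratio
#'
#' `PRR = [a / (a + b)] / [c / (c + d)]`: the event's share among the target
#' drug's reports relative to its share among all other reports.
#'
#' @param t A `contingency2x2`.
#' @param zero_cells `"haldane"` (default; +0.5 on all cells when any cell
#'   is zero) or `"strict"` (error on zero cells).
#' @return The PRR as a positive number.
#' @export
prr <- function(t, zero_cells = c("haldane", "strict")) {
  stopifnot(inherits(t, "contingency2x2"))
  z <- apply_zero_policy(t$a, t$b, t$c, t$d, zero_cells)
  if (z$a + z$b == 0 || z$c + z$d == 0) {
    stop("PRR undefined: empty margin after zero-cell policy", call. = FALSE)
  }
  out <- .prr_vec(z$a, z$b, z$c, z$d)
  if (is.na(out)) stop("PRR undefined: no comparator events (c = 0)", call. = FALSE)
  out
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d) / (b c)` with the log-scale Wald (Woolf) interval
#' `exp(ln ROR +/- z[1 - alpha/2] * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t A `contingency2x2`.
#' @param alpha Two-sided significance level in (0, 1); default 0.05 for a
#'   95% interval.
#' @param zero_cells Zero-cell policy, as in [prr()].
#' @return Tibble with one row: `ror`, `ci_low`, `ci_high`.
#' @export
ror_ci <- function(t, alpha = 0.05, zero_cells = c("haldane", "strict")) {
  stopifnot(inherits(t, "contingency2x2"), alpha > 0, alpha < 1)
  z <- apply_zero_policy(t$a, t$b, t$c, t$d, zero_cells)
  est <- .ror_ci_vec(z$a, z$b, z$c, z$d, alpha)
  tibble::tibble(ror = est$ror, ci_low = est$low, ci_high = est$high)
}

#' Chi-square statistic of a 2x2 table
#'
#' Closed form `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; with Yates'
#' continuity correction the deviation `|ad - bc|` is reduced by `N/2`
#' and floored at zero.
#'
#' @param t A `contingency2x2` with all four marginals positive.
#' @param corrected Apply Yates' continuity correction (default `TRUE`).
#' @return The statistic (non-negative scalar).
#' @export
chi_square <- function(t, corrected = TRUE) {
  stopifnot(inherits(t, "contingency2x2"))
  marg <- c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d)
  if (any(marg == 0)) stop("chi-square undefined: zero marginal", call. = FALSE)
  .chi2_vec(t$a, t$b, t$c, t$d, corrected)
}

#' Thresholds for Evans-criteria signal classification
#'
#' The conventional rule for a positive signal in spontaneous-report
#' disproportionality: at least 3 cases (`n > 2`), chi-square above 4 and
#' PRR above 2, all strict inequalities.
#'
#' @param min_cases Minimum case count `n` (default 3, i.e. `n > 2`).
#' @param chi2_threshold Chi-square must exceed this (default 4).
#' @param prr_threshold PRR must exceed this (default 2).
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(min_cases = 3, chi2_threshold = 4, prr_threshold = 2) {
  stopifnot(min_cases > 0, chi2_threshold > 0, prr_threshold > 0)
  structure(list(min_cases = as.integer(min_cases),
                 chi2_threshold = chi2_threshold,
                 prr_threshold = prr_threshold),
            class = "signal_criteria")
}

#' Classify drug-event pairs by the Evans criteria
#'
#' @param metrics Data frame with columns `n`, `prr`, `chi2` (e.g. a
#'   [signal_scan()] result).
#' @param criteria A [signal_criteria()].
#' @return Logical vector: `TRUE` where `n >= min_cases`, `chi2 >
#'   chi2_threshold` and `prr > prr_threshold` all hold.
#' @export
evans_classify <- function(metrics, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"),
            all(c("n", "prr", "chi2") %in% names(metrics)))
  out <- metrics$n >= criteria$min_cases &
    metrics$chi2 > criteria$chi2_threshold &
    metrics$prr > criteria$prr_threshold
  out & !is.na(out)
}

#' Disproportionality scan over every PT reported with a drug
#'
#' For each preferred term observed in the target drug's reports, builds the
#' 2x2 table against the rest of the database and computes the reporting
#' rate, PRR, ROR with confidence interval, chi-square and the Evans
#' classification. Zero-cell tables get the Haldane-Anscombe +0.5 correction
#' for PRR/ROR (flagged in `zero_corrected`); chi-square uses Yates'
#' correction by default (flagged in `corrected`). Non-signals are included
#' with `is_signal = FALSE`.
#'
#' @param db A deduplicated `report_db` containing both the target drug's
#'   reports and the comparator background.
#' @param drug Target drug name.
#' @param criteria A [signal_criteria()].
#' @param role Role defining the target-drug reports.
#' @param alpha CI significance level.
#' @param corrected Use Yates-corrected chi-square (default `TRUE`).
#' @param mapping Optional `pt_soc_map` to fill the `soc` column.
#' @return Tibble, one row per PT, ordered by `n` descending then PT:
#'   columns `pt`, `soc`, `a`, `b`, `c`, `d`, `n`, `r_percent`, `prr`,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `chi2`, `corrected`,
#'   `zero_corrected`, `is_signal`.
#' @export
signal_scan <- function(db, drug, criteria = signal_criteria(),
                        role = "PRIMARY_SUSPECT", alpha = 0.05,
                        corrected = TRUE, mapping = NULL) {
  stopifnot(inherits(db, "report_db"))
  drug <- normalize_term(drug)
  if (!drug %in% db$drugs$drug_name) {
    stop("drug '", drug, "' absent from database", call. = FALSE)
  }
  target_vids <- db$drugs |>
    dplyr::filter(.data$drug_name == drug, !is.na(.data$role_code),
                  .data$role_code == role) |>
    dplyr::pull(.data$.vid) |>
    unique()
  N <- n_reports(db)
  n_target <- length(target_vids)

  on_target <- db$events$.vid %in% target_vids
  a_tab <- db$events[on_target, ] |> dplyr::count(.data$pt, name = "a")
  tot_tab <- db$events |> dplyr::count(.data$pt, name = "n_pt")
  tab <- a_tab |>
    dplyr::inner_join(tot_tab, by = "pt") |>
    dplyr::mutate(
      b = n_target - .data$a,
      c = .data$n_pt - .data$a,
      d = N - n_target - .data$c,
      n = .data$a,
      r_percent = percent_of(.data$a, n_target)
    )

  z <- apply_zero_policy(tab$a, tab$b, tab$c, tab$d, "haldane")
  est <- .ror_ci_vec(z$a, z$b, z$c, z$d, alpha)
  tab$prr <- .prr_vec(z$a, z$b, z$c, z$d)
  tab$ror <- est$ror
  tab$ror_ci_low <- est$low
  tab$ror_ci_high <- est$high
  tab$chi2 <- .chi2_vec(tab$a, tab$b, tab$c, tab$d, corrected)
  tab$corrected <- corrected
  tab$zero_corrected <- z$corrected
  tab$soc <- soc_of(tab$pt, mapping)
  tab$is_signal <- evans_classify(tab, criteria)

  tab |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pt) |>
    dplyr::select("pt", "soc", "a", "b", "c", "d", "n", "r_percent", "prr",
                  "ror", "ror_ci_low", "ror_ci_high", "chi2", "corrected",
                  "zero_corrected", "is_signal")
}

#' Bubble-plot coordinates for a signal table
#'
#' Emits the plottable coordinates conventionally used to display
#' disproportionality strength: `x = log2(ROR)`, `y = sqrt(chi2)`, bubble
#' size = report count. No rendering is done; feed the result to any
#' plotting layer.
#'
#' @param metrics A [signal_scan()] result (or any data frame with columns
#'   `pt`, `ror`, `chi2`, `n`); `ror` must be positive.
#' @return Tibble with columns `pt`, `x`, `y`, `size`.
#' @export
bubble_coordinates <- function(metrics) {
  stopifnot(all(c("pt", "ror", "chi2", "n") %in% names(metrics)))
  if (any(metrics$ror <= 0, na.rm = TRUE)) {
    stop("bubble coordinates need ror > 0", call. = FALSE)
  }
  tibble::tibble(
    pt = metrics$pt,
    x = log2(metrics$ror),
    y = sqrt(metrics$chi2),
    size = metrics$n
  )
}
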