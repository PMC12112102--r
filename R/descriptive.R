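# Descriptive epidemiology of a curated case series: category distributions,
# reporting rates, top-k preferred terms, per-PT occurrence counts.

AGE_BIN_LEVELS <- c("<18", "18-64", "65-85", ">85", "NS")
DIMENSIONS <- c("role", "year", "region", "country", "sex", "age_bin", "outcome")

.region_cache <- new.env(parent = emptyenv())

# bundled UN M49 continental grouping, ISO-3166 alpha-2 -> region
country_region_table <- function() {
  if (is.null(.region_cache$tab)) {
    path <- system.file("extdata", "country_regions.tsv", package = "pvsignal")
    .region_cache$tab <- readr::read_tsv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  .region_cache$tab
}

region_of <- function(country) {
  tab <- country_region_table()
  hit <- stats::setNames(tab$region, tab$country)[normalize_term(country)]
  ifelse(is.na(hit), "UNKNOWN", unname(hit))
}

age_bin_of <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "NS",
    age_years < 18 ~ "<18",
    age_years <= 64 ~ "18-64",
    age_years <= 85 ~ "65-85",
    TRUE ~ ">85"
  )
}

distribution_table <- function(rows, dimension, total) {
  out <- tibble::tibble(
    category = as.character(rows$category),
    n = as.integer(rows$n),
    percent = percent_of(rows$n, total)
  )
  attr(out, "dimension") <- dimension
  attr(out, "case_total") <- total
  out
}

#' Report-level distribution over a descriptive dimension
#'
#' Counts reports by category for one of the standard dimensions and
#' expresses each count as a percentage of the case total (one decimal,
#' half-up). Missing demographics are first-class categories (`NS`,
#' `UNKNOWN`), not dropped, since in spontaneous-report data they usually
#' dominate. For every dimension except `outcome` the categories are
#' mutually exclusive, so counts sum to the case total; `outcome` delegates
#' to [outcome_summary()], whose rows are non-exclusive.
#'
#' @param db A `report_db`.
#' @param dimension One of `"role"`, `"year"`, `"region"`, `"country"`,
#'   `"sex"`, `"age_bin"`, `"outcome"`.
#' @param drug Target drug name; required for the `role` dimension, where a
#'   report is categorised by the highest-precedence role its mentions of
#'   `drug` carry (primary suspect > secondary suspect > concomitant >
#'   interacting), `NONE` if the drug is absent from the report.
#' @return Tibble with columns `category`, `n`, `percent`, plus
#'   `dimension` and `case_total` attributes.
#' @export
distribution <- function(db, dimension, drug = NULL) {
  stopifnot(inherits(db, "report_db"))
  if (!dimension %in% DIMENSIONS) {
    stop("unknown dimension '", dimension, "'; valid dimensions: ",
         paste(DIMENSIONS, collapse = ", "), call. = FALSE)
  }
  if (dimension == "outcome") return(outcome_summary(db))
  total <- n_reports(db)

  cat_vec <- switch(dimension,
    role = {
      if (is.null(drug)) stop("dimension 'role' requires a target drug", call. = FALSE)
      mentions <- db$drugs |>
        dplyr::filter(.data$drug_name == normalize_term(drug), !is.na(.data$role_code)) |>
        dplyr::mutate(rank = match(.data$role_code, ROLE_CODES)) |>
        dplyr::group_by(.data$.vid) |>
        dplyr::summarise(role = ROLE_CODES[min(.data$rank)], .groups = "drop")
      stats::setNames(mentions$role, mentions$.vid)[db$cases$.vid] |>
        (\(x) ifelse(is.na(x), "NONE", x))()
    },
    year = ifelse(is.na(db$cases$report_year), "NS", as.character(db$cases$report_year)),
    region = region_of(db$cases$country),
    country = db$cases$country,
    sex = db$cases$sex,
    age_bin = age_bin_of(db$cases$age_years)
  )

  counts <- tibble::tibble(category = cat_vec) |>
    dplyr::count(.data$category, name = "n")
  # exhaustive fixed category sets where the dimension has one
  fixed <- switch(dimension,
    role = c(ROLE_CODES, "NONE"), sex = c("F", "M", "NS"), age_bin = AGE_BIN_LEVELS,
    NULL
  )
  if (!is.null(fixed)) {
    counts <- tibble::tibble(category = fixed) |>
      dplyr::left_join(counts, by = "category") |>
      dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  } else {
    counts <- counts |> dplyr::arrange(dplyr::desc(.data$n), .data$category)
  }
  distribution_table(counts, dimension, total)
}

#' Distribution of unfavorable outcomes
#'
#' One row per outcome code plus an `ANY_UNFAVORABLE` row counting reports
#' with at least one outcome. A report contributes to every outcome it
#' carries, so the rows are non-exclusive and do not sum to the case total.
#'
#' @param db A `report_db`.
#' @return Tibble with columns `category`, `n`, `percent` (of the case
#'   total).
#' @export
outcome_summary <- function(db) {
  stopifnot(inherits(db, "report_db"))
  total <- n_reports(db)
  flat <- unlist(db$cases$outcomes)
  n_any <- sum(lengths(db$cases$outcomes) > 0)
  counts <- tibble::tibble(category = OUTCOME_CODES) |>
    dplyr::left_join(
      tibble::tibble(category = flat) |> dplyr::count(.data$category, name = "n"),
      by = "category"
    ) |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
    dplyr::bind_rows(tibble::tibble(category = "ANY_UNFAVORABLE", n = n_any))
  distribution_table(counts, "outcome", total)
}

#' Reporting rate of a preferred term
#'
#' The reporting rate R of a PT is the percentage of reports in the curated
#' series whose event set contains the term: `100 * n / |db|`. It is a
#' purely descriptive quantity — it makes no comparison against a
#' background and therefore cannot by itself support a signal.
#'
#' @param db A non-empty `report_db`.
#' @param pt Preferred term (any case).
#' @return Tibble with one row: `pt`, `n`, `r_percent` (one decimal,
#'   half-up).
#' @export
reporting_rate <- function(db, pt) {
  stopifnot(inherits(db, "report_db"))
  total <- n_reports(db)
  if (total == 0) stop("reporting rate undefined for an empty database", call. = FALSE)
  pt <- normalize_term(pt)
  n <- sum(db$events$pt == pt)
  tibble::tibble(pt = pt, n = as.integer(n), r_percent = percent_of(n, total))
}

#' Per-PT occurrence counts
#'
#' One occurrence = one (report, PT) pair after within-report collapse, the
#' counting unit shared by reporting rates and SOC aggregation.
#'
#' @param db A `report_db`.
#' @return Tibble with columns `pt`, `n`, sorted by `n` descending then PT.
#' @export
pt_occurrences <- function(db) {
  stopifnot(inherits(db, "report_db"))
  db$events |>
    dplyr::count(.data$pt, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pt)
}

#' Most frequently reported preferred terms
#'
#' The `k` PTs with the largest report counts, with their reporting rates.
#' Deterministic: sorted by count descending, ties broken alphabetically.
#'
#' @param db A non-empty `report_db`.
#' @param k Positive integer.
#' @return Tibble with columns `pt`, `n`, `r_percent`, at most `k` rows.
#' @export
top_terms <- function(db, k = 30) {
  stopifnot(inherits(db, "report_db"), k >= 1)
  total <- n_reports(db)
  if (total == 0) stop("top_terms undefined for an empty database", call. = FALSE)
  pt_occurrences(db) |>
    utils::head(n = k) |>
    dplyr::mutate(r_percent = percent_of(.data$n, total))
}
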