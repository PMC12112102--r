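# Curated spontaneous-report store: ingestion, deduplication, role filtering.
#
# A raw extract has one row per (report, drug, event). Rows sharing the same
# (case_id, report_year) are one *report version*; FAERS resubmissions of a
# case share the case id but carry a different receipt year, which is what
# deduplication later resolves.

ROLE_CODES <- c("PRIMARY_SUSPECT", "SECONDARY_SUSPECT", "CONCOMITANT", "INTERACTING")
OUTCOME_CODES <- c("DEATH", "LIFE_THREATENING", "HOSPITALIZATION", "DISABILITY", "OTHER")

#' Default column map for spontaneous-report extracts
#'
#' Field-to-column mapping used by [read_reports()]. Override any entry to
#' match a local extract layout, or supply a YAML file with a `columns:`
#' block. Fields `case_id`, `drug_name`, `role_code` and `pt` are mandatory;
#' all others are optional and become missing when absent.
#'
#' @return Named list mapping internal field names to file column names.
#' @export
default_column_map <- function() {
  list(
    case_id = "case_id", drug_name = "drug_name", role_code = "role_code",
    pt = "pt", sex = "sex", age = "age", age_unit = "age_unit",
    country = "country", event_year = "event_year", outcomes = "outcomes"
  )
}

# --- token parsers ----------------------------------------------------------

parse_role <- function(x) {
  key <- normalize_term(x)
  lookup <- c(
    "PS" = "PRIMARY_SUSPECT", "PRIMARY SUSPECT" = "PRIMARY_SUSPECT",
    "PRIMARY SUSPECT DRUG" = "PRIMARY_SUSPECT", "PRIMARY_SUSPECT" = "PRIMARY_SUSPECT",
    "SS" = "SECONDARY_SUSPECT", "SECONDARY SUSPECT" = "SECONDARY_SUSPECT",
    "SECONDARY SUSPECT DRUG" = "SECONDARY_SUSPECT", "SECONDARY_SUSPECT" = "SECONDARY_SUSPECT",
    "C" = "CONCOMITANT", "CONCOMITANT" = "CONCOMITANT",
    "I" = "INTERACTING", "INTERACTING" = "INTERACTING"
  )
  unname(lookup[key])
}

parse_sex <- function(x) {
  key <- normalize_term(x)
  out <- rep("NS", length(key))
  out[key %in% c("F", "FEMALE")] <- "F"
  out[key %in% c("M", "MALE")] <- "M"
  out
}

# age + unit -> years; unparseable values become NA, never errors
parse_age_years <- function(age, unit) {
  val <- suppressWarnings(as.numeric(age))
  key <- normalize_term(unit)
  factor_per_unit <- c(
    "YR" = 1, "YEAR" = 1, "YEARS" = 1, "Y" = 1,
    "MON" = 1 / 12, "MONTH" = 1 / 12, "MONTHS" = 1 / 12, "MO" = 1 / 12,
    "DY" = 1 / 365.25, "DAY" = 1 / 365.25, "DAYS" = 1 / 365.25, "D" = 1 / 365.25,
    "DEC" = 10, "DECADE" = 10
  )
  fac <- unname(factor_per_unit[key])
  fac[is.na(key) | !nzchar(key)] <- 1  # blank unit: assume years
  yrs <- val * fac
  yrs[!is.na(yrs) & yrs < 0] <- NA_real_
  yrs
}

# ';'-separated outcome tokens (FAERS codes or spelled-out forms) -> enum.
# Returns list(values = list of character vectors, bad = character of
# unrecognized tokens).
parse_outcomes <- function(x) {
  lookup <- c(
    "DE" = "DEATH", "DEATH" = "DEATH",
    "LT" = "LIFE_THREATENING", "LIFE_THREATENING" = "LIFE_THREATENING",
    "LIFE-THREATENING" = "LIFE_THREATENING", "LIFE THREATENING" = "LIFE_THREATENING",
    "HO" = "HOSPITALIZATION", "HOSPITALIZATION" = "HOSPITALIZATION",
    "HOSPITALIZATION - INITIAL OR PROLONGED" = "HOSPITALIZATION",
    "HOSPITALIZATION-INITIAL OR PROLONGED" = "HOSPITALIZATION",
    "DS" = "DISABILITY", "DISABILITY" = "DISABILITY",
    "OT" = "OTHER", "OTHER" = "OTHER"
  )
  bad <- character(0)
  values <- lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    toks <- normalize_term(strsplit(cell, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    hit <- lookup[toks]
    if (anyNA(hit)) bad <<- c(bad, toks[is.na(hit)])
    sort(unique(unname(hit[!is.na(hit)])))
  })
  list(values = values, bad = bad)
}

# --- report_db class --------------------------------------------------------

new_report_db <- function(cases, drugs, events, provenance) {
  structure(
    list(cases = cases, drugs = drugs, events = events, provenance = provenance),
    class = "report_db"
  )
}

#' Number of reports in a curated database
#' @param db A `report_db`.
#' @return Integer report count.
#' @export
n_reports <- function(db) {
  stopifnot(inherits(db, "report_db"))
  nrow(db$cases)
}

#' @export
print.report_db <- function(x, ...) {
  p <- x$provenance
  cat("<report_db> ", nrow(x$cases), " reports, ",
      nrow(x$events), " (report, PT) occurrences, ",
      length(unique(x$events$pt)), " distinct PTs\n", sep = "")
  cat("  provenance: ", p$rows_read, " rows read, ", p$reports_read,
      " report versions, ", p$duplicates_removed, " duplicates removed, ",
      p$role_excluded, " role-excluded\n", sep = "")
  cat("  deduplicated: ", p$deduplicated, "; role filtered: ",
      p$role_filtered, "\n", sep = "")
  invisible(x)
}

#' Read a spontaneous-report extract into a report database
#'
#' Parses a delimited (CSV/TSV) extract with one row per (report, drug,
#' event) into a `report_db`: one report per distinct (case id, report year)
#' row group, with within-report duplicate events collapsed, drug names and
#' preferred terms normalized (upper-case, whitespace-trimmed), outcome
#' tokens mapped to `{DEATH, LIFE_THREATENING, HOSPITALIZATION, DISABILITY,
#' OTHER}` and unparseable optional fields turned into missing values (with
#' a warning), never errors. Row order does not affect the database content.
#'
#' @param path Path to the delimited file (UTF-8, header row).
#' @param col_map Named list mapping the internal field names of
#'   [default_column_map()] to the file's column names, or the path of a
#'   YAML file with a `columns:` block. Unnamed fields keep their defaults.
#' @param delim Field delimiter; `NULL` picks `"\t"` for `.tsv`/`.tab`
#'   files and `","` otherwise.
#' @return A `report_db` with elements `cases`, `drugs`, `events` (tibbles)
#'   and `provenance` (counts of rows read, report versions, duplicates
#'   removed, role exclusions, plus pipeline-stage flags).
#' @seealso [deduplicate()], [filter_by_role()], [write_reports()]
#' @export
read_reports <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  cmap <- default_column_map()
  if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
    cfg <- yaml::read_yaml(col_map)
    col_map <- cfg$columns %||% cfg
  }
  if (!is.null(col_map)) cmap[names(col_map)] <- col_map
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }

  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) stop("empty input: no data rows in ", path, call. = FALSE)

  mandatory <- c("case_id", "drug_name", "role_code", "pt")
  for (f in mandatory) {
    if (!cmap[[f]] %in% names(raw)) {
      stop("schema error: mandatory column '", cmap[[f]], "' (field ", f,
           ") missing from header", call. = FALSE)
    }
  }
  get_col <- function(field) {
    col <- cmap[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }

  rows <- tibble::tibble(
    .row = seq_len(nrow(raw)),
    case_id = trimws(get_col("case_id")),
    drug_name = normalize_term(get_col("drug_name")),
    role_raw = get_col("role_code"),
    pt = normalize_term(get_col("pt")),
    sex = parse_sex(get_col("sex")),
    age_years = parse_age_years(get_col("age"), get_col("age_unit")),
    country = normalize_term(get_col("country")),
    report_year = suppressWarnings(as.integer(get_col("event_year"))),
    outcomes_raw = get_col("outcomes")
  )
  rows$country[is.na(rows$country) | !nzchar(rows$country)] <- "UNKNOWN"
  rows$role_code <- parse_role(rows$role_raw)
  bad_roles <- unique(rows$role_raw[is.na(rows$role_code) & !is.na(rows$role_raw)])
  if (length(bad_roles) > 0) {
    warning("unrecognized role code token(s) set to missing: ",
            paste(bad_roles, collapse = ", "), call. = FALSE)
  }
  oc <- parse_outcomes(rows$outcomes_raw)
  rows$outcomes <- oc$values
  if (length(oc$bad) > 0) {
    for (tok in unique(oc$bad)) {
      warning("unrecognized outcome token dropped: ", tok, call. = FALSE)
    }
  }
  blank_pt <- !nzchar(rows$pt) | is.na(rows$pt)
  if (any(blank_pt)) {
    warning(sum(blank_pt), " row(s) with blank preferred term dropped", call. = FALSE)
    rows <- rows[!blank_pt, , drop = FALSE]
  }
  if (nrow(rows) == 0) stop("empty input: no usable rows", call. = FALSE)

  # a report version is one (case_id, report_year) row group
  rows$.vid <- paste0(rows$case_id, "\r", ifelse(is.na(rows$report_year), "NA", rows$report_year))

  cases <- rows |>
    dplyr::group_by(.data$.vid) |>
    dplyr::summarise(
      case_id = dplyr::first(.data$case_id),
      report_year = dplyr::first(.data$report_year),
      country = dplyr::first(.data$country),
      sex = { s <- .data$sex[.data$sex != "NS"]; if (length(s)) s[1] else "NS" },
      age_years = { a <- .data$age_years[!is.na(.data$age_years)]; if (length(a)) a[1] else NA_real_ },
      outcomes = list(sort(unique(unlist(.data$outcomes)))),
      .input_order = min(.data$.row),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.input_order)

  drugs <- rows |>
    dplyr::distinct(.data$.vid, .data$case_id, .data$drug_name, .data$role_code) |>
    dplyr::filter(nzchar(.data$drug_name))

  events <- rows |>
    dplyr::distinct(.data$.vid, .data$case_id, pt = .data$pt)

  provenance <- list(
    rows_read = nrow(raw),
    reports_read = nrow(cases),
    duplicates_removed = 0L,
    role_excluded = 0L,
    deduplicated = FALSE,
    role_filtered = FALSE
  )
  new_report_db(cases, drugs, events, provenance)
}

#' Remove duplicate reports sharing a case identifier
#'
#' Retains exactly one report per `case_id`: the version with the latest
#' report year (a missing year loses to any known year), ties broken by
#' keeping the first version in input order. Later FAERS submissions of a
#' case supersede earlier ones, so the freshest version is the authoritative
#' one. Idempotent.
#'
#' @param db A `report_db`.
#' @return A `report_db` with unique `case_id`s;
#'   `provenance$duplicates_removed` is incremented by the number of
#'   versions dropped and `provenance$deduplicated` set to `TRUE`.
#' @export
deduplicate <- function(db) {
  stopifnot(inherits(db, "report_db"))
  keep <- db$cases |>
    dplyr::arrange(
      .data$case_id,
      dplyr::desc(!is.na(.data$report_year)),
      dplyr::desc(.data$report_year),
      .data$.input_order
    ) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE)
  removed <- nrow(db$cases) - nrow(keep)
  cases <- keep |> dplyr::arrange(.data$.input_order)
  vids <- cases$.vid
  db$cases <- cases
  db$drugs <- db$drugs |> dplyr::filter(.data$.vid %in% vids)
  db$events <- db$events |> dplyr::filter(.data$.vid %in% vids)
  db$provenance$duplicates_removed <- db$provenance$duplicates_removed + removed
  db$provenance$deduplicated <- TRUE
  db
}

#' Keep reports where a drug appears with a given role
#'
#' Retains the reports containing at least one mention of `drug` with role
#' `role` (the conventional curation step keeps the cases where the drug of
#' interest is the primary suspect); all other reports are counted as role
#' exclusions in the provenance. Requires a deduplicated database so that
#' report-level counts are well defined.
#'
#' @param db A deduplicated `report_db`.
#' @param drug Drug name (normalized internally).
#' @param role One of `"PRIMARY_SUSPECT"`, `"SECONDARY_SUSPECT"`,
#'   `"CONCOMITANT"`, `"INTERACTING"`.
#' @return Filtered `report_db`; `provenance$role_excluded` incremented.
#' @export
filter_by_role <- function(db, drug, role = "PRIMARY_SUSPECT") {
  stopifnot(inherits(db, "report_db"))
  if (!isTRUE(db$provenance$deduplicated)) {
    stop("filter_by_role() requires a deduplicated database; call deduplicate() first",
         call. = FALSE)
  }
  if (!role %in% ROLE_CODES) {
    stop("unknown role '", role, "'; accepted roles: ",
         paste(ROLE_CODES, collapse = ", "), call. = FALSE)
  }
  drug <- normalize_term(drug)
  hit_vids <- db$drugs |>
    dplyr::filter(.data$drug_name == drug, !is.na(.data$role_code), .data$role_code == role) |>
    dplyr::pull(.data$.vid) |>
    unique()
  excluded <- sum(!db$cases$.vid %in% hit_vids)
  db$cases <- db$cases |> dplyr::filter(.data$.vid %in% hit_vids)
  db$drugs <- db$drugs |> dplyr::filter(.data$.vid %in% hit_vids)
  db$events <- db$events |> dplyr::filter(.data$.vid %in% hit_vids)
  db$provenance$role_excluded <- db$provenance$role_excluded + excluded
  db$provenance$role_filtered <- TRUE
  db
}

#' Write a report database back to the extract layout
#'
#' Emits one row per (report, drug, event) with `';'`-joined outcome tokens,
#' using the default column names, so a curated database round-trips through
#' [read_reports()].
#'
#' @param db A `report_db`.
#' @param path Output file path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_reports <- function(db, path) {
  stopifnot(inherits(db, "report_db"))
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  case_cols <- db$cases |>
    dplyr::mutate(
      outcomes = vapply(.data$outcomes, paste, character(1), collapse = ";"),
      age = ifelse(is.na(.data$age_years), NA_character_, format(.data$age_years)),
      age_unit = ifelse(is.na(.data$age_years), NA_character_, "YR")
    ) |>
    dplyr::select(".vid", "case_id", "report_year", "country", "sex",
                  "age", "age_unit", "outcomes")
  rows <- db$drugs |>
    dplyr::select(".vid", "drug_name", "role_code") |>
    dplyr::inner_join(db$events |> dplyr::select(".vid", "pt"),
                      by = ".vid", relationship = "many-to-many") |>
    dplyr::inner_join(case_cols, by = ".vid") |>
    dplyr::transmute(
      case_id = .data$case_id, drug_name = .data$drug_name,
      role_code = .data$role_code, pt = .data$pt, sex = .data$sex,
      age = .data$age, age_unit = .data$age_unit, country = .data$country,
      event_year = .data$report_year, outcomes = .data$outcomes
    )
  readr::write_delim(rows, path, delim = delim, na = "")
  invisible(path)
}
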