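# Fixture builders and independent oracles shared across the suite.
# All fixtures are built in code; files go to tempdir().

# Write rows (default extract layout) to a temp CSV and return the path.
write_fixture_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(rows, path, na = "")
  path
}

# One extract row with sensible defaults.
fixture_row <- function(case_id, pt, drug_name = "DRUG_X", role_code = "PS",
                        sex = "", age = "", age_unit = "", country = "US",
                        event_year = 2023, outcomes = "") {
  tibble::tibble(case_id = case_id, drug_name = drug_name,
                 role_code = role_code, pt = pt, sex = sex,
                 age = as.character(age), age_unit = age_unit,
                 country = country, event_year = event_year,
                 outcomes = outcomes)
}

# Read a rows tibble straight into a report_db (suppressing parse warnings).
db_from_rows <- function(rows, ...) {
  path <- write_fixture_csv(rows)
  on.exit(unlink(path))
  suppressWarnings(read_reports(path, ...))
}

# A small curated four-report database: two drugs x two PTs, one PT each.
tiny_2x2_db <- function() {
  rows <- dplyr::bind_rows(
    fixture_row("C1", "PT A", drug_name = "DRUGX"),
    fixture_row("C2", "PT B", drug_name = "DRUGX"),
    fixture_row("C3", "PT A", drug_name = "DRUGY"),
    fixture_row("C4", "PT B", drug_name = "DRUGY")
  )
  deduplicate(db_from_rows(rows))
}

# Curated 782-case series matching the marginal counts the descriptive
# tables are validated against: 657 US / 39 JP / 28 FR cases, 39 aged 18-64
# and 18 aged 65-85, hospitalization on 243 cases and death on 86, and PT
# report counts 182/99/90/53/51 for five named terms.
marginal_fixture_db <- function() {
  n <- 782
  country <- c(rep("US", 657), rep("JP", 39), rep("FR", 28), rep("DE", 30),
               rep("GB", 28))
  age <- c(rep("50", 39), rep("70", 18), rep("", n - 57))
  outcomes <- vapply(seq_len(n), function(i) {
    toks <- c(if (i <= 243) "HO", if (i <= 86) "DE")
    paste(toks, collapse = ";")
  }, character(1))
  pts_of <- function(i) {
    c(if (i <= 182) "OFF LABEL USE", if (i <= 99) "FATIGUE",
      if (i <= 90) "NAUSEA", if (i <= 53) "ADRENAL INSUFFICIENCY",
      if (i <= 51) "HEADACHE", if (i > 182) "FILLER PT")
  }
  rows <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    fixture_row(sprintf("CASE%04d", i), pts_of(i), country = country[i],
                age = age[i], age_unit = ifelse(nzchar(age[i]), "YR", ""),
                outcomes = outcomes[i])
  }))
  filter_by_role(deduplicate(db_from_rows(rows)), "DRUG_X", "PRIMARY_SUSPECT")
}

# Independent chi-square oracle: expected counts under independence,
# sum over cells of (|O - E| - correction)^2 / E, deviation floored at 0.
chi2_oracle <- function(a, b, c, d, corrected = TRUE) {
  O <- c(a, b, c, d)
  N <- sum(O)
  row <- c(a + b, a + b, c + d, c + d)
  col <- c(a + c, b + d, a + c, b + d)
  E <- row * col / N
  dev <- abs(O - E)
  if (corrected) dev <- pmax(dev - 0.5, 0)
  sum(dev^2 / E)
}

# Random strictly-positive 2x2 tables for property tests.
random_tables <- function(n, max_cell = 500) {
  tibble::tibble(
    a = sample.int(max_cell, n, replace = TRUE),
    b = sample.int(max_cell, n, replace = TRUE),
    c = sample.int(max_cell, n, replace = TRUE),
    d = sample.int(max_cell, n, replace = TRUE)
  )
}

# Temp PT->SOC mapping file from named character vector (pt -> soc).
write_mapping_tsv <- function(map) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(pt = names(map), soc = unname(map)), path)
  path
}
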