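test_that("rows sharing a case id collapse into one report with unique events", {
  rows <- fixture_row("C1", c("Nausea", "Fatigue", "Nausea"))
  db <- db_from_rows(rows)
  expect_equal(n_reports(db), 1)
  expect_setequal(db$events$pt, c("NAUSEA", "FATIGUE"))
})

test_that("optional fields parse leniently: ages convert, blanks go missing", {
  rows <- dplyr::bind_rows(
    fixture_row("C1", "PT A", age = "52", age_unit = "YR"),
    fixture_row("C2", "PT A", age = "", age_unit = ""),
    fixture_row("C3", "PT A", age = "6", age_unit = "MON"),
    fixture_row("C4", "PT A", age = "oops", age_unit = "YR")
  )
  db <- db_from_rows(rows)
  ages <- db$cases$age_years[match(c("C1", "C2", "C3", "C4"), db$cases$case_id)]
  expect_equal(ages, c(52, NA, 0.5, NA))
})

test_that("malformed outcome tokens warn and are dropped, valid ones kept", {
  rows <- dplyr::bind_rows(
    lapply(1:18, function(i) fixture_row(paste0("C", i), "PT A", outcomes = "HO;DE")),
    fixture_row("C19", "PT A", outcomes = "HO;BOGUS"),
    fixture_row("C20", "PT A", outcomes = "NONSENSE")
  )
  path <- write_fixture_csv(rows)
  warns <- capture_warnings(db <- read_reports(path))
  expect_length(warns, 2)
  expect_match(warns, "unrecognized outcome token", all = TRUE)
  oc <- db$cases$outcomes[match(c("C19", "C20"), db$cases$case_id)]
  expect_equal(oc[[1]], "HOSPITALIZATION")
  expect_equal(oc[[2]], character(0))
  expect_equal(db$provenance$rows_read, 20)
})

test_that("outcome tokens accept both FAERS codes and spelled-out forms", {
  rows <- dplyr::bind_rows(
    fixture_row("C1", "PT A", outcomes = "de;Life-Threatening"),
    fixture_row("C2", "PT A", outcomes = "Hospitalization - Initial or Prolonged;ds;OTHER")
  )
  db <- db_from_rows(rows)
  expect_setequal(db$cases$outcomes[[match("C1", db$cases$case_id)]],
                  c("DEATH", "LIFE_THREATENING"))
  expect_setequal(db$cases$outcomes[[match("C2", db$cases$case_id)]],
                  c("HOSPITALIZATION", "DISABILITY", "OTHER"))
})

test_that("schema errors name the missing column; empty files are rejected", {
  bad <- tibble::tibble(case_id = "C1", drug_name = "D", role_code = "PS")
  path <- write_fixture_csv(bad)
  expect_error(read_reports(path), "pt")
  empty <- fixture_row("C1", "PT A")[0, ]
  expect_error(read_reports(write_fixture_csv(empty)), "empty input")
})

test_that("deduplication keeps the latest report year per case", {
  rows <- dplyr::bind_rows(
    fixture_row("C1", "PT OLD", event_year = 2021),
    fixture_row("C1", "PT NEW", event_year = 2023),
    # same case and year: one report version, merged at read time
    fixture_row("C2", "PT FIRST", event_year = 2022, country = "US"),
    fixture_row("C2", "PT SECOND", event_year = 2022, country = "FR"),
    # missing year loses to a known year
    fixture_row("C3", "PT UNDATED", event_year = NA),
    fixture_row("C3", "PT DATED", event_year = 2020)
  )
  db <- deduplicate(db_from_rows(rows))
  expect_equal(n_reports(db), 3)
  expect_equal(db$events$pt[db$events$case_id == "C1"], "PT NEW")
  expect_setequal(db$events$pt[db$events$case_id == "C2"],
                  c("PT FIRST", "PT SECOND"))
  expect_equal(db$events$pt[db$events$case_id == "C3"], "PT DATED")
  expect_equal(db$provenance$duplicates_removed, 2)
})

test_that("deduplication of a unique-case database is a no-op", {
  rows <- dplyr::bind_rows(lapply(1:5, function(i) fixture_row(paste0("C", i), "PT A")))
  db <- deduplicate(db_from_rows(rows))
  expect_equal(n_reports(db), 5)
  expect_equal(db$provenance$duplicates_removed, 0)
})

test_that("10 rows over 7 case ids leave 7 reports with 3 duplicates removed", {
  years <- list(C1 = c(2021, 2023), C2 = 2022, C3 = c(2020, 2021, 2022),
                C4 = 2023, C5 = 2021, C6 = 2024, C7 = 2019)
  rows <- dplyr::bind_rows(lapply(names(years), function(cid) {
    dplyr::bind_rows(lapply(years[[cid]], function(y) {
      fixture_row(cid, paste("PT", y), event_year = y)
    }))
  }))
  expect_equal(nrow(rows), 10)
  db <- deduplicate(db_from_rows(rows))
  expect_equal(n_reports(db), 7)
  expect_equal(db$provenance$duplicates_removed, 3)
  # latest version retained for every duplicated case
  expect_equal(db$events$pt[db$events$case_id == "C3"], "PT 2022")
})

test_that("role filter keeps any-mention matches and counts exclusions", {
  rows <- dplyr::bind_rows(
    fixture_row("C1", "PT A", role_code = "PS"),
    fixture_row("C2", "PT A", role_code = "C"),                 # concomitant only
    fixture_row("C3", "PT A", role_code = "PS"),
    fixture_row("C3", "PT A", drug_name = "DRUG_X", role_code = "C"),
    fixture_row("C4", "PT A", drug_name = "OTHER", role_code = "PS")
  )
  db <- deduplicate(db_from_rows(rows))
  out <- filter_by_role(db, "DRUG_X", "PRIMARY_SUSPECT")
  expect_setequal(out$cases$case_id, c("C1", "C3"))
  expect_equal(out$provenance$role_excluded, 2)
  expect_error(filter_by_role(db, "DRUG_X", "SUSPICIOUS"), "PRIMARY_SUSPECT")
})

test_that("role filter requires deduplication and rejects unfiltered input", {
  db <- db_from_rows(fixture_row("C1", "PT A"))
  expect_error(filter_by_role(db, "DRUG_X"), "deduplicate")
})

test_that("hand-enumerated role fixture: 9 of 12 reports retained", {
  rows <- dplyr::bind_rows(lapply(1:12, function(i) {
    fixture_row(paste0("C", i), "PT A",
                role_code = if (i <= 9) "PS" else c("SS", "C", "I")[i - 9])
  }))
  out <- filter_by_role(deduplicate(db_from_rows(rows)), "DRUG_X")
  expect_equal(n_reports(out), 9)
  expect_equal(out$provenance$role_excluded, 3)
})

test_that("dedup and role filter are idempotent and conserve provenance", {
  sim <- simulate_reports(synth_config(n_reports = 300, seed = 11))
  db <- db_from_rows(sim$rows)
  d1 <- deduplicate(db)
  d2 <- deduplicate(d1)
  expect_equal(d1$cases$case_id, d2$cases$case_id)
  expect_equal(d2$provenance$duplicates_removed, d1$provenance$duplicates_removed)
  f1 <- filter_by_role(d1, "DRUG_X")
  f2 <- filter_by_role(f1, "DRUG_X")
  expect_equal(n_reports(f1), n_reports(f2))
  # conservation: versions read = kept + duplicates removed + role-excluded
  expect_equal(f1$provenance$reports_read,
               n_reports(f1) + f1$provenance$duplicates_removed +
                 f1$provenance$role_excluded)
})

test_that("shuffling input rows changes no downstream content", {
  sim <- simulate_reports(synth_config(n_reports = 200, seed = 5,
                                       injected_signals = c("PT INJ" = 5)))
  shuffled <- sim$rows[sample.int(nrow(sim$rows)), ]
  db1 <- deduplicate(db_from_rows(sim$rows))
  db2 <- deduplicate(db_from_rows(shuffled))
  expect_equal(n_reports(db1), n_reports(db2))
  expect_equal(pt_occurrences(db1), pt_occurrences(db2))
  s1 <- signal_scan(db1, "DRUG_X")
  s2 <- signal_scan(db2, "DRUG_X")
  expect_equal(s1, s2)
})

test_that("a curated database round-trips through the extract layout", {
  sim <- simulate_reports(synth_config(n_reports = 150, seed = 3))
  db <- deduplicate(db_from_rows(sim$rows))
  path <- tempfile(fileext = ".csv")
  write_reports(db, path)
  back <- deduplicate(read_reports(path))
  expect_equal(n_reports(back), n_reports(db))
  expect_equal(pt_occurrences(back), pt_occurrences(db))
  expect_equal(sort(back$cases$case_id), sort(db$cases$case_id))
  unlink(path)
})
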