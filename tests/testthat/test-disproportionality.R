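test_that("contingency cells partition the database and match brute force", {
  db <- tiny_2x2_db()
  t <- contingency(db, "DRUGX", "PT A")
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_error(contingency(db, "NO SUCH DRUG", "PT A"), "absent")

  # 50-report random fixture vs an exhaustive double loop
  set.seed(99)
  rows <- dplyr::bind_rows(lapply(1:50, function(i) {
    fixture_row(paste0("C", i),
                pt = sample(c("HEADACHE", "NAUSEA", "RASH"), sample(1:2, 1)),
                drug_name = sample(c("DRUGX", "DRUGY", "DRUGZ"), 1))
  }))
  db50 <- deduplicate(db_from_rows(rows))
  t50 <- contingency(db50, "DRUGX", "NAUSEA")
  is_target <- vapply(db50$cases$.vid, function(v) {
    any(db50$drugs$.vid == v & db50$drugs$drug_name == "DRUGX" &
          db50$drugs$role_code == "PRIMARY_SUSPECT")
  }, logical(1))
  has_pt <- vapply(db50$cases$.vid, function(v) {
    any(db50$events$.vid == v & db50$events$pt == "NAUSEA")
  }, logical(1))
  expect_equal(t50$a, sum(is_target & has_pt))
  expect_equal(t50$b, sum(is_target & !has_pt))
  expect_equal(t50$c, sum(!is_target & has_pt))
  expect_equal(t50$d, sum(!is_target & !has_pt))
  expect_equal(t50$a + t50$b + t50$c + t50$d, n_reports(db50))

  # PT carried only by target reports gives c = 0
  rows0 <- dplyr::bind_rows(
    fixture_row("C1", "UNIQUE PT", drug_name = "DRUGX"),
    fixture_row("C2", "COMMON PT", drug_name = "DRUGY")
  )
  t0 <- contingency(deduplicate(db_from_rows(rows0)), "DRUGX", "UNIQUE PT")
  expect_equal(t0$c, 0)
})

test_that("PRR matches hand arithmetic, including the Haldane-corrected case", {
  expect_equal(prr(contingency_table(1, 1, 1, 1)), 1.0)
  expect_equal(prr(contingency_table(10, 90, 100, 9900)), 10.0)
  # zero cell: +0.5 everywhere, then the plain formula
  hand <- (0.5 / 101) / (50.5 / 9901)
  expect_equal(prr(contingency_table(0, 100, 50, 9850)), hand)
  expect_error(prr(contingency_table(0, 100, 50, 9850), zero_cells = "strict"),
               "Haldane")
})

test_that("ROR and Woolf CI match the frozen hand computation", {
  out <- ror_ci(contingency_table(10, 90, 100, 9900))
  expect_equal(out$ror, 11.0)
  # exp(ln 11 +/- 1.959964 * sqrt(1/10 + 1/90 + 1/100 + 1/9900))
  expect_equal(out$ci_low, 5.5594, tolerance = 1e-4)
  expect_equal(out$ci_high, 21.7645, tolerance = 1e-4)

  null <- ror_ci(contingency_table(1, 1, 1, 1))
  expect_equal(null$ror, 1.0)
  expect_lt(null$ci_low, 1)
  expect_gt(null$ci_high, 1)

  # odds-ratio symmetry: transposing the table leaves ROR unchanged
  t1 <- contingency_table(12, 34, 56, 780)
  t2 <- contingency_table(12, 56, 34, 780)
  expect_equal(ror_ci(t1)$ror, ror_ci(t2)$ror)

  expect_error(ror_ci(contingency_table(0, 5, 5, 5), zero_cells = "strict"),
               "Haldane")
})

test_that("chi-square closed form matches stats::chisq.test", {
  t <- contingency_table(10, 90, 100, 9900)
  m <- matrix(c(10, 100, 90, 9900), 2)
  expect_equal(chi_square(t, corrected = FALSE),
               unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic))
  expect_equal(chi_square(t, corrected = TRUE),
               unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic))
  expect_equal(chi_square(contingency_table(1, 1, 1, 1), corrected = FALSE), 0)
  expect_equal(chi_square(t, corrected = FALSE), 74.4541, tolerance = 1e-4)
  expect_error(chi_square(contingency_table(0, 0, 5, 5)), "marginal")
})

test_that("chi-square agrees with the expected-counts oracle on 200 random tables", {
  set.seed(2024)
  tabs <- random_tables(200)
  for (i in seq_len(nrow(tabs))) {
    t <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(chi_square(t, corrected = FALSE),
                 chi2_oracle(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i], FALSE),
                 tolerance = 1e-9)
    expect_equal(chi_square(t, corrected = TRUE),
                 chi2_oracle(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i], TRUE),
                 tolerance = 1e-9)
  }
})

test_that("chi-square is invariant under simultaneous row and column swap", {
  set.seed(31)
  tabs <- random_tables(50)
  for (i in seq_len(nrow(tabs))) {
    t1 <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    t2 <- contingency_table(tabs$d[i], tabs$c[i], tabs$b[i], tabs$a[i])
    expect_equal(chi_square(t1), chi_square(t2))
  }
})

test_that("PRR and ROR deviate from 1 on the same side, with ROR the larger", {
  set.seed(55)
  tabs <- random_tables(300)
  for (i in seq_len(nrow(tabs))) {
    t <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    p <- prr(t); r <- ror_ci(t)$ror
    expect_gte((p - 1) * (r - 1), 0)
    if (p > 1) expect_gte(r, p)
  }
})

test_that("increasing a with b, c, d fixed never decreases PRR or ROR", {
  base <- c(b = 50, c = 30, d = 900)
  prev_p <- -Inf; prev_r <- -Inf
  for (a in c(1, 2, 5, 10, 25, 60)) {
    t <- contingency_table(a, base["b"], base["c"], base["d"])
    p <- prr(t); r <- ror_ci(t)$ror
    expect_gte(p, prev_p)
    expect_gte(r, prev_r)
    prev_p <- p; prev_r <- r
  }
})

test_that("Evans classification applies the strict printed thresholds", {
  crit <- signal_criteria()
  cases <- tibble::tibble(
    n = c(4, 3, 2, 8, 3, 5, 4),
    prr = c(19.42, 4.66, 100, 2.25, 2.0, 1.99, 2.5),
    chi2 = c(49.57, 5.35, 100, 4.38, 10, 10, 4.0)
  )
  # n = 2 fails the case gate; prr = 2 and chi2 = 4 are not strictly above
  expect_equal(evans_classify(cases, crit),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  loose <- signal_criteria(min_cases = 1, chi2_threshold = 1, prr_threshold = 1)
  expect_true(all(evans_classify(cases[c(1, 3), ], loose)))
})

test_that("signal_scan equals per-PT manual computation on a fixture", {
  sim <- simulate_reports(synth_config(n_reports = 2500, seed = 21,
                                       injected_signals = c("PT INJ" = 10)))
  db <- deduplicate(db_from_rows(sim$rows))
  scan <- signal_scan(db, "DRUG_X")
  # every PT on the target drug appears exactly once, ordered n desc then pt
  expect_false(any(duplicated(scan$pt)))
  expect_equal(order(-scan$n, scan$pt), seq_len(nrow(scan)))
  for (i in sample.int(nrow(scan), 10)) {
    t <- contingency(db, "DRUG_X", scan$pt[i])
    expect_equal(unlist(t[c("a", "b", "c", "d")]),
                 c(a = scan$a[i], b = scan$b[i], c = scan$c[i], d = scan$d[i]))
    expect_equal(scan$prr[i], prr(t))
    expect_equal(scan$ror[i], ror_ci(t)$ror)
    expect_equal(scan$chi2[i], chi_square(t, corrected = TRUE))
    expect_equal(scan$is_signal[i],
                 evans_classify(scan[i, ], signal_criteria()))
  }
  # the injected association must be classified as a signal here
  expect_true(scan$is_signal[scan$pt == "PT INJ"])
})

test_that("bubble coordinates are the log2-ROR / root-chi-square pairs", {
  m <- tibble::tibble(pt = c("P1", "P2"), ror = c(1, 8), chi2 = c(0, 49),
                      n = c(3L, 7L))
  out <- bubble_coordinates(m)
  expect_equal(out$x, c(0, 3))
  expect_equal(out$y, c(0, 7))
  expect_equal(out$size, c(3L, 7L))
  # monotone in ROR at fixed chi2
  m2 <- tibble::tibble(pt = c("A", "B"), ror = c(2, 4), chi2 = c(9, 9),
                       n = c(1L, 1L))
  o2 <- bubble_coordinates(m2)
  expect_lt(o2$x[1], o2$x[2])
  expect_error(bubble_coordinates(tibble::tibble(pt = "X", ror = 0, chi2 = 1, n = 1L)),
               "ror > 0")
})
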