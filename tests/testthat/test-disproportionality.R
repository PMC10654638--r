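test_that("build_table counts primary-suspect and event co-occurrence", {
  st <- store_from_rows(c(
    "i1\tc1\t1\tProlia|primary_suspect\tdeath;pain\t\t\t\t\t2020\t",
    "i2\tc2\t1\tProlia|primary_suspect\tnausea\t\t\t\t\t2020\t",
    "i3\tc3\t1\tZOMETA|primary_suspect\tdeath\t\t\t\t\t2020\t",
    "i4\tc4\t1\tProlia|concomitant\tdeath\t\t\t\t\t2020\t"
  ), lexicon = two_drug_lexicon())
  dd <- deduplicate(st)
  tab <- build_table(dd, "denosumab", "death")
  expect_equal(c(tab$DE, tab$De, tab$dE, tab$de), c(1, 1, 2, 0))
  expect_equal(unname(table_margins(tab)[["N"]]), nrow(dd))
  ## degenerate store: every report has drug and event
  all_in <- make_store_direct(5, "denosumab", events = list("death"))
  t2 <- build_table(all_in, "denosumab", "death")
  expect_equal(c(t2$DE, t2$De, t2$dE, t2$de), c(5, 0, 0, 0))
})

test_that("ledger recount: table cells match an independent filter pass", {
  sim <- generate_reports(test_sim_config(3000, seed = 13))
  dd <- deduplicate(sim$store)
  drug <- "denosumab"; event <- "osteonecrosis of jaw"
  tab <- build_table(dd, drug, event)
  ## brute-force recount, row by row
  d <- vapply(seq_len(nrow(dd)), function(i) {
    any(dd$drug_canonical[[i]] == drug &
          dd$drug_role[[i]] == "primary_suspect", na.rm = TRUE)
  }, logical(1))
  e <- vapply(dd$events, function(v) event %in% v, logical(1))
  expect_equal(tab$DE, sum(d & e))
  expect_equal(tab$De, sum(d & !e))
  expect_equal(tab$dE, sum(!d & e))
  expect_equal(tab$de, sum(!d & !e))
  ## swapping the index drug to the background complements the D margin
  tb <- build_table(dd, "background", event)
  m <- table_margins(tab); mb <- table_margins(tb)
  expect_equal(unname(m[["N"]]), unname(mb[["N"]]))
  za <- table_margins(build_table(dd, "zoledronic acid", event))
  expect_equal(unname(m[["D"]] + mb[["D"]] + za[["D"]]), unname(m[["N"]]))
})

test_that("ROR matches cross-product arithmetic, with Wald interval", {
  expect_equal(compute_ror(contingency_table(10, 90, 100, 900))$ror, 1)
  r <- compute_ror(contingency_table(30, 70, 50, 950))
  expect_equal(r$ror, (30 * 950) / (70 * 50))
  se <- sqrt(1 / 30 + 1 / 70 + 1 / 50 + 1 / 950)
  expect_equal(r$ci_low, exp(log(r$ror) - 1.96 * se))
  expect_equal(r$ci_high, exp(log(r$ror) + 1.96 * se))
  ## zero cells: non-evaluable result with reason, never an error
  z <- compute_ror(contingency_table(5, 0, 3, 10))
  expect_false(z$evaluable)
  expect_true(is.na(z$ror))
  expect_match(z$reason, "zero")
})

test_that("PRR matches the ratio of proportions", {
  expect_equal(compute_prr(contingency_table(10, 90, 100, 900))$prr, 1)
  expect_equal(compute_prr(contingency_table(30, 70, 50, 950))$prr, 6)
  z <- compute_prr(contingency_table(5, 5, 0, 10))
  expect_false(z$evaluable)
})

test_that("Yates chi-squared matches the independent oracle and clamps", {
  ## exact independence: the continuity term is clamped to zero
  expect_equal(compute_chi2_yates(contingency_table(10, 90, 100, 900))$chi2, 0)
  got <- compute_chi2_yates(contingency_table(30, 70, 50, 950))$chi2
  expect_equal(got, chisq_oracle(30, 70, 50, 950), tolerance = 1e-12)
  expect_equal(round(got, 1), 80.6)
  z <- compute_chi2_yates(contingency_table(0, 0, 5, 5))
  expect_false(z$evaluable)
})

test_that("statistics agree with independent implementations on random tables", {
  tabs <- random_tables(300, seed = 99)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$DE[i]; b <- tabs$De[i]; c <- tabs$dE[i]; d <- tabs$de[i]
    tab <- contingency_table(a, b, c, d)
    expect_equal(compute_ror(tab)$ror, (a / b) / (c / d), tolerance = 1e-10)
    expect_equal(compute_prr(tab)$prr, (a / (a + b)) / (c / (c + d)),
                 tolerance = 1e-10)
    expect_equal(compute_chi2_yates(tab)$chi2, chisq_oracle(a, b, c, d),
                 tolerance = 1e-10)
  }
})

test_that("transpose symmetry and column-swap reciprocity hold", {
  tabs <- random_tables(50, seed = 7, max_cell = 1e4)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$DE[i]; b <- tabs$De[i]; c <- tabs$dE[i]; d <- tabs$de[i]
    expect_equal(compute_chi2_yates(contingency_table(a, b, c, d))$chi2,
                 compute_chi2_yates(contingency_table(a, c, b, d))$chi2,
                 tolerance = 1e-12)
    expect_equal(compute_ror(contingency_table(c, d, a, b))$ror,
                 1 / compute_ror(contingency_table(a, b, c, d))$ror,
                 tolerance = 1e-12)
  }
})

test_that("exact independence gives ror 1, prr 1, chi2 0", {
  for (k in c(1, 3, 10)) {
    tab <- contingency_table(5 * k, 45 * k, 50 * k, 450 * k)
    expect_equal(compute_ror(tab)$ror, 1)
    expect_equal(compute_prr(tab)$prr, 1)
    expect_equal(compute_chi2_yates(tab)$chi2, 0)
  }
})

test_that("evaluate_signal applies all five criteria", {
  ## DE below the count threshold can never be significant
  weak <- contingency_table(2, 8, 10, 980)
  expect_false(evaluate_signal(weak)$significant)
  ## the worked example passes every criterion
  s <- evaluate_signal(contingency_table(30, 70, 50, 950))
  expect_true(s$significant)
  expect_gt(s$ror, 2); expect_gt(s$prr, 2); expect_gt(s$chi2, 4)
  expect_gt(s$ci_low, 1)
  ## non-evaluable statistics fail their criterion
  ne <- evaluate_signal(contingency_table(10, 0, 5, 100))
  expect_false(ne$significant)
})

test_that("threshold boundary: inclusive by default, strict on request", {
  ## engineered table with ROR exactly 2.0; PRR is necessarily below the
  ## ROR, so relax the PRR threshold to isolate the boundary semantics
  tab <- contingency_table(40, 20, 100, 100)
  expect_equal(compute_ror(tab)$ror, 2)
  crit <- signal_criteria(min_prr = 1, min_chi2 = 1)
  crit_strict <- signal_criteria(min_prr = 1, min_chi2 = 1, strict = TRUE)
  expect_true(evaluate_signal(tab, crit)$significant)
  expect_false(evaluate_signal(tab, crit_strict)$significant)
})

test_that("detect_signals ranks by DE with lexicographic tie-break", {
  st <- make_store_direct(
    40, "denosumab",
    events = c(rep(list(c("zeta event", "alpha event")), 6),
               rep(list("beta event"), 6),
               rep(list("rare event"), 1),
               rep(list(character(0)), 27)))
  bg <- make_store_direct(200, "background", events = list(character(0)))
  bg$isr_id <- sprintf("B%07d", seq_len(200))
  bg$case_id <- sprintf("BC%06d", seq_len(200))
  full <- report_store(data.table::rbindlist(list(st, bg)),
                       deduplicated = TRUE)
  sig <- detect_signals(full, "denosumab")
  expect_s3_class(sig, "signal_table")
  ## every event with DE >= 1 appears once
  expect_setequal(sig$event,
                  c("zeta event", "alpha event", "beta event", "rare event"))
  ## equal-DE significant events are in lexicographic order
  top <- sig$event[sig$DE == 6]
  expect_identical(top, sort(top))
  expect_equal(attr(sig, "n_significant"), sum(sig$significant))
})

test_that("detect_signals flags exactly the planted strong signals", {
  cfg <- test_sim_config(20000, seed = 31, duplicate_rate = 0.1)
  sim <- generate_reports(cfg)
  dd <- deduplicate(sim$store)
  sig_dmab <- detect_signals(dd, "denosumab")
  expect_identical(sig_dmab$event[sig_dmab$significant],
                   "osteonecrosis of jaw")
  sig_za <- detect_signals(dd, "zoledronic acid")
  expect_identical(sig_za$event[sig_za$significant], "tooth extraction")
  ## empty overlap case
  none <- detect_signals(dd, "denosumab",
                         criteria = signal_criteria(min_ror = 1e6))
  expect_equal(attr(none, "n_significant"), 0L)
})
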