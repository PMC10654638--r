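## shared fixtures: all test data is built in code at run time

two_drug_lexicon <- function() {
  drug_lexicon(list(
    denosumab = c("DENOSUMAB", "Prolia", "Xgeva", "Ranmark"),
    "zoledronic acid" = c("ZOLEDRONIC ACID", "ZOLEDRONATE", "ACLASTA",
                          "RECLAST", "ZOMETA")
  ))
}

## direct bulk construction of a (deduplicated) single-role store; every
## argument recycles to n
make_store_direct <- function(n, drug, events = NULL, indications = NULL,
                              sex = NA_character_, age = NA_real_,
                              country = NA_character_, year = 2020L,
                              outcomes = NULL, dedup = TRUE) {
  as_listcol <- function(x) {
    if (is.null(x)) rep(list(character(0)), n)
    else if (is.list(x)) rep_len(x, n)
    else rep_len(list(x), n)
  }
  dt <- data.table::data.table(
    isr_id = sprintf("I%07d", seq_len(n)),
    case_id = sprintf("C%07d", seq_len(n)),
    version = 1L,
    drug_verbatim = as.list(rep_len(drug, n)),
    drug_canonical = as.list(rep_len(drug, n)),
    drug_role = rep(list("primary_suspect"), n),
    events = as_listcol(events),
    indications = as_listcol(indications),
    sex = rep_len(sex, n),
    age_years = rep_len(as.numeric(age), n),
    country = rep_len(country, n),
    year = rep_len(as.integer(year), n),
    outcomes = as_listcol(outcomes)
  )
  report_store(dt, deduplicated = dedup)
}

## tiny store from TSV-style rows (exercises the reader); each row is the
## tab-joined tail after isr_id, so tests stay readable
store_from_rows <- function(rows, lexicon = NULL, strict = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste(c("isr_id", "case_id", "version", "drugs", "events",
                    "indications", "sex", "age_years", "country", "year",
                    "outcomes"), collapse = "\t")
  writeLines(c(header, rows), path)
  read_reports(path, lexicon = lexicon, strict = strict)
}

## small, fast simulation world for unit tests
test_sim_config <- function(n_reports = 5000, seed = 1,
                            duplicate_rate = 0.2, planted = NULL, ...) {
  if (is.null(planted)) {
    planted <- list(
      planted_association("denosumab", "osteonecrosis of jaw", 8, 0.02),
      planted_association("zoledronic acid", "tooth extraction", 12, 0.015)
    )
  }
  sim_config(
    n_reports,
    drug_shares = c(denosumab = 0.35, "zoledronic acid" = 0.15),
    event_vocab = c("death" = 0.08, "pain" = 0.05, "nausea" = 0.04,
                    "osteonecrosis of jaw" = 0.02,
                    "tooth extraction" = 0.015),
    indication_vocab = list(
      denosumab = c("osteoporosis" = 0.5, "breast cancer" = 0.05),
      "zoledronic acid" = c("osteoporosis" = 0.3, "breast cancer" = 0.1),
      background = c("hypertension" = 0.2)
    ),
    planted = planted,
    duplicate_rate = duplicate_rate,
    seed = seed,
    ...
  )
}

## independent Yates chi-squared oracle (base R implementation)
chisq_oracle <- function(DE, De, dE, de) {
  m <- matrix(c(DE, De, dE, de), nrow = 2)
  suppressWarnings(unname(stats::chisq.test(m, correct = TRUE)$statistic))
}

random_tables <- function(n, seed, max_cell = 1e6) {
  withr::with_seed(seed, {
    data.frame(
      DE = sample.int(max_cell, n, replace = TRUE),
      De = sample.int(max_cell, n, replace = TRUE),
      dE = sample.int(max_cell, n, replace = TRUE),
      de = sample.int(max_cell, n, replace = TRUE)
    )
  })
}
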