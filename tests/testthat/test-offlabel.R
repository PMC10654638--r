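za_label <- function() {
  drug_label("zoledronic acid",
             approved_indications = c("osteoporosis", "bone metastasis"),
             labeled_aes = c("osteonecrosis of jaw", "pyrexia"))
}

test_that("find_offlabel ranks indications absent from the label", {
  st <- make_store_direct(
    40, "zoledronic acid",
    indications = c(rep(list("osteoporosis"), 20),
                    rep(list(c("breast cancer", "osteoporosis")), 5),
                    rep(list("prostate cancer"), 3),
                    rep(list("renal cancer"), 3),
                    rep(list(character(0)), 9)))
  off <- find_offlabel(st, "zoledronic acid", za_label())
  expect_identical(off$indication,
                   c("breast cancer", "prostate cancer", "renal cancer"))
  expect_equal(off$n, c(5L, 3L, 3L))
  ## ties broken lexicographically; percentages use the drug total (40)
  expect_equal(off$pct, c(12.5, 7.5, 7.5))
  expect_equal(attr(off, "drug_total"), 40L)
})

test_that("a store with only approved indications yields no off-label rows", {
  st <- make_store_direct(10, "zoledronic acid",
                          indications = list("osteoporosis"))
  expect_equal(nrow(find_offlabel(st, "zoledronic acid", za_label())), 0L)
})

test_that("off-label counts match a ledger recount on synthetic stores", {
  sim <- generate_reports(test_sim_config(3000, seed = 8))
  dd <- deduplicate(sim$store)
  label <- drug_label("denosumab", "osteoporosis", "death")
  off <- find_offlabel(dd, "denosumab", label)
  ps <- filter_primary_suspect(dd, "denosumab")
  recount <- sum(vapply(ps$indications,
                        function(v) "breast cancer" %in% v, logical(1)))
  expect_equal(off$n[off$indication == "breast cancer"], recount)
  ## observed vocabulary is partitioned into on- and off-label
  seen <- unique(unlist(ps$indications))
  expect_setequal(c(intersect(seen, label$approved_indications),
                    off$indication), seen)
})

test_that("profile_indication_aes excludes labeled AEs and uses the subgroup denominator", {
  st <- make_store_direct(
    30, "zoledronic acid",
    indications = c(rep(list("breast cancer"), 10),
                    rep(list(character(0)), 20)),
    events = c(rep(list(c("death", "osteonecrosis of jaw")), 4),
               rep(list("impaired healing"), 6),
               rep(list("death"), 20)))
  prof <- profile_indication_aes(st, "zoledronic acid", "breast cancer",
                                 za_label())
  expect_equal(attr(prof, "denominator"), 10L)
  ## labeled AE excluded; counts restricted to the subgroup
  expect_false("osteonecrosis of jaw" %in% prof$term)
  expect_equal(prof[term == "impaired healing"]$n, 6L)
  expect_equal(prof[term == "death"]$n, 4L)
  expect_equal(prof[term == "death"]$pct, 40)
})

test_that("an empty subgroup warns and returns an empty profile", {
  st <- make_store_direct(5, "zoledronic acid", indications = NULL)
  expect_warning(
    prof <- profile_indication_aes(st, "zoledronic acid", "breast cancer",
                                   za_label()),
    "no primary-suspect reports")
  expect_equal(nrow(prof), 0L)
})

test_that("grouping aggregates constituents, counting a report once per group", {
  gpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list("emotional disorder" =
                              c("confusional state", "depressed mood")),
                       gpath)
  grouping <- load_grouping(gpath)
  st <- make_store_direct(
    10, "zoledronic acid",
    indications = list("breast cancer"),
    events = c(list(c("confusional state", "depressed mood")),  # one report
               rep(list("confusional state"), 2),
               rep(list("depressed mood"), 3),
               rep(list(character(0)), 4)))
  prof <- profile_indication_aes(st, "zoledronic acid", "breast cancer",
                                 za_label(), grouping = grouping)
  grp <- prof[term == "emotional disorder"]
  expect_equal(grp$n, 6L)  # 1 + 2 + 3, double-carrier counted once
  expect_setequal(grp$members[[1]], c("confusional state", "depressed mood"))
  ## bounds: max member count <= grouped count <= sum of member counts
  expect_gte(grp$n, 4L)
  expect_lte(grp$n, 7L)
})

test_that("load_grouping validates membership and handles the empty file", {
  good <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(g1 = c("a term", "b term"), g2 = "c term"), good)
  g <- load_grouping(good)
  expect_length(g$groups, 2L)
  expect_identical(unname(g$member_to_group[["a term"]]), "g1")

  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", empty)
  expect_length(load_grouping(empty)$groups, 0L)

  dup_in <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(g1 = c("a term", "A  term")), dup_in)
  expect_error(load_grouping(dup_in), "twice")

  dup_across <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(g1 = "a term", g2 = c("a term", "b")), dup_across)
  expect_error(load_grouping(dup_across), "two groups")
})

test_that("bundled grouping fixture loads", {
  g <- load_grouping(system.file("extdata", "ae_grouping.json",
                                 package = "pvsignal"))
  expect_setequal(names(g$groups), c("emotional disorder",
                                     "cardiac disorders"))
})

test_that("emitted percentages recompute from n and the denominator", {
  sim <- generate_reports(test_sim_config(2000, seed = 19))
  dd <- deduplicate(sim$store)
  label <- drug_label("zoledronic acid", "osteoporosis", "death")
  off <- find_offlabel(dd, "zoledronic acid", label)
  expect_equal(off$pct,
               round(100 * off$n / attr(off, "drug_total") + 1e-12, 2))
  prof <- profile_indication_aes(dd, "zoledronic acid", "breast cancer",
                                 label)
  expect_equal(prof$pct,
               round(100 * prof$n / attr(prof, "denominator") + 1e-12, 1))
})
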