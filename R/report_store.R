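## Internal representation: a data.table with one row per individual safety
## report (ISR). Multi-valued fields are list columns of character vectors:
##   drug_verbatim / drug_canonical / drug_role  (parallel, per drug entry)
##   events / indications / outcomes
## Scalar columns: isr_id, case_id, version, sex, age_years, country, year.
## Unknown scalar values are NA; sex is one of "female"/"male"/NA.

DRUG_ROLES <- c("primary_suspect", "secondary_suspect", "concomitant",
                "interacting")
OUTCOME_CATEGORIES <- c("death", "life_threatening", "hospitalization",
                        "disability", "congenital_anomaly",
                        "required_intervention", "other")
SEX_LEVELS <- c("female", "male")

#' Construct a report store
#'
#' A report store is the in-memory collection of individual safety reports
#' (ISRs). Each report carries one or more drug entries with role codes
#' (primary suspect, secondary suspect, concomitant, interacting), a set of
#' adverse-event preferred terms, a set of indication terms, demographics
#' (sex, age, country), the report year, and serious-outcome flags. A case
#' may be present in several versions (duplicates); see [deduplicate()].
#'
#' @param reports a `data.frame`/`data.table` with columns `isr_id`,
#'   `case_id`, `version` (integer), list columns `drug_verbatim`,
#'   `drug_canonical`, `drug_role`, `events`, `indications`, `outcomes`
#'   (character vectors per report), and scalars `sex`, `age_years`,
#'   `country`, `year`.
#' @param deduplicated logical; `TRUE` asserts at most one report per
#'   `case_id` (validated).
#' @return an object of class `report_store` (a `data.table` subclass).
#' @export
report_store <- function(reports, deduplicated = FALSE) {
  required <- c("isr_id", "case_id", "version", "drug_verbatim",
                "drug_canonical", "drug_role", "events", "indications",
                "sex", "age_years", "country", "year", "outcomes")
  miss <- setdiff(required, names(reports))
  if (length(miss)) {
    stop("report_store missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ## assemble by reference to the column vectors — no deep copy of the list
  ## columns (copy-on-write protects the caller)
  dt <- data.table::setDT(
    stats::setNames(lapply(required, function(cl) reports[[cl]]), required))
  dt[, isr_id := as.character(isr_id)]
  dt[, case_id := as.character(case_id)]
  dt[, version := as.integer(version)]
  if (anyDuplicated(dt$isr_id)) {
    stop("isr_id values must be unique within a store", call. = FALSE)
  }
  if (any(dt$version < 0L, na.rm = TRUE)) {
    stop("report versions must be non-negative", call. = FALSE)
  }
  if (any(lengths(dt$drug_verbatim) == 0L)) {
    stop("every report must list at least one drug", call. = FALSE)
  }
  all_roles <- unlist(dt$drug_role, use.names = FALSE)
  if (!all(all_roles %in% DRUG_ROLES)) {
    bad_role <- !vapply(dt$drug_role,
                        function(r) all(r %in% DRUG_ROLES), logical(1))
    stop("unknown drug role code in report(s): ",
         paste(head(dt$isr_id[bad_role], 5L), collapse = ", "), call. = FALSE)
  }
  all_out <- unlist(dt$outcomes, use.names = FALSE)
  if (!all(all_out %in% OUTCOME_CATEGORIES)) {
    bad_out <- !vapply(dt$outcomes,
                       function(o) all(o %in% OUTCOME_CATEGORIES), logical(1))
    stop("unknown outcome category in report(s): ",
         paste(head(dt$isr_id[bad_out], 5L), collapse = ", "), call. = FALSE)
  }
  bad_sex <- !(is.na(dt$sex) | dt$sex %in% SEX_LEVELS)
  if (any(bad_sex)) stop("sex must be 'female', 'male' or NA", call. = FALSE)
  if (isTRUE(deduplicated) && anyDuplicated(dt$case_id)) {
    stop("store flagged deduplicated but has repeated case_ids", call. = FALSE)
  }
  data.table::setattr(dt, "deduplicated", isTRUE(deduplicated))
  data.table::setattr(dt, "class",
                      c("report_store", "data.table", "data.frame"))
  dt
}

#' @export
print.report_store <- function(x, ...) {
  cat("<report_store> ", nrow(x), " reports, ",
      data.table::uniqueN(x$case_id), " distinct cases",
      if (is_deduplicated(x)) " [deduplicated]", "\n", sep = "")
  invisible(x)
}

#' Is a store deduplicated?
#' @param store a [report_store()].
#' @return logical flag.
#' @export
is_deduplicated <- function(store) {
  isTRUE(attr(store, "deduplicated"))
}

#' Remove duplicate case versions
#'
#' Spontaneous-report databases carry successive submissions of the same
#' case; analyses must count each case once. For every `case_id` the report
#' with the highest `(version, isr_id)` lexicographic key is retained — the
#' latest submission, with the ISR identifier as a deterministic tie-break.
#' Idempotent; the result is flagged deduplicated.
#'
#' @param store a [report_store()].
#' @return a deduplicated [report_store()].
#' @export
deduplicate <- function(store) {
  stopifnot(inherits(store, "report_store"))
  ord <- order(store$case_id, store$version, store$isr_id, method = "radix")
  last_of_case <- !duplicated(store$case_id[ord], fromLast = TRUE)
  keep <- sort(ord[last_of_case])
  report_store(store[keep], deduplicated = TRUE)
}

#' Restrict to reports naming a drug as primary suspect
#'
#' Keeps reports in which at least one drug entry resolves to `drug` with
#' role code primary suspect — the restriction used to attribute an adverse
#' event to the drug most likely responsible.
#'
#' @param store a deduplicated [report_store()].
#' @param drug canonical drug name.
#' @param lexicon optional [drug_lexicon()]; when supplied, `drug` must be a
#'   canonical name of the lexicon (unknown names are a configuration error).
#' @return a [report_store()] with the matching subset.
#' @export
filter_primary_suspect <- function(store, drug, lexicon = NULL) {
  stopifnot(inherits(store, "report_store"))
  if (!is_deduplicated(store)) {
    stop("filter_primary_suspect() requires a deduplicated store; ",
         "call deduplicate() first", call. = FALSE)
  }
  drug <- normalize_term(drug)
  if (!is.null(lexicon) && !drug %in% lexicon_drugs(lexicon)) {
    stop("unknown canonical drug name: '", drug, "'", call. = FALSE)
  }
  hit <- ps_mask(store, drug)
  out <- store[hit]
  data.table::setattr(out, "deduplicated", TRUE)
  data.table::setattr(out, "class",
                      c("report_store", "data.table", "data.frame"))
  out
}

## logical mask: report has `drug` with role primary_suspect (flattened for
## speed on large stores)
ps_mask <- function(store, drug) {
  n <- nrow(store)
  if (n == 0L) return(logical(0))
  row <- rep.int(seq_len(n), lengths(store$drug_canonical))
  cn <- unlist(store$drug_canonical, use.names = FALSE)
  role <- unlist(store$drug_role, use.names = FALSE)
  hit <- row[!is.na(cn) & cn == drug & role == "primary_suspect"]
  mask <- logical(n)
  mask[hit] <- TRUE
  mask
}

## logical mask: report carries `term` in the given list column
term_mask <- function(col, term) {
  n <- length(col)
  if (n == 0L) return(logical(0))
  row <- rep.int(seq_len(n), lengths(col))
  val <- unlist(col, use.names = FALSE)
  mask <- logical(n)
  mask[row[!is.na(val) & val == term]] <- TRUE
  mask
}

SUB_DELIM <- ";"
REPORT_COLUMNS <- c("isr_id", "case_id", "version", "drugs", "events",
                    "indications", "sex", "age_years", "country", "year",
                    "outcomes")

#' Read / write report stores as tab-separated text
#'
#' The on-disk dialect is a UTF-8 TSV with a header row and columns
#' `isr_id, case_id, version, drugs, events, indications, sex, age_years,
#' country, year, outcomes`. Drug entries are serialized `"name|role"` and
#' joined by `";"`; `events`, `indications` and `outcomes` are `";"`-joined.
#' Empty strings denote unknown values. The round trip
#' `read_reports(write_reports(store))` is lossless given the same lexicon.
#'
#' @param path file path.
#' @param lexicon optional [drug_lexicon()] used to resolve canonical drug
#'   names at ingest; without it every drug is unresolved.
#' @param strict logical; `TRUE` (default) aborts on the first malformed row
#'   (reporting its line number), `FALSE` skips malformed rows with one
#'   warning listing them.
#' @return `read_reports()`: a [report_store()] (not deduplicated);
#'   `write_reports()`: `path`, invisibly.
#' @export
read_reports <- function(path, lexicon = NULL, strict = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", na.strings = NULL,
                          encoding = "UTF-8")
  miss <- setdiff(REPORT_COLUMNS, names(dt))
  if (length(miss)) {
    stop("report file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(dt)
  problems <- character(0)
  flag <- function(rows, what) {
    if (any(rows)) {
      problems <<- c(problems, paste0("line ", which(rows) + 1L, ": ", what))
    }
    rows
  }
  bad <- flag(dt$isr_id == "" | dt$case_id == "", "missing isr_id/case_id")
  ver <- suppressWarnings(as.integer(dt$version))
  bad <- bad | flag(is.na(ver) | ver < 0L, "bad version")
  yr <- suppressWarnings(as.integer(dt$year))
  bad <- bad | flag(dt$year != "" & is.na(yr), "bad year")
  split_sub <- function(x) strsplit(x, SUB_DELIM, fixed = TRUE)
  drugs_raw <- split_sub(dt$drugs)
  parsed <- lapply(drugs_raw, function(entries) {
    entries <- entries[entries != ""]
    parts <- strsplit(entries, "|", fixed = TRUE)
    ok <- lengths(parts) == 2L
    list(name = vapply(parts[ok], `[`, "", 1L),
         role = vapply(parts[ok], `[`, "", 2L),
         ok = all(ok) && length(entries) > 0L)
  })
  bad <- bad | flag(!vapply(parsed, `[[`, logical(1), "ok"),
                    "malformed drugs field")
  role_ok <- vapply(parsed, function(p) all(p$role %in% DRUG_ROLES),
                    logical(1))
  bad <- bad | flag(!role_ok, "unknown drug role")
  sex <- ifelse(dt$sex == "", NA_character_, tolower(dt$sex))
  bad <- bad | flag(!(is.na(sex) | sex %in% SEX_LEVELS), "bad sex")
  out_raw <- split_sub(dt$outcomes)
  out_ok <- vapply(out_raw, function(o) all(o[o != ""] %in% OUTCOME_CATEGORIES),
                   logical(1))
  bad <- bad | flag(!out_ok, "unknown outcome category")
  if (any(bad)) {
    msg <- paste(head(problems, 20L), collapse = "; ")
    if (strict) stop("malformed report row(s): ", msg, call. = FALSE)
    warning("skipping ", sum(bad), " malformed row(s): ", msg, call. = FALSE)
  }
  keep <- !bad
  norm_set <- function(lst) {
    lapply(lst, function(v) unique(normalize_term(v[v != ""])))
  }
  verbatim <- lapply(parsed[keep], `[[`, "name")
  canonical <- if (is.null(lexicon)) {
    lapply(verbatim, function(v) rep(NA_character_, length(v)))
  } else {
    lapply(verbatim, resolve_drug, lexicon = lexicon)
  }
  age <- suppressWarnings(as.numeric(dt$age_years))
  report_store(data.table::data.table(
    isr_id = dt$isr_id[keep],
    case_id = dt$case_id[keep],
    version = ver[keep],
    drug_verbatim = verbatim,
    drug_canonical = canonical,
    drug_role = lapply(parsed[keep], `[[`, "role"),
    events = norm_set(split_sub(dt$events)[keep]),
    indications = norm_set(split_sub(dt$indications)[keep]),
    sex = sex[keep],
    age_years = age[keep],
    country = ifelse(dt$country[keep] == "", NA_character_, dt$country[keep]),
    year = yr[keep],
    outcomes = lapply(out_raw[keep], function(o) unique(o[o != ""]))
  ))
}

#' @rdname read_reports
#' @param store a [report_store()].
#' @export
write_reports <- function(store, path) {
  stopifnot(inherits(store, "report_store"))
  join <- function(lst) vapply(lst, paste, "", collapse = SUB_DELIM)
  flat <- data.table::data.table(
    isr_id = store$isr_id,
    case_id = store$case_id,
    version = store$version,
    drugs = join(mapply(function(nm, role) paste(nm, role, sep = "|"),
                        store$drug_verbatim, store$drug_role,
                        SIMPLIFY = FALSE)),
    events = join(store$events),
    indications = join(store$indications),
    sex = ifelse(is.na(store$sex), "", store$sex),
    age_years = ifelse(is.na(store$age_years), "",
                       as.character(store$age_years)),
    country = ifelse(is.na(store$country), "", store$country),
    year = ifelse(is.na(store$year), "", as.character(store$year)),
    outcomes = join(store$outcomes)
  )
  data.table::fwrite(flat, path, sep = "\t", quote = FALSE)
  invisible(path)
}
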