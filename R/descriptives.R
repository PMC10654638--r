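#' Demographic summary for one drug's reports
#'
#' Sex, age and reporting-country composition of the drug's deduplicated
#' primary-suspect reports, in the layout customary for spontaneous-report
#' characteristics tables. Missing demographics are explicit "unknown"
#' categories, never dropped. Age median and quartiles are computed over
#' known ages only with linear-interpolation (type 7) quantiles; age bins
#' are `<18`, `[18, 40]`, `(40, 65]`, `>65`, plus unknown.
#'
#' @param store a deduplicated [report_store()].
#' @param drug canonical drug name.
#' @param top_countries how many countries to list individually before
#'   collapsing the rest into "others" (default 2, mirroring the usual
#'   US/Canada/others layout).
#' @param digits percentage rounding (default 2, half-away-from-zero).
#' @return an object of class `demographic_summary`: list with `total`,
#'   `sex` (`data.table` level/n/pct), `age_median`, `age_q1`, `age_q3`
#'   (NA when no age is known), `age_bins` (`data.table`), and `countries`
#'   (`data.table`).
#' @export
summarize_demographics <- function(store, drug, top_countries = 2L,
                                   digits = 2) {
  ps <- filter_primary_suspect(store, drug)
  total <- nrow(ps)
  sex_n <- c(female = sum(ps$sex == "female", na.rm = TRUE),
             male = sum(ps$sex == "male", na.rm = TRUE),
             unknown = sum(is.na(ps$sex)))
  sex <- data.table::data.table(level = names(sex_n), n = as.integer(sex_n),
                                pct = pct_of(as.integer(sex_n), total, digits))
  age <- ps$age_years[!is.na(ps$age_years)]
  qs <- if (length(age)) {
    stats::quantile(age, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  } else rep(NA_real_, 3L)
  bin_n <- c(
    "<18" = sum(age < 18),
    "18-40" = sum(age >= 18 & age <= 40),
    "41-65" = sum(age > 40 & age <= 65),
    ">65" = sum(age > 65),
    unknown = sum(is.na(ps$age_years))
  )
  bins <- data.table::data.table(bin = names(bin_n), n = as.integer(bin_n),
                                 pct = pct_of(as.integer(bin_n), total, digits))
  ctry <- ps$country
  known <- table(ctry[!is.na(ctry)])
  known <- sort(known, decreasing = TRUE)
  top <- head(names(known), top_countries)
  ctry_n <- c(as.integer(known[top]),
              others = sum(known[setdiff(names(known), top)]),
              unknown = sum(is.na(ctry)))
  names(ctry_n)[seq_along(top)] <- top
  countries <- data.table::data.table(
    country = names(ctry_n), n = as.integer(ctry_n),
    pct = pct_of(as.integer(ctry_n), total, digits))
  structure(list(drug = normalize_term(drug), total = total, sex = sex,
                 age_median = qs[2L], age_q1 = qs[1L], age_q3 = qs[3L],
                 age_bins = bins, countries = countries),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat("<demographic_summary> ", x$drug, " (n = ", x$total, ")\n", sep = "")
  cat("age median (IQR): ", x$age_median, " (", x$age_q1, "-", x$age_q3,
      ")\n", sep = "")
  cat("sex:\n"); print(x$sex)
  cat("age bins:\n"); print(x$age_bins)
  cat("countries:\n"); print(x$countries)
  invisible(x)
}

#' Serious-outcome summary for one drug's reports
#'
#' A report contributes once to every serious-outcome category it carries
#' (death, life-threatening, hospitalization, disability, congenital
#' anomaly, required intervention, other); percentages are of the drug's
#' total deduplicated primary-suspect reports, so rows do not sum to 100%.
#'
#' @inheritParams summarize_demographics
#' @param digits percentage rounding (default 2).
#' @return `data.table` with columns `outcome`, `n`, `pct` covering every
#'   category (zeros included); attribute `total` is the denominator.
#' @export
summarize_outcomes <- function(store, drug, digits = 2) {
  ps <- filter_primary_suspect(store, drug)
  total <- nrow(ps)
  counts <- term_counts(ps$outcomes)
  n <- counts$n[match(OUTCOME_CATEGORIES, counts$term)]
  n[is.na(n)] <- 0L
  out <- data.table::data.table(outcome = OUTCOME_CATEGORIES,
                                n = as.integer(n),
                                pct = pct_of(as.integer(n), total, digits))
  data.table::setattr(out, "total", total)
  out[]
}

#' Yearly report counts for one drug
#'
#' Counts the drug's deduplicated primary-suspect reports per calendar year
#' of the retained report version, as a machine-readable series (one row per
#' year, zero-filled across the range).
#'
#' @inheritParams summarize_demographics
#' @param year_range optional integer vector `c(first, last)`; defaults to
#'   the observed span.
#' @return `data.table` with columns `year`, `n`; counts sum to the drug
#'   total (reports with unknown year are appended as `year = NA` when
#'   present).
#' @export
yearly_counts <- function(store, drug, year_range = NULL) {
  ps <- filter_primary_suspect(store, drug)
  yrs <- ps$year
  known <- yrs[!is.na(yrs)]
  if (is.null(year_range)) {
    year_range <- if (length(known)) range(known) else integer(0)
  }
  out <- if (length(year_range)) {
    span <- seq(year_range[1L], year_range[2L])
    tab <- table(factor(known, levels = span))
    data.table::data.table(year = as.integer(span), n = as.integer(tab))
  } else {
    data.table::data.table(year = integer(0), n = integer(0))
  }
  if (anyNA(yrs)) {
    out <- rbind(out, data.table::data.table(year = NA_integer_,
                                             n = sum(is.na(yrs))))
  }
  out[]
}
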