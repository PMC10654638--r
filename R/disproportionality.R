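#' Two-by-two contingency table for one drug-event pair
#'
#' Cells follow the standard disproportionality layout: `DE` reports with the
#' index drug (primary suspect) and the event, `De` index-drug reports
#' without the event, `dE` all other reports with the event, `de` the
#' remainder. Margins `D = DE + De`, `d = dE + de`, `E = DE + dE`,
#' `e = De + de`, `N = D + d`. Cells may be real-valued in oracle mode
#' (tables reconstructed from published statistics); such tables are flagged.
#'
#' @param DE,De,dE,de non-negative cell values.
#' @param real_valued logical; `TRUE` marks an oracle-mode table whose cells
#'   need not be integers.
#' @return an object of class `contingency_table`.
#' @examples
#' contingency_table(30, 70, 50, 950)
#' @export
contingency_table <- function(DE, De, dE, de, real_valued = FALSE) {
  cells <- c(DE = DE, De = De, dE = dE, de = de)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("contingency cells must be finite and non-negative", call. = FALSE)
  }
  if (!real_valued && any(abs(cells - round(cells)) > 1e-8)) {
    stop("non-integer cells require real_valued = TRUE", call. = FALSE)
  }
  structure(list(DE = DE, De = De, dE = dE, de = de,
                 real_valued = isTRUE(real_valued)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$DE, x$De, x$dE, x$de), 2, 2,
              dimnames = list(c("event", "no event"), c("drug", "no drug")))
  cat("<contingency_table>", if (x$real_valued) " (real-valued)", "\n",
      sep = "")
  print(m)
  invisible(x)
}

#' Margins of a contingency table
#' @param table a [contingency_table()].
#' @return named numeric vector with `D`, `d`, `E`, `e`, `N`.
#' @export
table_margins <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  c(D = table$DE + table$De, d = table$dE + table$de,
    E = table$DE + table$dE, e = table$De + table$de,
    N = table$DE + table$De + table$dE + table$de)
}

#' Build the 2x2 table for a drug-event pair from a report store
#'
#' The exposed margin is the set of deduplicated reports naming `drug` as
#' primary suspect; the background is every other report in the store
#' (including any comparator drug's reports — the whole-collection
#' comparator used in spontaneous-report disproportionality).
#'
#' @param store a deduplicated [report_store()].
#' @param drug canonical drug name.
#' @param event adverse-event term (normalized internally).
#' @param lexicon optional [drug_lexicon()] for canonical-name validation.
#' @return a [contingency_table()] whose cells sum to `nrow(store)`.
#' @export
build_table <- function(store, drug, event, lexicon = NULL) {
  stopifnot(inherits(store, "report_store"))
  if (!is_deduplicated(store)) {
    stop("build_table() requires a deduplicated store", call. = FALSE)
  }
  drug <- normalize_term(drug)
  if (!is.null(lexicon) && !drug %in% lexicon_drugs(lexicon)) {
    stop("unknown canonical drug name: '", drug, "'", call. = FALSE)
  }
  event <- normalize_term(event)
  d_mask <- ps_mask(store, drug)
  e_mask <- term_mask(store$events, event)
  contingency_table(sum(d_mask & e_mask), sum(d_mask & !e_mask),
                    sum(!d_mask & e_mask), sum(!d_mask & !e_mask))
}

## ---- vectorized statistic kernels (shared by scalar API and detect_signals)

ror_kernel <- function(DE, De, dE, de, z = 1.96) {
  DE <- as.numeric(DE); De <- as.numeric(De)
  dE <- as.numeric(dE); de <- as.numeric(de)
  evaluable <- De > 0 & dE > 0 & de > 0 & DE > 0
  ror <- ci_low <- ci_high <- rep(NA_real_, length(DE))
  i <- which(evaluable)
  if (length(i)) {
    r <- (DE[i] * de[i]) / (De[i] * dE[i])
    se <- sqrt(1 / DE[i] + 1 / De[i] + 1 / dE[i] + 1 / de[i])
    ror[i] <- r
    ci_low[i] <- exp(log(r) - z * se)
    ci_high[i] <- exp(log(r) + z * se)
  }
  list(ror = ror, ci_low = ci_low, ci_high = ci_high, evaluable = evaluable)
}

prr_kernel <- function(DE, De, dE, de) {
  DE <- as.numeric(DE); De <- as.numeric(De)
  dE <- as.numeric(dE); de <- as.numeric(de)
  D <- DE + De
  d <- dE + de
  evaluable <- D > 0 & dE > 0 & d > 0
  prr <- rep(NA_real_, length(DE))
  i <- which(evaluable)
  prr[i] <- (DE[i] / D[i]) / (dE[i] / d[i])
  list(prr = prr, evaluable = evaluable)
}

chi2_kernel <- function(DE, De, dE, de) {
  DE <- as.numeric(DE); De <- as.numeric(De)
  dE <- as.numeric(dE); de <- as.numeric(de)
  D <- DE + De; d <- dE + de; E <- DE + dE; e <- De + de
  N <- D + d
  evaluable <- D > 0 & d > 0 & E > 0 & e > 0
  chi2 <- rep(NA_real_, length(DE))
  i <- which(evaluable)
  if (length(i)) {
    dev <- abs(DE[i] * de[i] - dE[i] * De[i]) - N[i] / 2
    dev[dev < 0] <- 0  # continuity term clamped at exact independence
    chi2[i] <- N[i] * dev^2 / (D[i] * d[i] * E[i] * e[i])
  }
  list(chi2 = chi2, evaluable = evaluable)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (DE/De)/(dE/de)`; the two-sided `100(1 - alpha)%` interval is
#' `exp(log ROR -/+ z * sqrt(1/DE + 1/De + 1/dE + 1/de))`. A zero in any
#' cell entering a denominator (or an empty index cell) makes the statistic
#' non-evaluable: the result carries `NA` values and a reason code, never an
#' error.
#'
#' @param table a [contingency_table()].
#' @param z normal quantile for the interval (default 1.96, the 95% level).
#' @return list with `ror`, `ci_low`, `ci_high`, `evaluable`, `reason`.
#' @examples
#' compute_ror(contingency_table(30, 70, 50, 950))
#' @export
compute_ror <- function(table, z = 1.96) {
  stopifnot(inherits(table, "contingency_table"))
  k <- ror_kernel(table$DE, table$De, table$dE, table$de, z)
  list(ror = k$ror, ci_low = k$ci_low, ci_high = k$ci_high,
       evaluable = k$evaluable,
       reason = if (k$evaluable) NA_character_ else "zero cell")
}

#' Proportional reporting ratio
#'
#' `PRR = (DE/D)/(dE/d)`: the event's share of the drug's reports over its
#' share of all other reports. Non-evaluable (with reason) when `dE = 0` or
#' a margin is empty.
#'
#' @param table a [contingency_table()].
#' @return list with `prr`, `evaluable`, `reason`.
#' @export
compute_prr <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  k <- prr_kernel(table$DE, table$De, table$dE, table$de)
  list(prr = k$prr, evaluable = k$evaluable,
       reason = if (k$evaluable) NA_character_ else "zero margin or dE")
}

#' Yates-corrected chi-squared statistic
#'
#' `chi2 = N * (|DE*de - dE*De| - N/2)^2 / (D * d * E * e)`, with the
#' continuity term clamped: when `|DE*de - dE*De| < N/2` the statistic is 0
#' (the literal formula would be positive at exact independence).
#' Non-evaluable when any margin is zero.
#'
#' @param table a [contingency_table()].
#' @return list with `chi2`, `evaluable`, `reason`.
#' @export
compute_chi2_yates <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  k <- chi2_kernel(table$DE, table$De, table$dE, table$de)
  list(chi2 = k$chi2, evaluable = k$evaluable,
       reason = if (k$evaluable) NA_character_ else "zero margin")
}

#' Signal significance criteria
#'
#' The standard criteria for a significant disproportionality signal:
#' at least `min_de` co-occurrence reports, `ROR >= min_ror`, lower 95% CI
#' bound strictly above `min_ci_low`, `PRR >= min_prr` and
#' `chi-squared >= min_chi2`. `strict = TRUE` switches the DE, ROR, PRR and
#' chi-squared comparisons from `>=` to `>` (the CI bound is strict either
#' way); the inclusive form is the default.
#'
#' @param min_de minimum co-occurrence count (default 3).
#' @param min_ror minimum reporting odds ratio (default 2).
#' @param min_ci_low strict lower bound for the CI low limit (default 1).
#' @param min_prr minimum proportional reporting ratio (default 2).
#' @param min_chi2 minimum Yates chi-squared (default 4).
#' @param z normal quantile for the ROR interval (default 1.96).
#' @param strict logical; use strict inequalities (default `FALSE`).
#' @return an object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_de = 3, min_ror = 2, min_ci_low = 1,
                            min_prr = 2, min_chi2 = 4, z = 1.96,
                            strict = FALSE) {
  vals <- c(min_de = min_de, min_ror = min_ror, min_ci_low = min_ci_low,
            min_prr = min_prr, min_chi2 = min_chi2, z = z)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all criteria thresholds must be positive", call. = FALSE)
  }
  structure(list(min_de = min_de, min_ror = min_ror, min_ci_low = min_ci_low,
                 min_prr = min_prr, min_chi2 = min_chi2, z = z,
                 strict = isTRUE(strict)),
            class = "signal_criteria")
}

#' @export
print.signal_criteria <- function(x, ...) {
  op <- if (x$strict) ">" else ">="
  cat("<signal_criteria> DE ", op, " ", x$min_de, ", ROR ", op, " ",
      x$min_ror, ", CI_low > ", x$min_ci_low, ", PRR ", op, " ", x$min_prr,
      ", chi2 ", op, " ", x$min_chi2, " (z = ", x$z, ")\n", sep = "")
  invisible(x)
}

## vectorized criteria check; non-evaluable statistics fail their criterion
criteria_mask <- function(DE, ror, ci_low, prr, chi2, criteria) {
  ge <- if (criteria$strict) `>` else `>=`
  ok <- function(x, thr, cmp) !is.na(x) & cmp(x, thr)
  ok(DE, criteria$min_de, ge) &
    ok(ror, criteria$min_ror, ge) &
    ok(ci_low, criteria$min_ci_low, `>`) &
    ok(prr, criteria$min_prr, ge) &
    ok(chi2, criteria$min_chi2, ge)
}

#' Evaluate one drug-event table against the signal criteria
#'
#' @param table a [contingency_table()].
#' @param criteria a [signal_criteria()].
#' @param drug,event optional labels carried through to the result.
#' @return one-row `data.table` with columns `drug`, `event`, `DE`, `ror`,
#'   `ci_low`, `ci_high`, `prr`, `chi2`, `significant`.
#' @examples
#' evaluate_signal(contingency_table(30, 70, 50, 950))
#' @export
evaluate_signal <- function(table, criteria = signal_criteria(),
                            drug = NA_character_, event = NA_character_) {
  stopifnot(inherits(table, "contingency_table"),
            inherits(criteria, "signal_criteria"))
  r <- ror_kernel(table$DE, table$De, table$dE, table$de, criteria$z)
  p <- prr_kernel(table$DE, table$De, table$dE, table$de)
  x <- chi2_kernel(table$DE, table$De, table$dE, table$de)
  data.table::data.table(
    drug = drug, event = event, DE = table$DE,
    ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
    prr = p$prr, chi2 = x$chi2,
    significant = criteria_mask(table$DE, r$ror, r$ci_low, p$prr, x$chi2,
                                criteria)
  )
}

#' Detect adverse-event signals for one drug
#'
#' Builds the 2x2 table for every event term observed at least once among
#' the drug's primary-suspect reports and evaluates the signal criteria.
#' Significant rows come first, sorted by co-occurrence count `DE`
#' descending with lexicographic tie-break on the event term.
#'
#' @param store a deduplicated [report_store()].
#' @param drug canonical drug name.
#' @param criteria a [signal_criteria()].
#' @param lexicon optional [drug_lexicon()] for name validation.
#' @return a `data.table` of class `signal_table` with one row per event
#'   (`DE >= 1`) and columns as in [evaluate_signal()]; attribute
#'   `n_significant` carries the significant-signal count.
#' @export
detect_signals <- function(store, drug, criteria = signal_criteria(),
                           lexicon = NULL) {
  stopifnot(inherits(store, "report_store"),
            inherits(criteria, "signal_criteria"))
  if (!is_deduplicated(store)) {
    stop("detect_signals() requires a deduplicated store", call. = FALSE)
  }
  drug <- normalize_term(drug)
  if (!is.null(lexicon) && !drug %in% lexicon_drugs(lexicon)) {
    stop("unknown canonical drug name: '", drug, "'", call. = FALSE)
  }
  d_mask <- ps_mask(store, drug)
  N <- nrow(store)
  D <- sum(d_mask)
  de_counts <- sorted_term_counts(store$events[d_mask])
  if (nrow(de_counts) == 0L) {
    out <- data.table::data.table(
      drug = character(0), event = character(0), DE = integer(0),
      ror = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
      prr = numeric(0), chi2 = numeric(0), significant = logical(0))
    data.table::setattr(out, "n_significant", 0L)
    data.table::setattr(out, "class",
                        c("signal_table", "data.table", "data.frame"))
    return(out)
  }
  e_tot <- term_counts(store$events)
  E <- e_tot$n[match(de_counts$term, e_tot$term)]
  DE <- de_counts$n
  De <- D - DE
  dE <- E - DE
  de <- N - D - dE
  r <- ror_kernel(DE, De, dE, de, criteria$z)
  p <- prr_kernel(DE, De, dE, de)
  x <- chi2_kernel(DE, De, dE, de)
  out <- data.table::data.table(
    drug = drug, event = de_counts$term, DE = DE,
    ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
    prr = p$prr, chi2 = x$chi2,
    significant = criteria_mask(DE, r$ror, r$ci_low, p$prr, x$chi2, criteria)
  )
  data.table::setorder(out, -significant, -DE, event)
  data.table::setattr(out, "n_significant", sum(out$significant))
  data.table::setattr(out, "class",
                      c("signal_table", "data.table", "data.frame"))
  out
}

#' @export
print.signal_table <- function(x, ...) {
  cat("<signal_table> ", nrow(x), " events, ",
      attr(x, "n_significant"), " significant\n", sep = "")
  NextMethod()
}

## count occurrences of each term across a list column (a report counts a
## term once, sets are deduplicated at ingest)
term_counts <- function(col) {
  terms <- unlist(col, use.names = FALSE)
  if (is.null(terms) || length(terms) == 0L) {
    return(data.table::data.table(term = character(0), n = integer(0)))
  }
  dt <- data.table::data.table(term = terms)
  dt[, .(n = .N), by = term]
}

sorted_term_counts <- function(col) {
  dt <- term_counts(col)
  data.table::setorder(dt, -n, term)
  dt
}
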