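#' Compare the significant signals of two drugs
#'
#' Intersects the significant-signal sets of two drugs (exact match on
#' normalized event terms) and classifies each shared event by the
#' difference of point RORs: `ror_diff = ror_a - ror_b`, direction
#' `a_stronger` / `b_stronger` / `tie`, and a tier label when the difference
#' exceeds the direction's threshold (`d > threshold_a` for a-stronger rows,
#' `d > threshold_b` for b-stronger rows). The thresholds are independent
#' because published comparisons use asymmetric cutoffs. The comparison uses
#' point estimates only — no interval-overlap test — so a tier records a
#' difference in reported association strength, not a formal inference.
#'
#' @param signals_a,signals_b signal tables from [detect_signals()] (run on
#'   the same store with the same criteria); only rows with
#'   `significant == TRUE` enter the overlap.
#' @param threshold_a ROR-difference cutoff for tiering a-stronger rows
#'   (default 20).
#' @param threshold_b cutoff for b-stronger rows (default 50).
#' @return an object of class `comparison_summary`: list with `n_overlap`,
#'   `n_a_stronger`, `n_b_stronger`, `n_tie`, and `records`, a `data.table`
#'   (`event`, `ror_a`, `ci_low_a`, `ror_b`, `ci_low_b`, `ror_diff`,
#'   `direction`, `tier`) sorted by `|ror_diff|` descending.
#' @export
compare_signals <- function(signals_a, signals_b, threshold_a = 20,
                            threshold_b = 50) {
  stopifnot(is.data.frame(signals_a), is.data.frame(signals_b),
            threshold_a > 0, threshold_b > 0)
  a <- data.table::as.data.table(signals_a)[significant == TRUE]
  b <- data.table::as.data.table(signals_b)[significant == TRUE]
  drug_a <- if (nrow(a)) a$drug[1L] else "a"
  drug_b <- if (nrow(b)) b$drug[1L] else "b"
  shared <- intersect(a$event, b$event)
  rec <- data.table::data.table(
    event = shared,
    ror_a = a$ror[match(shared, a$event)],
    ci_low_a = a$ci_low[match(shared, a$event)],
    ror_b = b$ror[match(shared, b$event)],
    ci_low_b = b$ci_low[match(shared, b$event)]
  )
  rec[, ror_diff := ror_a - ror_b]
  rec[, direction := data.table::fifelse(
    ror_diff > 0, "a_stronger",
    data.table::fifelse(ror_diff < 0, "b_stronger", "tie"))]
  rec[, tier := data.table::fifelse(
    direction == "a_stronger" & ror_diff > threshold_a,
    sprintf("d>%g", threshold_a),
    data.table::fifelse(
      direction == "b_stronger" & -ror_diff > threshold_b,
      sprintf("d>%g", threshold_b), NA_character_))]
  rec[, abs_diff := abs(ror_diff)]
  data.table::setorder(rec, -abs_diff, event)
  rec[, abs_diff := NULL]
  structure(list(
    drug_a = drug_a, drug_b = drug_b,
    n_overlap = nrow(rec),
    n_a_stronger = sum(rec$direction == "a_stronger"),
    n_b_stronger = sum(rec$direction == "b_stronger"),
    n_tie = sum(rec$direction == "tie"),
    threshold_a = threshold_a, threshold_b = threshold_b,
    records = rec[]
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("<comparison_summary> ", x$n_overlap, " shared significant signals (",
      x$drug_a, " vs ", x$drug_b, "): ",
      x$n_a_stronger, " a-stronger, ", x$n_b_stronger, " b-stronger, ",
      x$n_tie, " ties\n", sep = "")
  tiers <- x$records[!is.na(tier)]
  if (nrow(tiers)) {
    cat("tiered records:\n")
    print(tiers)
  }
  invisible(x)
}

#' @export
#' @rdname compare_signals
#' @param x a `comparison_summary`.
#' @param ... unused.
as.data.frame.comparison_summary <- function(x, ...) {
  as.data.frame(x$records)
}
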