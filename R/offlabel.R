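#' Find off-label indications for a drug
#'
#' An off-label indication is any normalized indication term recorded in the
#' drug's primary-suspect reports that is absent from the merged approved
#' indication set of the drug's label (all marketed specifications combined).
#' A report contributes once per distinct indication it carries; the
#' percentage denominator is the drug's total deduplicated primary-suspect
#' report count (reports with no recorded indication stay in the
#' denominator).
#'
#' @param store a deduplicated [report_store()].
#' @param drug canonical drug name.
#' @param label the drug's [drug_label()].
#' @param digits rounding for the percentage column (default 2,
#'   half-away-from-zero).
#' @return `data.table` with columns `indication`, `n`, `pct`, sorted by `n`
#'   descending (ties lexicographic); attribute `drug_total` carries the
#'   denominator.
#' @export
find_offlabel <- function(store, drug, label, digits = 2) {
  stopifnot(inherits(store, "report_store"), inherits(label, "drug_label"))
  ps <- filter_primary_suspect(store, drug)
  total <- nrow(ps)
  counts <- sorted_term_counts(ps$indications)
  out <- counts[!term %in% label$approved_indications]
  data.table::setnames(out, "term", "indication")
  out[, pct := pct_of(n, total, digits)]
  data.table::setattr(out, "drug_total", total)
  out[]
}

#' Profile unlabeled adverse events within an indication subgroup
#'
#' Restricts to the drug's primary-suspect reports that carry the given
#' indication and tabulates the adverse events absent from the drug's
#' labeled-AE set, optionally aggregated under umbrella terms via a grouping
#' map (see [load_grouping()]). A report counts once per group even when it
#' carries several constituent terms. Percentages use the subgroup size
#' (number of reports with the indication) as denominator.
#'
#' @param store a deduplicated [report_store()].
#' @param drug canonical drug name.
#' @param indication indication term defining the subgroup.
#' @param label the drug's [drug_label()].
#' @param grouping optional grouping map from [load_grouping()] (umbrella
#'   term -> constituent terms).
#' @param digits rounding for the percentage column (default 1).
#' @return `data.table` with columns `term`, `n`, `pct`, `members` (list
#'   column of constituent terms for grouped rows), sorted by `n` descending;
#'   attribute `denominator` carries the subgroup size. A zero-size subgroup
#'   yields an empty profile with a warning.
#' @export
profile_indication_aes <- function(store, drug, indication, label,
                                   grouping = NULL, digits = 1) {
  stopifnot(inherits(store, "report_store"), inherits(label, "drug_label"))
  indication <- normalize_term(indication)
  ps <- filter_primary_suspect(store, drug)
  sub <- ps[term_mask(ps$indications, indication)]
  denom <- nrow(sub)
  empty <- data.table::data.table(term = character(0), n = integer(0),
                                  pct = numeric(0), members = list())
  if (denom == 0L) {
    warning("no primary-suspect reports of '", drug, "' carry indication '",
            indication, "'", call. = FALSE)
    data.table::setattr(empty, "denominator", 0L)
    return(empty[])
  }
  ## unlabeled events, then umbrella aggregation (a report counts once per
  ## group, so grouping happens per report before counting)
  events <- lapply(sub$events, function(ev) ev[!ev %in% label$labeled_aes])
  if (!is.null(grouping)) {
    stopifnot(inherits(grouping, "ae_grouping"))
    events <- lapply(events, function(ev) {
      g <- grouping$member_to_group[ev]
      unique(ifelse(is.na(g), ev, g))
    })
  }
  counts <- sorted_term_counts(events)
  if (nrow(counts) == 0L) {
    data.table::setattr(empty, "denominator", denom)
    return(empty[])
  }
  counts[, pct := pct_of(n, denom, digits)]
  members <- if (is.null(grouping)) {
    rep(list(character(0)), nrow(counts))
  } else {
    lapply(counts$term, function(t) {
      if (t %in% names(grouping$groups)) grouping$groups[[t]]
      else character(0)
    })
  }
  counts[, members := members]
  data.table::setattr(counts, "denominator", denom)
  counts[]
}

#' Load an adverse-event grouping map
#'
#' Umbrella groupings collapse clinically related preferred terms (for
#' example an "emotional disorder" umbrella over confusional state, anxiety,
#' depressed mood, ...) into a single profile row. The file is JSON:
#' `{"group name": ["member term", ...], ...}`. Terms are normalized; a
#' member may not appear twice within a group nor in two groups. An empty
#' file yields the identity grouping (no aggregation).
#'
#' @param path path to the JSON grouping file.
#' @return an object of class `ae_grouping` with components `groups` (named
#'   list of member vectors) and `member_to_group` (named lookup vector).
#' @export
load_grouping <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw) %||% character(0), "_")]
  if (length(raw) == 0L) {
    return(structure(list(groups = list(),
                          member_to_group = character(0)),
                     class = "ae_grouping"))
  }
  groups <- lapply(raw, function(m) normalize_term(as.character(m)))
  names(groups) <- normalize_term(names(raw))
  for (g in names(groups)) {
    if (anyDuplicated(groups[[g]])) {
      stop("grouping '", g, "' lists a member term twice: ",
           paste(unique(groups[[g]][duplicated(groups[[g]])]), collapse = ", "),
           call. = FALSE)
    }
  }
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("term(s) assigned to two groups: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  lookup <- rep(names(groups), lengths(groups))
  names(lookup) <- members
  structure(list(groups = groups, member_to_group = lookup),
            class = "ae_grouping")
}

#' @export
print.ae_grouping <- function(x, ...) {
  cat("<ae_grouping> ", length(x$groups), " groups, ",
      length(x$member_to_group), " member terms\n", sep = "")
  invisible(x)
}
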