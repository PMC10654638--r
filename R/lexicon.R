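#' Drug synonym lexicon
#'
#' A lexicon maps each canonical drug name to the set of synonyms under which
#' it appears verbatim in reports (generic name plus trade names). All names
#' are normalized with [normalize_term()]; the canonical name itself is always
#' a synonym of itself. No synonym may map to two canonical names.
#'
#' @param entries named list: canonical drug name -> character vector of
#'   synonyms (trade and generic name variants).
#' @return an object of class `drug_lexicon`.
#' @examples
#' lex <- drug_lexicon(list(
#'   denosumab = c("Prolia", "Xgeva", "Ranmark"),
#'   "zoledronic acid" = c("Zometa", "Reclast", "Aclasta", "zoledronate")
#' ))
#' resolve_drug("ZOMETA", lex)
#' @export
drug_lexicon <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == "")) {
    stop("lexicon entries must be a named list (canonical name -> synonyms)",
         call. = FALSE)
  }
  canon <- normalize_term(names(entries))
  if (anyDuplicated(canon)) {
    stop("duplicate canonical names in lexicon", call. = FALSE)
  }
  syns <- lapply(seq_along(entries), function(i) {
    unique(c(canon[i], normalize_term(as.character(entries[[i]]))))
  })
  names(syns) <- canon
  all_syn <- unlist(syns, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    dup <- unique(all_syn[duplicated(all_syn)])
    stop("synonym(s) mapped to more than one canonical name: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  map <- rep(canon, lengths(syns))
  names(map) <- all_syn
  structure(list(entries = syns, map = map), class = "drug_lexicon")
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon> ", length(x$entries), " drugs, ",
      length(x$map), " synonyms\n", sep = "")
  invisible(x)
}

#' Resolve a verbatim drug name to its canonical name
#'
#' Looks up the normalized verbatim name in the lexicon. Unknown names return
#' `NA_character_` (unresolved) — never an error, since spontaneous reports
#' routinely carry drugs outside the study scope.
#'
#' @param verbatim character vector of verbatim drug names as reported.
#' @param lexicon a [drug_lexicon()].
#' @return character vector of canonical names; `NA` where unresolved.
#' @export
resolve_drug <- function(verbatim, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  key <- tolower(gsub("\\s+", " ", trimws(as.character(verbatim))))
  out <- unname(lexicon$map[key])
  out[key == "" | is.na(key)] <- NA_character_
  out
}

#' Canonical drug names in a lexicon
#' @param lexicon a [drug_lexicon()].
#' @return character vector of canonical names.
#' @export
lexicon_drugs <- function(lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  names(lexicon$entries)
}

#' Drug label: approved indications and labeled adverse events
#'
#' Represents the merged product label for one drug: the union of approved
#' indications and of labeled adverse events across all marketed
#' specifications (dosage forms). Terms are normalized.
#'
#' @param drug canonical drug name.
#' @param approved_indications character vector of approved indication terms.
#' @param labeled_aes character vector of adverse-event terms on the label.
#' @return an object of class `drug_label`.
#' @export
drug_label <- function(drug, approved_indications, labeled_aes) {
  structure(list(
    drug = normalize_term(drug),
    approved_indications = unique(normalize_term(as.character(approved_indications))),
    labeled_aes = unique(normalize_term(as.character(labeled_aes)))
  ), class = "drug_label")
}

#' @export
print.drug_label <- function(x, ...) {
  cat("<drug_label> ", x$drug, ": ", length(x$approved_indications),
      " approved indications, ", length(x$labeled_aes), " labeled AEs\n",
      sep = "")
  invisible(x)
}

#' Read a drug configuration file (lexicon + labels)
#'
#' The configuration is a JSON object keyed by canonical drug name; each
#' entry may carry `synonyms`, `approved_indications` and `labeled_aes`
#' arrays. Keys starting with `"_"` (comments) are ignored.
#'
#' @param path path to the JSON file.
#' @return list with components `lexicon` (a [drug_lexicon()]) and `labels`
#'   (named list of [drug_label()] objects).
#' @examples
#' cfg <- read_drug_config(system.file("extdata", "drug_config.json",
#'                                     package = "pvsignal"))
#' lexicon_drugs(cfg$lexicon)
#' @export
read_drug_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  syn <- lapply(raw, function(e) as.character(e$synonyms %||% character(0)))
  lex <- drug_lexicon(syn)
  labels <- lapply(names(raw), function(nm) {
    drug_label(nm,
               raw[[nm]]$approved_indications %||% character(0),
               raw[[nm]]$labeled_aes %||% character(0))
  })
  names(labels) <- normalize_term(names(raw))
  list(lexicon = lex, labels = labels)
}
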