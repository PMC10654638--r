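#' Event probability implied by a planted reporting odds ratio
#'
#' Inverts the odds construction of the reporting odds ratio to set a
#' generative probability: given the background event probability `p0` and a
#' target ROR, returns `p1` with `odds(p1) = ror * odds(p0)`, i.e.
#' `p1 = ror * p0 / (1 - p0 + ror * p0)`. Events drawn with probability `p1`
#' in the index-drug arm and `p0` elsewhere have population ROR exactly
#' `ror`.
#'
#' @param target_ror positive target reporting odds ratio.
#' @param p0 background event probability in (0, 1).
#' @return the index-arm probability `p1` (vectorized).
#' @examples
#' planted_event_prob(4, 0.05)   # 0.2/1.15
#' @export
planted_event_prob <- function(target_ror, p0) {
  stopifnot(all(target_ror > 0), all(p0 > 0), all(p0 < 1))
  target_ror * p0 / (1 - p0 + target_ror * p0)
}

#' Planted drug-event association
#'
#' Ground-truth association for the simulator: the named drug's reports
#' carry `event` with the probability implied by `target_ror` over the
#' background probability `background_event_prob`.
#'
#' @param drug canonical drug name (must hold a share in the simulation).
#' @param event adverse-event term.
#' @param target_ror positive target reporting odds ratio.
#' @param background_event_prob background per-report event probability.
#' @return an object of class `planted_association`.
#' @export
planted_association <- function(drug, event, target_ror,
                                background_event_prob) {
  stopifnot(target_ror > 0,
            background_event_prob > 0, background_event_prob < 1)
  p1 <- planted_event_prob(target_ror, background_event_prob)
  if (p1 <= 0 || p1 >= 1) {
    stop("infeasible planted association: implied index-arm probability ",
         signif(p1, 4), call. = FALSE)
  }
  structure(list(drug = normalize_term(drug), event = normalize_term(event),
                 target_ror = target_ror,
                 background_event_prob = background_event_prob, p1 = p1),
            class = "planted_association")
}

#' Simulation configuration for FAERS-like report stores
#'
#' Describes a synthetic spontaneous-reporting world: a handful of study
#' drugs plus a catch-all `"background"` pseudo-drug absorbing the remaining
#' exposure share (so the non-exposed margin of every 2x2 table is well
#' populated, as when a whole database serves as comparator); a vocabulary
#' of adverse-event terms drawn independently per report; planted drug-event
#' associations with known target RORs; per-drug indication probabilities;
#' duplicate case versions; and demographic, country, year and
#' serious-outcome distributions.
#'
#' Defaults state a scaled-down two-drug world patterned on antiresorptive
#' pharmacovigilance data: ~76% female reports, median age near 68,
#' mostly-US reporting, years 2004-2022 with an increasing trend, death and
#' hospitalization as dominant serious outcomes, and a 0.6 duplicate rate
#' (spontaneous databases shrink by roughly that factor at case-level
#' deduplication).
#'
#' @param n_reports total pre-deduplication reports to emit.
#' @param drug_shares named probabilities per canonical drug; any deficit to
#'   1 is assigned to `"background"`.
#' @param event_vocab named background probabilities per event term.
#' @param indication_vocab named list: drug -> named per-term probabilities.
#' @param planted list of [planted_association()] objects (or lists with the
#'   same fields).
#' @param duplicate_rate fraction of emitted reports that are re-submissions
#'   of an earlier case (`[0, 1)`).
#' @param sex_probs named probabilities for `female`, `male`, `unknown`.
#' @param age_mean,age_sd,age_unknown_rate age model: known ages are
#'   truncated-normal (rounded to years, clamped to `[0, 110]`).
#' @param country_probs named country probabilities; `"unknown"` is the
#'   missing category.
#' @param year_probs named probabilities per report year.
#' @param outcome_probs named per-category probabilities of serious-outcome
#'   flags (independent per category).
#' @param concomitant_rate probability a report lists one extra
#'   non-suspect drug (secondary suspect / concomitant / interacting).
#' @param other_drug_pool verbatim names for the extra non-study drugs.
#' @param lexicon optional [drug_lexicon()]; when given, verbatim drug names
#'   are sampled uniformly from each drug's synonyms (trade-name variants).
#' @param seed integer seed; every draw derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reports,
                       drug_shares = c(denosumab = 0.35,
                                       "zoledronic acid" = 0.15),
                       event_vocab = default_event_vocab(),
                       indication_vocab = default_indication_vocab(),
                       planted = default_planted(),
                       duplicate_rate = 0.6,
                       sex_probs = c(female = 0.76, male = 0.12,
                                     unknown = 0.12),
                       age_mean = 68, age_sd = 13, age_unknown_rate = 0.44,
                       country_probs = c("united states" = 0.70,
                                         canada = 0.07, japan = 0.06,
                                         germany = 0.06, france = 0.05,
                                         britain = 0.03, unknown = 0.03),
                       year_probs = default_year_probs(),
                       outcome_probs = c(death = 0.18,
                                         hospitalization = 0.13,
                                         life_threatening = 0.012,
                                         disability = 0.025,
                                         congenital_anomaly = 0.001,
                                         required_intervention = 0.01,
                                         other = 0.30),
                       concomitant_rate = 0.25,
                       other_drug_pool = c("aspirin", "metformin",
                                           "omeprazole", "atorvastatin"),
                       lexicon = NULL,
                       seed = 1L) {
  stopifnot(length(n_reports) == 1L, n_reports >= 1)
  names(drug_shares) <- normalize_term(names(drug_shares))
  share_sum <- sum(drug_shares)
  if (share_sum > 1 + 1e-9) {
    stop("drug_shares sum to ", signif(share_sum, 6), " > 1", call. = FALSE)
  }
  if (!"background" %in% names(drug_shares)) {
    drug_shares <- c(drug_shares, background = 1 - share_sum)
  } else if (abs(share_sum - 1) > 1e-9) {
    stop("drug_shares including 'background' must sum to 1", call. = FALSE)
  }
  check_probs <- function(p, what, allow_zero = TRUE) {
    lo_ok <- if (allow_zero) p >= 0 else p > 0
    if (any(!is.finite(p)) || any(!lo_ok) || any(p > 1)) {
      stop(what, " must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  check_probs(drug_shares, "drug_shares")
  names(event_vocab) <- normalize_term(names(event_vocab))
  check_probs(event_vocab, "event_vocab")
  names(indication_vocab) <- normalize_term(names(indication_vocab))
  indication_vocab <- lapply(indication_vocab, function(v) {
    names(v) <- normalize_term(names(v)); check_probs(v, "indication_vocab"); v
  })
  if (!(duplicate_rate >= 0 && duplicate_rate < 1)) {
    stop("duplicate_rate must be in [0, 1)", call. = FALSE)
  }
  planted <- lapply(planted, function(p) {
    if (inherits(p, "planted_association")) p
    else planted_association(p$drug, p$event, p$target_ror,
                             p$background_event_prob)
  })
  for (p in planted) {
    if (!p$drug %in% setdiff(names(drug_shares), "background")) {
      stop("planted association names unknown drug '", p$drug, "'",
           call. = FALSE)
    }
    if (p$event %in% names(event_vocab)) {
      if (abs(event_vocab[[p$event]] - p$background_event_prob) > 1e-12) {
        stop("planted background probability for '", p$event,
             "' conflicts with event_vocab", call. = FALSE)
      }
    } else {
      event_vocab[p$event] <- p$background_event_prob
    }
  }
  key <- vapply(planted, function(p) paste(p$drug, p$event, sep = "\r"), "")
  if (anyDuplicated(key)) {
    stop("duplicate planted association for the same drug-event pair",
         call. = FALSE)
  }
  check_probs(sex_probs[c("female", "male", "unknown")], "sex_probs",
              allow_zero = TRUE)
  check_probs(country_probs, "country_probs")
  check_probs(year_probs, "year_probs")
  check_probs(outcome_probs[OUTCOME_CATEGORIES], "outcome_probs")
  stopifnot(concomitant_rate >= 0, concomitant_rate <= 1)
  structure(list(
    n_reports = as.integer(n_reports), drug_shares = drug_shares,
    event_vocab = event_vocab, indication_vocab = indication_vocab,
    planted = planted, duplicate_rate = duplicate_rate,
    sex_probs = sex_probs, age_mean = age_mean, age_sd = age_sd,
    age_unknown_rate = age_unknown_rate, country_probs = country_probs,
    year_probs = year_probs, outcome_probs = outcome_probs,
    concomitant_rate = concomitant_rate, other_drug_pool = other_drug_pool,
    lexicon = lexicon, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_reports, " reports, drugs: ",
      paste(sprintf("%s (%.2f)", names(x$drug_shares), x$drug_shares),
            collapse = ", "),
      "; ", length(x$event_vocab), " event terms, ", length(x$planted),
      " planted associations, duplicate rate ", x$duplicate_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

default_event_vocab <- function() {
  c("death" = 0.10, "pain" = 0.08, "back pain" = 0.05, "arthralgia" = 0.05,
    "nausea" = 0.04, "pyrexia" = 0.03, "headache" = 0.03, "fall" = 0.03,
    "bone pain" = 0.02, "osteonecrosis of jaw" = 0.02,
    "tooth extraction" = 0.015, "hypocalcaemia" = 0.01)
}

default_indication_vocab <- function() {
  list(
    denosumab = c("osteoporosis" = 0.45,
                  "osteoporosis postmenopausal" = 0.20,
                  "bone metastasis" = 0.10, "breast cancer" = 0.02,
                  "prostate cancer" = 0.02),
    "zoledronic acid" = c("osteoporosis" = 0.30, "bone metastasis" = 0.20,
                          "hypercalcaemia of malignancy" = 0.05,
                          "breast cancer" = 0.04, "prostate cancer" = 0.03),
    background = c("hypertension" = 0.20, "diabetes mellitus" = 0.15,
                   "depression" = 0.10)
  )
}

default_year_probs <- function() {
  yrs <- 2004:2022
  w <- seq_along(yrs)  # roughly linear growth in reporting volume
  p <- w / sum(w)
  names(p) <- yrs
  p
}

default_planted <- function() {
  list(
    planted_association("denosumab", "osteonecrosis of jaw", 8, 0.02),
    planted_association("zoledronic acid", "osteonecrosis of jaw", 4, 0.02),
    planted_association("zoledronic acid", "tooth extraction", 12, 0.015)
  )
}

## per-component RNG streams: deterministic stage seeds derived from the
## config seed so adding vocabulary does not shift unrelated draws
stage_seed <- function(seed, stage) {
  stages <- c(drugs = 1L, events = 2L, indications = 3L, demographics = 4L,
              outcomes = 5L, years = 6L, duplicates = 7L, concomitants = 8L)
  (as.integer(seed) + 7919L * stages[[stage]]) %% 2147483345L + 1L
}

#' Generate a synthetic report store with known ground truth
#'
#' Emits exactly `n_reports` pre-deduplication reports: one primary-suspect
#' drug per case drawn from `drug_shares`; adverse events drawn
#' independently per vocabulary term (at the planted index-arm probability
#' for planted pairs, the background probability otherwise); indications per
#' drug; demographics, year and outcomes from their configured
#' distributions; and duplicate case versions injected by re-emitting a
#' `duplicate_rate` fraction of reports as exact-payload copies with
#' incremented version numbers. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return list with `store` (a [report_store()], not deduplicated) and
#'   `ledger`, the ground truth: `associations` (per planted pair: target
#'   ROR, probabilities and expected cells at the deduplicated size),
#'   `case_drug` (true index drug per case), `duplicate_of` (isr of the
#'   original submission per duplicate), `n_cases`, `n_duplicates`.
#' @examples
#' sim <- generate_reports(sim_config(500, seed = 7))
#' sim$ledger$n_cases
#' @export
generate_reports <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(seed %||% config$seed)
  n <- config$n_reports
  n_dup <- as.integer(round(config$duplicate_rate * n))
  n_cases <- n - n_dup
  if (n_cases < 1L) stop("duplicate_rate leaves no base cases", call. = FALSE)
  drugs <- names(config$drug_shares)

  set.seed(stage_seed(seed, "drugs"))
  idx_drug <- sample(drugs, n_cases, replace = TRUE,
                     prob = config$drug_shares)
  verbatim <- idx_drug
  if (!is.null(config$lexicon)) {
    for (cn in intersect(lexicon_drugs(config$lexicon), drugs)) {
      rows <- which(idx_drug == cn)
      syns <- config$lexicon$entries[[cn]]
      if (length(rows) && length(syns) > 1L) {
        verbatim[rows] <- sample(syns, length(rows), replace = TRUE)
      }
    }
  }

  set.seed(stage_seed(seed, "events"))
  vocab <- names(config$event_vocab)
  occ_row <- integer(0)
  occ_term <- character(0)
  planted_key <- vapply(config$planted,
                        function(p) paste(p$drug, p$event, sep = "\r"), "")
  for (t in vocab) {
    p <- rep(config$event_vocab[[t]], n_cases)
    for (pa in config$planted) {
      if (pa$event == t) p[idx_drug == pa$drug] <- pa$p1
    }
    hit <- which(runif(n_cases) < p)
    occ_row <- c(occ_row, hit)
    occ_term <- c(occ_term, rep(t, length(hit)))
  }
  events <- relist_by_row(occ_row, occ_term, n_cases)

  set.seed(stage_seed(seed, "indications"))
  ind_row <- integer(0)
  ind_term <- character(0)
  for (g in names(config$indication_vocab)) {
    rows <- which(idx_drug == g)
    if (!length(rows)) next
    for (t in names(config$indication_vocab[[g]])) {
      hit <- rows[runif(length(rows)) < config$indication_vocab[[g]][[t]]]
      ind_row <- c(ind_row, hit)
      ind_term <- c(ind_term, rep(t, length(hit)))
    }
  }
  indications <- relist_by_row(ind_row, ind_term, n_cases)

  set.seed(stage_seed(seed, "demographics"))
  sex <- sample(c("female", "male", NA_character_), n_cases, replace = TRUE,
                prob = config$sex_probs[c("female", "male", "unknown")])
  age <- pmin(pmax(round(rnorm(n_cases, config$age_mean, config$age_sd)), 0),
              110)
  age[runif(n_cases) < config$age_unknown_rate] <- NA_real_
  country <- sample(names(config$country_probs), n_cases, replace = TRUE,
                    prob = config$country_probs)
  country[country == "unknown"] <- NA_character_

  set.seed(stage_seed(seed, "years"))
  year <- as.integer(sample(names(config$year_probs), n_cases,
                            replace = TRUE, prob = config$year_probs))

  set.seed(stage_seed(seed, "outcomes"))
  out_row <- integer(0)
  out_cat <- character(0)
  for (cat in names(config$outcome_probs)) {
    hit <- which(runif(n_cases) < config$outcome_probs[[cat]])
    out_row <- c(out_row, hit)
    out_cat <- c(out_cat, rep(cat, length(hit)))
  }
  outcomes <- relist_by_row(out_row, out_cat, n_cases)

  set.seed(stage_seed(seed, "concomitants"))
  has_con <- runif(n_cases) < config$concomitant_rate
  con_name <- sample(config$other_drug_pool, n_cases, replace = TRUE)
  con_role <- sample(c("secondary_suspect", "concomitant", "interacting"),
                     n_cases, replace = TRUE, prob = c(0.2, 0.7, 0.1))

  drug_verbatim <- as.list(verbatim)
  drug_canonical <- as.list(idx_drug)
  drug_role <- rep(list("primary_suspect"), n_cases)
  for (i in which(has_con)) {
    drug_verbatim[[i]] <- c(drug_verbatim[[i]], con_name[i])
    drug_canonical[[i]] <- c(drug_canonical[[i]], NA_character_)
    drug_role[[i]] <- c(drug_role[[i]], con_role[i])
  }

  case_id <- sprintf("C%07d", seq_len(n_cases))
  base <- data.table::setDT(list(
    case_id = case_id, version = rep(1L, n_cases),
    drug_verbatim = drug_verbatim, drug_canonical = drug_canonical,
    drug_role = drug_role, events = events, indications = indications,
    sex = sex, age_years = age, country = country, year = year,
    outcomes = outcomes))

  set.seed(stage_seed(seed, "duplicates"))
  dup_of <- if (n_dup > 0L) sort(sample(n_cases, n_dup, replace = TRUE))
            else integer(0)
  full <- if (n_dup > 0L) {
    dup <- base[dup_of]
    dup[, version := 1L + data.table::rowid(case_id)]
    data.table::rbindlist(list(base, dup))
  } else base
  full[, isr_id := sprintf("ISR%08d", seq_len(nrow(full)))]
  store <- report_store(full)

  ledger <- list(
    n_cases = n_cases,
    n_duplicates = n_dup,
    case_drug = data.table::data.table(case_id = case_id, drug = idx_drug),
    duplicate_of = data.table::data.table(
      isr_id = full$isr_id[seq_len(n_dup) + n_cases],
      original_isr = full$isr_id[dup_of],
      case_id = full$case_id[seq_len(n_dup) + n_cases]),
    associations = data.table::rbindlist(lapply(config$planted, function(p) {
      tab <- expected_table(config, p$drug, p$event)
      data.table::data.table(
        drug = p$drug, event = p$event, target_ror = p$target_ror,
        p0 = p$background_event_prob, p1 = p$p1,
        E_DE = tab$DE, E_De = tab$De, E_dE = tab$dE, E_de = tab$de)
    }))
  )
  list(store = store, ledger = ledger)
}

## scatter (row, value) pairs into a list column of length n
relist_by_row <- function(rows, values, n) {
  out <- vector("list", n)
  out[] <- list(character(0))
  if (length(rows)) {
    o <- order(rows)
    grouped <- split(values[o], rows[o])
    out[as.integer(names(grouped))] <- grouped
  }
  out
}

#' Expected 2x2 table under the generative model
#'
#' Expectation of each contingency cell for a drug-event pair at the
#' deduplicated store size: `P(event | drug g)` is the planted index-arm
#' probability where `(g, event)` is planted and the background probability
#' otherwise, mixed over drug shares for the non-exposed margin. When the
#' event is planted for the index drug only, the ROR of the expected table
#' equals the planted target ROR exactly (odds construction identity); when
#' several drugs plant the same event, the background mixture shifts the
#' population ROR accordingly.
#'
#' @param config a [sim_config()].
#' @param drug canonical drug name holding a share in `config`.
#' @param event event term in the configured vocabulary.
#' @return a real-valued [contingency_table()] scaled to the expected
#'   deduplicated report count.
#' @export
expected_table <- function(config, drug, event) {
  stopifnot(inherits(config, "sim_config"))
  drug <- normalize_term(drug)
  event <- normalize_term(event)
  if (!drug %in% names(config$drug_shares)) {
    stop("drug '", drug, "' holds no share in the configuration",
         call. = FALSE)
  }
  if (!event %in% names(config$event_vocab)) {
    stop("event '", event, "' is not in the configured vocabulary",
         call. = FALSE)
  }
  p_event_given <- function(g) {
    for (pa in config$planted) {
      if (pa$drug == g && pa$event == event) return(pa$p1)
    }
    config$event_vocab[[event]]
  }
  n_cases <- config$n_reports -
    as.integer(round(config$duplicate_rate * config$n_reports))
  shares <- config$drug_shares
  pd <- shares[[drug]]
  pe_d <- p_event_given(drug)
  others <- setdiff(names(shares), drug)
  pe_other <- sum(vapply(others, function(g) shares[[g]] * p_event_given(g),
                         numeric(1)))
  contingency_table(
    DE = n_cases * pd * pe_d,
    De = n_cases * pd * (1 - pe_d),
    dE = n_cases * pe_other,
    de = n_cases * (1 - pd - pe_other),
    real_valued = TRUE
  )
}
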