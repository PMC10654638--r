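## Reconstruction oracle: published disproportionality tables print, per
## drug-event pair, the co-occurrence count DE, the drug total D, the ROR
## (with CI lower bound) and the PRR (with Yates chi-squared) — but not the
## background cells dE and de. Because ROR and PRR share the single unknown
## background odds r = dE/de, the PRR is determined by (DE, D, ROR) alone,
## and the full table is recoverable from (DE, D, ROR, chi2) by solving for
## the background scale. This lets printed tables be verified without the
## source database.

#' PRR implied by a printed (DE, D, ROR) triple
#'
#' With `De = D - DE` and the background odds `r = dE/de = (DE/De)/ROR`,
#' the proportional reporting ratio is `(DE/D) * (1 + r) / r` regardless of
#' the background size.
#'
#' @param DE co-occurrence count.
#' @param D total reports for the drug (`DE < D`).
#' @param ror reporting odds ratio.
#' @return the implied PRR (numeric, vectorized).
#' @examples
#' implied_prr(6043, 117857, 53.025)   # ~ 50.357
#' @export
implied_prr <- function(DE, D, ror) {
  stopifnot(all(DE > 0), all(D > DE), all(ror > 0))
  De <- D - DE
  r <- (DE / De) / ror
  (DE / D) * (1 + r) / r
}

#' Reconstruct a 2x2 table from printed summary statistics
#'
#' Recovers a real-valued contingency table from the printed co-occurrence
#' count `DE`, drug total `D`, `ROR` and Yates chi-squared. The index column
#' is fixed at `(DE, De = D - DE)`; the background column is `(dE, de) =
#' (r*s, s)` with `r = (DE/De)/ROR`, and the scale `s` is found by bracketed
#' bisection so that the Yates statistic of the table matches `chi2` to
#' relative tolerance `tol`. The chi-squared is increasing in `s` towards a
#' finite asymptote `(|DE - r*De| - (1 + r)/2)^2 / (D * r)`; a target at or
#' above the asymptote is unsolvable and raises an error naming it.
#'
#' @param DE co-occurrence count.
#' @param D drug total (`DE < D`).
#' @param ror printed reporting odds ratio.
#' @param chi2 printed Yates chi-squared.
#' @param tol relative tolerance on the chi-squared match (default `1e-9`).
#' @return a real-valued [contingency_table()] whose [compute_ror()] and
#'   [compute_chi2_yates()] reproduce `ror` and `chi2`.
#' @examples
#' tab <- reconstruct_table(6043, 117857, 53.025, 193469.11)
#' compute_ror(tab)$ci_low   # ~ 51.377
#' @export
reconstruct_table <- function(DE, D, ror, chi2, tol = 1e-9) {
  stopifnot(DE > 0, D > DE, ror > 0, chi2 > 0)
  De <- D - DE
  r <- (DE / De) / ror
  chi2_at <- function(s) chi2_kernel(DE, De, r * s, s)$chi2
  asymptote <- (abs(DE - r * De) - (1 + r) / 2)^2 / (D * r)
  if (chi2 >= asymptote) {
    stop(sprintf(paste0("chi2 = %.6g is at or above the large-background ",
                        "asymptote %.6g for these (DE, D, ROR); ",
                        "no table exists"), chi2, asymptote), call. = FALSE)
  }
  ## bracket the background scale on a log grid, then bisect
  lo <- 1e-6
  hi <- max(D, 1)
  while (chi2_at(hi) < chi2) {
    hi <- hi * 2
    if (hi > 1e18) {
      stop("bracket search failed: chi-squared never reached the target ",
           "below background scale 1e18", call. = FALSE)
    }
  }
  if (chi2_at(lo) > chi2) {
    stop("bracket search failed: chi-squared exceeds the target even for a ",
         "vanishing background; the statistic is not monotone here",
         call. = FALSE)
  }
  for (it in seq_len(200L)) {
    mid <- sqrt(lo * hi)
    if (chi2_at(mid) < chi2) lo <- mid else hi <- mid
    if ((hi - lo) < tol * lo) break
  }
  s <- sqrt(lo * hi)
  got <- chi2_at(s)
  if (abs(got - chi2) > max(tol * 1e3, 1e-6) * chi2) {
    stop(sprintf("bisection did not converge: chi2 %.9g vs target %.9g",
                 got, chi2), call. = FALSE)
  }
  contingency_table(DE, De, r * s, s, real_valued = TRUE)
}

#' Verify printed signal statistics against the reconstruction oracle
#'
#' For each row of a printed signal table — columns `drug`, `event`, `DE`,
#' `D`, `ror`, `ci_low`, `prr`, `chi2` — recomputes the PRR implied by
#' `(DE, D, ror)` and the CI lower bound of the table reconstructed from
#' `(DE, D, ror, chi2)`, and compares both with the printed values. Rounding
#' of the printed inputs propagates, so tolerances are relative.
#'
#' @param path TSV of printed rows; defaults to the table bundled with the
#'   package.
#' @param prr_rtol,ci_rtol relative tolerances for the PRR and CI checks
#'   (defaults `1e-3` and `2e-3`).
#' @return `data.table` with the printed values, the recomputed `prr_implied`
#'   and `ci_low_recon`, their relative errors and per-row `prr_ok` /
#'   `ci_ok` flags.
#' @export
verify_printed_stats <- function(path = NULL, prr_rtol = 1e-3,
                                 ci_rtol = 2e-3) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_signals.tsv", package = "pvsignal")
  }
  dt <- data.table::fread(path, sep = "\t")
  need <- c("drug", "event", "DE", "D", "ror", "ci_low", "prr", "chi2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("printed-signal file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt[, prr_implied := implied_prr(DE, D, ror)]
  dt[, ci_low_recon := vapply(seq_len(.N), function(i) {
    compute_ror(reconstruct_table(DE[i], D[i], ror[i], chi2[i]))$ci_low
  }, numeric(1))]
  dt[, prr_rel_err := abs(prr_implied - prr) / prr]
  dt[, ci_rel_err := abs(ci_low_recon - ci_low) / ci_low]
  dt[, prr_ok := prr_rel_err <= prr_rtol]
  dt[, ci_ok := ci_rel_err <= ci_rtol]
  dt[]
}
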