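#' Per-algorithm signal criteria
#'
#' Defaults follow the conventional screening thresholds: ROR and PRR
#' positive when `a >= 3` and the 95% CI lower bound exceeds 1; the MHRA
#' composite when `PRR > 2`, `chi2 > 4` and `a > 3` (note the strict count
#' gate, kept distinct from the `a >= 3` gate of ROR/PRR); BCPNN when
#' `IC - 2SD > 0`; MGPS when `EB05 > 2`.
#'
#' @param ror_min_a,ror_ci_lo ROR gates (`a >= ror_min_a`, `ror_lo > ror_ci_lo`).
#' @param prr_min_a,prr_ci_lo PRR gates.
#' @param mhra_prr,mhra_chi2,mhra_a_gt MHRA gates (`prr > `, `chi2 > `, `a > `).
#' @param bcpnn_ic025 BCPNN gate (`ic025 > `).
#' @param mgps_eb05 MGPS gate (`eb05 > `).
#' @return Named list of thresholds.
#' @export
signal_criteria <- function(ror_min_a = 3, ror_ci_lo = 1,
                            prr_min_a = 3, prr_ci_lo = 1,
                            mhra_prr = 2, mhra_chi2 = 4, mhra_a_gt = 3,
                            bcpnn_ic025 = 0, mgps_eb05 = 2) {
  crit <- list(
    ror_min_a = ror_min_a, ror_ci_lo = ror_ci_lo,
    prr_min_a = prr_min_a, prr_ci_lo = prr_ci_lo,
    mhra_prr = mhra_prr, mhra_chi2 = mhra_chi2, mhra_a_gt = mhra_a_gt,
    bcpnn_ic025 = bcpnn_ic025, mgps_eb05 = mgps_eb05
  )
  if (!all(vapply(crit, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    rlang::abort("signal criteria must be finite scalars")
  }
  crit
}

#' BCPNN signal-strength tier
#'
#' Tiers the screening bound `IC - 2SD`: `<= 0` no signal (`-`), `(0, 1.5]`
#' weak (`+`), `(1.5, 3]` moderate (`++`), `> 3` strong (`+++`).
#'
#' @param ic025 Numeric vector of `IC - 2SD` values.
#' @return Character vector in `{-, +, ++, +++}` (NA propagates).
#' @export
tier_bcpnn <- function(ic025) {
  as.character(cut(ic025, breaks = c(-Inf, 0, 1.5, 3, Inf),
                   labels = c("-", "+", "++", "+++"), right = TRUE))
}

#' Flag important medical events
#'
#' Case-insensitive exact PT-name membership in an IME reference list (such
#' as the EMA's important-medical-event PT list, supplied by the user as a
#' one-column CSV).
#'
#' @param terms Character vector of PT names.
#' @param ime_list Character vector of IME PT names.
#' @return Logical vector.
#' @export
flag_ime <- function(terms, ime_list) {
  if (length(ime_list) == 0) {
    rlang::warn("empty IME list: all terms flagged FALSE")
    return(rep(FALSE, length(terms)))
  }
  tolower(trimws(terms)) %in% tolower(trimws(ime_list))
}

#' Apply signal criteria to disproportionality results
#'
#' One decision row per term with `a >= 1` (terms never reported for the
#' target drug are excluded entirely); undefined-flagged statistics evaluate
#' as negative.
#'
#' @param results Tibble from [dispro_stats()] (needs `term`, `a`, and the
#'   per-statistic columns).
#' @param criteria See [signal_criteria()].
#' @param ime_list Optional IME PT list for flagging.
#' @return Tibble with per-algorithm positivity flags, the BCPNN tier, the
#'   IME flag and `n_positive_algorithms`.
#' @export
evaluate_signals <- function(results, criteria = signal_criteria(),
                             ime_list = NULL) {
  if (!is.list(criteria) || is.null(criteria$ror_min_a)) {
    rlang::abort("`criteria` must come from signal_criteria()")
  }
  res <- dplyr::filter(results, .data$a >= 1)
  flag <- function(x) !is.na(x) & x
  out <- res |>
    dplyr::transmute(
      term = .data$term,
      a = .data$a,
      positive_ror = flag(.data$a >= criteria$ror_min_a &
                            .data$ror_lo > criteria$ror_ci_lo),
      positive_prr = flag(.data$a >= criteria$prr_min_a &
                            .data$prr_lo > criteria$prr_ci_lo),
      positive_mhra = flag(.data$prr > criteria$mhra_prr &
                             .data$chi2 > criteria$mhra_chi2 &
                             .data$a > criteria$mhra_a_gt),
      positive_bcpnn = flag(.data$ic025 > criteria$bcpnn_ic025),
      positive_mgps = flag(.data$eb05 > criteria$mgps_eb05),
      bcpnn_tier = dplyr::coalesce(tier_bcpnn(.data$ic025), "-")
    )
  out$ime <- if (is.null(ime_list)) NA else flag_ime(out$term, ime_list)
  out$n_positive_algorithms <- out$positive_ror + out$positive_prr +
    out$positive_mhra + out$positive_bcpnn + out$positive_mgps
  out
}

signal_algorithms <- c("ror", "prr", "mhra", "bcpnn", "mgps")

#' Multi-algorithm overlap summary
#'
#' Counts, over all terms positive on at least one algorithm, every observed
#' intersection pattern of the five algorithms (UpSet input), the
#' per-algorithm totals, the equivalent Venn counts, and the IME split of
#' detected terms.
#'
#' @param decisions Tibble from [evaluate_signals()].
#' @return An `overlap_summary`: list with `per_algorithm`, `patterns`
#'   (tibble: membership columns + count), `venn` (named pattern counts),
#'   `ime_crosstab`, `n_union`.
#' @export
overlap_summary <- function(decisions) {
  cols <- paste0("positive_", signal_algorithms)
  stopifnot(all(cols %in% names(decisions)))
  memb <- as.matrix(decisions[cols])
  pos_any <- rowSums(memb) > 0
  d <- decisions[pos_any, , drop = FALSE]
  memb <- memb[pos_any, , drop = FALSE]
  pattern_key <- apply(memb, 1, function(r) {
    paste(signal_algorithms[as.logical(r)], collapse = "&")
  })
  patterns <- tibble::as_tibble(memb) |>
    stats::setNames(signal_algorithms) |>
    dplyr::mutate(pattern = pattern_key) |>
    dplyr::count(dplyr::across(dplyr::all_of(signal_algorithms)),
                 .data$pattern, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count))
  per_algorithm <- colSums(memb)
  names(per_algorithm) <- signal_algorithms
  all_five <- rowSums(memb) == 5
  ime_crosstab <- if (!all(is.na(d$ime))) {
    table(ime = d$ime, all_five_positive = all_five)
  } else {
    NULL
  }
  structure(
    list(
      per_algorithm = per_algorithm,
      patterns = patterns,
      venn = stats::setNames(patterns$count, patterns$pattern),
      ime_crosstab = ime_crosstab,
      n_union = nrow(d)
    ),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\n")
  cat("  union of positives:", x$n_union, "terms\n")
  cat("  per algorithm:",
      paste(sprintf("%s=%d", names(x$per_algorithm), x$per_algorithm),
            collapse = ", "), "\n")
  cat("  intersection patterns:", nrow(x$patterns), "\n")
  invisible(x)
}
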