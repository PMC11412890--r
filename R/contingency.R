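#' Count distinct drug-event combinations
#'
#' The counting unit throughout the package is the distinct
#' (report, term) *combination*, not the report: one report mentioning k
#' distinct preferred terms contributes k combinations (a report listing the
#' same PT twice contributes once). At the SOC level, each report contributes
#' one combination per distinct system organ class its PTs map to; PTs absent
#' from the map are counted under `"unmapped"` and logged, never dropped
#' silently.
#'
#' @param target_reports,background_reports Clean report tibbles (disjoint by
#'   `primaryid`); target = the drug under study as primary suspect,
#'   background = all other deduplicated reports of the period.
#' @param level `"pt"` or `"soc"`.
#' @param pt_to_soc Tibble with columns `pt`, `soc`; required at SOC level.
#' @return A `combination_counts` tibble with columns `term`, `n_target`,
#'   `n_other`, and attributes `m_target`, `m_other` (total combinations per
#'   arm), `level`, and `unmapped_pts`.
#' @export
count_combinations <- function(target_reports, background_reports,
                               level = c("pt", "soc"), pt_to_soc = NULL) {
  level <- match.arg(level)
  overlap <- intersect(target_reports$primaryid,
                       background_reports$primaryid)
  if (length(overlap) > 0) {
    rlang::abort("target and background reports must be disjoint by primaryid")
  }
  if (level == "soc" && is.null(pt_to_soc)) {
    rlang::abort("SOC-level counting needs a `pt_to_soc` map")
  }

  long_terms <- function(reports) {
    long <- tibble::tibble(
      primaryid = rep(reports$primaryid, lengths(reports$reactions)),
      term = as.character(unlist(reports$reactions, use.names = FALSE))
    ) |>
      dplyr::distinct()
    if (level == "soc") {
      long <- long |>
        dplyr::left_join(pt_to_soc, by = c(term = "pt"))
      unmapped <- unique(long$term[is.na(long$soc)])
      long <- long |>
        dplyr::transmute(
          primaryid = .data$primaryid,
          term = dplyr::coalesce(.data$soc, "unmapped")
        ) |>
        dplyr::distinct()
      attr(long, "unmapped") <- unmapped
    }
    long
  }

  lt <- long_terms(target_reports)
  lb <- long_terms(background_reports)
  unmapped <- union(attr(lt, "unmapped") %||% character(),
                    attr(lb, "unmapped") %||% character())
  if (length(unmapped) > 0) {
    rlang::inform(paste0(length(unmapped),
                         " PT(s) missing from the SOC map counted as 'unmapped'"))
  }

  counts <- dplyr::full_join(
    dplyr::count(lt, .data$term, name = "n_target"),
    dplyr::count(lb, .data$term, name = "n_other"),
    by = "term"
  ) |>
    dplyr::mutate(
      n_target = dplyr::coalesce(.data$n_target, 0L),
      n_other = dplyr::coalesce(.data$n_other, 0L)
    ) |>
    dplyr::arrange(.data$term)

  structure(
    counts,
    m_target = nrow(lt),
    m_other = nrow(lb),
    level = level,
    unmapped_pts = unmapped,
    class = c("combination_counts", class(counts))
  )
}

#' Build 2x2 contingency tables from combination counts
#'
#' For each term: `a` = target-drug reports mentioning the term, `b` = all
#' other target-drug combinations, `c` = background reports mentioning the
#' term, `d` = all other background combinations, so `a + b` is the total
#' number of target-drug combinations and `n = a + b + c + d`.
#'
#' @param counts A `combination_counts` object.
#' @param terms Optional character vector restricting the output (a term with
#'   no target count yields `a = 0`); default: every term observed.
#' @return Tibble with columns `term`, `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_tables <- function(counts, terms = NULL) {
  stopifnot(inherits(counts, "combination_counts"))
  m_target <- attr(counts, "m_target")
  m_other <- attr(counts, "m_other")
  df <- tibble::as_tibble(counts)
  if (!is.null(terms)) {
    missing <- setdiff(terms, df$term)
    if (length(missing) > 0) {
      df <- dplyr::bind_rows(
        df,
        tibble::tibble(term = missing, n_target = 0L, n_other = 0L)
      )
    }
    df <- df[match(terms, df$term), , drop = FALSE]
  }
  out <- df |>
    dplyr::transmute(
      term = .data$term,
      a = as.integer(.data$n_target),
      b = as.integer(m_target - .data$n_target),
      c = as.integer(.data$n_other),
      d = as.integer(m_other - .data$n_other),
      n = as.integer(m_target + m_other)
    )
  if (any(out$b < 0 | out$d < 0)) {
    rlang::abort("corrupted combination counts: negative contingency cell")
  }
  out
}

#' 2x2 table for a single term
#'
#' @inheritParams contingency_tables
#' @param term One term name.
#' @return One-row tibble `term, a, b, c, d, n`.
#' @export
make_contingency <- function(counts, term) {
  stopifnot(length(term) == 1)
  contingency_tables(counts, terms = term)
}

#' Partition reports for stratified analyses
#'
#' Year, sex and age-band partitions are disjoint and exhaustive over
#' non-missing values (reports with a missing key go to the audit, not a
#' stratum). Indication partitions select reports whose primary-suspect
#' indications contain the given PT and may overlap.
#'
#' @param reports Clean report tibble.
#' @param by One of `"receipt_year"`, `"indication_pt"`, `"sex"`,
#'   `"age_band"`.
#' @param indications Character vector of indication PTs (required for
#'   `by = "indication_pt"`).
#' @param age_breaks Breaks for `age_band` (left-closed), default
#'   `<18, 18-44, 45-64, >=65`.
#' @return Named list of report tibbles; `attr(, "n_missing")` counts reports
#'   excluded for a missing key.
#' @export
stratify_reports <- function(reports,
                             by = c("receipt_year", "indication_pt", "sex",
                                    "age_band"),
                             indications = NULL,
                             age_breaks = c(0, 18, 45, 65, Inf)) {
  by <- match.arg(by)
  if (by == "indication_pt") {
    if (is.null(indications)) {
      rlang::abort("indication stratification needs `indications`")
    }
    out <- lapply(indications, function(ind) {
      keep <- vapply(reports$indications, function(x) ind %in% x, logical(1))
      reports[keep, , drop = FALSE]
    })
    names(out) <- indications
    attr(out, "n_missing") <- 0L
    return(out)
  }
  key <- switch(by,
    receipt_year = as.character(reports$receipt_year),
    sex = reports$sex,
    age_band = {
      lab <- c("<18", "18-44", "45-64", ">=65")
      as.character(cut(reports$age_years, breaks = age_breaks,
                       labels = lab, right = FALSE))
    }
  )
  miss <- is.na(key)
  out <- split(reports[!miss, , drop = FALSE], key[!miss])
  attr(out, "n_missing") <- sum(miss)
  out
}
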