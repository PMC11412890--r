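#' Percentage in printed-table style
#'
#' `100 * numerator / denominator`, rounded half-up to two decimals — the
#' rounding convention of published report-count tables.
#'
#' @param numerator,denominator Counts (`denominator > 0`).
#' @return Percent rounded to 2 decimals; NA with a warning when the
#'   denominator is zero.
#' @export
#' @examples
#' percentage(66705, 77384) # 86.20
percentage <- function(numerator, denominator) {
  bad <- denominator == 0
  if (any(bad, na.rm = TRUE)) {
    rlang::warn("percentage undefined for zero denominator")
  }
  out <- round_half_up(100 * numerator / denominator, 2)
  out[bad] <- NA_real_
  out
}

summary_block <- function(block, item, count, denom) {
  tibble::tibble(
    block = block, item = item, count = as.integer(count),
    percent = percentage(count, denom), value = NA_real_
  )
}

#' Demographic and reporting summary of a report set
#'
#' Reproduces the usual descriptive table of a spontaneous-report study: sex,
#' age bands (`<18`, `18-44`, `45-64`, `>=65`, missing), age median and
#' quartiles, receipt year, reporter occupation, top reporting countries,
#' route, seriousness, and the outcome distribution. Outcomes are
#' multi-select: one report can carry several, so the block's percents may
#' jointly exceed 100. Missing values appear as explicit `"Not Specified"`
#' rows. All percents use the number of reports as denominator.
#'
#' @param reports Clean report tibble.
#' @param top_countries How many countries to list individually (default 5).
#' @return Tibble with columns `block`, `item`, `count`, `percent`, `value`
#'   (the `value` column carries the age median/quartiles).
#' @export
demographic_summary <- function(reports, top_countries = 5) {
  stopifnot(nrow(reports) > 0)
  n <- nrow(reports)

  tab_of <- function(block, x, order = NULL) {
    x <- ifelse(is.na(x), "Not Specified", as.character(x))
    counts <- table(x)
    items <- if (is.null(order)) names(sort(counts, decreasing = TRUE)) else {
      c(intersect(order, names(counts)),
        setdiff(names(sort(counts, decreasing = TRUE)), order))
    }
    summary_block(block, items, as.integer(counts[items]), n)
  }

  sex <- tab_of("sex", reports$sex, order = c("F", "M", "Not Specified"))

  band <- cut(reports$age_years, breaks = c(0, 18, 45, 65, Inf),
              labels = c("<18", "18-44", "45-64", ">=65"), right = FALSE)
  age_band <- tab_of("age_group", band,
                     order = c("<18", "18-44", "45-64", ">=65",
                               "Not Specified"))

  qs <- stats::quantile(reports$age_years, c(0.25, 0.5, 0.75), na.rm = TRUE,
                        type = 7)
  age_stats <- tibble::tibble(
    block = "age_years",
    item = c("Q1", "median", "Q3"),
    count = NA_integer_, percent = NA_real_,
    value = as.numeric(qs)
  )

  year <- tab_of("reporting_year", reports$receipt_year,
                 order = as.character(sort(unique(reports$receipt_year))))
  reporter <- tab_of("reporter", reports$reporter)

  ctab <- sort(table(reports$country), decreasing = TRUE)
  top <- utils::head(names(ctab), top_countries)
  country <- dplyr::bind_rows(
    summary_block("country", top, as.integer(ctab[top]), n),
    if (length(ctab) > length(top) || anyNA(reports$country)) {
      rest <- sum(ctab) - sum(ctab[top]) + sum(is.na(reports$country))
      summary_block("country", "Other/Not Specified", rest, n)
    }
  )

  route <- tab_of("route", reports$route)
  serious <- summary_block(
    "seriousness", c("Serious", "Non-Serious"),
    c(sum(reports$serious), sum(!reports$serious)), n
  )

  oc <- table(unlist(reports$outcomes, use.names = FALSE))
  outcomes <- if (length(oc) > 0) {
    oc <- sort(oc, decreasing = TRUE)
    summary_block("outcomes", names(oc), as.integer(oc), n)
  } else {
    NULL
  }

  dplyr::bind_rows(sex, age_band, age_stats, year, reporter, country, route,
                   serious, outcomes)
}

#' Rank indications of the suspect drug
#'
#' Counts reports whose primary-suspect indications contain each indication
#' PT (a report carrying two indications counts once under each), ranked by
#' descending count with alphabetical tie-break; percent denominator is the
#' number of reports.
#'
#' @param reports Clean report tibble (target-drug reports).
#' @return Tibble `indication`, `count`, `percent`.
#' @export
indication_ranking <- function(reports) {
  n <- nrow(reports)
  long <- tibble::tibble(
    primaryid = rep(reports$primaryid, lengths(reports$indications)),
    indication = unlist(reports$indications, use.names = FALSE)
  ) |>
    dplyr::distinct()
  long |>
    dplyr::count(.data$indication, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$indication) |>
    dplyr::mutate(percent = percentage(.data$count, n))
}

#' Report proportions by system organ class
#'
#' Shares of drug-event combinations per SOC: the numerator is the number of
#' (report, SOC) combinations under each SOC, the denominator the total
#' number of combinations, so the percents sum to 100 up to rounding.
#' Unmapped PTs appear under `"unmapped"`.
#'
#' @param reports Clean report tibble.
#' @param pt_to_soc Tibble with columns `pt`, `soc`.
#' @return Tibble `soc`, `count`, `percent`, sorted by descending count.
#' @export
soc_report_proportions <- function(reports, pt_to_soc) {
  long <- tibble::tibble(
    primaryid = rep(reports$primaryid, lengths(reports$reactions)),
    pt = unlist(reports$reactions, use.names = FALSE)
  ) |>
    dplyr::distinct() |>
    dplyr::left_join(pt_to_soc, by = "pt") |>
    dplyr::transmute(primaryid = .data$primaryid,
                     soc = dplyr::coalesce(.data$soc, "unmapped")) |>
    dplyr::distinct()
  total <- nrow(long)
  long |>
    dplyr::count(.data$soc, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$soc) |>
    dplyr::mutate(percent = percentage(.data$count, total))
}
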