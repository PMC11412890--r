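#' Column aliases for FAERS quarterly tables
#'
#' FAERS switched its key column from `ISR` (legacy, pre-2012Q4) to
#' `PRIMARYID`; a few demographic columns were renamed at the same time. The
#' reader accepts either dialect through this alias map: the first name found
#' in a file's header is renamed to the canonical (list-name) form.
#'
#' @return Named list mapping canonical column names to accepted header names
#'   (case-insensitive).
#' @export
faers_column_aliases <- function() {
  list(
    primaryid        = c("primaryid", "isr"),
    caseid           = c("caseid", "case"),
    fda_dt           = c("fda_dt"),
    age              = c("age"),
    age_cod          = c("age_cod"),
    sex              = c("sex", "gndr_cod"),
    occp_cod         = c("occp_cod"),
    reporter_country = c("reporter_country", "occr_country"),
    drug_seq         = c("drug_seq"),
    role_cod         = c("role_cod"),
    drugname         = c("drugname"),
    prod_ai          = c("prod_ai"),
    route            = c("route"),
    pt               = c("pt"),
    indi_drug_seq    = c("indi_drug_seq", "drug_seq"),
    indi_pt          = c("indi_pt"),
    outc_cod         = c("outc_cod", "outc_code")
  )
}

# Mandatory canonical columns per table; used for header validation.
faers_required_columns <- function() {
  list(
    demo = c("primaryid", "caseid", "fda_dt"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
    reac = c("primaryid", "pt"),
    indi = c("primaryid", "indi_drug_seq", "indi_pt"),
    outc = c("primaryid", "outc_cod")
  )
}

read_faers_table <- function(path, table, aliases) {
  if (!file.exists(path)) {
    rlang::abort(paste0("FAERS ", toupper(table), " file not found: ", path))
  }
  df <- suppressWarnings(readr::read_delim(
    path,
    delim = "$", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE,
    name_repair = "minimal"
  ))
  if (nrow(df) == 0 && ncol(df) <= 1) {
    rlang::warn(paste0("FAERS ", toupper(table), " file is empty: ", path))
    req <- faers_required_columns()[[table]]
    out <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(req)), req
    ))
    return(out)
  }
  names(df) <- tolower(trimws(names(df)))
  for (canon in names(aliases)) {
    # a header name that is itself canonical (for another field) is not
    # up for grabs as an alias, e.g. DRUG's drug_seq vs INDI's indi_drug_seq
    candidates <- setdiff(aliases[[canon]], setdiff(names(aliases), canon))
    hit <- intersect(candidates, names(df))
    if (length(hit) > 0 && !(canon %in% names(df))) {
      names(df)[match(hit[1], names(df))] <- canon
    }
  }
  if (table == "indi" && !"indi_drug_seq" %in% names(df) &&
      "drug_seq" %in% names(df)) {
    names(df)[match("drug_seq", names(df))] <- "indi_drug_seq"
  }
  req <- faers_required_columns()[[table]]
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "FAERS ", toupper(table), " header lacks mandatory column(s): ",
      paste(missing, collapse = ", "), " (", path, ")"
    ))
  }
  tibble::as_tibble(df)
}

new_faers_raw <- function(demo, drug, reac, indi, outc, audit = list()) {
  structure(
    list(demo = demo, drug = drug, reac = reac, indi = indi, outc = outc),
    audit = audit,
    class = "faers_raw"
  )
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("<faers_raw>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  audit <- attr(x, "audit")
  if (!is.null(audit$dedup)) {
    cat(sprintf(
      "  dedup: %d in, %d kept, %d duplicate, %d deleted\n",
      audit$dedup$input, audit$dedup$kept,
      audit$dedup$dropped_duplicate, audit$dedup$dropped_deleted
    ))
  }
  invisible(x)
}

#' Read one FAERS-style quarter of "$"-delimited ASCII tables
#'
#' Loads the DEMO, DRUG, REAC and (optionally) INDI and OUTC tables of a
#' quarterly FAERS extract. Files are "$"-delimited with a header row; both
#' the legacy `ISR` and current `PRIMARYID` key dialects are accepted (see
#' [faers_column_aliases()]). Rows lacking a parseable report key are counted
#' in the audit and dropped, never fatal.
#'
#' @param paths Named character vector or list with elements `demo`, `drug`,
#'   `reac` and optionally `indi`, `outc`, giving one file path each.
#' @param aliases Column alias map, see [faers_column_aliases()].
#' @return A `faers_raw` object: a list of five tibbles (`demo`, `drug`,
#'   `reac`, `indi`, `outc`) keyed by `primaryid`, with a row-level audit in
#'   `attr(, "audit")`.
#' @export
read_faers_quarter <- function(paths, aliases = faers_column_aliases()) {
  paths <- as.list(paths)
  need <- c("demo", "drug", "reac")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0) {
    rlang::abort(paste0("`paths` must name files for: ",
                        paste(missing, collapse = ", ")))
  }
  tabs <- list()
  audit <- list(bad_rows = c())
  for (tb in c("demo", "drug", "reac", "indi", "outc")) {
    if (is.null(paths[[tb]])) {
      req <- faers_required_columns()[[tb]]
      tabs[[tb]] <- tibble::as_tibble(stats::setNames(
        rep(list(character()), length(req)), req
      ))
      next
    }
    df <- read_faers_table(paths[[tb]], tb, aliases)
    bad <- is.na(df$primaryid) | df$primaryid == ""
    audit$bad_rows[tb] <- sum(bad)
    tabs[[tb]] <- df[!bad, , drop = FALSE]
  }
  if (any(audit$bad_rows > 0)) {
    rlang::inform(paste0(
      "dropped rows without a report key: ",
      paste(sprintf("%s=%d", names(audit$bad_rows),
                    audit$bad_rows)[audit$bad_rows > 0], collapse = ", ")
    ))
  }
  new_faers_raw(tabs$demo, tabs$drug, tabs$reac, tabs$indi, tabs$outc,
                audit = audit)
}

#' Combine several quarters into one raw extract
#'
#' @param ... `faers_raw` objects (or a single list of them).
#' @return A `faers_raw` with row-bound tables.
#' @export
bind_faers_quarters <- function(...) {
  qs <- list(...)
  if (length(qs) == 1 && !inherits(qs[[1]], "faers_raw")) qs <- qs[[1]]
  stopifnot(all(vapply(qs, inherits, logical(1), "faers_raw")))
  new_faers_raw(
    demo = dplyr::bind_rows(lapply(qs, `[[`, "demo")),
    drug = dplyr::bind_rows(lapply(qs, `[[`, "drug")),
    reac = dplyr::bind_rows(lapply(qs, `[[`, "reac")),
    indi = dplyr::bind_rows(lapply(qs, `[[`, "indi")),
    outc = dplyr::bind_rows(lapply(qs, `[[`, "outc"))
  )
}

#' Deduplicate case versions
#'
#' FAERS ships one row per report *version*; a case (shared `caseid`) may
#' appear many times as follow-ups arrive. Per FDA guidance, the latest
#' version is kept: the record with the largest `fda_dt`, ties broken by the
#' largest `primaryid`. Cases listed in a deleted-case file are removed
#' entirely.
#'
#' @param raw A `faers_raw` object.
#' @param deleted_caseids Optional character vector of caseids to drop
#'   (FAERS publishes these only from 2019Q1 on; absence is normal).
#' @return The filtered `faers_raw`; the audit in `attr(, "audit")$dedup`
#'   records `input`, `kept`, `dropped_duplicate` and `dropped_deleted`
#'   (which always sum: input = kept + duplicate + deleted).
#' @export
deduplicate_cases <- function(raw, deleted_caseids = NULL) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo
  n_input <- nrow(demo)
  if (!is.null(deleted_caseids)) {
    deleted <- demo$caseid %in% as.character(deleted_caseids)
  } else {
    deleted <- rep(FALSE, n_input)
  }
  n_deleted <- sum(deleted)
  demo <- demo[!deleted, , drop = FALSE]

  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  # fall back to lexicographic rank when primaryid is not numeric
  if (anyNA(pid)) pid <- as.numeric(factor(demo$primaryid))
  fda[is.na(fda)] <- -Inf

  keep <- demo |>
    dplyr::mutate(.fda = fda, .pid = pid) |>
    dplyr::arrange(dplyr::desc(.data$.fda), dplyr::desc(.data$.pid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select(-".fda", -".pid")
  n_kept <- nrow(keep)

  keep_ids <- keep$primaryid
  out <- new_faers_raw(
    demo = keep,
    drug = dplyr::filter(raw$drug, .data$primaryid %in% keep_ids),
    reac = dplyr::filter(raw$reac, .data$primaryid %in% keep_ids),
    indi = dplyr::filter(raw$indi, .data$primaryid %in% keep_ids),
    outc = dplyr::filter(raw$outc, .data$primaryid %in% keep_ids),
    audit = attr(raw, "audit") %||% list()
  )
  audit <- attr(out, "audit")
  audit$dedup <- list(
    input = n_input,
    kept = n_kept,
    dropped_duplicate = n_input - n_deleted - n_kept,
    dropped_deleted = n_deleted
  )
  attr(out, "audit") <- audit
  out
}

#' Dedup audit counts
#' @param raw A `faers_raw` that went through [deduplicate_cases()].
#' @return A list with input/kept/dropped counts, or `NULL`.
#' @export
dedup_audit <- function(raw) (attr(raw, "audit") %||% list())$dedup

#' Convert a reported age to years
#'
#' FAERS records age as a value plus a unit code (`AGE_COD`). Decades,
#' months, weeks, days and hours are converted to years; unknown unit codes
#' and implausible results (outside 0-130 years) become missing with a
#' warning, never an error.
#'
#' @param value Numeric vector of age values.
#' @param unit_code Character vector of unit codes (`YR`, `DEC`, `MON`, `WK`,
#'   `DY`, `HR`); missing codes are treated as years when the value is
#'   plausible.
#' @return Numeric vector of ages in years (NA where unusable).
#' @export
#' @examples
#' normalize_age(c(72, 18, 2), c("YR", "MON", "DEC")) # 72, 1.5, 20
normalize_age <- function(value, unit_code) {
  value <- suppressWarnings(as.numeric(value))
  unit_code <- toupper(trimws(as.character(unit_code)))
  factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1429,
               DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factors[unit_code])
  f[is.na(unit_code) | unit_code == ""] <- 1
  unknown <- !is.na(unit_code) & unit_code != "" &
    !(unit_code %in% names(factors))
  if (any(unknown, na.rm = TRUE)) {
    rlang::warn(paste0("unknown age unit code(s): ",
                       paste(unique(unit_code[unknown]), collapse = ", ")))
  }
  out <- value * f
  oor <- !is.na(out) & (out < 0 | out > 130)
  if (any(oor)) {
    rlang::warn(sprintf("%d age value(s) outside [0, 130] set to missing",
                        sum(oor)))
  }
  out[oor] <- NA_real_
  out
}

occp_labels <- c(
  CN = "consumer", MD = "physician", PH = "pharmacist",
  HP = "other health-professional", OT = "other health-professional",
  LW = "lawyer"
)

outc_labels <- c(
  HO = "hospitalization", DE = "death", LT = "life-threatening",
  DS = "disability", RI = "required-intervention",
  CA = "congenital-anomaly", OT = "other"
)

serious_codes <- c("DE", "LT", "HO", "DS", "CA", "RI")

#' Build clean per-report records from a raw extract
#'
#' Joins the five raw tables into one tibble with a row per report:
#' demographics, seriousness and outcomes, the receipt year, the drug entries
#' as a list-column, and the deduplicated reaction PT set. A report is serious
#' when any outcome code among DE/LT/HO/DS/CA/RI is present. Reports outside
#' the study window or with no reaction PT are dropped and counted in the
#' audit (they cannot contribute to any contingency cell).
#'
#' Each report's `ps_drug`, `ps_prod_ai`, `route` and `indications` are taken
#' from its first primary-suspect drug entry (lowest `drug_seq`), so that
#' background reports carry their own suspect drug for expected-count
#' modelling; [filter_primary_suspect()] re-resolves these against a target
#' pattern.
#'
#' @param raw A `faers_raw`, normally after [deduplicate_cases()].
#' @param window Integer length-2 study window of receipt years (inclusive).
#' @return Tibble with columns `primaryid`, `caseid`, `receipt_year`,
#'   `age_years`, `sex`, `reporter`, `country`, `serious`, `outcomes` (list),
#'   `route`, `ps_drug`, `ps_prod_ai`, `indications` (list), `reactions`
#'   (list), `drugs` (list of per-entry tibbles). Audit counts in
#'   `attr(, "clean_audit")`.
#' @export
clean_reports <- function(raw, window = c(2014, 2024)) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo

  base <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    receipt_year = as.integer(
      suppressWarnings(as.numeric(demo$fda_dt)) %/% 10000
    ),
    age_years = if (all(c("age", "age_cod") %in% names(demo))) {
      suppressWarnings(normalize_age(demo$age, demo$age_cod))
    } else {
      NA_real_
    },
    sex = if ("sex" %in% names(demo)) {
      ifelse(toupper(trimws(demo$sex)) %in% c("F", "M"),
             toupper(trimws(demo$sex)), NA_character_)
    } else {
      NA_character_
    },
    reporter = if ("occp_cod" %in% names(demo)) {
      unname(occp_labels[toupper(trimws(demo$occp_cod))])
    } else {
      NA_character_
    },
    country = if ("reporter_country" %in% names(demo)) {
      dplyr::na_if(trimws(demo$reporter_country), "")
    } else {
      NA_character_
    }
  )

  outc <- raw$outc |>
    dplyr::mutate(outc_cod = toupper(trimws(.data$outc_cod))) |>
    dplyr::filter(.data$outc_cod %in% names(outc_labels)) |>
    dplyr::distinct(.data$primaryid, .data$outc_cod)
  outc_by <- outc |>
    dplyr::summarise(
      outcomes = list(unname(outc_labels[.data$outc_cod])),
      serious = any(.data$outc_cod %in% serious_codes),
      .by = "primaryid"
    )

  reac_by <- raw$reac |>
    dplyr::mutate(pt = trimws(.data$pt)) |>
    dplyr::filter(!is.na(.data$pt), .data$pt != "") |>
    dplyr::distinct(.data$primaryid, .data$pt) |>
    dplyr::summarise(reactions = list(.data$pt), .by = "primaryid")

  drug <- raw$drug |>
    dplyr::mutate(
      drug_seq = suppressWarnings(as.numeric(.data$drug_seq)),
      role_cod = toupper(trimws(.data$role_cod)),
      drugname = trimws(.data$drugname),
      prod_ai = if ("prod_ai" %in% names(raw$drug)) {
        trimws(.data$prod_ai)
      } else {
        NA_character_
      },
      route = if ("route" %in% names(raw$drug)) {
        tolower(trimws(.data$route))
      } else {
        NA_character_
      }
    ) |>
    dplyr::select(dplyr::any_of(c("primaryid", "drug_seq", "role_cod",
                                  "drugname", "prod_ai", "route")))
  indi_by <- raw$indi |>
    dplyr::mutate(
      indi_drug_seq = suppressWarnings(as.numeric(.data$indi_drug_seq)),
      indi_pt = trimws(.data$indi_pt)
    ) |>
    dplyr::filter(!is.na(.data$indi_pt), .data$indi_pt != "") |>
    dplyr::distinct(.data$primaryid, .data$indi_drug_seq, .data$indi_pt) |>
    dplyr::summarise(indications = list(.data$indi_pt),
                     .by = c("primaryid", "indi_drug_seq"))
  drug <- drug |>
    dplyr::left_join(indi_by,
                     by = c(primaryid = "primaryid",
                            drug_seq = "indi_drug_seq"))
  drug$indications <- lapply(drug$indications, function(x) x %||% character())

  # first PS entry per report supplies the report-level suspect-drug fields
  ps_first <- drug |>
    dplyr::filter(.data$role_cod == "PS") |>
    dplyr::arrange(.data$primaryid, .data$drug_seq) |>
    dplyr::distinct(.data$primaryid, .keep_all = TRUE) |>
    dplyr::transmute(
      primaryid = .data$primaryid,
      ps_drug = tolower(.data$drugname),
      ps_prod_ai = tolower(.data$prod_ai),
      route = .data$route,
      indications = .data$indications
    )

  drugs_by <- drug |>
    dplyr::select(-"indications") |>
    tidyr::nest(drugs = -"primaryid")
  indil <- list(key = paste(drug$primaryid, drug$drug_seq),
                ind = drug$indications)

  out <- base |>
    dplyr::left_join(outc_by, by = "primaryid") |>
    dplyr::left_join(reac_by, by = "primaryid") |>
    dplyr::left_join(ps_first, by = "primaryid") |>
    dplyr::left_join(drugs_by, by = "primaryid")
  out$serious[is.na(out$serious)] <- FALSE
  out$outcomes <- lapply(out$outcomes, function(x) x %||% character())
  out$indications <- lapply(out$indications, function(x) x %||% character())
  out$reactions <- lapply(out$reactions, function(x) x %||% character())
  # reattach per-entry indications inside the drugs list-column on demand:
  # kept flat here for speed; filter_primary_suspect() re-joins them.
  attr(out, "drug_indications") <- indil

  n_all <- nrow(out)
  in_window <- !is.na(out$receipt_year) &
    out$receipt_year >= window[1] & out$receipt_year <= window[2]
  has_reac <- lengths(out$reactions) > 0
  audit <- list(
    input = n_all,
    dropped_out_of_window = sum(!in_window),
    dropped_no_reaction = sum(in_window & !has_reac),
    kept = sum(in_window & has_reac)
  )
  out <- out[in_window & has_reac, , drop = FALSE]
  attr(out, "clean_audit") <- audit
  out
}

#' Select reports with the target drug as primary suspect
#'
#' Keeps reports having at least one drug entry with role code `PS` whose
#' drug name *or* product active ingredient matches any pattern
#' (case-insensitive substring). The matched entry (lowest `drug_seq` among
#' matches) supplies `ps_drug`, `ps_prod_ai`, `route` and `indications`.
#'
#' @param reports Clean report tibble from [clean_reports()] (must retain the
#'   `drugs` list-column).
#' @param name_patterns Non-empty character vector of substrings to match.
#' @return Subset tibble of `reports` with suspect-drug fields set from the
#'   matching entry.
#' @export
filter_primary_suspect <- function(reports,
                                   name_patterns = c("rivaroxaban",
                                                     "xarelto")) {
  if (length(name_patterns) == 0) {
    rlang::abort("`name_patterns` must be non-empty")
  }
  if (!"drugs" %in% names(reports)) {
    rlang::abort("`reports` must carry the `drugs` list-column")
  }
  flat <- reports |>
    dplyr::select("primaryid", "drugs") |>
    tidyr::unnest("drugs")
  pat <- stringr::regex(
    paste0(vapply(name_patterns, function(p) {
      paste0("\\Q", p, "\\E")
    }, character(1)), collapse = "|"),
    ignore_case = TRUE
  )
  hit <- flat |>
    dplyr::filter(
      .data$role_cod == "PS",
      stringr::str_detect(dplyr::coalesce(.data$drugname, ""), pat) |
        stringr::str_detect(dplyr::coalesce(.data$prod_ai, ""), pat)
    ) |>
    dplyr::arrange(.data$primaryid, .data$drug_seq) |>
    dplyr::distinct(.data$primaryid, .keep_all = TRUE)

  indil <- attr(reports, "drug_indications")
  key <- paste(hit$primaryid, hit$drug_seq)
  hit_ind <- if (!is.null(indil)) {
    idx <- match(key, indil$key)
    lapply(seq_along(idx), function(i) {
      if (is.na(idx[i])) character() else indil$ind[[idx[i]]]
    })
  } else {
    rep(list(character()), nrow(hit))
  }

  out <- reports |>
    dplyr::semi_join(hit, by = "primaryid")
  m <- match(out$primaryid, hit$primaryid)
  out$ps_drug <- tolower(hit$drugname[m])
  out$ps_prod_ai <- tolower(hit$prod_ai[m])
  out$route <- hit$route[m]
  out$indications <- hit_ind[m]
  out
}
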