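#' Configuration for the synthetic report generator
#'
#' The generator emulates the structure of a FAERS extract: per-report
#' demographics with realistic missingness, one primary-suspect drug plus
#' concomitant entries, per-drug indications, one-or-more reaction PTs,
#' duplicate case versions, and receipt years spanning a study window.
#' Defaults reproduce the marginals of a large oral-anticoagulant report
#' population: year weights, sex, reporter occupation, country, route and
#' seriousness shares from published descriptive tables; age centred on a
#' median of 72 years (IQR roughly 61-80); about 2.3 drug-event combinations
#' per report. Drug and event marginals are Zipf-distributed; designated
#' `signal_pairs` multiply the event probability by `rho >= 1` (renormalised)
#' whenever the report's suspect drug is the pair's drug.
#'
#' @param n_reports Number of reports.
#' @param n_drugs,n_events Vocabulary sizes; drug 1 is the target drug and is
#'   named `target_drug`, events are `pt_001` ... mapped onto `n_socs`
#'   system organ classes by [sim_pt_soc_map()].
#' @param drug_zipf,event_zipf Zipf (power-law) exponents of the marginals.
#' @param signal_pairs Tibble with columns `drug`, `event`, `rho`
#'   (multiplier `>= 1`), or `NULL` for a global null.
#' @param events_per_report Poisson mean mu: each report draws
#'   `1 + Poisson(mu)` reaction mentions (so every report keeps at least one
#'   PT after cleaning); distinct PTs are retained.
#' @param years,year_weights Receipt years and their sampling weights.
#' @param sex_probs,reporter_probs,country_probs,route_probs Named sampling
#'   probabilities (a `missing` element yields an empty field).
#' @param age_mean,age_sd,age_missing Normal age model (years, truncated to
#'   1-105) and missingness rate.
#' @param serious_rate Probability a report is serious (gets at least one
#'   DE/LT/HO/DS/CA/RI outcome code).
#' @param outcome_probs Named probabilities of the primary serious outcome
#'   code, conditional on a serious report.
#' @param indication_probs Named indication shares for target-drug reports.
#' @param second_indication_rate Chance a target report carries a second,
#'   independently drawn indication.
#' @param concomitant_mean Poisson mean of extra non-suspect drug entries.
#' @param duplicate_case_rate Fraction of cases that gain 1-2 later versions.
#' @param n_socs Number of synthetic system organ classes.
#' @param target_drug Name given to drug 1.
#' @param seed Default seed used by [simulate_reports()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reports = 50000,
                       n_drugs = 25,
                       n_events = 120,
                       drug_zipf = 1,
                       event_zipf = 1,
                       signal_pairs = NULL,
                       events_per_report = 1.3,
                       years = 2014:2024,
                       year_weights = c(3.67, 19.06, 17.93, 13.35, 11.91,
                                        8.38, 17.29, 2.89, 2.83, 2.25, 0.43),
                       sex_probs = c(F = 0.4624, M = 0.4774,
                                     missing = 0.0602),
                       reporter_probs = c(CN = 0.5384, MD = 0.2640,
                                          PH = 0.1221, HP = 0.0624,
                                          LW = 0.0066, missing = 0.0065),
                       country_probs = c(US = 0.7438, DE = 0.0381,
                                         JP = 0.0345, FR = 0.0283,
                                         GB = 0.0235, other = 0.1318),
                       route_probs = c(Oral = 0.9869, Other = 0.0129,
                                       Transplacental = 0.0002),
                       age_mean = 72, age_sd = 14, age_missing = 0.2083,
                       serious_rate = 0.862,
                       outcome_probs = c(HO = 0.6024, DE = 0.1484,
                                         LT = 0.0434, DS = 0.0189,
                                         RI = 0.0028, CA = 0.0001),
                       indication_probs = c(
                         "Atrial fibrillation" = 0.3345,
                         "Cerebrovascular accident prophylaxis" = 0.1713,
                         "Deep vein thrombosis" = 0.1595,
                         "Pulmonary embolism" = 0.0807,
                         "Thrombosis prophylaxis" = 0.0754,
                         "Other indication" = 0.1786
                       ),
                       second_indication_rate = 0.1,
                       concomitant_mean = 0.5,
                       duplicate_case_rate = 0.05,
                       n_socs = 12,
                       target_drug = "rivaroxaban",
                       seed = 20140101) {
  stopifnot(n_reports >= 1, n_drugs >= 2, n_events >= 2,
            length(years) == length(year_weights),
            events_per_report >= 0, duplicate_case_rate >= 0,
            duplicate_case_rate < 1)
  if (!is.null(signal_pairs)) {
    signal_pairs <- tibble::as_tibble(signal_pairs)
    stopifnot(all(c("drug", "event", "rho") %in% names(signal_pairs)),
              all(signal_pairs$rho >= 1))
  }
  probs_ok <- function(p) all(p >= 0) && abs(sum(p) - 1) < 0.02
  stopifnot(probs_ok(sex_probs), probs_ok(route_probs),
            probs_ok(indication_probs))
  structure(as.list(environment()), class = "sim_config")
}

#' Drug name vocabulary of a configuration
#' @param config A `sim_config`.
#' @return Character vector, drug 1 first.
#' @export
sim_drug_names <- function(config) {
  c(config$target_drug,
    sprintf("drug_%02d", seq_len(config$n_drugs)[-1]))
}

#' Event (PT) vocabulary of a configuration
#' @param config A `sim_config`.
#' @return Character vector `pt_001` ...
#' @export
sim_event_names <- function(config) {
  sprintf("pt_%03d", seq_len(config$n_events))
}

#' Synthetic PT-to-SOC map
#'
#' Assigns the synthetic PT vocabulary round-robin onto `n_socs` system
#' organ classes, so rank-adjacent events land in different classes.
#'
#' @param config A `sim_config`.
#' @return Tibble `pt`, `soc`.
#' @export
sim_pt_soc_map <- function(config) {
  idx <- seq_len(config$n_events)
  tibble::tibble(
    pt = sim_event_names(config),
    soc = sprintf("soc_%02d", (idx - 1) %% config$n_socs + 1)
  )
}

#' Synthetic important-medical-event PT list
#'
#' A fixed subset (every third PT) of the synthetic vocabulary standing in
#' for a curated IME reference list.
#'
#' @param config A `sim_config`.
#' @return Character vector of PT names.
#' @export
sim_ime_list <- function(config) {
  ev <- sim_event_names(config)
  ev[seq_along(ev) %% 3 == 1]
}

zipf_probs <- function(k, s) {
  p <- (1 / seq_len(k))^s
  p / sum(p)
}

# per-drug event probabilities after applying rho multipliers
sim_event_probs <- function(config) {
  q <- zipf_probs(config$n_events, config$event_zipf)
  events <- sim_event_names(config)
  drugs <- sim_drug_names(config)
  out <- list(base = q)
  if (!is.null(config$signal_pairs) && nrow(config$signal_pairs) > 0) {
    for (g in unique(config$signal_pairs$drug)) {
      if (!g %in% drugs) {
        rlang::abort(paste0("signal pair drug not in vocabulary: ", g))
      }
      r <- rep(1, config$n_events)
      rows <- config$signal_pairs[config$signal_pairs$drug == g, ]
      ei <- match(rows$event, events)
      if (anyNA(ei)) {
        rlang::abort("signal pair event not in vocabulary")
      }
      r[ei] <- rows$rho
      p <- q * r
      s <- sum(p)
      if (!is.finite(s) || s <= 0) {
        rlang::abort("degenerate signal-pair renormalisation")
      }
      out[[g]] <- p / s
    }
  }
  out
}

sample_named <- function(n, probs) {
  labs <- names(probs)
  labs[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic FAERS-style report set
#'
#' Draws `n_reports` reports under the generative model of [sim_config()]
#' and materialises them as the five "$"-delimited-style raw tables (DEMO,
#' DRUG, REAC, INDI, OUTC) plus ground truth. Deterministic for a fixed
#' seed. When `duplicate_case_rate > 0`, later case versions are injected
#' via [inject_duplicates()] and the version to keep is recorded.
#'
#' @param config A `sim_config`.
#' @param seed Overrides `config$seed`.
#' @return A `faers_sim`: list with `tables` (a `faers_raw`) and `truth`
#'   (signal pairs, keep-version ids, expected cell counts, config echo).
#' @export
simulate_reports <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  set.seed(seed)
  n <- config$n_reports
  drugs <- sim_drug_names(config)
  events <- sim_event_names(config)

  caseid <- as.character(20000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")

  year <- sample(config$years, n, replace = TRUE,
                 prob = config$year_weights)
  month <- sample.int(9, n, replace = TRUE)
  day <- sample.int(27, n, replace = TRUE)
  fda_dt <- sprintf("%d%02d%02d", year, month, day)

  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                         1), 105))
  age_chr <- as.character(age)
  age_cod <- rep("YR", n)
  u <- stats::runif(n)
  mon <- u < 0.02
  dec <- u >= 0.02 & u < 0.03
  age_chr[mon] <- as.character(age[mon] * 12)
  age_cod[mon] <- "MON"
  age_chr[dec] <- as.character(age[dec] / 10)
  age_cod[dec] <- "DEC"
  miss_age <- stats::runif(n) < config$age_missing
  age_chr[miss_age] <- ""
  age_cod[miss_age] <- ""

  sex <- sample_named(n, config$sex_probs)
  sex[sex == "missing"] <- ""
  occp <- sample_named(n, config$reporter_probs)
  occp[occp == "missing"] <- ""
  country <- sample_named(n, config$country_probs)
  route <- sample_named(n, config$route_probs)

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    age = age_chr, age_cod = age_cod, sex = sex, occp_cod = occp,
    reporter_country = country
  )

  # suspect drug and reactions -------------------------------------------
  drug_idx <- sample.int(config$n_drugs, n, replace = TRUE,
                         prob = zipf_probs(config$n_drugs,
                                           config$drug_zipf))
  drug_name <- drugs[drug_idx]
  k <- 1L + stats::rpois(n, config$events_per_report)
  probs <- sim_event_probs(config)
  dist_key <- ifelse(drug_name %in% names(probs), drug_name, "base")
  rep_id <- rep(seq_len(n), k)
  key_long <- rep(dist_key, k)
  event_idx <- integer(length(rep_id))
  for (gkey in unique(key_long)) {
    sel <- key_long == gkey
    event_idx[sel] <- sample.int(config$n_events, sum(sel), replace = TRUE,
                                 prob = probs[[gkey]])
  }
  reac_long <- dplyr::distinct(
    tibble::tibble(row = rep_id, event = event_idx)
  )
  reac <- tibble::tibble(
    primaryid = primaryid[reac_long$row],
    pt = events[reac_long$event]
  )

  # drug table: PS entry + concomitants ----------------------------------
  ps_rows <- tibble::tibble(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = toupper(drug_name), prod_ai = toupper(drug_name),
    route = route
  )
  n_con <- stats::rpois(n, config$concomitant_mean)
  con_rep <- rep(seq_len(n), n_con)
  con_seq <- unlist(lapply(n_con[n_con > 0], seq_len), use.names = FALSE)
  con_rows <- tibble::tibble(
    primaryid = primaryid[con_rep],
    drug_seq = as.character(1L + con_seq),
    role_cod = sample(c("C", "SS", "I"), length(con_rep), replace = TRUE,
                      prob = c(0.7, 0.2, 0.1)),
    drugname = toupper(drugs[sample.int(config$n_drugs, length(con_rep),
                                        replace = TRUE)]),
    prod_ai = NA_character_,
    route = NA_character_
  )
  con_rows$prod_ai <- con_rows$drugname
  drug <- dplyr::arrange(dplyr::bind_rows(ps_rows, con_rows),
                         .data$primaryid, .data$drug_seq)

  # indications for the PS entry ------------------------------------------
  is_target <- drug_idx == 1L
  ind1 <- character(n)
  ind1[is_target] <- sample_named(sum(is_target), config$indication_probs)
  ind1[!is_target] <- sprintf("indication_%02d", drug_idx[!is_target])
  second <- is_target & stats::runif(n) < config$second_indication_rate
  ind2 <- character(n)
  ind2[second] <- sample_named(sum(second), config$indication_probs)
  indi <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid, indi_drug_seq = "1",
                   indi_pt = ind1),
    tibble::tibble(primaryid = primaryid[second], indi_drug_seq = "1",
                   indi_pt = ind2[second])
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$primaryid)

  # outcomes ---------------------------------------------------------------
  serious <- stats::runif(n) < config$serious_rate
  main_out <- character(n)
  main_out[serious] <- sample_named(sum(serious),
                                    config$outcome_probs /
                                      sum(config$outcome_probs))
  extra_ot <- stats::runif(n) < 0.32
  outc <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid[serious],
                   outc_cod = main_out[serious]),
    tibble::tibble(primaryid = primaryid[serious & extra_ot],
                   outc_cod = "OT"),
    tibble::tibble(primaryid = primaryid[!serious & extra_ot],
                   outc_cod = "OT")
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$primaryid)

  tables <- new_faers_raw(demo, drug, reac, indi, outc)
  keep <- tibble::tibble(caseid = caseid, keep_primaryid = primaryid)
  if (config$duplicate_case_rate > 0) {
    tables <- inject_duplicates(tables, config$duplicate_case_rate,
                                seed = seed + 1L)
    dup_truth <- attr(tables, "dup_truth")
    keep$keep_primaryid[match(dup_truth$caseid, keep$caseid)] <-
      dup_truth$keep_primaryid
  }

  structure(
    list(
      tables = tables,
      truth = list(
        seed = seed,
        signal_pairs = config$signal_pairs,
        keep = keep,
        expected = expected_tables(config),
        config = config
      )
    ),
    class = "faers_sim"
  )
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("<faers_sim>", nrow(x$truth$keep), "cases, seed", x$truth$seed, "\n")
  print(x$tables)
  invisible(x)
}

#' Inject duplicate case versions
#'
#' A fraction `rate` of caseids gains one or two additional report versions
#' with a strictly later receipt date (next calendar month, same year) and a
#' perturbed age, mimicking FAERS follow-up versions. The version that the
#' dedup rule must keep (latest date) is recorded in `attr(, "dup_truth")`.
#'
#' @param raw A `faers_raw`.
#' @param rate Fraction of cases to duplicate, in `[0, 1)`.
#' @param seed RNG seed.
#' @return The augmented `faers_raw` with `dup_truth` attribute
#'   (`caseid`, `keep_primaryid`).
#' @export
inject_duplicates <- function(raw, rate, seed = 1L) {
  stopifnot(inherits(raw, "faers_raw"), rate >= 0, rate < 1)
  if (rate == 0) {
    attr(raw, "dup_truth") <- tibble::tibble(caseid = character(),
                                             keep_primaryid = character())
    return(raw)
  }
  set.seed(seed)
  demo <- raw$demo
  pick <- stats::runif(nrow(demo)) < rate
  chosen <- demo[pick, , drop = FALSE]
  n_extra <- sample(1:2, nrow(chosen), replace = TRUE, prob = c(0.7, 0.3))

  rows <- rep(seq_len(nrow(chosen)), n_extra)
  version <- unlist(lapply(n_extra, seq_len), use.names = FALSE)
  dup_demo <- chosen[rows, , drop = FALSE]
  old_primaryid <- dup_demo$primaryid
  dup_demo$primaryid <- paste0(dup_demo$caseid, 1L + version)
  dt <- as.numeric(dup_demo$fda_dt)
  dup_demo$fda_dt <- as.character(dt + 100 * version) # +1 month per version
  age_num <- suppressWarnings(as.numeric(dup_demo$age))
  bump <- !is.na(age_num) & dup_demo$age_cod == "YR"
  dup_demo$age[bump] <- as.character(age_num[bump] + 1)

  vmap <- tibble::tibble(primaryid = old_primaryid,
                         .new_id = dup_demo$primaryid)
  copy_rows <- function(tab) {
    extra <- dplyr::inner_join(tab, vmap, by = "primaryid",
                               relationship = "many-to-many")
    if (nrow(extra) == 0) return(tab)
    extra$primaryid <- extra$.new_id
    extra$.new_id <- NULL
    dplyr::bind_rows(tab, extra)
  }

  out <- new_faers_raw(
    demo = dplyr::bind_rows(demo, dup_demo),
    drug = copy_rows(raw$drug),
    reac = copy_rows(raw$reac),
    indi = copy_rows(raw$indi),
    outc = copy_rows(raw$outc),
    audit = attr(raw, "audit") %||% list()
  )
  keep <- tibble::tibble(caseid = dup_demo$caseid,
                         keep_primaryid = dup_demo$primaryid,
                         version = version) |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$version)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select("caseid", "keep_primaryid")
  attr(out, "dup_truth") <- keep
  out
}

#' Expected contingency cells under the generative model
#'
#' Closed-form expectations of the 2x2 cells for each configured signal pair
#' (and the null ROR = 1 check when `rho = 1`). With `K = 1 + Poisson(mu)`
#' reaction draws and per-drug event probability `p`, the chance a report
#' mentions the event at least once is `1 - (1 - p) exp(-mu p)` (the +1 draw
#' times the Poisson generating function); cell expectations follow from the
#' drug marginal and the per-event presence probabilities, accounting
#' exactly for the `rho` renormalisation.
#'
#' @param config A `sim_config`.
#' @param pairs Optional tibble `drug`, `event` to evaluate (defaults to the
#'   configured signal pairs).
#' @return Tibble `drug`, `event`, `rho`, `ea`, `eb`, `ec`, `ed`,
#'   `expected_ror`.
#' @export
expected_tables <- function(config, pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pairs <- pairs %||% config$signal_pairs
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble::tibble(drug = character(), event = character(),
                          rho = numeric(), ea = numeric(), eb = numeric(),
                          ec = numeric(), ed = numeric(),
                          expected_ror = numeric()))
  }
  pairs <- tibble::as_tibble(pairs)
  drugs <- sim_drug_names(config)
  events <- sim_event_names(config)
  pi_g <- zipf_probs(config$n_drugs, config$drug_zipf)
  probs <- sim_event_probs(config)
  mu <- config$events_per_report
  n <- config$n_reports

  presence <- function(p) 1 - (1 - p) * exp(-mu * p)
  # per drug: expected combinations per report and per-event presence
  pres <- vapply(drugs, function(g) {
    p <- probs[[if (g %in% names(probs)) g else "base"]]
    presence(p)
  }, numeric(config$n_events))
  # expected distinct events per report, by drug
  m_per_report <- unname(colSums(pres))
  pi_g <- unname(pi_g)

  out <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$drug[i]
    e <- pairs$event[i]
    gi <- match(g, drugs)
    ei <- match(e, events)
    if (is.na(gi) || is.na(ei)) {
      rlang::abort("pair refers to unknown drug or event")
    }
    ea <- unname(n * pi_g[gi] * pres[ei, gi])
    eb <- unname(n * pi_g[gi] * m_per_report[gi] - ea)
    ec <- unname(sum(n * pi_g[-gi] * pres[ei, -gi]))
    ed <- unname(sum(n * pi_g[-gi] * m_per_report[-gi]) - ec)
    rho <- if ("rho" %in% names(pairs)) pairs$rho[i] else 1
    tibble::tibble(drug = g, event = e, rho = rho, ea = ea, eb = eb,
                   ec = ec, ed = ed,
                   expected_ror = (ea * ed) / (eb * ec))
  })
  dplyr::bind_rows(out)
}

#' Write a raw extract as "$"-delimited quarterly files
#'
#' Emits DEMO/DRUG/REAC/INDI/OUTC files in the same dialect
#' [read_faers_quarter()] parses (round-trip tested), plus a
#' `ground_truth.json` when given a `faers_sim`.
#'
#' @param x A `faers_raw` or `faers_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_faers_quarter <- function(x, dir) {
  sim <- NULL
  if (inherits(x, "faers_sim")) {
    sim <- x
    x <- x$tables
  }
  stopifnot(inherits(x, "faers_raw"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (tb in names(x)) {
    path <- file.path(dir, paste0(toupper(tb), ".txt"))
    readr::write_delim(x[[tb]], path, delim = "$", na = "")
    paths[tb] <- path
  }
  if (!is.null(sim)) {
    gt <- file.path(dir, "ground_truth.json")
    cfg <- sim$truth$config
    jsonlite::write_json(
      list(
        seed = sim$truth$seed,
        signal_pairs = sim$truth$signal_pairs,
        keep = sim$truth$keep,
        config = cfg[!vapply(cfg, is.function, logical(1))]
      ),
      gt, auto_unbox = TRUE, digits = NA, null = "null"
    )
    paths["ground_truth"] <- gt
  }
  invisible(paths)
}

#' File paths of a written quarter
#' @param dir Directory written by [write_faers_quarter()].
#' @return Named list suitable for [read_faers_quarter()].
#' @export
faers_quarter_paths <- function(dir) {
  list(
    demo = file.path(dir, "DEMO.txt"),
    drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"),
    indi = file.path(dir, "INDI.txt"),
    outc = file.path(dir, "OUTC.txt")
  )
}
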