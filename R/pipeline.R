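#' Build a run configuration
#'
#' Either `faers_dir` (a directory, or vector of directories, each holding
#' DEMO/DRUG/REAC/INDI/OUTC files) or `synthetic` (a [sim_config()]) must be
#' given, not both.
#'
#' @param faers_dir Directory/ies of raw quarterly files.
#' @param synthetic A `sim_config` to simulate instead of reading files.
#' @param target_patterns Substring patterns selecting the target drug.
#' @param window Study window of receipt years.
#' @param levels Analysis levels, subset of `c("pt", "soc")`.
#' @param criteria Signal thresholds, see [signal_criteria()].
#' @param yates,zero_correction Chi-square / zero-cell options.
#' @param bcpnn BCPNN hyperparameters.
#' @param mgps_starts Start list for the prior fit.
#' @param pt_to_soc SOC map tibble (or path to a 2-column CSV `pt,soc`);
#'   defaults to [sim_pt_soc_map()] for synthetic runs.
#' @param ime_list IME PT character vector (or path to a 1-column CSV).
#' @param subgroup_indications Indication PTs to rerun as subgroups.
#' @param trend_terms Terms for the IC time series (default: top SOCs or top
#'   PTs by count).
#' @param trend_mode `"per_year"` or `"cumulative"`.
#' @param deleted_caseids Optional caseids to drop at dedup.
#' @param seed Seed for synthetic sources.
#' @return A `run_config` list.
#' @export
run_config <- function(faers_dir = NULL, synthetic = NULL,
                       target_patterns = c("rivaroxaban", "xarelto"),
                       window = c(2014, 2024),
                       levels = c("pt", "soc"),
                       criteria = signal_criteria(),
                       yates = TRUE, zero_correction = TRUE,
                       bcpnn = bcpnn_hyper(),
                       mgps_starts = faersignal::mgps_starts(),
                       pt_to_soc = NULL,
                       ime_list = NULL,
                       subgroup_indications = character(),
                       trend_terms = NULL,
                       trend_mode = c("per_year", "cumulative"),
                       deleted_caseids = NULL,
                       seed = 1L) {
  if (is.null(faers_dir) == is.null(synthetic)) {
    rlang::abort("give exactly one of `faers_dir` or `synthetic`")
  }
  stopifnot(length(window) == 2, window[1] <= window[2])
  levels <- match.arg(levels, c("pt", "soc"), several.ok = TRUE)
  if (is.character(pt_to_soc) && length(pt_to_soc) == 1) {
    pt_to_soc <- readr::read_csv(pt_to_soc, show_col_types = FALSE)
  }
  if (is.character(ime_list) && length(ime_list) == 1 &&
      file.exists(ime_list)) {
    ime_list <- readr::read_csv(ime_list, show_col_types = FALSE)[[1]]
  }
  structure(
    list(
      faers_dir = faers_dir, synthetic = synthetic,
      target_patterns = target_patterns, window = window, levels = levels,
      criteria = criteria, yates = yates,
      zero_correction = zero_correction, bcpnn = bcpnn,
      mgps_starts = mgps_starts, pt_to_soc = pt_to_soc,
      ime_list = ime_list, subgroup_indications = subgroup_indications,
      trend_terms = trend_terms, trend_mode = match.arg(trend_mode),
      deleted_caseids = deleted_caseids, seed = seed
    ),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; `synthetic` may
#' be a mapping of [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    sp <- y$synthetic$signal_pairs
    if (!is.null(sp)) {
      y$synthetic$signal_pairs <- dplyr::bind_rows(lapply(sp,
                                                          tibble::as_tibble))
    }
    y$synthetic <- do.call(sim_config, y$synthetic)
  }
  if (!is.null(y$criteria)) y$criteria <- do.call(signal_criteria, y$criteria)
  if (!is.null(y$bcpnn)) y$bcpnn <- do.call(bcpnn_hyper, y$bcpnn)
  if (!is.null(y$window)) y$window <- as.numeric(y$window)
  do.call(run_config, y)
}

analysis_stage <- function(target, background, level, pt_to_soc, prior_cells,
                           config) {
  counts <- suppressMessages(
    count_combinations(target, background, level = level,
                       pt_to_soc = pt_to_soc)
  )
  tables <- contingency_tables(counts)
  prior <- fit_mgps_prior(prior_cells, starts = config$mgps_starts)
  stats <- dispro_stats(tables, prior = prior,
                        zero_correction = config$zero_correction,
                        yates = config$yates, hyper = config$bcpnn)
  decisions <- evaluate_signals(stats, criteria = config$criteria,
                                ime_list = config$ime_list)
  list(counts = counts, stats = stats, prior = prior,
       decisions = decisions, overlap = overlap_summary(decisions))
}

#' Run the full signal-detection analysis
#'
#' End-to-end orchestration: ingest (or simulate), deduplicate, clean,
#' split target vs background, and per level compute combination counts,
#' all five disproportionality statistics, signal decisions, overlap
#' summaries, descriptives, IC time trends, and per-indication subgroup
#' reruns. When `out_dir` is given every result table is written as TSV
#' (JSON for Venn counts) together with a run manifest; reruns with the
#' same config and seed are identical.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @param out_dir Optional output directory.
#' @return Invisible list with `reports` (target/background), per-level
#'   results, `descriptives`, `indications`, `trend`, `subgroups`,
#'   `manifest`.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$synthetic)) {
    sim <- simulate_reports(config$synthetic, seed = config$seed)
    raw <- sim$tables
    if (is.null(config$pt_to_soc)) {
      config$pt_to_soc <- sim_pt_soc_map(config$synthetic)
    }
    if (is.null(config$ime_list)) {
      config$ime_list <- sim_ime_list(config$synthetic)
    }
  } else {
    dirs <- config$faers_dir
    missing <- dirs[!dir.exists(dirs)]
    if (length(missing) > 0) {
      rlang::abort(paste0("input directory not found: ",
                          paste(missing, collapse = ", ")))
    }
    quarters <- lapply(dirs, function(d) {
      read_faers_quarter(faers_quarter_paths(d))
    })
    raw <- bind_faers_quarters(quarters)
  }

  raw <- deduplicate_cases(raw, deleted_caseids = config$deleted_caseids)
  reports <- clean_reports(raw, window = config$window)
  target <- filter_primary_suspect(reports, config$target_patterns)
  background <- dplyr::anti_join(reports, target, by = "primaryid")

  prior_cells_pt <- drug_event_cells(reports, level = "pt")

  results <- list()
  for (lv in config$levels) {
    cells <- if (lv == "pt") {
      prior_cells_pt
    } else {
      drug_event_cells(reports, level = "soc",
                       pt_to_soc = config$pt_to_soc)
    }
    results[[lv]] <- analysis_stage(target, background, lv,
                                    config$pt_to_soc, cells, config)
  }

  descriptives <- demographic_summary(target)
  indications <- indication_ranking(target)
  soc_props <- if (!is.null(config$pt_to_soc)) {
    soc_report_proportions(target, config$pt_to_soc)
  } else {
    NULL
  }

  trend_terms <- config$trend_terms
  if (is.null(trend_terms)) {
    lv0 <- if ("soc" %in% config$levels) "soc" else "pt"
    trend_terms <- results[[lv0]]$stats |>
      dplyr::arrange(dplyr::desc(.data$a)) |>
      dplyr::slice_head(n = 3) |>
      dplyr::pull("term")
    trend_level <- lv0
  } else {
    trend_level <- if ("soc" %in% config$levels &&
                         all(trend_terms %in%
                               unique(config$pt_to_soc$soc))) "soc" else "pt"
  }
  trend <- dplyr::bind_rows(lapply(trend_terms, function(tm) {
    tr <- ic_time_series(target, background, tm, level = trend_level,
                         mode = config$trend_mode,
                         pt_to_soc = config$pt_to_soc,
                         hyper = config$bcpnn)
    dplyr::mutate(tibble::as_tibble(tr), term = tm, .before = 1)
  }))

  subgroups <- list()
  for (ind in config$subgroup_indications) {
    sub_all <- stratify_reports(reports, by = "indication_pt",
                                indications = ind)[[1]]
    sub_target <- stratify_reports(target, by = "indication_pt",
                                   indications = ind)[[1]]
    sub_bg <- dplyr::anti_join(sub_all, sub_target, by = "primaryid")
    if (nrow(sub_target) == 0) next
    cells <- drug_event_cells(sub_all, level = "pt")
    if (nrow(cells) < 50) cells <- prior_cells_pt
    subgroups[[ind]] <- analysis_stage(sub_target, sub_bg, "pt",
                                       config$pt_to_soc, cells, config)
  }

  manifest <- list(
    package = as.character(utils::packageVersion("faersignal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    window = config$window,
    levels = config$levels,
    target_patterns = config$target_patterns,
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("mgps_starts"))]),
    dedup = dedup_audit(raw),
    clean = attr(reports, "clean_audit"),
    n_target = nrow(target),
    n_background = nrow(background)
  )

  out <- list(
    target = target, background = background, results = results,
    descriptives = descriptives, indications = indications,
    soc_proportions = soc_props, trend = trend, subgroups = subgroups,
    manifest = manifest, config = config
  )

  if (!is.null(out_dir)) write_analysis_outputs(out, out_dir)
  invisible(out)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, paste, character(1), collapse = ";")
  )), path)
}

write_analysis_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lv in names(out$results)) {
    res <- out$results[[lv]]
    write_tsv_quiet(res$stats, file.path(out_dir,
                                         paste0("statistics_", lv, ".tsv")))
    write_tsv_quiet(res$decisions,
                    file.path(out_dir, paste0("decisions_", lv, ".tsv")))
    plot_tabs <- export_plot_tables(res$stats, res$decisions,
                                    pt_to_soc = out$config$pt_to_soc)
    write_tsv_quiet(plot_tabs$volcano,
                    file.path(out_dir, paste0("volcano_", lv, ".tsv")))
    write_tsv_quiet(plot_tabs$upset,
                    file.path(out_dir, paste0("upset_", lv, ".tsv")))
    if (!is.null(plot_tabs$heatmap)) {
      write_tsv_quiet(plot_tabs$heatmap,
                      file.path(out_dir, paste0("heatmap_", lv, ".tsv")))
    }
    jsonlite::write_json(as.list(res$overlap$venn),
                         file.path(out_dir, paste0("venn_", lv, ".json")),
                         auto_unbox = TRUE)
  }
  write_tsv_quiet(out$descriptives, file.path(out_dir, "descriptives.tsv"))
  write_tsv_quiet(out$indications, file.path(out_dir, "indications.tsv"))
  if (!is.null(out$soc_proportions)) {
    write_tsv_quiet(out$soc_proportions,
                    file.path(out_dir, "soc_proportions.tsv"))
  }
  write_tsv_quiet(out$trend, file.path(out_dir, "trend.tsv"))
  for (ind in names(out$subgroups)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", tolower(ind))
    write_tsv_quiet(out$subgroups[[ind]]$decisions,
                    file.path(out_dir,
                              paste0("decisions_subgroup_", safe, ".tsv")))
    write_tsv_quiet(out$subgroups[[ind]]$stats,
                    file.path(out_dir,
                              paste0("statistics_subgroup_", safe, ".tsv")))
  }
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' Plot-ready tables for volcano, heatmap, UpSet and Venn displays
#'
#' The figures of a disproportionality study are visual summaries of these
#' exact tables. Volcano: per term, `log2` of each statistic variant against
#' `-ln(p)` from the chi-square test (p floored at the smallest positive
#' double before the log; `ic025`, already a log2-scale quantity, is also
#' carried raw). Heatmap: positive-PT counts per (SOC, algorithm). UpSet: the
#' binary membership matrix. Venn: per-pattern counts.
#'
#' @param stats Tibble from [dispro_stats()].
#' @param decisions Tibble from [evaluate_signals()].
#' @param pt_to_soc Optional SOC map for the heatmap (PT-level decisions).
#' @return List with `volcano`, `heatmap` (or NULL), `upset`, `venn`.
#' @export
export_plot_tables <- function(stats, decisions, pt_to_soc = NULL) {
  p_floor <- pmax(stats$p_chi2, .Machine$double.xmin)
  volcano <- tibble::tibble(
    term = stats$term,
    a = stats$a,
    log2_ror = log2(stats$ror),
    log2_prr = log2(stats$prr),
    ic025 = stats$ic025,
    log2_ic025 = ifelse(stats$ic025 > 0,
                        log2(pmax(stats$ic025, 1e-300)), NA_real_),
    log2_eb05 = log2(stats$eb05),
    neg_ln_p = -log(p_floor)
  )
  heatmap <- NULL
  if (!is.null(pt_to_soc)) {
    heatmap <- decisions |>
      dplyr::left_join(pt_to_soc, by = c(term = "pt")) |>
      dplyr::mutate(soc = dplyr::coalesce(.data$soc, "unmapped")) |>
      tidyr::pivot_longer(dplyr::all_of(paste0("positive_",
                                               signal_algorithms)),
                          names_to = "algorithm", values_to = "positive",
                          names_prefix = "positive_") |>
      dplyr::summarise(n_positive_pts = sum(.data$positive),
                       .by = c("soc", "algorithm"))
  }
  upset <- decisions |>
    dplyr::select("term", dplyr::all_of(paste0("positive_",
                                               signal_algorithms)),
                  "ime") |>
    dplyr::filter(dplyr::if_any(dplyr::starts_with("positive_")))
  venn <- overlap_summary(decisions)$venn
  list(volcano = volcano, heatmap = heatmap, upset = upset, venn = venn)
}
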