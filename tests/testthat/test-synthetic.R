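test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_reports = 500, n_drugs = 6, n_events = 20, seed = 101)
  s1 <- simulate_reports(cfg)
  s2 <- simulate_reports(cfg)
  for (tb in names(s1$tables)) {
    expect_identical(s1$tables[[tb]], s2$tables[[tb]])
  }
  expect_identical(s1$truth$keep, s2$truth$keep)
})

test_that("null-model counts fall in the binomial band and ROR is near 1", {
  cfg <- sim_config(n_reports = 50000, duplicate_case_rate = 0, seed = 102)
  sim <- simulate_reports(cfg)
  rep <- clean_reports(sim$tables)
  tg <- filter_primary_suspect(rep, "rivaroxaban")
  bg <- dplyr::anti_join(rep, tg, by = "primaryid")
  # the largest drug x most common event: observed a within 3 sd of expected
  exp_tab <- expected_tables(cfg, pairs = tibble::tibble(
    drug = "rivaroxaban", event = "pt_001"
  ))
  tab <- contingency_tables(count_combinations(tg, bg), terms = "pt_001")
  expect_lt(abs(tab$a - exp_tab$ea), 3 * sqrt(exp_tab$ea))
  expect_equal(exp_tab$expected_ror, 1, tolerance = 1e-9)
  st <- compute_ror(tab)
  expect_lt(abs(log(st$ror)), 3 * sqrt(1 / tab$a + 1 / tab$c))
})

test_that("an injected rho = 5 pair yields the expected enrichment", {
  cfg <- sim_config(
    n_reports = 20000,
    signal_pairs = tibble::tibble(drug = "rivaroxaban", event = "pt_010",
                                  rho = 5),
    duplicate_case_rate = 0, seed = 103
  )
  sim <- simulate_reports(cfg)
  rep <- clean_reports(sim$tables)
  tg <- filter_primary_suspect(rep, "rivaroxaban")
  bg <- dplyr::anti_join(rep, tg, by = "primaryid")
  tab <- contingency_tables(count_combinations(tg, bg), terms = "pt_010")
  st <- compute_ror(tab)
  expect_true(st$ror >= 3 && st$ror <= 8)
  # and the closed-form expectation predicted it
  et <- expected_tables(cfg)
  expect_equal(st$ror, et$expected_ror, tolerance = 0.25)
})

test_that("expected cells are exact on a toy configuration", {
  cfg <- sim_config(n_reports = 1000, n_drugs = 2, n_events = 2,
                    drug_zipf = 0, event_zipf = 0,
                    events_per_report = 0.5,
                    signal_pairs = tibble::tibble(drug = "rivaroxaban",
                                                  event = "pt_002",
                                                  rho = 3),
                    duplicate_case_rate = 0, seed = 104)
  et <- expected_tables(cfg)
  # hand arithmetic: uniform marginals, rho = 3 on event 2 for drug 1
  # drug 1: p = (0.25, 0.75); drug 2: p = (0.5, 0.5); mu = 0.5
  pres <- function(p) 1 - (1 - p) * exp(-0.5 * p)
  ea <- 500 * pres(0.75)
  eb <- 500 * (pres(0.25) + pres(0.75)) - ea
  ec <- 500 * pres(0.5)
  ed <- 500 * (pres(0.5) + pres(0.5)) - ec
  expect_equal(et$ea, ea, tolerance = 1e-12)
  expect_equal(et$eb, eb, tolerance = 1e-12)
  expect_equal(et$ec, ec, tolerance = 1e-12)
  expect_equal(et$ed, ed, tolerance = 1e-12)

  # Monte-Carlo mean of the a cell over replicates within 3 MC SE
  as <- vapply(1:200, function(i) {
    s <- simulate_reports(cfg, seed = 10000 + i)
    rep <- clean_reports(s$tables)
    tg <- filter_primary_suspect(rep, "rivaroxaban")
    bg <- dplyr::anti_join(rep, tg, by = "primaryid")
    contingency_tables(count_combinations(tg, bg), terms = "pt_002")$a
  }, numeric(1))
  mc_se <- stats::sd(as) / sqrt(length(as))
  expect_lt(abs(mean(as) - ea), 3 * mc_se)
})

test_that("duplicate injection is controlled and reversible", {
  cfg <- sim_config(n_reports = 1000, n_drugs = 5, n_events = 15,
                    duplicate_case_rate = 0, seed = 105)
  sim <- simulate_reports(cfg)

  # rate 0 leaves the input untouched
  un <- inject_duplicates(sim$tables, 0)
  expect_identical(un$demo, sim$tables$demo)

  dup <- inject_duplicates(sim$tables, 0.1, seed = 106)
  truth <- attr(dup, "dup_truth")
  # ~100 duplicated caseids, binomial 3 sigma band
  expect_lt(abs(nrow(truth) - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_gt(nrow(dup$demo), 1000)

  # dedup recovers exactly the recorded keep-set
  ded <- deduplicate_cases(dup)
  expected_keep <- sim$tables$demo$primaryid
  expected_keep[match(truth$caseid,
                      sim$tables$demo$caseid)] <- truth$keep_primaryid
  expect_setequal(ded$demo$primaryid, expected_keep)
  # and duplicate versions carry later dates, so reactions are preserved
  expect_setequal(
    paste(ded$demo$caseid),
    paste(sim$tables$demo$caseid)
  )
})

test_that("written quarters round-trip through the reader", {
  cfg <- sim_config(n_reports = 300, n_drugs = 5, n_events = 15,
                    duplicate_case_rate = 0.08, seed = 107)
  sim <- simulate_reports(cfg)
  d <- tempfile()
  paths <- write_faers_quarter(sim, d)
  expect_true(file.exists(paths[["ground_truth"]]))
  raw <- read_faers_quarter(faers_quarter_paths(d))
  for (tb in c("demo", "drug", "reac", "indi", "outc")) {
    expect_equal(nrow(raw[[tb]]), nrow(sim$tables[[tb]]))
  }
  # cleaned content identical whether from memory or from disk
  mem <- clean_reports(deduplicate_cases(sim$tables))
  dsk <- clean_reports(deduplicate_cases(raw))
  expect_equal(dplyr::arrange(mem, primaryid)$reactions,
               dplyr::arrange(dsk, primaryid)$reactions)
  expect_equal(dplyr::arrange(mem, primaryid)$age_years,
               dplyr::arrange(dsk, primaryid)$age_years)
})

test_that("configuration validation catches degenerate setups", {
  expect_error(sim_config(n_reports = 0))
  expect_error(sim_config(duplicate_case_rate = 1))
  expect_error(sim_config(signal_pairs = tibble::tibble(
    drug = "rivaroxaban", event = "pt_001", rho = 0.5
  )))
  cfg <- sim_config(n_reports = 10, signal_pairs = tibble::tibble(
    drug = "no_such_drug", event = "pt_001", rho = 2
  ))
  expect_error(simulate_reports(cfg), "vocabulary")
})
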