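test_that("a hand-authored quarter joins into the expected cases", {
  paths <- write_fixture_quarter()
  raw <- suppressMessages(read_faers_quarter(paths))
  expect_s3_class(raw, "faers_raw")
  expect_equal(nrow(raw$demo), 3)
  # per-case distinct reaction counts: Epistaxis is listed twice for 100011
  rep <- clean_reports(raw, window = c(2014, 2024))
  expect_equal(nrow(rep), 3)
  counts <- sort(lengths(rep$reactions[match(
    c("100011", "100021", "100031"), rep$primaryid
  )]), decreasing = TRUE)
  expect_equal(unname(counts), c(2, 2, 2))
  # age unit conversion happened during cleaning
  expect_equal(rep$age_years[rep$primaryid == "100021"], 1.5)
  # seriousness from outcome codes: OT alone is not serious
  expect_true(rep$serious[rep$primaryid == "100011"])
  expect_false(rep$serious[rep$primaryid == "100031"])
})

test_that("reports without reactions are dropped with an audit trail", {
  paths <- write_fixture_quarter()
  # add a DEMO row with no REAC rows
  cat("100041$10004$20180101$60$YR$F$MD$US\n",
      file = paths$demo, append = TRUE)
  raw <- suppressMessages(read_faers_quarter(paths))
  rep <- clean_reports(raw)
  expect_equal(nrow(rep), 3)
  expect_false("100041" %in% rep$primaryid)
  expect_equal(attr(rep, "clean_audit")$dropped_no_reaction, 1)
})

test_that("format errors name the offending column; empty files warn", {
  d <- tempfile(); dir.create(d)
  writeLines(c("caseid$fda_dt", "1$20150101"), file.path(d, "DEMO.txt"))
  paths <- write_fixture_quarter()
  paths$demo <- file.path(d, "DEMO.txt")
  expect_error(read_faers_quarter(paths), "primaryid")

  writeLines(character(), file.path(d, "OUTC.txt"))
  paths <- write_fixture_quarter()
  paths$outc <- file.path(d, "OUTC.txt")
  expect_warning(read_faers_quarter(paths), "empty")
})

test_that("deduplication keeps the latest version with max-primaryid ties", {
  raw <- new_raw_for_dedup <- local({
    demo <- tibble::tibble(
      primaryid = c("90011", "90012", "90021", "90022", "90031"),
      caseid = c("9001", "9001", "9002", "9002", "9003"),
      fda_dt = c("20150101", "20160101", "20170301", "20170301", "20140101")
    )
    faersignal:::new_faers_raw(
      demo,
      tibble::tibble(primaryid = character(), drug_seq = character(),
                     role_cod = character(), drugname = character()),
      tibble::tibble(primaryid = character(), pt = character()),
      tibble::tibble(primaryid = character(), indi_drug_seq = character(),
                     indi_pt = character()),
      tibble::tibble(primaryid = character(), outc_cod = character())
    )
  })
  out <- deduplicate_cases(raw)
  expect_setequal(out$demo$primaryid, c("90012", "90022", "90031"))
  audit <- dedup_audit(out)
  expect_equal(audit$input, 5)
  expect_equal(audit$kept, 3)
  expect_equal(audit$kept + audit$dropped_duplicate + audit$dropped_deleted,
               audit$input)

  # deleted caseids removed entirely
  out2 <- deduplicate_cases(raw, deleted_caseids = "9003")
  expect_false("90031" %in% out2$demo$primaryid)
  expect_equal(dedup_audit(out2)$dropped_deleted, 1)
  expect_equal(dedup_audit(out2)$kept, 2)

  # idempotence
  twice <- deduplicate_cases(out)
  expect_equal(twice$demo, out$demo)
})

test_that("age normalisation converts units and rejects the implausible", {
  expect_equal(normalize_age(72, "YR"), 72)
  expect_equal(normalize_age(18, "MON"), 1.5)
  expect_equal(normalize_age(2, "DEC"), 20)
  expect_equal(normalize_age(730.5, "DY"), 2)
  expect_warning(out <- normalize_age(5, "LIGHTYEARS"), "unknown")
  expect_true(is.na(out))
  expect_warning(out <- normalize_age(200, "YR"), "130")
  expect_true(is.na(out))
  expect_warning(out <- normalize_age(-3, "YR"))
  expect_true(is.na(out))
})

test_that("primary-suspect filtering is PS-role, both-field, case-insensitive substring", {
  paths <- write_fixture_quarter()
  rep <- clean_reports(suppressMessages(read_faers_quarter(paths)))
  tg <- filter_primary_suspect(rep, c("rivaroxaban", "xarelto"))
  # 100011: XARELTO as PS (brand name match); 100031: Rivaroxaban PS;
  # 100021 has rivaroxaban only as SS -> excluded
  expect_setequal(tg$primaryid, c("100011", "100031"))
  expect_true(all(!is.na(tg$ps_drug)))
  # output is a subset of input
  expect_true(all(tg$primaryid %in% rep$primaryid))
  # indications attach from the matched PS entry
  expect_setequal(tg$indications[[which(tg$primaryid == "100011")]],
                  c("Atrial fibrillation", "Thrombosis"))
  expect_error(filter_primary_suspect(rep, character()), "non-empty")
})

test_that("a larger mixed fixture keeps exactly the PS matches", {
  set.seed(11)
  sim <- simulate_reports(sim_config(
    n_reports = 200, n_drugs = 5, n_events = 12,
    duplicate_case_rate = 0, seed = 11
  ))
  rep <- clean_reports(sim$tables)
  tg <- filter_primary_suspect(rep, "rivaroxaban")
  # ground truth: PS entries written by the generator
  truth <- sim$tables$drug
  truth <- truth[truth$role_cod == "PS" &
                   grepl("rivaroxaban", truth$drugname,
                         ignore.case = TRUE), ]
  expect_setequal(tg$primaryid, intersect(truth$primaryid, rep$primaryid))
})
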