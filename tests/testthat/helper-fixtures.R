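# Hand-built clean-report tibbles and raw fixtures used across tests.

make_reports <- function(primaryid, reactions, receipt_year = 2015,
                         indications = list(character()),
                         age_years = NA_real_, sex = NA_character_,
                         serious = TRUE) {
  n <- length(primaryid)
  tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = as.character(primaryid),
    receipt_year = as.integer(rep_len(receipt_year, n)),
    age_years = rep_len(age_years, n),
    sex = rep_len(sex, n),
    reporter = NA_character_,
    country = NA_character_,
    serious = rep_len(serious, n),
    outcomes = rep_len(list(character()), n),
    route = "oral",
    ps_drug = "target",
    ps_prod_ai = "target",
    indications = rep_len(indications, n),
    reactions = reactions
  )
}

# random clean report sets for property tests
random_reports <- function(n, n_terms = 8, years = 2014:2018,
                           prefix = "r") {
  terms <- sprintf("pt_%02d", seq_len(n_terms))
  reactions <- lapply(seq_len(n), function(i) {
    sample(terms, 1 + stats::rpois(1, 1.2), replace = TRUE)
  })
  make_reports(paste0(prefix, seq_len(n)), reactions,
               receipt_year = years[sample.int(length(years), n,
                                               replace = TRUE)])
}

# random valid 2x2 tables with decent margins
random_tables <- function(n, max_cell = 2000, min_cell = 1) {
  tibble::tibble(
    term = sprintf("t%03d", seq_len(n)),
    a = sample(min_cell:50, n, replace = TRUE),
    b = sample(min_cell:max_cell, n, replace = TRUE),
    c = sample(min_cell:max_cell, n, replace = TRUE),
    d = sample(min_cell:(10 * max_cell), n, replace = TRUE)
  )
}

# write a tiny hand-authored quarter to disk; returns paths
write_fixture_quarter <- function(dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(name, lines) {
    path <- file.path(dir, name)
    writeLines(lines, path)
    path
  }
  list(
    demo = w("DEMO.txt", c(
      "primaryid$caseid$fda_dt$age$age_cod$sex$occp_cod$reporter_country",
      "100011$10001$20150301$72$YR$F$MD$US",
      "100021$10002$20160712$18$MON$M$CN$DE",
      "100031$10003$20170115$$$$$"
    )),
    drug = w("DRUG.txt", c(
      "primaryid$drug_seq$role_cod$drugname$prod_ai$route",
      "100011$1$PS$XARELTO$RIVAROXABAN$Oral",
      "100011$2$C$ASPIRIN$ASPIRIN$Oral",
      "100021$1$PS$WARFARIN$WARFARIN$Oral",
      "100021$2$SS$RIVAROXABAN$RIVAROXABAN$Oral",
      "100031$1$PS$Rivaroxaban$RIVAROXABAN$Oral"
    )),
    reac = w("REAC.txt", c(
      "primaryid$pt",
      "100011$Epistaxis",
      "100011$Gastrointestinal haemorrhage",
      "100011$Epistaxis",
      "100021$Fall",
      "100021$Anaemia",
      "100031$Haematuria",
      "100031$Rectal haemorrhage"
    )),
    indi = w("INDI.txt", c(
      "primaryid$indi_drug_seq$indi_pt",
      "100011$1$Atrial fibrillation",
      "100011$1$Thrombosis",
      "100021$1$Deep vein thrombosis",
      "100031$1$Atrial fibrillation"
    )),
    outc = w("OUTC.txt", c(
      "primaryid$outc_cod",
      "100011$HO",
      "100011$OT",
      "100021$DE",
      "100031$OT"
    ))
  )
}
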