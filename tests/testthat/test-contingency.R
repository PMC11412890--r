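test_that("combination counting uses distinct (report, term) pairs", {
  target <- make_reports(c("t1", "t2"), list(c("X", "Y"), "X"))
  background <- make_reports("b1", list("Y"))
  cc <- count_combinations(target, background)
  expect_equal(cc$n_target[cc$term == "X"], 2)
  expect_equal(cc$n_target[cc$term == "Y"], 1)
  expect_equal(attr(cc, "m_target"), 3)
  expect_equal(attr(cc, "m_other"), 1)

  # a PT listed twice in one report contributes once
  target2 <- make_reports("t1", list(c("X", "X")))
  cc2 <- count_combinations(target2, background)
  expect_equal(cc2$n_target[cc2$term == "X"], 1)
})

test_that("counts match brute-force enumeration on a 1000-report fixture", {
  set.seed(301)
  target <- random_reports(300, n_terms = 5, prefix = "t")
  background <- random_reports(700, n_terms = 5, prefix = "b")
  cc <- count_combinations(target, background)
  oracle <- brute_combination_counts(target, background)
  expect_equal(attr(cc, "m_target"), oracle$m_target)
  expect_equal(attr(cc, "m_other"), oracle$m_other)
  expect_equal(cc$n_target[match(oracle$terms, cc$term)],
               unname(oracle$n_target))
  expect_equal(cc$n_other[match(oracle$terms, cc$term)],
               unname(oracle$n_other))

  # SOC level with an unmapped PT
  map <- tibble::tibble(pt = sprintf("pt_%02d", 1:4),
                        soc = c("s1", "s1", "s2", "s2"))
  cc_soc <- suppressMessages(
    count_combinations(target, background, level = "soc", pt_to_soc = map)
  )
  oracle_soc <- brute_combination_counts(target, background, level = "soc",
                                         pt_to_soc = map)
  expect_equal(cc_soc$n_target[match(oracle_soc$terms, cc_soc$term)],
               unname(oracle_soc$n_target))
  expect_true("unmapped" %in% cc_soc$term)
})

test_that("2x2 construction is the Table-1 arithmetic", {
  target <- make_reports(paste0("t", 1:6),
                         c(rep(list("X"), 4), rep(list(c("Y", "Z")), 3))[1:6])
  background <- make_reports(paste0("b", 1:8),
                             c(rep(list("X"), 3), rep(list("Y"), 5)))
  cc <- count_combinations(target, background)
  tab <- make_contingency(cc, "X")
  m_t <- attr(cc, "m_target"); m_o <- attr(cc, "m_other")
  expect_equal(tab$a, 4)
  expect_equal(tab$b, m_t - 4)
  expect_equal(tab$c, 3)
  expect_equal(tab$d, m_o - 3)
  expect_equal(tab$n, m_t + m_o)
  expect_equal(tab$a + tab$b + tab$c + tab$d, tab$n)

  # a term never seen for the target drug gets a = 0, b = M_target
  tabz <- make_contingency(cc, "Y")
  expect_true(tabz$a > 0)
  only_bg <- contingency_tables(cc, terms = "X")
  expect_equal(only_bg$a + only_bg$b, m_t)

  all_tabs <- contingency_tables(cc)
  expect_true(all(all_tabs$b >= 0 & all_tabs$d >= 0))
  expect_true(all(all_tabs$a + all_tabs$b + all_tabs$c + all_tabs$d ==
                    all_tabs$n))
})

test_that("corrupted counts raise an internal-consistency error", {
  target <- make_reports("t1", list("X"))
  background <- make_reports("b1", list("X"))
  cc <- count_combinations(target, background)
  attr(cc, "m_target") <- 0 # corrupt: n_target(X)=1 > m_target
  expect_error(contingency_tables(cc), "negative")
})

test_that("target and background must be disjoint", {
  r <- make_reports("same", list("X"))
  expect_error(count_combinations(r, r), "disjoint")
})

test_that("stratification partitions as documented", {
  rep <- make_reports(paste0("r", 1:6), rep(list("X"), 6),
                      receipt_year = c(2014, 2014, 2015, 2016, 2016, 2016))
  parts <- stratify_reports(rep, by = "receipt_year")
  expect_equal(unname(vapply(parts, nrow, integer(1))), c(2, 1, 3))

  # overlapping indication subsets
  rep2 <- make_reports(
    c("r1", "r2"), list("X", "Y"),
    indications = list(c("Atrial fibrillation", "Thrombosis"))
  )
  parts2 <- stratify_reports(rep2, by = "indication_pt",
                             indications = c("Atrial fibrillation",
                                             "Thrombosis"))
  expect_equal(nrow(parts2[["Atrial fibrillation"]]), 2)
  expect_equal(nrow(parts2[["Thrombosis"]]), 2)

  # missing-year reports land in the audit, not a stratum
  rep3 <- rep
  rep3$receipt_year[1] <- NA
  parts3 <- stratify_reports(rep3, by = "receipt_year")
  expect_equal(attr(parts3, "n_missing"), 1)
  expect_equal(sum(vapply(parts3, nrow, integer(1))), 5)

  expect_error(stratify_reports(rep, by = "favourite_colour"))
})

test_that("yearly stratum tables sum to the pooled table", {
  set.seed(77)
  target <- random_reports(120, prefix = "t")
  background <- random_reports(300, prefix = "b")
  pooled <- contingency_tables(count_combinations(target, background))
  years <- sort(unique(c(target$receipt_year, background$receipt_year)))
  parts <- lapply(years, function(y) {
    tt <- target[target$receipt_year == y, ]
    bb <- background[background$receipt_year == y, ]
    contingency_tables(count_combinations(tt, bb),
                       terms = sort(pooled$term))
  })
  summed <- Reduce(function(x, y) {
    dplyr::mutate(x, a = a + y$a, b = b + y$b, c = c + y$c, d = d + y$d)
  }, parts)
  pooled <- dplyr::arrange(pooled, term)
  expect_equal(summed$a, pooled$a)
  expect_equal(summed$b, pooled$b)
  expect_equal(summed$c, pooled$c)
  expect_equal(summed$d, pooled$d)
})
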