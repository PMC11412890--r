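tbl1 <- function(a, b, c, d) tibble::tibble(term = "x", a = a, b = b,
                                            c = c, d = d)

test_that("ROR point estimate and Wald interval match closed forms", {
  sym <- compute_ror(tbl1(10, 10, 10, 10))
  expect_equal(sym$ror, 1)
  expect_lt(sym$ror_lo, 1); expect_gt(sym$ror_hi, 1)

  r <- compute_ror(tbl1(10, 90, 100, 9900))
  expect_equal(r$ror, 11)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(se^2, 0.121212, tolerance = 1e-5)
  expect_equal(r$ror_lo, 11 * exp(-1.96 * se))
  expect_equal(r$ror_lo, 5.56, tolerance = 1e-3)
  expect_equal(r$ror_hi, 21.77, tolerance = 1e-3)
  expect_false(r$ror_corrected)

  # Haldane correction on a zero cell
  h <- compute_ror(tbl1(0, 10, 10, 10))
  expect_true(h$ror_corrected)
  expect_equal(h$ror, (0.5 * 10.5) / (10.5 * 10.5))
  # correction off: undefined-flagged, not an error
  u <- compute_ror(tbl1(0, 10, 10, 10), zero_correction = FALSE)
  expect_true(u$ror_undefined)
  expect_true(is.na(u$ror))
  z <- compute_ror(tbl1(0, 0, 0, 0))
  expect_true(z$ror_undefined)
})

test_that("PRR matches its closed form and sits below the ROR when > 1", {
  expect_equal(compute_prr(tbl1(10, 10, 10, 10))$prr, 1)
  expect_equal(compute_prr(tbl1(10, 90, 100, 9900))$prr, 10)
  expect_true(compute_prr(tbl1(5, 5, 0, 10),
                          zero_correction = FALSE)$prr_undefined)

  set.seed(42)
  tabs <- random_tables(200)
  st <- compute_prr(compute_ror(tabs))
  gt1 <- st$ror > 1
  expect_true(all(st$ror[gt1] > st$prr[gt1]))
  expect_true(all(st$ror[!gt1] <= st$prr[!gt1]))
  # equality exactly at independence
  ind <- compute_prr(compute_ror(tbl1(20, 40, 30, 60)))
  expect_equal(ind$ror, 1); expect_equal(ind$prr, 1)
})

test_that("confidence bounds are geometrically symmetric about the estimate", {
  set.seed(43)
  st <- compute_prr(compute_ror(random_tables(200)))
  expect_equal(st$ror_lo * st$ror_hi, st$ror^2, tolerance = 1e-9)
  expect_equal(st$prr_lo * st$prr_hi, st$prr^2, tolerance = 1e-9)
})

test_that("MHRA chi-square matches hand evaluation with and without Yates", {
  ind <- compute_chi2(tbl1(10, 10, 10, 10), yates = FALSE)
  expect_equal(ind$chi2, 0)
  expect_equal(ind$p_chi2, 1)
  expect_equal(compute_chi2(tbl1(10, 90, 100, 9900), yates = FALSE)$chi2,
               74.45, tolerance = 1e-3)
  expect_equal(compute_chi2(tbl1(10, 90, 100, 9900), yates = TRUE)$chi2,
               66.33, tolerance = 1e-3)
  # agreement with stats::chisq.test as an independent check
  m <- matrix(c(10, 90, 100, 9900), nrow = 2, byrow = TRUE)
  expect_equal(
    compute_chi2(tbl1(10, 90, 100, 9900), yates = TRUE)$chi2,
    unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic)
  )
  # zero margin is undefined, and the inner term is floored at zero
  expect_true(compute_chi2(tbl1(0, 0, 5, 5),
                           zero_correction = FALSE)$chi2_undefined)
  tiny <- compute_chi2(tbl1(1, 1, 1, 1), yates = TRUE)
  expect_equal(tiny$chi2, 0)
})

test_that("BCPNN closed-form moments behave as specified", {
  # prior centring: the all-zero table has IC exactly 0
  z <- compute_bcpnn(tbl1(0, 0, 0, 0))
  expect_identical(z$ic, 0)
  expect_true(z$ic025 < 0 && z$ic975 > 0)

  # large-sample limit: observed/expected = 10 -> IC ~ log2(10)
  big <- compute_bcpnn(tbl1(100, 900, 900, 98100))
  expect_equal(big$ic, log2(10), tolerance = 0.05)

  # screening bound is E(IC) - 2 SD; printed interval is +-1.96 SD
  expect_equal(big$ic025, big$ic - 2 * big$ic_sd)
  expect_equal(big$ic_lo, big$ic - 1.96 * big$ic_sd)
  expect_true(big$ic025 < big$ic && big$ic < big$ic975)
})

test_that("BCPNN moments agree with a posterior-sampling oracle", {
  set.seed(99)
  tabs <- random_tables(10)
  st <- compute_bcpnn(tabs)
  for (i in seq_len(nrow(tabs))) {
    mc <- bcpnn_mc_oracle(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_lt(abs(st$ic[i] - mc$mean), 3 * mc$se + 1e-4)
  }
})

test_that("statistics depend only on the target term's cells", {
  # relabelling background terms (which reshuffles how c+d splits across
  # other terms) must leave every statistic for the target term unchanged
  set.seed(7)
  target <- random_reports(80, n_terms = 6, prefix = "t")
  background <- random_reports(200, n_terms = 6, prefix = "b")
  relabel <- background
  relabel$reactions <- lapply(relabel$reactions, function(x) {
    ifelse(x == "pt_01", "pt_01", paste0("zz_", x))
  })
  t1 <- contingency_tables(count_combinations(target, background),
                           terms = "pt_01")
  t2 <- contingency_tables(count_combinations(target, relabel),
                           terms = "pt_01")
  s1 <- compute_bcpnn(compute_chi2(compute_prr(compute_ror(t1))))
  s2 <- compute_bcpnn(compute_chi2(compute_prr(compute_ror(t2))))
  expect_equal(s1$c, s2$c)
  expect_equal(dplyr::select(s1, -term), dplyr::select(s2, -term))
})

test_that("the ROR->PRR identity reproduces published table rows", {
  # (a, M, printed ROR) -> printed PRR, all from one signal-strength table
  rows <- tibble::tibble(
    a = c(571, 13436, 2368, 2872, 722),
    ror = c(756.520, 80.477, 81.979, 73.978, 169.898),
    prr_printed = c(754.089, 74.460, 80.899, 72.797, 169.210)
  )
  implied <- prr_implied_by_ror(rows$a, 177465, rows$ror)
  expect_equal(implied, rows$prr_printed, tolerance = 0.1 / 700)
  expect_true(all(abs(implied - rows$prr_printed) < 0.1))

  # null identity and degenerate input
  expect_equal(prr_implied_by_ror(12, 500, 1), 1)
  expect_warning(out <- prr_implied_by_ror(0, 10, 2))
  expect_true(is.na(out))
})

test_that("dispro_stats composes all five statistics", {
  set.seed(5)
  tabs <- random_tables(60)
  st <- dispro_stats(tabs)
  expect_true(all(c("ror", "prr", "chi2", "ic", "ic025", "ebgm", "eb05",
                    "eb95", "E", "qn") %in% names(st)))
  expect_true(all(st$eb05 <= st$ebgm & st$ebgm <= st$eb95))
  expect_warning(dispro_stats(random_tables(10)), "50")
})
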