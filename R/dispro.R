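#' Reporting odds ratio with 95% Wald interval
#'
#' `ROR = ad / bc`, with log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and two-sided 95% bounds
#' `exp(log ROR +- 1.96 se)`. When any cell is zero and `zero_correction` is
#' on, the Haldane-Anscombe 0.5 is added to all four cells before computing
#' (flagged per row); with the correction off a zero denominator yields an
#' undefined-flagged row, never an error.
#'
#' @param tables Data frame with integer cell columns `a`, `b`, `c`, `d`.
#' @param zero_correction Apply the +0.5 correction when a cell is zero.
#' @return `tables` with columns `ror`, `ror_lo`, `ror_hi`, `ror_corrected`,
#'   `ror_undefined` appended.
#' @export
compute_ror <- function(tables, zero_correction = TRUE) {
  assert_cells(tables)
  cells <- with(tables, cbind(a, b, c, d))
  has_zero <- rowSums(cells == 0) > 0
  corrected <- has_zero & zero_correction
  cc <- cells + 0.5 * corrected
  ca <- as.vector(cc[, 1]); cb <- as.vector(cc[, 2])
  ccl <- as.vector(cc[, 3]); cd <- as.vector(cc[, 4])
  undefined <- ca == 0 | cb == 0 | ccl == 0 | cd == 0 |
    rowSums(cells) == 0
  lror <- log(ca) + log(cd) - log(cb) - log(ccl)
  se <- sqrt(unname(rowSums(1 / cc)))
  out <- dplyr::mutate(
    tables,
    ror = exp(lror),
    ror_lo = exp(lror - 1.96 * se),
    ror_hi = exp(lror + 1.96 * se),
    ror_corrected = corrected,
    ror_undefined = undefined | !is.finite(lror) | !is.finite(se)
  )
  out$ror[out$ror_undefined] <- NA_real_
  out$ror_lo[out$ror_undefined] <- NA_real_
  out$ror_hi[out$ror_undefined] <- NA_real_
  out
}

#' Proportional reporting ratio with 95% interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, with log-scale standard error
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Zero-cell handling mirrors
#' [compute_ror()]; a table with `c = 0` (and correction off) or an empty
#' target margin is undefined-flagged.
#'
#' @inheritParams compute_ror
#' @return `tables` with `prr`, `prr_lo`, `prr_hi`, `prr_corrected`,
#'   `prr_undefined` appended.
#' @export
compute_prr <- function(tables, zero_correction = TRUE) {
  assert_cells(tables)
  cells <- with(tables, cbind(a, b, c, d))
  has_zero <- rowSums(cells == 0) > 0
  corrected <- has_zero & zero_correction
  cc <- cells + 0.5 * corrected
  a <- as.vector(cc[, 1]); b <- as.vector(cc[, 2])
  cl <- as.vector(cc[, 3]); d <- as.vector(cc[, 4])
  undefined <- (a + b) == 0 | cl == 0 | a == 0
  lprr <- log(a) - log(a + b) - log(cl) + log(cl + d)
  se <- sqrt(pmax(1 / a - 1 / (a + b) + 1 / cl - 1 / (cl + d), 0))
  out <- dplyr::mutate(
    tables,
    prr = exp(lprr),
    prr_lo = exp(lprr - 1.96 * se),
    prr_hi = exp(lprr + 1.96 * se),
    prr_corrected = corrected,
    prr_undefined = undefined | !is.finite(lprr) | !is.finite(se)
  )
  out$prr[out$prr_undefined] <- NA_real_
  out$prr_lo[out$prr_undefined] <- NA_real_
  out$prr_hi[out$prr_undefined] <- NA_real_
  out
}

#' MHRA chi-square statistic
#'
#' `chi2 = n (|ad - bc| - [n/2])^2 / ((a+b)(c+d)(a+c)(b+d))`, with the Yates
#' continuity term `n/2` applied by default (MHRA convention) and the inner
#' difference floored at zero. A zero margin yields an undefined-flagged row.
#'
#' @inheritParams compute_ror
#' @param yates Apply the Yates continuity correction.
#' @return `tables` with `chi2`, `p_chi2`, `chi2_yates`, `chi2_undefined`
#'   appended; `p_chi2` from the 1-df chi-square distribution.
#' @export
compute_chi2 <- function(tables, yates = TRUE, zero_correction = TRUE) {
  assert_cells(tables)
  cells <- with(tables, cbind(a, b, c, d))
  has_zero <- rowSums(cells == 0) > 0
  corrected <- has_zero & zero_correction
  cc <- cells + 0.5 * corrected
  a <- as.vector(cc[, 1]); b <- as.vector(cc[, 2])
  cl <- as.vector(cc[, 3]); d <- as.vector(cc[, 4])
  n <- a + b + cl + d
  margins <- cbind(a + b, cl + d, a + cl, b + d)
  undefined <- rowSums(margins == 0) > 0
  dev <- abs(a * d - b * cl) - if (yates) n / 2 else 0
  dev <- pmax(dev, 0)
  chi2 <- n * dev^2 / (margins[, 1] * margins[, 2] *
                         margins[, 3] * margins[, 4])
  chi2[undefined] <- NA_real_
  out <- dplyr::mutate(
    tables,
    chi2 = chi2,
    p_chi2 = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    chi2_yates = yates,
    chi2_undefined = undefined
  )
  out
}

#' BCPNN hyperparameters
#'
#' Defaults follow the standard information-component prior: marginal Beta
#' priors `Beta(alpha1, alpha - alpha1)` and `Beta(beta1, beta - beta1)` for
#' the drug and event probabilities, joint `Beta(gamma11, gamma - gamma11)`
#' with `gamma` chosen per table so the prior IC expectation is zero.
#'
#' @param alpha1,beta1,alpha,beta,gamma11 Positive reals.
#' @return Named numeric vector.
#' @export
bcpnn_hyper <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                        gamma11 = 1) {
  c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
    gamma11 = gamma11)
}

#' BCPNN information component (closed-form moments)
#'
#' Computes the information component `IC = log2 of observed-to-expected
#' reporting` under the Bayesian confidence propagation neural network model,
#' using the closed-form posterior moments:
#' `gamma = gamma11 (n+alpha)(n+beta) / ((a+b+alpha1)(a+c+beta1))`, then
#' `E(IC) = log2[(a+gamma11)(n+alpha)(n+beta) /
#'               ((n+gamma)(a+b+alpha1)(a+c+beta1))]` and
#' `V(IC) = (ln 2)^-2 [ (n-a+gamma-gamma11)/((a+gamma11)(1+n+gamma))
#'   + (n-a-b+alpha-alpha1)/((a+b+alpha1)(1+n+alpha))
#'   + (n-a-c+beta-beta1)/((a+c+beta1)(1+n+beta)) ]`.
#' Zero cells need no correction; on the all-zero table the IC is exactly 0
#' (the prior is centred).
#'
#' The screening bound `ic025 = E(IC) - 2 SD` (the conventional "IC-2SD");
#' `ic_lo`/`ic_hi` additionally carry the +-1.96 SD interval printed in
#' published tables.
#'
#' @inheritParams compute_ror
#' @param hyper See [bcpnn_hyper()].
#' @return `tables` with `ic`, `ic_sd`, `ic025`, `ic975`, `ic_lo`, `ic_hi`
#'   appended.
#' @export
compute_bcpnn <- function(tables, hyper = bcpnn_hyper()) {
  assert_cells(tables)
  a <- tables$a; b <- tables$b; cl <- tables$c; d <- tables$d
  n <- a + b + cl + d
  a1 <- hyper[["alpha1"]]; b1 <- hyper[["beta1"]]
  al <- hyper[["alpha"]]; be <- hyper[["beta"]]; g11 <- hyper[["gamma11"]]
  gamma <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + cl + b1))
  ic <- log2((a + g11) * (n + al) * (n + be) /
               ((n + gamma) * (a + b + a1) * (a + cl + b1)))
  vic <- ((n - a + gamma - g11) / ((a + g11) * (1 + n + gamma)) +
            (n - a - b + al - a1) / ((a + b + a1) * (1 + n + al)) +
            (n - a - cl + be - b1) / ((a + cl + b1) * (1 + n + be))) /
    log(2)^2
  sd <- sqrt(vic)
  dplyr::mutate(
    tables,
    ic = ic,
    ic_sd = sd,
    ic025 = ic - 2 * sd,
    ic975 = ic + 2 * sd,
    ic_lo = ic - 1.96 * sd,
    ic_hi = ic + 1.96 * sd
  )
}

#' PRR implied by a published count and ROR
#'
#' From the 2x2 algebra with `a + b = M` (the total number of target-drug
#' combinations), the PRR is determined by `a`, `M` and the ROR alone,
#' independent of how the background splits into `c` and `d`:
#' `PRR = (a/M) (1 + ROR (M - a) / a)`. This validates published ROR/PRR
#' pairs without access to the full reporting database.
#'
#' @param a Count of target drug-event combinations (a > 0).
#' @param m Total target-drug combinations (a <= m).
#' @param ror Reporting odds ratio (> 0).
#' @return Implied PRR (NA with a warning when `a = 0`).
#' @export
#' @examples
#' prr_implied_by_ror(571, 177465, 756.520) # ~754.09
prr_implied_by_ror <- function(a, m, ror) {
  bad <- a <= 0 | a > m | ror <= 0
  if (any(bad, na.rm = TRUE)) {
    rlang::warn("prr_implied_by_ror undefined for a = 0, a > m or ror <= 0")
  }
  out <- (a / m) * (1 + ror * (m - a) / a)
  out[bad] <- NA_real_
  out
}

#' All five disproportionality statistics per term
#'
#' Convenience wrapper chaining [compute_ror()], [compute_prr()],
#' [compute_chi2()], [compute_bcpnn()] and [compute_ebgm()] on a table of
#' 2x2 cells, one row per term.
#'
#' @inheritParams compute_ror
#' @param prior An `mgps_prior` (see [fit_mgps_prior()]); if `NULL` and the
#'   input has at least 50 rows, a prior is fitted from the input's own
#'   `(a, E)` cells, otherwise the MGPS columns are left `NA` with a warning.
#' @param yates Yates correction for the chi-square component.
#' @param hyper BCPNN hyperparameters, see [bcpnn_hyper()].
#' @return Input tibble augmented with every statistic's columns.
#' @export
dispro_stats <- function(tables, prior = NULL, zero_correction = TRUE,
                         yates = TRUE, hyper = bcpnn_hyper()) {
  out <- tables |>
    compute_ror(zero_correction = zero_correction) |>
    compute_prr(zero_correction = zero_correction) |>
    compute_chi2(yates = yates, zero_correction = zero_correction) |>
    compute_bcpnn(hyper = hyper)
  if (is.null(prior)) {
    if (nrow(out) >= 50) {
      cells <- dplyr::transmute(
        out, a = .data$a,
        E = (.data$a + .data$b) * (.data$a + .data$c) /
          (.data$a + .data$b + .data$c + .data$d)
      )
      prior <- fit_mgps_prior(cells)
    } else {
      rlang::warn("no MGPS prior supplied and < 50 cells to fit one; MGPS columns set NA")
      return(dplyr::mutate(out, E = NA_real_, qn = NA_real_,
                           ebgm = NA_real_, eb05 = NA_real_,
                           eb95 = NA_real_))
    }
  }
  compute_ebgm(out, prior)
}
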