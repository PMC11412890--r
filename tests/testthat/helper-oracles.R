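# Independent oracles: brute-force enumeration, Monte-Carlo posterior
# sampling, grid quadrature. Deliberately naive and separate from the
# package's own code paths.

# enumerate all (report, term) pairs with loops
brute_combination_counts <- function(target, background, level = "pt",
                                     pt_to_soc = NULL) {
  enumerate <- function(reports) {
    pairs <- list()
    for (i in seq_len(nrow(reports))) {
      terms <- unique(reports$reactions[[i]])
      if (level == "soc") {
        socs <- pt_to_soc$soc[match(terms, pt_to_soc$pt)]
        socs[is.na(socs)] <- "unmapped"
        terms <- unique(socs)
      }
      for (tm in terms) {
        pairs[[length(pairs) + 1]] <- c(reports$primaryid[i], tm)
      }
    }
    do.call(rbind, pairs)
  }
  pt <- enumerate(target)
  pb <- enumerate(background)
  terms <- sort(unique(c(pt[, 2], pb[, 2])))
  list(
    n_target = vapply(terms, function(tm) sum(pt[, 2] == tm), numeric(1)),
    n_other = vapply(terms, function(tm) sum(pb[, 2] == tm), numeric(1)),
    m_target = nrow(pt),
    m_other = nrow(pb),
    terms = terms
  )
}

# Monte-Carlo estimate (with batch-mean SE) of the information component as
# log2 of the ratio of posterior means, sampling the three conjugate Beta
# posteriors of the BCPNN model directly.
bcpnn_mc_oracle <- function(a, b, c, d, hyper = faersignal::bcpnn_hyper(),
                            n_draws = 1e5, n_batch = 20) {
  n <- a + b + c + d
  a1 <- hyper[["alpha1"]]; b1 <- hyper[["beta1"]]
  al <- hyper[["alpha"]]; be <- hyper[["beta"]]; g11 <- hyper[["gamma11"]]
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  per_batch <- n_draws / n_batch
  est <- vapply(seq_len(n_batch), function(i) {
    p11 <- stats::rbeta(per_batch, a + g11, n - a + gam - g11)
    p1 <- stats::rbeta(per_batch, a + b + a1, n - a - b + al - a1)
    p2 <- stats::rbeta(per_batch, a + c + b1, n - a - c + be - b1)
    log2(mean(p11) / (mean(p1) * mean(p2)))
  }, numeric(1))
  list(mean = mean(est), se = stats::sd(est) / sqrt(n_batch))
}

# posterior quantile of the gamma-mixture by trapezoid CDF on a lambda grid
mgps_quadrature_quantile <- function(p, prior, a, E, n_grid = 400000) {
  q1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E))
  q2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E))
  qn <- prior$w * q1 / (prior$w * q1 + (1 - prior$w) * q2)
  hi <- max(stats::qgamma(1 - 1e-10, prior$alpha1 + a, prior$beta1 + E),
            stats::qgamma(1 - 1e-10, prior$alpha2 + a, prior$beta2 + E))
  # integrate in u with lambda = u^3: regularises the density singularity
  # at 0 that gamma shapes below 1 (a = 0, sub-unit prior shape) produce
  u <- seq(0, hi^(1 / 3), length.out = n_grid)
  lam <- u^3
  dens_lam <- qn * stats::dgamma(lam, prior$alpha1 + a, prior$beta1 + E) +
    (1 - qn) * stats::dgamma(lam, prior$alpha2 + a, prior$beta2 + E)
  integrand <- dens_lam * 3 * u^2
  integrand[1] <- 0
  h <- u[2] - u[1]
  cdf <- cumsum((integrand + dplyr::lag(integrand, default = 0)) / 2 * h)
  stats::approx(cdf, lam, xout = p, ties = "ordered")$y
}

# a plain single-gamma prior object for closed-form EBGM checks
degenerate_prior <- function(shape = 1, rate = 1) {
  structure(
    list(alpha1 = shape, beta1 = rate, alpha2 = shape, beta2 = rate,
         w = 0.5, loglik = NA_real_, iterations = 0L, converged = TRUE,
         n_cells = 0L, start_used = 0L),
    class = "mgps_prior"
  )
}
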