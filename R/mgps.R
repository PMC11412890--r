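#' Default multi-start points for the MGPS prior fit
#'
#' The first start is DuMouchel's canonical prior
#' `(alpha1, beta1, alpha2, beta2, w) = (0.2, 0.1, 2, 4, 1/3)`; the others
#' spread over high/low-mean and balanced mixtures so the optimiser is not
#' hostage to one basin.
#'
#' @return List of named numeric vectors.
#' @export
mgps_starts <- function() {
  list(
    c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2,   beta2 = 4,   w = 1 / 3),
    c(alpha1 = 1,   beta1 = 1,   alpha2 = 1,   beta2 = 1,   w = 0.5),
    c(alpha1 = 0.5, beta1 = 0.25, alpha2 = 3,  beta2 = 3,   w = 0.2),
    c(alpha1 = 2,   beta1 = 0.5, alpha2 = 0.5, beta2 = 2,   w = 0.5),
    c(alpha1 = 5,   beta1 = 2,   alpha2 = 1,   beta2 = 4,   w = 0.1)
  )
}

# mixture log-marginal of counts a given expecteds E:
# w NB(a; alpha1, beta1/(beta1+E)) + (1-w) NB(a; alpha2, beta2/(beta2+E))
mgps_loglik <- function(par, a, E) {
  # extreme transformed parameters can overflow dnbinom; the optimiser
  # treats the resulting -Inf/NaN as a rejected step
  suppressWarnings({
    l1 <- stats::dnbinom(a, size = par[["alpha1"]],
                         prob = par[["beta1"]] / (par[["beta1"]] + E),
                         log = TRUE)
    l2 <- stats::dnbinom(a, size = par[["alpha2"]],
                         prob = par[["beta2"]] / (par[["beta2"]] + E),
                         log = TRUE)
  })
  sum(lse2(log(par[["w"]]) + l1, log1p(-par[["w"]]) + l2))
}

mgps_untransform <- function(theta) {
  c(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
    alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
    w = stats::plogis(theta[5]))
}

#' Fit the two-component gamma mixture prior of the gamma Poisson shrinker
#'
#' Maximises the marginal negative-binomial mixture likelihood of the
#' observed counts `a` given their expected counts `E` over the five prior
#' parameters `(alpha1, beta1, alpha2, beta2, w)`, on a log/logit transformed
#' scale so positivity and `w in (0,1)` hold by construction. Multiple
#' deterministic starts (see [mgps_starts()]) guard against local optima; the
#' best converged solution wins. Components are relabelled so component 1 has
#' the larger prior mean `alpha/beta`, making the fit label-switch-proof.
#'
#' @param cells Data frame with columns `a` (observed combination count) and
#'   `E` (expected count, > 0), one row per drug-event cell; at least 50
#'   cells.
#' @param starts List of start vectors; default [mgps_starts()].
#' @param control Passed to [stats::optim()] (BFGS).
#' @return An object of class `mgps_prior`: the five parameters plus fit
#'   diagnostics (`loglik`, `iterations`, `converged`, `n_cells`,
#'   `start_used`). `tidy()` and `glance()` methods are provided.
#' @export
fit_mgps_prior <- function(cells, starts = mgps_starts(),
                           control = list(maxit = 500)) {
  if (!all(c("a", "E") %in% names(cells))) {
    rlang::abort("`cells` needs columns `a` and `E`")
  }
  a <- as.numeric(cells$a)
  E <- as.numeric(cells$E)
  if (length(a) < 50) rlang::abort("need at least 50 cells to fit the prior")
  if (any(!is.finite(E) | E <= 0)) rlang::abort("every E must be positive")

  negll <- function(theta) {
    par <- mgps_untransform(theta)
    ll <- mgps_loglik(par, a, E)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  fits <- lapply(seq_along(starts), function(i) {
    s <- starts[[i]]
    theta0 <- c(log(s[["alpha1"]]), log(s[["beta1"]]),
                log(s[["alpha2"]]), log(s[["beta2"]]),
                stats::qlogis(s[["w"]]))
    fit <- tryCatch(
      stats::optim(theta0, negll, method = "BFGS", control = control),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    list(value = fit$value, par = fit$par,
         counts = fit$counts[["function"]],
         convergence = fit$convergence, start = i)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    rlang::abort("MGPS prior fit failed from every start")
  }
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  converged <- best$convergence == 0
  if (!converged && all(vapply(fits, `[[`, integer(1), "convergence") != 0)) {
    rlang::warn("MGPS prior fit did not formally converge from any start; returning best found")
  }
  par <- mgps_untransform(best$par)
  # canonical orientation: component 1 has the larger prior mean
  if (par[["alpha1"]] / par[["beta1"]] < par[["alpha2"]] / par[["beta2"]]) {
    par <- c(alpha1 = par[["alpha2"]], beta1 = par[["beta2"]],
             alpha2 = par[["alpha1"]], beta2 = par[["beta1"]],
             w = 1 - par[["w"]])
  }
  structure(
    list(
      alpha1 = par[["alpha1"]], beta1 = par[["beta1"]],
      alpha2 = par[["alpha2"]], beta2 = par[["beta2"]],
      w = par[["w"]],
      loglik = -best$value,
      iterations = best$counts,
      converged = converged,
      n_cells = length(a),
      start_used = best$start
    ),
    class = "mgps_prior"
  )
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("<mgps_prior> two-component gamma mixture\n")
  cat(sprintf("  comp 1: Gamma(shape %.4g, rate %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  comp 2: Gamma(shape %.4g, rate %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  cat(sprintf("  logLik %.2f on %d cells (%sconverged)\n",
              x$loglik, x$n_cells, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w)
  )
}

#' @export
glance.mgps_prior <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_cells = x$n_cells,
    iterations = x$iterations, converged = x$converged,
    start_used = x$start_used
  )
}

# posterior mixture weight on component 1 given (a, E)
mgps_qn <- function(prior, a, E) {
  l1 <- stats::dnbinom(a, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  1 / (1 + exp(log1p(-prior$w) + l2 - log(prior$w) - l1))
}

# mixture posterior CDF of the relative reporting rate lambda
mgps_post_cdf <- function(lambda, prior, a, E, qn) {
  qn * stats::pgamma(lambda, shape = prior$alpha1 + a,
                     rate = prior$beta1 + E) +
    (1 - qn) * stats::pgamma(lambda, shape = prior$alpha2 + a,
                             rate = prior$beta2 + E)
}

# vectorised bisection for mixture posterior quantiles, abs tol on lambda
mgps_post_quantile <- function(p, prior, a, E, qn, tol = 1e-6) {
  hi <- pmax(
    stats::qgamma(0.999999, shape = prior$alpha1 + a, rate = prior$beta1 + E),
    stats::qgamma(0.999999, shape = prior$alpha2 + a, rate = prior$beta2 + E)
  ) + 1
  lo <- rep(0, length(a))
  for (i in seq_len(ceiling(log2(max(hi) / tol)) + 5)) {
    mid <- (lo + hi) / 2
    below <- mgps_post_cdf(mid, prior, a, E, qn) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol / 2) break
  }
  (lo + hi) / 2
}

#' Empirical-Bayes geometric mean and posterior percentiles
#'
#' Given a fitted [fit_mgps_prior()] prior, the posterior of the relative
#' reporting rate `lambda` for a cell with observed count `a` and expected
#' count `E = (a+b)(a+c)/n` is the gamma mixture
#' `Qn Gamma(alpha1 + a, beta1 + E) + (1 - Qn) Gamma(alpha2 + a, beta2 + E)`.
#' The EBGM is the geometric mean `exp(E[log lambda])` (digamma closed form);
#' `eb05`/`eb95` are the posterior 5th/95th percentiles found by bisection on
#' the mixture CDF to absolute tolerance 1e-6.
#'
#' @param tables Data frame with cells `a`, `b`, `c`, `d` (or precomputed
#'   column `E` alongside `a`).
#' @param prior An `mgps_prior`.
#' @return `tables` with `E`, `qn`, `ebgm`, `eb05`, `eb95` appended.
#' @export
compute_ebgm <- function(tables, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  a <- as.numeric(tables$a)
  if ("E" %in% names(tables)) {
    E <- as.numeric(tables$E)
  } else {
    assert_cells(tables)
    n <- with(tables, a + b + c + d)
    E <- with(tables, (a + b) * (a + c) / n)
  }
  qn <- mgps_qn(prior, a, E)
  eblog <- qn * (digamma(prior$alpha1 + a) - log(prior$beta1 + E)) +
    (1 - qn) * (digamma(prior$alpha2 + a) - log(prior$beta2 + E))
  dplyr::mutate(
    tables,
    E = E,
    qn = qn,
    ebgm = exp(eblog),
    eb05 = mgps_post_quantile(0.05, prior, a, E, qn),
    eb95 = mgps_post_quantile(0.95, prior, a, E, qn)
  )
}

#' Drug-event cells for prior fitting
#'
#' Builds the full set of (suspect drug, term) combination counts across a
#' cleaned report set, with expected counts from the row/column margins
#' (`E = n_drug * n_term / n_total` in combination units), the input the
#' shrinker's prior is fitted on.
#'
#' @param reports Clean report tibble (each report's `ps_drug` identifies its
#'   suspect drug; reports without one are skipped).
#' @param level `"pt"` or `"soc"`.
#' @param pt_to_soc SOC map when `level = "soc"`.
#' @return Tibble with columns `drug`, `term`, `a`, `E`.
#' @export
drug_event_cells <- function(reports, level = c("pt", "soc"),
                             pt_to_soc = NULL) {
  level <- match.arg(level)
  keep <- !is.na(reports$ps_drug)
  reports <- reports[keep, , drop = FALSE]
  long <- tibble::tibble(
    primaryid = rep(reports$primaryid, lengths(reports$reactions)),
    drug = rep(reports$ps_drug, lengths(reports$reactions)),
    term = unlist(reports$reactions, use.names = FALSE)
  ) |>
    dplyr::distinct()
  if (level == "soc") {
    if (is.null(pt_to_soc)) rlang::abort("SOC level needs `pt_to_soc`")
    long <- long |>
      dplyr::left_join(pt_to_soc, by = c(term = "pt")) |>
      dplyr::transmute(primaryid = .data$primaryid, drug = .data$drug,
                       term = dplyr::coalesce(.data$soc, "unmapped")) |>
      dplyr::distinct()
  }
  n_total <- nrow(long)
  cells <- long |> dplyr::count(.data$drug, .data$term, name = "a")
  drug_m <- long |> dplyr::count(.data$drug, name = "n_drug")
  term_m <- long |> dplyr::count(.data$term, name = "n_term")
  cells |>
    dplyr::left_join(drug_m, by = "drug") |>
    dplyr::left_join(term_m, by = "term") |>
    dplyr::mutate(E = .data$n_drug * .data$n_term / n_total) |>
    dplyr::select("drug", "term", "a", "E")
}
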