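#' Round half away from zero
#'
#' Printed pharmacovigilance tables use commercial ("half-up") rounding, which
#' differs from R's banker's rounding at exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35, where round() gives 2.34
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# logsumexp over two vectors, elementwise
lse2 <- function(x, y) {
  m <- pmax(x, y)
  # guard -Inf/-Inf
  out <- m + log(exp(x - m) + exp(y - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

assert_cells <- function(tables) {
  need <- c("a", "b", "c", "d")
  missing <- setdiff(need, names(tables))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "`tables` must contain contingency cell columns a, b, c, d; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  bad <- with(tables, a < 0 | b < 0 | c < 0 | d < 0)
  if (any(bad, na.rm = TRUE)) {
    rlang::abort("contingency cells must be non-negative")
  }
  invisible(tables)
}
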