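#' Sample-size constants of Tajima's D
#'
#' Computes the eight coefficients of Tajima's D statistic for a sample of
#' `n` haploid genomes: the harmonic sums `a1 = sum(1/i)` and
#' `a2 = sum(1/i^2)` over `i = 1, ..., n - 1`, the auxiliary quantities
#' `b1`, `b2`, `c1`, `c2`, and the normalising coefficients `e1 = c1/a1`
#' and `e2 = c2/(a1^2 + a2)`. `a1` is Watterson's correction factor: the
#' expected number of segregating sites under the neutral equilibrium
#' infinite-sites model is `theta * a1`.
#'
#' @param n Haploid sample size, a single integer `>= 2`. The variance
#'   coefficients `b1`, `b2`, `c1`, `c2`, `e1`, `e2` require `n >= 4`
#'   (with `n = 2` or `3` the D statistic is degenerate); by default they
#'   are required.
#' @param require_D If `TRUE` (default) an error is raised for `n < 4`;
#'   with `FALSE` and `n` of 2 or 3 only `a1` and `a2` are returned and the
#'   remaining coefficients are `NA`.
#'
#' @return An object of class `"tajima_constants"`: a list with elements
#'   `n`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#'
#' @examples
#' tajima_constants(4)$a1   # 1 + 1/2 + 1/3
#' tajima_constants(1135)
#' @export
tajima_constants <- function(n, require_D = TRUE) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2")
  n <- as.integer(n)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  if (n < 4L) {
    if (require_D)
      stop("'n' must be >= 4 for the variance coefficients of Tajima's D")
    out <- list(n = n, a1 = a1, a2 = a2, b1 = NA_real_, b2 = NA_real_,
                c1 = NA_real_, c2 = NA_real_, e1 = NA_real_, e2 = NA_real_)
    class(out) <- "tajima_constants"
    return(out)
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  out <- list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
              c1 = c1, c2 = c2, e1 = e1, e2 = e2)
  class(out) <- "tajima_constants"
  out
}

#' @export
print.tajima_constants <- function(x, digits = 6, ...) {
  cat("Tajima's D constants (n =", x$n, "haploid genomes)\n")
  v <- unlist(x[c("a1", "a2", "b1", "b2", "c1", "c2", "e1", "e2")])
  print(signif(v, digits))
  invisible(x)
}
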