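#' Solve for the mean number of segregating sites from a mean D
#'
#' For fixed mean pairwise differences `k > 0` and sample size `n`,
#' Tajima's D evaluated at substituted means is strictly decreasing in
#' `S`, so a target mean D determines a unique mean `S`. This inverts the
#' D formula by root finding, which is how a mean `S` per window can be
#' recovered when only the mean D and the mean pairwise diversity of a
#' (nearly) neutral sequence class are reported.
#'
#' The attainable range of D is `(-a1*sqrt(...) limit, +Inf)` in principle;
#' in practice D ranges from large positive values as `S -> 0+` down to
#' `-1/(a1*sqrt(e2))` as `S -> Inf`. A `D_target` at or below the lower
#' limit is rejected with an error naming the attainable interval.
#'
#' @param D_target Target mean D value.
#' @param k Mean pairwise differences per window, `> 0`.
#' @param n Haploid sample size (`>= 4`) or a [tajima_constants] object.
#' @param tol Convergence tolerance on D (default `1e-10`).
#' @param variance Variance form passed to [tajima_D].
#' @return The unique `S > 0` with `tajima_D(k, S, n) == D_target` to
#'   within `tol`.
#' @examples
#' cst <- tajima_constants(1135)
#' solve_S_from_D(0, k = 0.3, n = cst)      # = 0.3 * a1 exactly
#' solve_S_from_D(-0.9, k = 0.3, n = cst)
#' @export
solve_S_from_D <- function(D_target, k, n, tol = 1e-10,
                           variance = c("classical", "squared")) {
  variance <- match.arg(variance)
  cst <- if (inherits(n, "tajima_constants")) n else tajima_constants(n)
  if (length(k) != 1 || !is.finite(k) || k <= 0)
    stop("'k' must be a single positive value")
  if (D_target == 0) return(k * cst$a1)
  D_inf <- -1 / (cst$a1 * sqrt(cst$e2))  # limit of D as S -> Inf
  if (D_target <= D_inf)
    stop(sprintf(
      "D_target = %g is unattainable: for k = %g, n = %d, D lies in (%.4f, Inf)",
      D_target, k, cst$n, D_inf))
  f <- function(S) tajima_D(k, S, cst, variance = variance) - D_target
  lo <- k * cst$a1 / 10
  hi <- k * cst$a1 * 10
  while (f(lo) < 0 && lo > .Machine$double.xmin) lo <- lo / 10
  while (f(hi) > 0 && hi < 1 / .Machine$double.eps) hi <- hi * 10
  if (f(lo) < 0 || f(hi) > 0)
    stop("failed to bracket a root for 'D_target'")
  uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
          f.lower = f(lo), f.upper = f(hi))$root
}

#' Neutral-sequence summary implied by a mean D and diversity
#'
#' Builds the full windowed summary of a purely neutral sequence class
#' from its per-site pairwise diversity `pi_n` and mean Tajima's D `D_n`:
#' the window mean pairwise differences `k_n = L * pi_n`, the mean number
#' of segregating sites `S_n` obtained by inverting the D formula
#' ([solve_S_from_D]), the per-site Watterson diversity
#' `theta_wn = S_n / (L*a1)`, and the implied skew
#' `delta_theta_w = 1 - pi_n/theta_wn = 1 - k_n*a1/S_n`.
#'
#' @param pi_n Per-site pairwise diversity, `> 0`.
#' @param D_n Mean Tajima's D of the neutral class (negative under an
#'   excess of rare variants).
#' @param L Window length in basepairs (default 100).
#' @param n Haploid sample size or a [tajima_constants] object.
#' @param variance Variance form passed to [tajima_D].
#' @return An object of class `"neutral_summary"`: a list with `L`, `n`,
#'   `pi_n`, `k_n`, `D_n`, `S_n`, `theta_wn`, `delta_theta_w`.
#' @examples
#' neutral_summary(pi_n = 0.003, D_n = -0.9, L = 100, n = 1135)
#' @export
neutral_summary <- function(pi_n, D_n, L = 100, n = 1135,
                            variance = c("classical", "squared")) {
  variance <- match.arg(variance)
  if (length(pi_n) != 1 || !is.finite(pi_n) || pi_n <= 0)
    stop("'pi_n' must be a single positive value")
  cst <- if (inherits(n, "tajima_constants")) n else tajima_constants(n)
  k_n <- L * pi_n
  S_n <- solve_S_from_D(D_n, k_n, cst, variance = variance)
  out <- list(L = L, n = cst$n, pi_n = pi_n, k_n = k_n, D_n = D_n,
              S_n = S_n, theta_wn = S_n / (L * cst$a1),
              delta_theta_w = 1 - k_n * cst$a1 / S_n)
  class(out) <- "neutral_summary"
  out
}

#' @export
print.neutral_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Neutral sequence summary (n = %d, L = %d bp)\n",
              x$n, as.integer(x$L)))
  cat(sprintf("  pi_n = %g, mean D = %g\n", x$pi_n, x$D_n))
  cat(sprintf("  implied mean S per window = %.*g\n", digits + 2, x$S_n))
  cat(sprintf("  theta_w per site = %.*g\n", digits, x$theta_wn))
  cat(sprintf("  delta_theta_w = %.*f\n", digits, x$delta_theta_w))
  invisible(x)
}
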