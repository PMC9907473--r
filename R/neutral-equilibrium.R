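#' Simulate neutral coalescent windows
#'
#' Draws independent windows under the Kingman coalescent without
#' recombination (appropriate for short windows in a highly selfing
#' species, where the effective recombination rate is very low), with
#' infinite-sites mutation at window-scaled rate `M` (`M = theta` for the
#' whole window, so `E[S] = M*a1` and `E[k] = M` at equilibrium).
#' Optionally the population grows exponentially at rate `growth`
#' (coalescent time units), which skews the site frequency spectrum
#' toward rare variants.
#'
#' @param reps Number of independent windows (genealogies) to simulate.
#' @param n Haploid sample size.
#' @param M Window-scaled mutation rate (`theta` per window), `> 0`.
#' @param growth Exponential growth rate in coalescent units; 0 = constant
#'   population size (equilibrium).
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A data frame with one row per window and columns `k` (mean
#'   pairwise differences), `S` (segregating sites) and `tbar2` (the
#'   genealogy's mean pairwise coalescence time; `E[k | tree] = M * tbar2`,
#'   useful for rescaling `M` under growth).
#' @examples
#' w <- sim_neutral_windows(200, n = 20, M = 1, seed = 1)
#' mean(w$S) / tajima_constants(20)$a1  # close to M
#' @export
sim_neutral_windows <- function(reps, n, M, growth = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(sim_windows_cpp(as.integer(reps), as.integer(n),
                                as.numeric(M), as.numeric(growth)))
}

#' Expected Tajima's D under the neutral equilibrium model
#'
#' Monte-Carlo estimate of the mean of Tajima's D over short windows under
#' the neutral equilibrium infinite-sites coalescent, as a function of the
#' window-scaled mutation rate `M` and sample size `n`. Although the
#' expectation of the numerator `k - S/a1` is zero at equilibrium, the mean
#' of the *ratio* is slightly negative, increasingly so for larger `M`:
#' the denominator grows more slowly with `S` than the numerator, and the
#' two are correlated.
#'
#' Windows with `S = 0` (a substantial fraction when `M` is small) have an
#' undefined D. Both conventions are reported: D set to 0 at `S = 0`
#' (`mean_D`), and the mean conditioned on `S >= 1` (`mean_D_cond`).
#'
#' @param M Window-scaled mutation rate (e.g. `M = 0.3` for a 100-bp
#'   window at per-site diversity 0.003).
#' @param n Haploid sample size.
#' @param reps Monte-Carlo replicates (default `1e5`).
#' @param seed Optional integer seed.
#' @param se_target Optional standard-error target for `mean_D`; a warning
#'   is issued if the attained Monte-Carlo error exceeds it.
#' @return An object of class `"neutral_D"`: a list with `M`, `n`, `reps`,
#'   `mean_D`, `se_D`, `mean_D_cond`, `se_D_cond`, `mean_S`, `mean_k`,
#'   `p_S0` (fraction of windows with `S = 0`), and `seed`.
#' @examples
#' expected_D(M = 1, n = 50, reps = 5000, seed = 1)
#' @export
expected_D <- function(M, n, reps = 1e5, seed = NULL, se_target = NULL) {
  w <- sim_neutral_windows(reps, n, M, growth = 0, seed = seed)
  D <- tajima_D(w$k, w$S, n)
  seg <- w$S > 0
  Dc <- D[seg]
  out <- list(M = M, n = n, reps = reps,
              mean_D = mean(D), se_D = sd(D) / sqrt(length(D)),
              mean_D_cond = if (any(seg)) mean(Dc) else NA_real_,
              se_D_cond = if (sum(seg) > 1) sd(Dc) / sqrt(length(Dc)) else NA_real_,
              mean_S = mean(w$S), mean_k = mean(w$k),
              p_S0 = mean(!seg), seed = seed)
  class(out) <- "neutral_D"
  if (!is.null(se_target) && is.finite(out$se_D) && out$se_D > se_target)
    warning(sprintf("attained standard error %.2g exceeds target %.2g; increase 'reps'",
                    out$se_D, se_target))
  out
}

#' @export
print.neutral_D <- function(x, digits = 4, ...) {
  cat(sprintf("Neutral equilibrium Tajima's D (M = %g, n = %d, %d windows)\n",
              x$M, x$n, as.integer(x$reps)))
  cat(sprintf("  mean D (S=0 -> D=0): %.*f  (se %.*f)\n", digits, x$mean_D,
              digits, x$se_D))
  cat(sprintf("  mean D | S >= 1    : %.*f  (se %.*f)\n", digits, x$mean_D_cond,
              digits, x$se_D_cond))
  cat(sprintf("  mean S = %.4g (M*a1 = %.4g), mean k = %.4g, P(S=0) = %.3f\n",
              x$mean_S, x$M * tajima_constants(x$n)$a1, x$mean_k, x$p_S0))
  invisible(x)
}

#' Mean D and S across a grid of mutation rates
#'
#' Simulates neutral equilibrium windows at each value of an increasing
#' grid of window-scaled mutation rates and tabulates the mean number of
#' segregating sites and the mean of Tajima's D under both `S = 0`
#' conventions. The expectations of both `S` and `-D` increase with the
#' mutation rate, so that across loci differing only in mutation rate the
#' level of polymorphism and D are negatively correlated.
#'
#' @param M_grid Strictly increasing numeric vector of window-scaled
#'   mutation rates, at least 3 values.
#' @param n Haploid sample size.
#' @param reps Replicates per grid point.
#' @param seed Optional integer seed (one stream across the whole scan).
#' @return A data frame with columns `M`, `n`, `reps`, `seed`, `mean_S`,
#'   `mean_k`, `mean_D`, `se_D`, `mean_D_cond`, `se_D_cond`, `p_S0`.
#'   Attribute `cor_S_D` holds the correlation, across grid points, of
#'   `mean_S` with `mean_D` (negative: more polymorphic loci have more
#'   negative D).
#' @examples
#' neutral_D_scan(c(0.5, 1, 2), n = 30, reps = 2000, seed = 1)
#' @export
neutral_D_scan <- function(M_grid, n, reps = 1e5, seed = NULL) {
  if (length(M_grid) < 3)
    stop("'M_grid' must contain at least 3 mutation rates")
  if (any(diff(M_grid) <= 0))
    stop("'M_grid' must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(M_grid, function(M) {
    e <- expected_D(M, n, reps = reps, seed = NULL)
    data.frame(M = M, n = n, reps = reps,
               seed = if (is.null(seed)) NA_integer_ else seed,
               mean_S = e$mean_S, mean_k = e$mean_k,
               mean_D = e$mean_D, se_D = e$se_D,
               mean_D_cond = e$mean_D_cond, se_D_cond = e$se_D_cond,
               p_S0 = e$p_S0)
  })
  out <- do.call(rbind, rows)
  attr(out, "cor_S_D") <- if (nrow(out) > 2) cor(out$mean_S, out$mean_D) else NA_real_
  out
}
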