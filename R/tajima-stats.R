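#' Tajima's D from mean pairwise differences and segregating sites
#'
#' Evaluates `D = (k - S/a1) / sqrt(V(S))` for a sample of `n` haploid
#' genomes, where `k` is the (mean) number of pairwise differences per
#' window and `S` the (mean) number of segregating sites. Both `k` and `S`
#' may be non-integer: the statistic is routinely evaluated at window
#' *means* substituted for the per-window values.
#'
#' Two variance forms are available. `"classical"` is Tajima's
#' `V = e1*S + e2*S*(S - 1)`, identically equal to the rearrangement
#' `(e1 - e2)*S + e2*S^2`; it is the form used throughout this package,
#' for integer per-window `S` and for substituted means alike. `"squared"`
#' replaces `S*(S - 1)` by `S^2` (i.e. `V = e1*S + e2*S^2`), which treats
#' the second moment of `S` as the square of its mean; it is provided for
#' comparison and differs appreciably only at small `S`.
#'
#' Windows with `S = 0` have an undefined ratio; by the usual data-analysis
#' convention they are assigned `D = 0`.
#'
#' @param k Mean pairwise differences per window (`>= 0`); vectorised.
#' @param S Segregating sites per window (`>= 0`, possibly non-integer);
#'   vectorised, recycled against `k`.
#' @param n Haploid sample size (single integer `>= 4`), or a
#'   [tajima_constants] object.
#' @param variance `"classical"` (default) or `"squared"`; see Details.
#' @return Numeric vector of D values; exactly 0 where `S = 0`.
#' @examples
#' cst <- tajima_constants(10)
#' tajima_D(5 / cst$a1, 5, 10)   # numerator vanishes -> 0
#' tajima_D(0.3, 5.21, 1135)
#' @export
tajima_D <- function(k, S, n, variance = c("classical", "squared")) {
  variance <- match.arg(variance)
  cst <- if (inherits(n, "tajima_constants")) n else tajima_constants(n)
  if (is.na(cst$e1)) stop("'n' must be >= 4 to compute Tajima's D")
  if (any(!is.finite(k)) || any(!is.finite(S)) || any(k < 0) || any(S < 0))
    stop("'k' and 'S' must be finite and non-negative")
  xs <- cbind(k = k, S = S)   # recycles
  k <- xs[, "k"]; S <- xs[, "S"]
  V <- if (variance == "classical") cst$e1 * S + cst$e2 * S * (S - 1)
       else cst$e1 * S + cst$e2 * S^2
  D <- ifelse(S == 0, 0, (k - S / cst$a1) / sqrt(V))
  unname(D)
}

#' Skew of the site frequency spectrum: delta-theta-w
#'
#' The statistic `1 - pi / theta_w`, where `pi` is pairwise nucleotide
#' diversity and `theta_w` Watterson's diversity (both per site, or both
#' per window — only their ratio enters). Positive values indicate an
#' excess of low-frequency variants relative to the neutral equilibrium
#' expectation `pi = theta_w`; negative values a deficit.
#'
#' @param pi Pairwise diversity (`>= 0`); vectorised.
#' @param theta_w Watterson diversity; vectorised, recycled. Where
#'   `theta_w = 0` the measure is undefined and `NA` is returned (not 0).
#' @return Numeric vector `1 - pi/theta_w`, `NA` where `theta_w = 0`.
#' @examples
#' delta_theta_w(0.003, 0.004)  # 0.25: theta_w a third larger than pi
#' @export
delta_theta_w <- function(pi, theta_w) {
  if (any(pi < 0, na.rm = TRUE) || any(theta_w < 0, na.rm = TRUE))
    stop("'pi' and 'theta_w' must be non-negative")
  xs <- cbind(pi = pi, tw = theta_w)
  unname(ifelse(xs[, "tw"] == 0, NA_real_, 1 - xs[, "pi"] / xs[, "tw"]))
}

#' Window summary statistics from a haplotype matrix
#'
#' Computes the standard windowed diversity statistics from an `n x L`
#' binary haplotype matrix (rows = sampled haploid genomes, columns =
#' sites, entries 0 = ancestral, 1 = derived): the number of segregating
#' sites `S`, the mean pairwise difference count `k` (averaged over all
#' `choose(n, 2)` pairs), per-site `pi = k/L` and `theta_w = S/(L*a1)`,
#' Tajima's `D`, and the skew `delta_theta_w`.
#'
#' A column with derived-allele count `c` (with `0 < c < n`) contributes
#' `c*(n - c)/choose(n, 2)` to `k`; monomorphic columns contribute nothing.
#'
#' @param x Binary matrix with `n >= 4` rows; entries must be 0 or 1.
#' @param L Window length in basepairs; defaults to `ncol(x)`. Supply it
#'   explicitly when the matrix holds only the variable columns of a wider
#'   window.
#' @return An object of class `"window_stats"`: a list with elements
#'   `n`, `L`, `k`, `S`, `pi`, `theta_w`, `D`, `delta_theta_w`.
#'   `D = 0` and `delta_theta_w = NA` when `S = 0`.
#' @examples
#' m <- matrix(0L, 4, 10); m[1, 3] <- 1L  # one singleton among 4 genomes
#' window_stats(m)$k                      # 3/6 = 0.5
#' @export
window_stats <- function(x, L = ncol(x)) {
  if (!is.matrix(x) || nrow(x) < 4)
    stop("'x' must be a matrix with at least 4 rows")
  if (!all(x %in% c(0L, 1L)))
    stop("'x' must contain only 0 (ancestral) and 1 (derived)")
  n <- nrow(x)
  counts <- colSums(x)
  poly <- counts > 0 & counts < n
  S <- sum(poly)
  nC2 <- n * (n - 1) / 2
  k <- sum(counts[poly] * (n - counts[poly])) / nC2
  window_stats_from_kS(k, S, n, L)
}

# Shared constructor: fills the derived fields from (k, S, n, L).
window_stats_from_kS <- function(k, S, n, L, cst = tajima_constants(n)) {
  pi <- k / L
  theta_w <- S / (L * cst$a1)
  out <- list(n = cst$n, L = L, k = k, S = S, pi = pi, theta_w = theta_w,
              D = tajima_D(k, S, cst),
              delta_theta_w = delta_theta_w(pi, theta_w))
  class(out) <- "window_stats"
  out
}

#' @export
print.window_stats <- function(x, digits = 5, ...) {
  cat(sprintf("Window statistics (n = %d, L = %d bp)\n", x$n, as.integer(x$L)))
  v <- c(k = x$k, S = x$S, pi = x$pi, theta_w = x$theta_w,
         D = x$D, delta_theta_w = x$delta_theta_w)
  print(signif(v, digits))
  invisible(x)
}
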