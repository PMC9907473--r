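#' Per-site moments at mutation-selection balance under strong selection
#'
#' For a site under purifying selection so strong that the deleterious
#' variant is held at its deterministic mutation-selection equilibrium
#' frequency `q_bar = u/s` (selection against homozygotes, the relevant
#' case in a highly selfing population), and `q_bar << 1/n`, the chance
#' that the site segregates in a sample of `n` haploid genomes is
#' approximately `n*q_bar`, and a segregating site carries a single copy
#' of the deleterious allele. The per-site contributions are then
#' `pi = 2*q_bar` and `theta_w = n*q_bar/a1`.
#'
#' @param u Per-site per-generation mutation rate, `> 0`.
#' @param s Selection coefficient against mutant homozygotes, `> 0`.
#' @param n Haploid sample size or a [tajima_constants] object.
#' @param h Optional dominance coefficient: if supplied, `q_bar = u/(h*s)`
#'   (selection on heterozygotes); the default (`NULL`) uses `q_bar = u/s`.
#' @return An object of class `"selected_moments"`: a list with `u`, `s`,
#'   `n`, `q_bar`, `seg_prob = n*q_bar`, `pi_site = 2*q_bar`,
#'   `theta_w_site = n*q_bar/a1`, and a logical `valid` which is `FALSE`
#'   when `n*q_bar > 0.1` (the singleton approximation `q_bar << 1/n` is
#'   strained). `n*q_bar >= 1` is an error: the model does not apply.
#' @examples
#' selected_moments(u = 7e-9, s = 7e-5, n = 1135)
#' @export
selected_moments <- function(u, s, n, h = NULL) {
  cst <- if (inherits(n, "tajima_constants")) n else tajima_constants(n)
  if (!is.finite(u) || u <= 0) stop("'u' must be > 0")
  if (!is.finite(s) || s <= 0) stop("'s' must be > 0")
  q_bar <- if (is.null(h)) u / s else u / (h * s)
  seg_prob <- cst$n * q_bar
  if (seg_prob >= 1)
    stop(sprintf(
      "n*q_bar = %.3g >= 1: selection too weak for the singleton model (need s >> n*u)",
      seg_prob))
  out <- list(u = u, s = s, n = cst$n, q_bar = q_bar, seg_prob = seg_prob,
              pi_site = 2 * q_bar, theta_w_site = seg_prob / cst$a1,
              valid = seg_prob <= 0.1)
  class(out) <- "selected_moments"
  out
}

#' @export
print.selected_moments <- function(x, ...) {
  cat(sprintf("Selected-site moments: u = %g, s = %g, n = %d\n", x$u, x$s, x$n))
  cat(sprintf("  q_bar = u/s = %g;  P(segregating) = n*q_bar = %g\n",
              x$q_bar, x$seg_prob))
  cat(sprintf("  per-site pi = %g, theta_w = %g\n", x$pi_site, x$theta_w_site))
  if (!x$valid)
    cat("  [flag] n*q_bar > 0.1: singleton approximation strained\n")
  invisible(x)
}

#' Mixture of neutral and strongly selected sites in a window
#'
#' The central model of the package: an `L`-bp window contains a
#' proportion `p_n` of effectively neutral sites and `1 - p_n` sites under
#' strong purifying selection at mutation-selection balance. Window means
#' add across the two site classes,
#' \deqn{\bar k = p_n \bar k_n + (1-p_n) L \, 2\bar q, \qquad
#'       \bar S = p_n \bar S_n + (1-p_n) L \, n\bar q,}
#' and the mean Tajima's D of the mixed window is approximated by
#' substituting these means into the D formula. The skew is
#' `delta_theta_w = 1 - kbar*a1/Sbar`. The ratio `D_mix / D_n` to the
#' purely neutral mean D is the quantity of interest: with sufficiently
#' strong selection it falls below 1 — windows containing selected sites
#' look *less* skewed by D than neutral windows with the same mutation
#' rate, even though every segregating selected site is a singleton.
#'
#' When the neutral class is at equilibrium (`D_n = 0`), the substituted
#' neutral D vanishes and the ratio is formed against a simulated neutral
#' mean D supplied via `D_ref` (see [expected_D]); the substitution
#' approximation itself is unreliable in that regime.
#'
#' @param neutral A [neutral_summary] describing the purely neutral
#'   sequence class (its `L` and `n` are inherited).
#' @param s Selection coefficient against mutant homozygotes.
#' @param u Per-site mutation rate at the selected sites (default
#'   `7e-9`).
#' @param p_n Proportion of neutral sites in the window, in `[0, 1]`
#'   (default 0.45).
#' @param D_ref Reference neutral mean D for the ratio; defaults to
#'   `neutral$D_n`. Supply a simulated equilibrium mean when `D_n = 0`.
#' @param h Optional dominance coefficient, passed to [selected_moments].
#' @return An object of class `"mixture_model"`: a list with the inputs,
#'   the [selected_moments], and elements `k_mix`, `S_mix`, `pi_mix`,
#'   `theta_w_mix`, `D_mix`, `D_ratio = D_mix/D_ref`, `delta_theta_w_mix`.
#' @examples
#' ns <- neutral_summary(pi_n = 0.003, D_n = -0.9, L = 100, n = 1135)
#' m <- mixture_model(ns, s = 1e-3)
#' m$D_ratio
#' @seealso [strong_selection_D] for the large-`s` closed-form
#'   approximation; [sweep_selection], [sweep_proportion],
#'   [sweep_mutation_contrast] for parameter sweeps;
#'   [simulate.mixture_model] for the coalescent oracle.
#' @export
mixture_model <- function(neutral, s, u = 7e-9, p_n = 0.45,
                          D_ref = neutral$D_n, h = NULL) {
  if (!inherits(neutral, "neutral_summary"))
    stop("'neutral' must be a neutral_summary object")
  if (length(p_n) != 1 || !is.finite(p_n) || p_n < 0 || p_n > 1)
    stop("'p_n' must be a single value in [0, 1]")
  cst <- tajima_constants(neutral$n)
  sel <- selected_moments(u, s, cst, h = h)
  L <- neutral$L
  k_mix <- p_n * neutral$k_n + (1 - p_n) * L * sel$pi_site
  S_mix <- p_n * neutral$S_n + (1 - p_n) * L * sel$seg_prob
  D_mix <- tajima_D(k_mix, S_mix, cst)
  out <- list(neutral = neutral, selected = sel, p_n = p_n, u = u, s = s,
              n = cst$n, L = L, D_ref = D_ref,
              k_mix = k_mix, S_mix = S_mix,
              pi_mix = k_mix / L, theta_w_mix = S_mix / (L * cst$a1),
              D_mix = D_mix,
              D_ratio = if (D_ref != 0) D_mix / D_ref else NA_real_,
              delta_theta_w_mix = if (S_mix > 0) 1 - k_mix * cst$a1 / S_mix
                                  else NA_real_)
  class(out) <- "mixture_model"
  out
}

#' @export
print.mixture_model <- function(x, digits = 4, ...) {
  cat(sprintf("Neutral/selected mixture window (n = %d, L = %d bp)\n",
              x$n, as.integer(x$L)))
  cat(sprintf("  p_n = %g, u = %g, s = %g (q_bar = %g%s)\n", x$p_n, x$u, x$s,
              x$selected$q_bar,
              if (x$selected$valid) "" else "; validity flag raised"))
  cat(sprintf("  neutral: pi_n = %g, D_n = %g, S_n = %.4g\n",
              x$neutral$pi_n, x$neutral$D_n, x$neutral$S_n))
  cat(sprintf("  mixed:   k = %.4g, S = %.4g, D = %.*f\n",
              x$k_mix, x$S_mix, digits, x$D_mix))
  cat(sprintf("  D ratio (mixed/neutral) = %.*f, delta_theta_w = %.*f\n",
              digits, x$D_ratio, digits, x$delta_theta_w_mix))
  invisible(x)
}

#' @export
coef.mixture_model <- function(object, ...) {
  c(p_n = object$p_n, pi_n = object$neutral$pi_n, D_n = object$neutral$D_n,
    u = object$u, s = object$s, q_bar = object$selected$q_bar,
    n = object$n, L = object$L)
}

#' @export
summary.mixture_model <- function(object, ...) {
  print(object)
  cat("\nStrong-selection approximation:\n")
  Dapprox <- tryCatch(strong_selection_D(object), warning = function(w) {
    cat("  [", conditionMessage(w), "]\n", sep = "")
    suppressWarnings(strong_selection_D(object))
  })
  cat(sprintf("  D ~ %.4f (full substitution: %.4f)\n", Dapprox, object$D_mix))
  invisible(object)
}

#' Re-evaluate a mixture model over new selection strengths
#'
#' @param object A [mixture_model].
#' @param s Vector of selection coefficients at which to evaluate.
#' @param ... Unused.
#' @return A data frame with columns `s`, `q_bar`, `valid`, `k_mix`,
#'   `S_mix`, `D_mix`, `D_ratio`, `delta_theta_w_mix`.
#' @export
predict.mixture_model <- function(object, s = object$s, ...) {
  rows <- lapply(s, function(si) {
    m <- mixture_model(object$neutral, s = si, u = object$u,
                       p_n = object$p_n, D_ref = object$D_ref)
    data.frame(s = si, q_bar = m$selected$q_bar, valid = m$selected$valid,
               k_mix = m$k_mix, S_mix = m$S_mix, D_mix = m$D_mix,
               D_ratio = m$D_ratio, delta_theta_w_mix = m$delta_theta_w_mix)
  })
  do.call(rbind, rows)
}

#' Strong-selection closed-form approximation to the mixed mean D
#'
#' Under selection strong enough that selected sites contribute negligibly
#' to the window means, `kbar ~ p_n*kbar_n` and `Sbar ~ p_n*Sbar_n`, and
#' for large samples `e2 << e1`, so the denominator of D reduces to
#' `sqrt(e1*p_n*Sbar_n)` and
#' \deqn{\bar D \approx \frac{p_n(\bar k_n - \bar S_n/a_1)}
#'                           {\sqrt{e_1 p_n \bar S_n}} \propto \sqrt{p_n}.}
#' D is negative whenever the neutral SFS is skewed toward rare variants
#' (`kbar_n < Sbar_n/a1`), and its magnitude *increases* with the
#' proportion of neutral sites, maximal when all sites are neutral. The
#' approximation is invalid when the neutral class is near equilibrium
#' (`D_n` close to 0); a warning is issued in that case.
#'
#' @param object A [mixture_model].
#' @return The approximate mean D (scalar).
#' @export
strong_selection_D <- function(object) {
  if (!inherits(object, "mixture_model"))
    stop("'object' must be a mixture_model")
  cst <- tajima_constants(object$n)
  if (abs(object$neutral$D_n) < 0.05)
    warning("neutral class close to equilibrium (D_n ~ 0): the strong-selection approximation is invalid there")
  k <- object$p_n * object$neutral$k_n
  S <- object$p_n * object$neutral$S_n
  (k - S / cst$a1) / sqrt(cst$e1 * S)
}
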