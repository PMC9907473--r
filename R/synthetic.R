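#' Calibrate an exponential growth rate to a target neutral mean D
#'
#' Finds the exponential growth rate under which simulated neutral
#' windows have a given mean Tajima's D, while the window-scaled mutation
#' rate is rescaled so the realised mean pairwise diversity stays at the
#' target `pi_n` (growth shortens genealogies, so holding diversity fixed
#' requires a higher mutation rate). Growth skews the site frequency
#' spectrum toward rare variants and can only make the mean D more
#' negative than its equilibrium value; a `D_target` above the
#' equilibrium mean is rejected.
#'
#' The mean D is a monotone decreasing function of the growth rate, so a
#' simple bisection on simulated means suffices. Each evaluation first
#' estimates the mean pairwise coalescence time of the genealogy at the
#' candidate growth rate (which fixes the rescaled `M` exactly, since the
#' realised mean `k` is linear in `M`), then simulates windows at that
#' `M` to measure the mean D.
#'
#' @param D_target Target mean neutral D (under the `S=0 -> D=0`
#'   convention), at most the equilibrium mean.
#' @param pi_n Target per-site pairwise diversity.
#' @param n Haploid sample size.
#' @param L Window length in basepairs (default 100).
#' @param reps Windows per Monte-Carlo evaluation (default `3e4`).
#' @param tol Tolerance on the achieved mean D (default 0.01; cannot
#'   meaningfully be below the Monte-Carlo standard error).
#' @param seed Optional integer seed.
#' @param max_iter Maximum bisection iterations (default 40).
#' @return An object of class `"growth_calibration"`: a list with
#'   `growth`, `M` (rescaled window mutation rate), `D_target`, `pi_n`,
#'   `n`, `L`, `mean_D`, `se_D`, `mean_k`, `evaluations`, `seed`.
#' @examples
#' \donttest{
#' cal <- calibrate_growth(-0.5, pi_n = 0.01, n = 50, reps = 5000, seed = 1)
#' }
#' @export
calibrate_growth <- function(D_target, pi_n, n, L = 100, reps = 3e4,
                             tol = 0.01, seed = NULL, max_iter = 40) {
  if (!is.null(seed)) set.seed(seed)
  k_target <- pi_n * L
  evals <- 0L
  eval_g <- function(g) {
    # stage 1: mean pairwise coalescence time fixes the rescaled M
    M_cal <- if (g == 0) k_target else {
      pre <- sim_windows_cpp(max(2000L, as.integer(reps / 5)), as.integer(n),
                             1.0, g)
      k_target / mean(pre[, "tbar2"])
    }
    w <- sim_windows_cpp(as.integer(reps), as.integer(n), M_cal, g)
    D <- tajima_D(w[, "k"], w[, "S"], n)
    evals <<- evals + 1L
    list(M = M_cal, mean_D = mean(D), se_D = sd(D) / sqrt(length(D)),
         mean_k = mean(w[, "k"]))
  }
  e0 <- eval_g(0)
  if (D_target > e0$mean_D + max(tol, 2 * e0$se_D))
    stop(sprintf(
      "D_target = %g exceeds the equilibrium mean D (%.4f): growth can only skew D downward",
      D_target, e0$mean_D))
  if (abs(D_target - e0$mean_D) <= tol) {
    out <- list(growth = 0, M = e0$M, D_target = D_target, pi_n = pi_n,
                n = n, L = L, mean_D = e0$mean_D, se_D = e0$se_D,
                mean_k = e0$mean_k, evaluations = evals, seed = seed)
    class(out) <- "growth_calibration"
    return(out)
  }
  g_lo <- 0; g_hi <- 1
  e_hi <- eval_g(g_hi)
  while (e_hi$mean_D > D_target) {
    g_lo <- g_hi
    g_hi <- g_hi * 2
    if (g_hi > 1e6) stop("failed to bracket the growth rate")
    e_hi <- eval_g(g_hi)
  }
  best <- e_hi; g_best <- g_hi
  for (it in seq_len(max_iter)) {
    g_mid <- (g_lo + g_hi) / 2
    e_mid <- eval_g(g_mid)
    if (abs(e_mid$mean_D - D_target) < abs(best$mean_D - D_target)) {
      best <- e_mid; g_best <- g_mid
    }
    if (abs(e_mid$mean_D - D_target) <= tol) break
    if (e_mid$mean_D > D_target) g_lo <- g_mid else g_hi <- g_mid
  }
  out <- list(growth = g_best, M = best$M, D_target = D_target, pi_n = pi_n,
              n = n, L = L, mean_D = best$mean_D, se_D = best$se_D,
              mean_k = best$mean_k, evaluations = evals, seed = seed)
  class(out) <- "growth_calibration"
  out
}

#' @export
print.growth_calibration <- function(x, ...) {
  cat(sprintf("Growth calibration (n = %d, L = %d bp, pi target %g)\n",
              x$n, as.integer(x$L), x$pi_n))
  cat(sprintf("  growth rate = %.6g, rescaled M = %.4g\n", x$growth, x$M))
  cat(sprintf("  achieved mean D = %.4f (target %.4f, se %.4f), mean k = %.4g\n",
              x$mean_D, x$D_target, x$se_D, x$mean_k))
  cat(sprintf("  %d Monte-Carlo evaluations\n", x$evaluations))
  invisible(x)
}

#' Simulate mixed neutral/selected windows (summary statistics)
#'
#' The simulation oracle for the mixture model: each window consists of
#' `floor(p_n * L)` neutral sites whose variants descend from a single
#' coalescent genealogy (with the calibrated growth rate and rescaled
#' mutation rate), plus `L - floor(p_n * L)` selected sites, each of
#' which independently segregates with probability `n * q_bar` and, when
#' segregating, carries a singleton. Selected sites are independent of
#' the neutral genealogy (no linkage), matching the additive-means
#' structure of the analytic model. Only the per-window `(k, S)` are
#' returned; the full haplotype matrix carries no further information
#' for `D` and `delta_theta_w`.
#'
#' @param reps Number of windows.
#' @param calib A [calibrate_growth] result (or a list with elements
#'   `growth`, `M`, `n`, `L` — `M` the window-scaled neutral mutation
#'   rate for a full window of `L` neutral sites).
#' @param p_n Proportion of neutral sites (default 0.45).
#' @param u,s Mutation rate and selection coefficient at selected sites.
#' @param seed Optional integer seed.
#' @return Data frame with one row per window: `k`, `S`, `D` (with the
#'   `S=0 -> D=0` convention), plus the component columns `k_neut`,
#'   `S_neut`, `S_sel`.
#' @export
sim_mixed_windows <- function(reps, calib, p_n = 0.45, u = 7e-9, s,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- calib$n; L <- calib$L
  cst <- tajima_constants(n)
  L_n <- floor(p_n * L)
  L_s <- L - L_n
  if (L_n > 0) {
    M_frag <- calib$M * L_n / L
    w <- sim_windows_cpp(as.integer(reps), as.integer(n), M_frag,
                         calib$growth)
    k_neut <- w[, "k"]; S_neut <- w[, "S"]
  } else {
    k_neut <- S_neut <- numeric(reps)
  }
  if (L_s > 0) {
    sel <- selected_moments(u, s, cst)
    S_sel <- rbinom(reps, L_s, sel$seg_prob)
  } else {
    S_sel <- integer(reps)
  }
  k <- k_neut + S_sel * 2 / n   # each singleton adds (n-1)/choose(n,2) = 2/n
  S <- S_neut + S_sel
  data.frame(k = k, S = S, D = tajima_D(k, S, cst),
             k_neut = k_neut, S_neut = S_neut, S_sel = S_sel)
}

#' Monte-Carlo mean D and skew of mixed windows
#'
#' Runs [sim_mixed_windows] and summarises: the mean Tajima's D under the
#' `S=0 -> D=0` convention (with Monte-Carlo standard error), the mean
#' conditioned on `S >= 1`, and the skew measured two ways — from the
#' ratio of the mean `k` and mean `S` (`delta_sub`, the substituted form
#' the analytic model uses) and as the mean of the per-window
#' `delta_theta_w` over windows with `S >= 1` (`mean_delta`).
#'
#' @inheritParams sim_mixed_windows
#' @return An object of class `"oracle_mean_D"`: a list with `reps`,
#'   `mean_D`, `se_D`, `mean_D_cond`, `se_D_cond`, `delta_sub`,
#'   `mean_delta`, `se_delta`, `mean_k`, `mean_S`, `p_S0`, `seed`.
#' @export
oracle_mean_D <- function(reps, calib, p_n = 0.45, u = 7e-9, s,
                          seed = NULL) {
  w <- sim_mixed_windows(reps, calib, p_n = p_n, u = u, s = s, seed = seed)
  cst <- tajima_constants(calib$n)
  seg <- w$S > 0
  dl <- 1 - w$k[seg] * cst$a1 / w$S[seg]
  out <- list(reps = reps, p_n = p_n, u = u, s = s,
              mean_D = mean(w$D), se_D = sd(w$D) / sqrt(nrow(w)),
              mean_D_cond = mean(w$D[seg]),
              se_D_cond = sd(w$D[seg]) / sqrt(sum(seg)),
              delta_sub = 1 - mean(w$k) * cst$a1 / mean(w$S),
              mean_delta = mean(dl), se_delta = sd(dl) / sqrt(length(dl)),
              mean_k = mean(w$k), mean_S = mean(w$S), p_S0 = mean(!seg),
              seed = seed)
  class(out) <- "oracle_mean_D"
  out
}

#' @export
print.oracle_mean_D <- function(x, ...) {
  cat(sprintf("Simulated mixed windows (%d reps; p_n = %g, u = %g, s = %g)\n",
              as.integer(x$reps), x$p_n, x$u, x$s))
  cat(sprintf("  mean D = %.4f (se %.4f); conditional on S>=1: %.4f (se %.4f)\n",
              x$mean_D, x$se_D, x$mean_D_cond, x$se_D_cond))
  cat(sprintf("  delta_theta_w: substituted %.4f, per-window mean %.4f (se %.4f)\n",
              x$delta_sub, x$mean_delta, x$se_delta))
  cat(sprintf("  mean k = %.4g, mean S = %.4g, P(S=0) = %.3f\n",
              x$mean_k, x$mean_S, x$p_S0))
  invisible(x)
}

#' Generate one mixed window as a haplotype matrix
#'
#' Full-resolution counterpart of [sim_mixed_windows]: returns the
#' `n x L` binary haplotype matrix of one window. Columns
#' `1..floor(p_n*L)` are the neutral sites (variants from one coalescent
#' genealogy, each mutation assigned to a distinct neutral column); the
#' remaining columns are selected sites, each independently a singleton
#' (on a uniformly chosen haplotype) with probability `n * q_bar`, else
#' monomorphic. Derived alleles are coded 1.
#'
#' @inheritParams sim_mixed_windows
#' @param p_n Proportion of neutral sites; `p_n = 1` gives a purely
#'   neutral window.
#' @param u,s Selected-site mutation rate and selection coefficient
#'   (ignored when `p_n = 1`).
#' @return Integer matrix of 0/1 with `n` rows and `L` columns.
#' @examples
#' cal <- list(growth = 0, M = 1, n = 12, L = 100)
#' m <- generate_mixed_window(cal, p_n = 1, seed = 1)
#' window_stats(m)
#' @export
generate_mixed_window <- function(calib, p_n = 0.45, u = 7e-9, s = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- calib$n; L <- calib$L
  L_n <- floor(p_n * L)
  L_s <- L - L_n
  mat <- matrix(0L, n, L)
  if (L_n > 0) {
    carriers <- sim_window_carriers_cpp(as.integer(n),
                                        calib$M * L_n / L, calib$growth)
    nm <- length(carriers)
    if (nm > L_n)
      stop(sprintf(
        "window drew %d neutral mutations but has only %d neutral sites; infinite-sites placement impossible",
        nm, L_n))
    if (nm > 0) {
      cols <- if (nm == 1) sample.int(L_n, 1) else sample.int(L_n, nm)
      for (z in seq_len(nm)) mat[carriers[[z]], cols[z]] <- 1L
    }
  }
  if (L_s > 0) {
    if (is.null(s)) stop("'s' must be supplied when p_n < 1")
    sel <- selected_moments(u, s, n)
    hit <- runif(L_s) < sel$seg_prob
    if (any(hit)) {
      rows <- sample.int(n, sum(hit), replace = TRUE)
      mat[cbind(rows, L_n + which(hit))] <- 1L
    }
  }
  mat
}

#' Simulate windows from a mixture model
#'
#' Draws mixed windows from the generative counterpart of a
#' [mixture_model]: the neutral sites follow a coalescent whose growth
#' rate has been calibrated so purely neutral windows match the model's
#' `(pi_n, D_n)`, and the selected sites are independent singletons.
#' Supply a pre-computed [calibrate_growth] result via `calib` to avoid
#' re-running the calibration.
#'
#' @param object A [mixture_model].
#' @param nsim Number of windows (default 1000).
#' @param seed Optional integer seed.
#' @param calib Optional [calibrate_growth] result matching the model's
#'   neutral class; computed if omitted (`reps_cal` windows per
#'   calibration step).
#' @param reps_cal Calibration replicates when `calib` is omitted.
#' @param ... Unused.
#' @return The [sim_mixed_windows] data frame, with the calibration
#'   attached as attribute `"calib"`.
#' @export
simulate.mixture_model <- function(object, nsim = 1000, seed = NULL,
                                   calib = NULL, reps_cal = 3e4, ...) {
  if (is.null(calib))
    calib <- calibrate_growth(object$neutral$D_n, object$neutral$pi_n,
                              object$n, object$L, reps = reps_cal,
                              seed = seed)
  w <- sim_mixed_windows(nsim, calib, p_n = object$p_n, u = object$u,
                         s = object$s, seed = seed)
  attr(w, "calib") <- calib
  w
}
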