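#' Default selection-coefficient grid
#'
#' Log2-spaced selection coefficients spanning the regimes from near
#' model breakdown (weak selection, `q_bar` approaching `1/n`) to
#' saturation (selected sites effectively never segregate), clipped to
#' the validity region `n*q_bar < 1` of the singleton model.
#'
#' @param n Haploid sample size.
#' @param u Per-site mutation rate at selected sites.
#' @param points Number of grid points before clipping (default 16).
#' @param range Range of `s` (default `c(1e-6, 1e-2)`).
#' @return Increasing numeric vector of selection coefficients with
#'   `n*u/s < 1`.
#' @export
default_s_grid <- function(n = 1135, u = 7e-9, points = 16,
                           range = c(1e-6, 1e-2)) {
  s <- 2^seq(log2(range[1]), log2(range[2]), length.out = points)
  keep <- n * u / s < 1
  if (!all(keep))
    message(sprintf("dropping %d grid point(s) with n*q_bar >= 1 (model invalid)",
                    sum(!keep)))
  s[keep]
}

# One long-format row of a sweep table.
mixture_sweep_row <- function(neutral, s, u, p_n, D_ref, panel, cst) {
  m <- mixture_model(neutral, s = s, u = u, p_n = p_n, D_ref = D_ref)
  data.frame(panel = panel, p_n = p_n, pi_n = neutral$pi_n,
             D_n = neutral$D_n, D_ref = D_ref, u = u, s = s,
             q_bar = m$selected$q_bar, valid = m$selected$valid,
             k_mix = m$k_mix, S_mix = m$S_mix, D_mix = m$D_mix,
             D_ratio = m$D_ratio,
             delta_theta_w_mix = m$delta_theta_w_mix,
             delta_theta_w_n = neutral$delta_theta_w)
}

# Resolve a neutral class for a sweep: numeric D_n -> inversion;
# "equilibrium" -> S_n = k_n*a1 with a simulated reference mean D.
resolve_neutral <- function(D_n, pi_n, L, cst, eq_ref) {
  if (identical(D_n, "equilibrium")) {
    ns <- neutral_summary(pi_n = pi_n, D_n = 0, L = L, n = cst)
    M <- pi_n * L
    key <- sprintf("%.10g", M)
    list(ns = ns, D_ref = eq_ref[[key]], label = "equilibrium")
  } else {
    ns <- neutral_summary(pi_n = pi_n, D_n = D_n, L = L, n = cst)
    list(ns = ns, D_ref = D_n, label = sprintf("D_n=%g", D_n))
  }
}

# Simulated equilibrium mean D for every M needed by a sweep.
equilibrium_refs <- function(M_values, n, reps_eq, seed) {
  if (!is.null(seed)) set.seed(seed)
  refs <- list()
  for (M in unique(M_values))
    refs[[sprintf("%.10g", M)]] <- expected_D(M, n, reps = reps_eq)$mean_D
  refs
}

#' Sweep of the mixed-window D ratio over selection strength
#'
#' Evaluates the mixture model over a grid of selection coefficients for
#' several neutral diversities (i.e. mutation rates: `u` is scaled in
#' proportion to `pi_n`, with `u_ref` at `pi_ref`) and several neutral
#' mean D values, including the no-skew equilibrium case. Produces the
#' long-format table behind the classic two-axis display: the ratio
#' `D_mix/D_n` (solid curves, left axis) and `delta_theta_w` of the mixed
#' sequence (dashed curves, right axis) against `log2(s)`.
#'
#' In the equilibrium rows the substituted neutral D is zero, so the
#' ratio is formed against a simulated equilibrium mean D (`reps_eq`
#' windows per mutation rate); `delta_theta_w_mix` there is independent
#' of the mutation rate because both window means are proportional to `u`.
#'
#' @param s_grid Selection coefficients; default [default_s_grid].
#' @param pi_n_set Neutral per-site diversities (default
#'   `c(0.0015, 0.003, 0.006)`).
#' @param D_n_set Neutral mean D values; a list that may mix numbers and
#'   the string `"equilibrium"` (default
#'   `list(-0.9, -0.45, -0.225, "equilibrium")`).
#' @param p_n Proportion of neutral sites (default 0.45).
#' @param n,L Sample size and window length (defaults 1135, 100).
#' @param u_ref,pi_ref Reference mutation rate and the diversity it
#'   corresponds to (defaults `7e-9`, `0.003`); each `pi_n` uses
#'   `u = u_ref * pi_n / pi_ref`.
#' @param reps_eq Replicates for the simulated equilibrium reference mean
#'   D (default `2e5`).
#' @param seed Seed for the equilibrium simulation.
#' @return A long-format data frame with columns `panel`, `p_n`, `pi_n`,
#'   `D_n`, `D_ref`, `u`, `s`, `q_bar`, `valid`, `k_mix`, `S_mix`,
#'   `D_mix`, `D_ratio`, `delta_theta_w_mix`, `delta_theta_w_n`.
#' @examples
#' tab <- sweep_selection(s_grid = c(1e-4, 1e-3), pi_n_set = 0.003,
#'                        D_n_set = list(-0.9), n = 200, reps_eq = 100)
#' @export
sweep_selection <- function(s_grid = NULL,
                            pi_n_set = c(0.0015, 0.003, 0.006),
                            D_n_set = list(-0.9, -0.45, -0.225, "equilibrium"),
                            p_n = 0.45, n = 1135, L = 100,
                            u_ref = 7e-9, pi_ref = 0.003,
                            reps_eq = 2e5, seed = NULL) {
  cst <- tajima_constants(n)
  u_max <- u_ref * max(pi_n_set) / pi_ref
  if (is.null(s_grid)) s_grid <- default_s_grid(n, u_max)
  needs_eq <- any(vapply(D_n_set, identical, logical(1), y = "equilibrium"))
  eq_ref <- if (needs_eq)
    equilibrium_refs(pi_n_set * L, n, reps_eq, seed) else list()
  rows <- list()
  for (D_n in D_n_set) for (pi_n in pi_n_set) {
    u <- u_ref * pi_n / pi_ref
    nr <- resolve_neutral(D_n, pi_n, L, cst, eq_ref)
    for (s in s_grid[n * u / s_grid < 1])
      rows[[length(rows) + 1L]] <-
        mixture_sweep_row(nr$ns, s, u, p_n, nr$D_ref, nr$label, cst)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep of the mixed-window D ratio over the neutral-site proportion
#'
#' Evaluates the mixture model over a grid of neutral-site proportions
#' `p_n` at fixed neutral diversity and skew, across a grid of selection
#' coefficients. At `p_n = 1` the window is purely neutral and the ratio
#' is identically 1. A `log2_D_ratio` column is included since the ratio
#' spans orders of magnitude across `p_n`.
#'
#' @param p_n_grid Neutral-site proportions (default
#'   `c(0.25, 0.45, 0.65, 0.85)`).
#' @param s_grid Selection coefficients; default [default_s_grid].
#' @param pi_n,D_n Neutral diversity and mean D (defaults 0.003, -0.9).
#' @param n,L,u As in [sweep_selection]; `u` applies to both site classes.
#' @return Long-format data frame as in [sweep_selection], plus
#'   `log2_D_ratio`.
#' @export
sweep_proportion <- function(p_n_grid = c(0.25, 0.45, 0.65, 0.85),
                             s_grid = NULL, pi_n = 0.003, D_n = -0.9,
                             n = 1135, L = 100, u = 7e-9) {
  cst <- tajima_constants(n)
  if (is.null(s_grid)) s_grid <- default_s_grid(n, u)
  ns <- neutral_summary(pi_n = pi_n, D_n = D_n, L = L, n = cst)
  rows <- list()
  for (p in p_n_grid) for (s in s_grid)
    rows[[length(rows) + 1L]] <-
      mixture_sweep_row(ns, s, u, p, D_n, sprintf("p_n=%g", p), cst)
  out <- do.call(rbind, rows)
  out$log2_D_ratio <- ifelse(out$D_ratio > 0, log2(out$D_ratio), NA_real_)
  rownames(out) <- NULL
  out
}

#' Mixed windows versus purely neutral windows of twice the mutation rate
#'
#' Contrasts a purely neutral reference sequence with mutation rate
#' `u_neutral` and diversity `pi_neutral` against mixed windows whose
#' sites mutate at the lower rate `u_mixed` (neutral-site diversity
#' scaled accordingly: `pi_mixed = pi_neutral * u_mixed / u_neutral`).
#' This is the configuration in which a genuine mutation-rate difference
#' and a neutral/selected mixture can produce similar reductions in the
#' magnitude of D. Evaluated across selection coefficients for several
#' neutral mean D values including the no-skew equilibrium case.
#'
#' @param s_grid Selection coefficients; default [default_s_grid].
#' @param D_n_set Neutral mean D values, possibly including
#'   `"equilibrium"` (default `list(-0.9, -0.45, -0.225, "equilibrium")`).
#' @param pi_neutral Diversity of the purely neutral reference
#'   (default 0.006).
#' @param u_neutral,u_mixed Mutation rates of the neutral reference and
#'   of the mixed windows (defaults `1.4e-8`, `7e-9`).
#' @param p_n,n,L As in [sweep_selection].
#' @param reps_eq,seed Equilibrium-reference simulation controls.
#' @return Long-format data frame as in [sweep_selection], plus
#'   `log2_D_ratio`; `pi_n` is the mixed windows' neutral-site diversity.
#' @export
sweep_mutation_contrast <- function(s_grid = NULL,
                                    D_n_set = list(-0.9, -0.45, -0.225,
                                                   "equilibrium"),
                                    pi_neutral = 0.006,
                                    u_neutral = 1.4e-8, u_mixed = 7e-9,
                                    p_n = 0.45, n = 1135, L = 100,
                                    reps_eq = 2e5, seed = NULL) {
  cst <- tajima_constants(n)
  if (is.null(s_grid)) s_grid <- default_s_grid(n, u_mixed)
  pi_mixed <- pi_neutral * u_mixed / u_neutral
  needs_eq <- any(vapply(D_n_set, identical, logical(1), y = "equilibrium"))
  eq_ref <- if (needs_eq)
    equilibrium_refs(pi_neutral * L, n, reps_eq, seed) else list()
  rows <- list()
  for (D_n in D_n_set) {
    # reference: purely neutral sequence at the higher mutation rate
    ref <- resolve_neutral(D_n, pi_neutral, L, cst, eq_ref)
    # mixed windows: neutral sites at the lower rate, same skew target
    mix_ns <- if (identical(D_n, "equilibrium"))
      neutral_summary(pi_n = pi_mixed, D_n = 0, L = L, n = cst)
    else
      neutral_summary(pi_n = pi_mixed, D_n = D_n, L = L, n = cst)
    for (s in s_grid)
      rows[[length(rows) + 1L]] <-
        mixture_sweep_row(mix_ns, s, u_mixed, p_n, ref$D_ref, ref$label, cst)
  }
  out <- do.call(rbind, rows)
  out$log2_D_ratio <- ifelse(out$D_ratio > 0, log2(out$D_ratio), NA_real_)
  rownames(out) <- NULL
  out
}

#' Two-axis plot of a sweep table
#'
#' Draws the classic display for one panel of a sweep table: solid curves
#' for the D ratio (left axis) and dashed curves for `delta_theta_w` of
#' the mixed sequence (right axis), against `log2(s)`, one colour per
#' grouping value (`pi_n` or `p_n`).
#'
#' @param tab A table from [sweep_selection], [sweep_proportion] or
#'   [sweep_mutation_contrast].
#' @param panel Which `panel` value to draw (default: first).
#' @param group Column to colour by (default `"pi_n"`).
#' @return Invisibly, the subset plotted.
#' @export
plot_sweep <- function(tab, panel = tab$panel[1], group = "pi_n") {
  d <- tab[tab$panel == panel, ]
  if (nrow(d) == 0) stop("no rows for panel ", panel)
  gs <- sort(unique(d[[group]]))
  cols <- seq_along(gs)
  op <- par(mar = c(4.5, 4.2, 2.5, 4.2))
  on.exit(par(op))
  plot(NA, xlim = range(log2(d$s)), ylim = range(d$D_ratio, na.rm = TRUE),
       xlab = expression(log[2](s)), ylab = "mean D ratio (mixed / neutral)",
       main = panel)
  for (i in seq_along(gs))
    lines(log2(d$s[d[[group]] == gs[i]]), d$D_ratio[d[[group]] == gs[i]],
          col = cols[i], lty = 1)
  par(new = TRUE)
  plot(NA, xlim = range(log2(d$s)),
       ylim = range(d$delta_theta_w_mix, na.rm = TRUE),
       axes = FALSE, xlab = "", ylab = "")
  axis(4)
  mtext(expression(Delta * theta[w]), side = 4, line = 2.5)
  for (i in seq_along(gs))
    lines(log2(d$s[d[[group]] == gs[i]]),
          d$delta_theta_w_mix[d[[group]] == gs[i]], col = cols[i], lty = 2)
  legend("bottomright", legend = paste(group, "=", gs), col = cols, lty = 1,
         bty = "n", cex = 0.8)
  invisible(d)
}
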