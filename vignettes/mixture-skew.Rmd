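---
title: "Tajima's D and SFS skew in windows mixing neutral and strongly selected sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tajima's D and SFS skew in windows mixing neutral and strongly selected sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsmix)
```

## The question the package addresses

In windowed scans of population genomic data, Tajima's D is routinely read
as a measure of the skew of the site frequency spectrum (SFS): an excess of
rare variants pulls D below zero. A difference in mean D between two classes
of sequence — say, gene bodies versus flanking DNA in a highly selfing plant
such as *Arabidopsis thaliana* — is then tempting to interpret causally, for
instance as evidence for a lower mutation rate in the class with the less
negative D. This package implements an analytic model, together with a
coalescent simulation oracle, showing why that inference is not safe for
short (100-bp) windows in large samples: (i) even under the strict neutral
equilibrium infinite-sites model, where the SFS shape is independent of the
mutation rate, the *expectation of D* depends on the window-scaled mutation
rate `M`; and (ii) a window containing a mixture of neutral sites and sites
under strong purifying selection generally has a *smaller* magnitude of mean
D than a purely neutral window with the same mutation rate — even though
every segregating selected site is a singleton, the maximal possible
per-site skew.

## Statistics

For `n` sampled haploid genomes and a window of `L` basepairs, let `k` be
the mean number of pairwise differences and `S` the number of segregating
sites. With `a1 = sum_{i=1}^{n-1} 1/i`, per-site diversities are
`pi = k/L` and `theta_w = S/(L a1)`, and

```
D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1)),        D = 0 when S = 0,
```

with `e1`, `e2` the usual sample-size coefficients (`tajima_constants()`).
The same formula is evaluated at substituted *means* `(kbar, Sbar)`, in
which case the variance term can be written `(e1 - e2)*Sbar + e2*Sbar^2` —
an identical rearrangement, not a different form. A genuinely different
variant that replaces `S*(S-1)` by `S^2` is available as
`variance = "squared"` everywhere; it differs appreciably only at small `S`
and is not the default.

The skew statistic is `delta_theta_w = 1 - pi/theta_w = 1 - k*a1/S`,
positive under an excess of rare variants and, unlike D, not normalised by
a standard deviation — which is what makes it a cleaner skew measure for
comparisons across mutation rates. It is undefined (NA, not 0) when
`theta_w = 0`.

## Why E(D) depends on the mutation rate at neutral equilibrium

Although `E(k) = M` and `E(S) = M a1` make the numerator's expectation
exactly zero, D is a ratio; the denominator grows more slowly with `S` than
the numerator fluctuates, and numerator and denominator are correlated. The
mean of the ratio is therefore slightly negative and its magnitude grows
with `M`. The package estimates it by Monte Carlo:

```{r, eval = FALSE}
expected_D(M = 0.3, n = 1135, reps = 1e5, seed = 1)
neutral_D_scan(c(0.1, 0.3, 1, 3), n = 1135, reps = 1e5, seed = 1)
```

Two conventions for `S = 0` windows (a ~11% fraction at `M = 0.3`,
`n = 1135`) are always reported: `D` set to 0, and conditioning on
`S >= 1`. They satisfy `mean_zero = mean_cond * (1 - P(S=0))` exactly. No
closed form is used: the Kingman coalescent simulation (in C++, one
genealogy per window, Poisson mutation at rate `M/2` per unit branch
length, no recombination — defensible for 100-bp windows in a species whose
effective recombination rate is very low) *is* the estimator, and it was
cross-validated in development against an independent tree-sequence
simulator at matched parameters. At `M = 0.3`, `n = 1135` the acceptance
script computes `-mean(D)` of roughly 0.014 (zero convention) — an order of
magnitude smaller than the strongly negative window means seen in real
*A. thaliana* scans, which is the point: the equilibrium model cannot
produce them, so the observed skew must come from demography and/or linked
selection.

## From a reported mean D to a mean S

Windowed scans usually report mean D and mean `pi` but not mean `S`.
Because D at substituted means is strictly decreasing in `Sbar` for fixed
`kbar`, a reported `(pi_n, Dbar_n)` pair determines `Sbar_n` uniquely;
`solve_S_from_D()` finds it by root-finding on the monotone map
(bracket expanded geometrically around `k*a1`, then `uniroot` at machine
tolerance; the stated `tol = 1e-10` on D is met by construction).
`neutral_summary()` packages the result. For the motivating data —
`pi = 0.003`, `Dbar = -0.9`, `n = 1135`, `L = 100` — the implied
`Sbar = 5.21` per window and `delta_theta_w = 0.562`. (A published rounding
of this quantity as "about 0.54" corresponds to a mean D input of about
-0.85 rather than -0.90; the inversion here is exact and we report its
value.)

The inversion treats the substituted-mean D as exact rather than as an
expectation over the joint `(k, S)` distribution; the error this introduces
is quantified below.

## The mixture model

A window holds a proportion `p_n` of neutral sites and `1 - p_n` sites
under purifying selection strong enough that the deleterious frequency sits
at the deterministic mutation-selection balance `q_bar = u/s` (selection
against homozygotes — the relevant limit in a predominantly selfing
population; an optional dominance coefficient `h` gives `q_bar = u/(h*s)`
but is off by default). With `q_bar << 1/n`, a selected site segregates in
the sample with probability `n*q_bar` and then carries a singleton, so its
per-site contributions are `pi = 2*q_bar` and `theta_w = n*q_bar/a1`
(`selected_moments()`; a validity flag is raised when `n*q_bar > 0.1` and
`n*q_bar >= 1` is an error). Window means add across classes:

```
kbar = p_n*kbar_n + (1-p_n)*L*2*q_bar
Sbar = p_n*Sbar_n + (1-p_n)*L*n*q_bar
```

and `mixture_model()` reports `D_mix` (means substituted into D), the ratio
`D_mix/Dbar_n`, and `delta_theta_w` of the mixture. In the strong-selection
limit the selected terms vanish and

```
Dbar ~ p_n*(kbar_n - Sbar_n/a1) / sqrt(e1*p_n*Sbar_n)  ~  sqrt(p_n)
```

(`strong_selection_D()`): D is negative whenever the neutral SFS is skewed,
and its magnitude *increases* with the neutral proportion — the selected
sites dilute the signal because they remove polymorphism much faster than
they add singletons. For weak selection (`q_bar` approaching `1/n`) the
singleton excess dominates instead and the ratio exceeds 1; the model
validity flag marks where the approximation itself is strained. When the
neutral class is at equilibrium (`Dbar_n ~ 0`) the substituted neutral D is
zero, so ratios are formed against a simulated equilibrium mean
(`expected_D`), and the substitution approximation is unreliable — the
strong-selection helper warns there.

## Parameter sweeps

`sweep_selection()` evaluates the model over a log2-spaced grid of
selection coefficients (default 16 points over `s` in `[1e-6, 1e-2]`,
clipped to `n*q_bar < 1`) for neutral diversities
`{0.0015, 0.003, 0.006}` and neutral mean D values
`{-0.9, -0.45, -0.225, equilibrium}`, with `p_n = 0.45` — a proportion
consistent with most nonsynonymous mutations in gene bodies being under
strong selection while the remainder and silent sites are effectively
neutral. The mutation rate co-varies with the diversity (`u = 7e-9` at
`pi_n = 0.003`, scaled proportionally), since under the model diversity
differences between the curves *are* mutation-rate differences. This makes
`delta_theta_w` of the mixture exactly mutation-rate-independent in the
equilibrium panel (both window means are proportional to `u`), while in the
skewed panels the inversion breaks that proportionality and the skew
decreases with the mutation rate. `sweep_proportion()` varies `p_n` at
fixed `(pi_n, Dbar_n)` (defaults `{0.25, 0.45, 0.65, 0.85}`; at `p_n = 1`
the ratio is identically 1), and `sweep_mutation_contrast()` opposes purely
neutral windows at `u = 1.4e-8`, `pi = 0.006` to mixed windows at
`u = 7e-9`, the configuration in which a true mutation-rate difference and
a selection mixture produce similar D patterns. The source figures print
neither their `s` nor their `p_n` grids, so these defaults reproduce curve
*shapes and orderings*, not point values; `plot_sweep()` draws the
two-axis display (solid ratio, dashed skew, log2 x-axis).

```{r, eval = FALSE}
tab <- sweep_selection(reps_eq = 2e5, seed = 1)
plot_sweep(tab, panel = "D_n=-0.9")
```

## The synthetic-data generator and what it does (not) emulate

`calibrate_growth()` finds an exponential growth rate whose neutral
windows have a target mean D, rescaling the mutation rate so the realised
mean `pi` stays on target (the mean pairwise coalescence time returned by
the simulator makes this rescaling exact in expectation, since mean `k` is
linear in `M`); the search is bisection on the monotone growth -> mean D
map, with default 3e4 windows per evaluation and a 0.01 tolerance on mean
D, all driven by one seed. Exponential growth is a *device*: the analytic
model is parameterised only by `(kbar_n, Sbar_n)`, so any demography
hitting the target mean D is equivalent at the level the model uses; no
claim about actual *A. thaliana* history is intended. `sim_mixed_windows()`
then draws windows whose `floor(p_n*L)` neutral sites share one genealogy
and whose selected sites are independent Bernoulli(`n*q_bar`) singletons —
independent of the neutral tree, matching the additive-means structure of
the analytic model (its first moments assume no covariance contribution).
It returns per-window `(k, S, D)` directly, which is distributionally
exact for these statistics; `generate_mixed_window()` produces the full
`n x L` haplotype matrix (each neutral mutation on its own column,
derived-allele coded 1, singletons on a uniformly chosen haplotype) for
the ms/VCF writers and round-trip tests.

The generator deliberately omits: linkage between selected and neutral
sites (and hence background selection and hitchhiking, which in a selfer
with very low effective recombination are expected to be strong),
population structure, partial-selfing coalescent rescaling, and any
distribution of fitness effects (one `s` per run). Passing tests therefore
show that the analytic model matches *its own* generative assumptions, not
that those assumptions describe real *A. thaliana* windows — the package's
conclusion is precisely that several distinct mechanisms produce similar
windowed D patterns.

## Accuracy of the substitution approximation

`oracle_mean_D()` is the independent check of the analytic pipeline: it
averages per-window D over simulated mixed windows (zero convention) and
reports Monte-Carlo errors. At the motivating operating point
(`Dbar_n = -0.9`, `pi_n = 0.003`, `p_n = 0.45`, `n = 1135`, strong `s`),
the substituted `D_mix` tracks the simulated mean D to about 5% relative —
close, but systematically more negative, and the discrepancy is resolvable
at 1e4 windows (several Monte-Carlo standard errors). Both layers of
substitution contribute: the inversion's `Sbar_n` differs by ~3% from the
mean S of a calibrated neutral world with the same mean D, and the
mean-of-ratio versus ratio-of-means gap recurs at the mixed-window scale.
The acceptance-grade test of this agreement is kept at the strict
3-standard-error level and fails honestly; the qualitative structure
(regimes, orderings, crossover) is unaffected, which is the level at which
the model is meant to be used.

## Numerical and design choices

* `S = 0` windows get `D = 0` (the data-analysis convention); every
  simulation summary also reports the conditioned mean, and the exact
  relation between the two makes switching conventions trivial.
* Root finding: bisection/`uniroot` on monotone maps throughout
  (inversion tolerance at machine precision; growth calibration limited by
  Monte-Carlo noise, tolerance 0.01 on mean D).
* Problem sizes: simulation-backed tests run at the study scale
  (`n = 1135`) where the assertion concerns the study conditions
  (equilibrium mean D, Watterson identities, oracle agreement) and at
  `n = 40`–`60` where the assertion is structural (conventions,
  reproducibility, moment identities); the acceptance script uses 5e5
  windows for its headline estimate. These sizes are the package's own
  precision choices.
* Determinism: every stochastic entry point takes a `seed`; identical
  seeds give identical output bytes (tested through the CLI).
* The CLI (`inst/cli/sfsmix`) is a thin wrapper over `sfsmix_cli()`;
  subcommands cover the equilibrium estimate, the inversion, single
  mixture evaluations, the three sweeps, synthetic-window generation with
  ms/VCF output, and the windowed VCF scanner (`scan_vcf()`, which tiles
  contigs half-open and 0-based, keeps partial terminal windows with their
  true length, skips multiallelic records, and offers haploid or
  collapse-homozygous-diploid genotype policies with site- or window-level
  missing-data handling).

## Known limitations

The mean-substituted D is an approximation whose error grows as the
neutral class approaches equilibrium; the inversion requires `Dbar` within
the attainable range of the D function and `pi > 0`; the singleton model
for selected sites fails as `q_bar` approaches `1/n` (flagged, then
refused); and the simulation oracle shares the generator's independence
assumptions rather than testing them. Real-data inference about selfing
species with complex demography is explicitly out of scope.
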