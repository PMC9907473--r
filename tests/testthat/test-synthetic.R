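test_that("growth calibration returns zero growth at the equilibrium mean", {
  # at n = 50, M = 1 the equilibrium mean D is about -0.045
  cal <- calibrate_growth(-0.045, pi_n = 0.01, n = 50, reps = 5000,
                          tol = 0.03, seed = 21)
  expect_equal(cal$growth, 0)
  expect_equal(cal$M, 1)
  expect_error(calibrate_growth(0.3, pi_n = 0.01, n = 50, reps = 3000,
                                seed = 2), "equilibrium")
})

test_that("calibration hits the target mean D while preserving diversity", {
  cal <- calibrate_growth(-0.5, pi_n = 0.01, n = 50, reps = 8000,
                          tol = 0.02, seed = 31)
  expect_gt(cal$growth, 0)
  expect_lt(abs(cal$mean_D - (-0.5)), 0.02 + 2 * cal$se_D)
  expect_equal(cal$mean_k, 1, tolerance = 0.05)   # pi held at target
  expect_gt(cal$M, 1)   # growth requires a higher mutation rate for same pi
  # a milder skew target needs a smaller growth rate
  cal2 <- calibrate_growth(-0.25, pi_n = 0.01, n = 50, reps = 8000,
                           tol = 0.02, seed = 32)
  expect_lt(cal2$growth, cal$growth)
})

test_that("selected sites obey the singleton-model moments", {
  # pure selected window: S ~ Binomial(L, n*q_bar), every variant a singleton
  cal <- list(growth = 0, M = 1, n = 100, L = 200)
  s <- 2e-5; u <- 7e-9
  sm <- selected_moments(u, s, 100)
  w <- sim_mixed_windows(4000, cal, p_n = 0, u = u, s = s, seed = 41)
  expect_true(all(w$k_neut == 0) && all(w$S_neut == 0))
  se <- sd(w$S_sel) / sqrt(nrow(w))
  expect_lt(abs(mean(w$S_sel) - 200 * sm$seg_prob), 3 * se)
  # per-site pi at selected sites ~ 2*q_bar
  pi_sel <- mean(w$k) / 200
  se_pi <- sd(w$k / 200) / sqrt(nrow(w))
  expect_lt(abs(pi_sel - sm$pi_site), 3 * se_pi)
  # each singleton contributes exactly 2/n to k
  expect_equal(w$k, w$S_sel * 2 / 100)
})

test_that("purely neutral mixed windows match the equilibrium module", {
  cal <- list(growth = 0, M = 1, n = 60, L = 100)
  w <- sim_mixed_windows(20000, cal, p_n = 1, s = 1, seed = 51)
  cst <- tajima_constants(60)
  expect_lt(abs(mean(w$S) - cst$a1) , 3 * sd(w$S) / sqrt(nrow(w)))
  expect_lt(abs(mean(w$k) - 1), 3 * sd(w$k) / sqrt(nrow(w)))
  e <- expected_D(M = 1, n = 60, reps = 20000, seed = 52)
  se_comb <- sqrt((sd(w$D) / sqrt(nrow(w)))^2 + e$se_D^2)
  expect_lt(abs(mean(w$D) - e$mean_D), 3 * se_comb)
})

test_that("oracle summary is internally consistent", {
  cal <- list(growth = 0, M = 0.8, n = 60, L = 100)
  o <- oracle_mean_D(5000, cal, p_n = 0.45, s = 1e-4, seed = 61)
  expect_true(is.finite(o$mean_D) && is.finite(o$se_D))
  expect_equal(o$delta_sub,
               1 - o$mean_k * tajima_constants(60)$a1 / o$mean_S)
  expect_gt(o$se_D, 0)
  # q_bar = 0 limit: with s enormous the distribution is purely neutral
  o2 <- oracle_mean_D(5000, cal, p_n = 0.45, s = 100, seed = 61)
  w2 <- sim_mixed_windows(5000, cal, p_n = 0.45, s = 100, seed = 61)
  expect_true(all(w2$S_sel == 0))
  expect_equal(o2$mean_D, mean(w2$D))
})

test_that("haplotype-matrix generation matches the summary-level generator", {
  cal <- list(growth = 2, M = 1.5, n = 40, L = 100)
  set.seed(71)
  stats <- t(replicate(300, {
    m <- generate_mixed_window(cal, p_n = 0.45, u = 7e-9, s = 2e-6)
    ws <- window_stats(m)
    c(k = ws$k, S = ws$S)
  }))
  w <- sim_mixed_windows(3000, cal, p_n = 0.45, u = 7e-9, s = 2e-6, seed = 72)
  # means agree between the matrix path and the summary path
  se_S <- sqrt(var(stats[, "S"]) / 300 + var(w$S) / 3000)
  se_k <- sqrt(var(stats[, "k"]) / 300 + var(w$k) / 3000)
  expect_lt(abs(mean(stats[, "S"]) - mean(w$S)), 3 * se_S)
  expect_lt(abs(mean(stats[, "k"]) - mean(w$k)), 3 * se_k)
})

test_that("matrix generator limits and determinism", {
  cal <- list(growth = 0, M = 1, n = 12, L = 50)
  m1 <- generate_mixed_window(cal, p_n = 1, seed = 81)
  m2 <- generate_mixed_window(cal, p_n = 1, seed = 81)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(12, 50))
  expect_true(all(m1 %in% 0:1))
  # enormous s: selected sites all monomorphic
  m3 <- generate_mixed_window(cal, p_n = 0.5, s = 1e6, seed = 82)
  expect_true(all(m3[, 26:50] == 0))
  expect_error(generate_mixed_window(cal, p_n = 0.5, seed = 83), "'s'")
})

test_that("simulate method draws windows from the model's conditions", {
  ns <- neutral_summary(0.01, -0.3, L = 100, n = 40)
  m <- mixture_model(ns, s = 1e-4, u = 7e-9, p_n = 0.45)
  w <- simulate(m, nsim = 2000, seed = 91, reps_cal = 5000)
  cal <- attr(w, "calib")
  expect_s3_class(cal, "growth_calibration")
  expect_equal(nrow(w), 2000)
  expect_lt(abs(cal$mean_D - (-0.3)), 0.02 + 3 * cal$se_D)
})
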