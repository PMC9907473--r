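test_that("selected-site moments follow the mutation-selection formulas", {
  sm <- selected_moments(u = 7e-9, s = 7e-5, n = 1135)
  expect_equal(sm$q_bar, 1e-4)
  expect_equal(sm$seg_prob, 0.1135)
  expect_equal(sm$pi_site, 2e-4)
  expect_equal(sm$theta_w_site, 0.1135 / tajima_constants(1135)$a1)
  # internal consistency of the singleton model
  expect_equal(sm$pi_site, sm$seg_prob * 2 / 1135)
  expect_false(sm$valid)            # n*q_bar = 0.1135 > 0.1: flagged
  expect_true(selected_moments(7e-9, 1e-3, 1135)$valid)
})

test_that("selected-site validity boundary and dominance variant", {
  u <- 7e-9; n <- 1135
  expect_error(selected_moments(u, u * n / 1.01, n), ">= 1")
  expect_error(selected_moments(u, -1, n), "'s'")
  expect_error(selected_moments(0, 1e-3, n), "'u'")
  smh <- selected_moments(u, 1e-3, n, h = 0.5)
  expect_equal(smh$q_bar, u / (0.5 * 1e-3))
})

test_that("a purely neutral window reproduces the neutral summary", {
  ns <- neutral_summary(0.003, -0.9, 100, 1135)
  m <- mixture_model(ns, s = 1e-3, p_n = 1)
  expect_equal(m$k_mix, ns$k_n)
  expect_equal(m$S_mix, ns$S_n)
  expect_equal(m$D_mix, -0.9, tolerance = 1e-8)
  expect_equal(m$D_ratio, 1, tolerance = 1e-8)
  expect_equal(m$delta_theta_w_mix, ns$delta_theta_w, tolerance = 1e-8)
})

test_that("very strong selection removes the selected contribution", {
  ns <- neutral_summary(0.003, -0.9, 100, 1135)
  m <- mixture_model(ns, s = 100, p_n = 0.45)
  expect_equal(m$k_mix, 0.45 * ns$k_n, tolerance = 1e-4)
  expect_equal(m$S_mix, 0.45 * ns$S_n, tolerance = 1e-4)
  expect_lt(m$D_ratio, 1)
  expect_equal(m$delta_theta_w_mix, ns$delta_theta_w, tolerance = 0.001)
})

test_that("strong-selection approximation tracks the full substitution", {
  ns <- neutral_summary(0.003, -0.9, 100, 1135)
  m <- mixture_model(ns, s = 1e-2)
  Da <- strong_selection_D(m)
  expect_lt(Da, 0)                       # skewed neutral input -> D < 0
  expect_equal(Da, m$D_mix, tolerance = 0.1)
  # |D| increases with the neutral proportion, maximal at p_n = 1
  Ds <- vapply(c(0.25, 0.45, 0.75, 1), function(p)
    strong_selection_D(mixture_model(ns, s = 1e-2, p_n = p)), numeric(1))
  expect_true(all(diff(abs(Ds)) > 0))
  # sqrt(p_n) proportionality of the approximation
  expect_equal(Ds[1] / Ds[4], sqrt(0.25), tolerance = 1e-10)
  # invalid near equilibrium
  ns0 <- neutral_summary(0.003, -0.01, 100, 1135)
  expect_warning(strong_selection_D(mixture_model(ns0, s = 1e-2)),
                 "equilibrium")
})

test_that("mixture input validation", {
  ns <- neutral_summary(0.003, -0.9, 100, 1135)
  expect_error(mixture_model(ns, s = 1e-3, p_n = 1.4), "p_n")
  expect_error(mixture_model(list(), s = 1e-3), "neutral_summary")
})

test_that("model methods: coef, predict, print", {
  ns <- neutral_summary(0.003, -0.9, 100, 1135)
  m <- mixture_model(ns, s = 1e-3)
  cf <- coef(m)
  expect_equal(unname(cf["q_bar"]), 7e-6)
  pr <- predict(m, s = c(1e-4, 1e-3, 1e-2))
  expect_equal(nrow(pr), 3)
  expect_equal(pr$D_mix[2], m$D_mix)
  expect_output(print(m), "D ratio")
  expect_output(summary(m), "Strong-selection")
})

test_that("selection sweep reproduces the qualitative regime structure", {
  sg <- default_s_grid(1135, 1.4e-8, points = 12)
  tab <- sweep_selection(s_grid = sg, pi_n_set = c(0.0015, 0.003, 0.006),
                         D_n_set = list(-0.9, -0.45), n = 1135)
  d9 <- tab[tab$panel == "D_n=-0.9" & tab$pi_n == 0.003, ]
  # ratio falls below 1 and keeps decreasing beyond the crossover
  cross <- which(d9$D_ratio < 1)[1]
  expect_false(is.na(cross))
  expect_true(all(diff(d9$D_ratio[cross:nrow(d9)]) < 0))
  # skew of the mixed windows decreases with selection strength
  expect_true(all(diff(d9$delta_theta_w_mix) < 0))
  # at the strongest selection the mixed skew returns to the neutral value
  last <- d9[nrow(d9), ]
  expect_lt(abs(last$delta_theta_w_mix - last$delta_theta_w_n), 0.02)
  # |D_mix| increases with the mutation rate at fixed strong s
  smax <- max(tab$s)
  Dm <- tab[tab$panel == "D_n=-0.9" & tab$s == smax, ]
  Dm <- Dm[order(Dm$pi_n), ]
  expect_true(all(diff(abs(Dm$D_mix)) > 0))
})

test_that("equilibrium panel skew is independent of the mutation rate", {
  tab <- sweep_selection(s_grid = c(1e-4, 1e-3, 1e-2),
                         pi_n_set = c(0.0015, 0.003, 0.006),
                         D_n_set = list("equilibrium"),
                         n = 300, reps_eq = 2000, seed = 5)
  sp <- split(tab$delta_theta_w_mix, tab$pi_n)
  expect_equal(sp[[1]], sp[[2]], tolerance = 1e-12)
  expect_equal(sp[[2]], sp[[3]], tolerance = 1e-12)
  # the ratio is taken against a simulated (finite) equilibrium reference
  expect_true(all(is.finite(tab$D_ref)))
})

test_that("proportion sweep: purely neutral rows have ratio exactly 1", {
  tab <- sweep_proportion(p_n_grid = c(0.45, 1), s_grid = c(1e-4, 1e-3, 1e-2),
                          n = 1135)
  expect_equal(tab$D_ratio[tab$p_n == 1], rep(1, 3), tolerance = 1e-8)
  expect_equal(tab$log2_D_ratio[tab$p_n == 1], rep(0, 3), tolerance = 1e-8)
  # rows at p_n = 0.45 match the selection sweep at identical parameters
  sel <- sweep_selection(s_grid = c(1e-4, 1e-3, 1e-2), pi_n_set = 0.003,
                         D_n_set = list(-0.9), n = 1135)
  p45 <- tab[tab$p_n == 0.45, ]
  expect_equal(p45$D_mix, sel$D_mix, tolerance = 1e-12)
  expect_equal(p45$D_ratio, sel$D_ratio, tolerance = 1e-12)
})

test_that("mutation-contrast sweep scales the mixed neutral class", {
  tab <- sweep_mutation_contrast(s_grid = c(1e-3, 1e-2),
                                 D_n_set = list(-0.9), n = 1135)
  expect_equal(unique(tab$pi_n), 0.003)   # 0.006 * u_mixed/u_neutral
  expect_true(all(tab$D_ref == -0.9))
  # the reference neutral sequence is more diverse, so the ratio differs
  # from the equal-rate sweep
  sel <- sweep_selection(s_grid = c(1e-3, 1e-2), pi_n_set = 0.003,
                         D_n_set = list(-0.9), n = 1135)
  expect_equal(tab$D_mix, sel$D_mix, tolerance = 1e-12)
})
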