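test_that("constants match direct harmonic summation across sample sizes", {
  for (n in c(4, 5, 17, 100, 733, 1135, 2000)) {
    cst <- tajima_constants(n)
    i <- seq_len(n - 1)
    expect_equal(cst$a1, sum(1 / i))
    expect_equal(cst$a2, sum(1 / i^2))
    expect_equal(cst$e1, cst$c1 / cst$a1)
    expect_equal(cst$e2, cst$c2 / (cst$a1^2 + cst$a2))
    expect_true(all(unlist(cst[c("a1", "a2", "b1", "b2", "c1", "c2",
                                 "e1", "e2")]) > 0))
  }
})

test_that("closed-form small-n constants and argument checking", {
  expect_equal(tajima_constants(2, require_D = FALSE)$a1, 1)
  expect_equal(tajima_constants(4)$a1, 1 + 1/2 + 1/3)
  expect_error(tajima_constants(1), "n")
  expect_error(tajima_constants(3), ">= 4")
  expect_true(is.na(tajima_constants(3, require_D = FALSE)$e1))
  a1s <- vapply(4:60, function(n) tajima_constants(n)$a1, numeric(1))
  expect_true(all(diff(a1s) > 0))
})

test_that("tajima_D handles the zero cases and rejects bad input", {
  cst <- tajima_constants(10)
  expect_equal(tajima_D(5 / cst$a1, 5, 10), 0)
  expect_identical(tajima_D(0.7, 0, 10), 0)       # S = 0 convention
  expect_identical(tajima_D(0, 0, 1135), 0)
  expect_error(tajima_D(-0.1, 2, 10), "non-negative")
  expect_error(tajima_D(0.1, -2, 10), "non-negative")
  expect_error(tajima_D(1, 1, 3), ">= 4")
})

test_that("tajima_D reproduces an independently computed reference value", {
  # frozen from a tskit (tree-sequence toolkit) computation on a small
  # simulated sample: n = 10, S = 3, k = 19/15
  expect_equal(tajima_D(19 / 15, 3, 10), 0.6996173750913012, tolerance = 1e-12)
  # and the first-principles inline evaluation agrees on arbitrary input
  for (x in list(c(0.3, 5.21), c(2, 4), c(0.05, 1)))
    expect_equal(tajima_D(x[1], x[2], 47), direct_D(x[1], x[2], 47))
})

test_that("tajima_D is strictly decreasing in S for fixed k", {
  S <- seq(0.05, 40, length.out = 300)
  for (n in c(10, 1135)) {
    D <- tajima_D(0.3, S, n)
    expect_true(all(diff(D) < 0))
  }
})

test_that("the two variance forms differ only in the S^2 vs S(S-1) term", {
  cst <- tajima_constants(50)
  S <- 3.7; k <- 0.4
  Dc <- tajima_D(k, S, 50)
  Ds <- tajima_D(k, S, 50, variance = "squared")
  expect_equal(Dc, (k - S / cst$a1) /
                 sqrt((cst$e1 - cst$e2) * S + cst$e2 * S^2))
  expect_equal(Ds, (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S^2))
  expect_true(abs(Ds) < abs(Dc))  # denominator strictly larger
})

test_that("delta_theta_w arithmetic, undefined flag, and sign convention", {
  expect_equal(delta_theta_w(0.003, 0.003), 0)
  expect_equal(delta_theta_w(0.003, 0.004), 0.25)
  expect_true(is.na(delta_theta_w(0.001, 0)))
  expect_true(delta_theta_w(0.002, 0.004) > 0)   # excess of rare variants
  expect_true(delta_theta_w(0.004, 0.002) < 0)
  expect_error(delta_theta_w(-0.1, 0.2), "non-negative")
})

test_that("window_stats matches brute-force pairwise enumeration", {
  set.seed(71)
  for (rep in 1:8) {
    m <- random_window(10, 20)
    ws <- window_stats(m)
    expect_equal(ws$k, brute_force_k(m))
    expect_equal(ws$S, brute_force_S(m))
    expect_equal(ws$D, tajima_D(ws$k, ws$S, 10))
    expect_equal(ws$pi * ws$L, ws$k)
    expect_equal(ws$theta_w * ws$L * tajima_constants(10)$a1, ws$S)
    # conservation: per-column contributions c(n-c)/C(n,2) sum to k
    cc <- colSums(m)
    poly <- cc > 0 & cc < 10
    expect_equal(sum(cc[poly] * (10 - cc[poly])) / choose(10, 2), ws$k)
  }
})

test_that("window_stats degenerate and toy cases", {
  m0 <- matrix(0L, 6, 30)
  ws <- window_stats(m0)
  expect_equal(ws$S, 0)
  expect_equal(ws$k, 0)
  expect_identical(ws$D, 0)
  expect_true(is.na(ws$delta_theta_w))
  m1 <- matrix(0L, 4, 10); m1[2, 5] <- 1L   # one singleton among 4 genomes
  ws1 <- window_stats(m1)
  expect_equal(ws1$S, 1)
  expect_equal(ws1$k, 0.5)                   # 3 mismatching pairs of 6
  expect_error(window_stats(matrix(0L, 3, 5)), "4 rows")
  expect_error(window_stats(matrix(2L, 5, 5)), "0")
})
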