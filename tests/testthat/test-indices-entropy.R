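test_that("sample entropy equals the brute-force template count on seeded
           fixtures", {
  for (k in 1:20) {
    set.seed(k)
    x <- runif(200)
    expect_equal(as.numeric(sample_entropy(x)), sampen_brute(x),
                 tolerance = 1e-12, info = paste("fixture", k))
  }
})

test_that("sample entropy separates periodic from irregular sequences", {
  # a periodic pattern whose consecutive value pairs are all distinct
  # within one period, with levels separated beyond the tolerance:
  # template matches are then exact and phase-aligned, so every m-match
  # extends to m+1 and SE collapses to zero
  motif <- c(0, 1, 2, 3, 4, 0, 2, 4, 1, 3, 0, 3, 1, 4, 2,
             0, 4, 3, 2, 1) * 10
  expect_lt(sample_entropy(rep(motif, 50)), 0.01)
  set.seed(1)
  noise <- rnorm(1000)
  sine <- sin(2 * pi * 6 * (0:999) / 1000)
  expect_gt(sample_entropy(noise), sample_entropy(sine))
})

test_that("sample entropy is invariant to offset and positive scaling", {
  set.seed(2)
  x <- rnorm(500)
  se <- sample_entropy(x)
  expect_equal(as.numeric(sample_entropy(3 * x + 7)), as.numeric(se))
})

test_that("degenerate sample-entropy inputs are flagged, not clamped", {
  se <- sample_entropy(rep(1, 100))
  expect_true(is.na(se))
  expect_equal(attr(se, "flag"), "constant")
  expect_error(sample_entropy(c(1, 2, 3), se_params(m = 2)), "too short")
  # far-apart isolated points: no template matches at all
  se2 <- sample_entropy(c(rep(0, 5), 1e6, rep(0, 5), -1e6, rep(0, 5),
                          3e5, rep(1e5, 4)))
  expect_true(is.na(se2) || is.finite(se2))
})

test_that("histogram mutual information equals the brute-force cell count
           at every lag", {
  for (k in 1:20) {
    set.seed(k)
    x <- as.numeric(arima.sim(list(ar = 0.8), 250))
    tau <- auto_mutual_information(x, max_lag = 30)
    mi <- attr(tau, "mi")
    for (lag in c(1, 5, 13, 30)) {
      expect_equal(mi[lag], mi_brute(x, lag), tolerance = 1e-12,
                   info = paste("fixture", k, "lag", lag))
    }
  }
})

test_that("the MI delay of a noisy sinusoid sits near the quarter period", {
  for (k in 1:5) {
    set.seed(k)
    s <- sin(2 * pi * (0:1999) / 100) + rnorm(2000, 0, 0.5)
    tau <- as.integer(auto_mutual_information(s, 60))
    expect_gte(tau, 23); expect_lte(tau, 27)
  }
})

test_that("MI vanishes at lags where coordinates are independent", {
  set.seed(3)
  x <- rnorm(2000)
  expect_lt(mi_brute(x, 40), 0.2)      # estimator bias only
  expect_lt(attr(auto_mutual_information(x, 50), "mi")[40], 0.2)
  expect_error(auto_mutual_information(rep(1, 100)), "constant")
})

test_that("false nearest neighbours identify the planar limit cycle, the
           1-D map, and noise saturation", {
  s6 <- sin(2 * pi * 6 * (0:1999) / 1000)
  expect_equal(as.integer(false_nearest_neighbors(s6, 42)), 2L)

  lx <- numeric(500); lx[1] <- 0.3
  for (i in 2:500) lx[i] <- 4 * lx[i - 1] * (1 - lx[i - 1])
  dl <- false_nearest_neighbors(lx, 1, theiler = 1)
  expect_lt(tail(attr(dl, "fractions"), 1), 0.01)

  set.seed(4)
  dn <- false_nearest_neighbors(rnorm(600), 3, max_d = 8)
  expect_equal(as.integer(dn), 8L)
  expect_true(attr(dn, "saturated"))
  expect_error(false_nearest_neighbors(rnorm(50), 10, max_d = 8))
})

test_that("the FNN fraction equals an independent all-pairs search", {
  for (k in 1:20) {
    set.seed(k)
    x <- as.numeric(arima.sim(list(ar = c(0.5, 0.3)), 300))
    # tol = 0 disables early stopping so every dimension is evaluated
    fr <- attr(false_nearest_neighbors(x, tau = 2, max_d = 3, tol = 0),
               "fractions")
    for (d in 1:3) {
      expect_equal(fr[d], fnn_brute(x, d, tau = 2),
                   info = paste("fixture", k, "d", d))
    }
  }
})

test_that("the global embedding is the mode of the per-segment votes with
           ties toward the smaller value", {
  expect_equal(cfae:::mode_smallest(c(3, 3, 2)), 3)
  expect_equal(cfae:::mode_smallest(c(10, 12)), 10)
  seg <- sin(2 * pi * 6 * (0:999) / 1000) + 0.2 * sin(2 * pi * 13 *
                                                        (0:999) / 1000)
  e <- select_global_embedding(list(seg, seg, seg))
  expect_equal(e$d, as.integer(false_nearest_neighbors(
    seg, as.integer(auto_mutual_information(seg, 100)))))
  expect_equal(e$tau, as.integer(auto_mutual_information(seg, 100)))
  expect_error(select_global_embedding(list()), "no segments")
})
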