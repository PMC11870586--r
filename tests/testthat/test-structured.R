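# Structured coalescent with deleterious allelic classes and its phase-type
# extension to piecewise-constant demography.

test_that("classic B formula: limits and direct evaluation", {
  expect_equal(classic_B(1e-6, -0.01, 0), 1 - 1e-4)
  expect_gt(classic_B(1e-6, -0.01, 0.5), 1 - 1e-4)
  expect_lt(abs(classic_B(1e-6, -0.01, 0.5) - 1), 1e-6)
  expect_equal(classic_B(1e-8, -0.01, 1e-4), 1 - 1e-6 / 1.01^2, tolerance = 1e-12)
  expect_error(classic_B(1e-3, -1e-4, 0), "balance")
})

test_that("lambda >= 1 across the admissible grid, with correct limits", {
  us <- 10^seq(-9, -4, length.out = 6)
  ss <- -10^seq(-3, 0, length.out = 7)
  rs <- c(0, 10^seq(-8, log10(0.5), length.out = 7))
  for (u in us) for (s in ss) {
    if (abs(s) <= u) next
    for (r in rs) {
      m <- structured_model(u, s, r)
      expect_gte(m$lambda, 1)
    }
  }
  # r = 0: 1/lambda = 1 - p exactly
  m0 <- structured_model(1e-5, -0.01, 0)
  expect_equal(1 / m0$lambda, 1 - m0$p, tolerance = 1e-12)
  # p -> 0: lambda -> 1
  expect_equal(structured_model(1e-12, -0.01, 1e-3)$lambda, 1, tolerance = 1e-8)
})

test_that("1/lambda equals classic B up to O(p^2)", {
  s <- -0.01; r <- 1e-3
  dev <- vapply(c(1e-5, 5e-6, 2.5e-6), function(u)
    abs(1 / structured_model(u, s, r)$lambda - classic_B(u, s, r)),
    numeric(1))
  # halving u (hence p) should quarter the deviation
  expect_lt(dev[2] / dev[1], 0.3)
  expect_lt(dev[3] / dev[2], 0.3)
})

test_that("initial class occupancy is the stationary binomial mixture", {
  m <- structured_model(1e-5, -0.01, 1e-4)
  p <- m$p
  expect_equal(m$init, c((1 - p)^2, 2 * p * (1 - p), p^2))
  expect_equal(sum(m$init), 1)
})

test_that("per-epoch coalescence probabilities: totals and neutral limit", {
  dem <- demography(c(1e4, 1e3), c(Inf, 5000))
  pr <- epoch_coalescence_probabilities(dem, 1e-6, -0.01, 1e-4)
  expect_equal(sum(pr$prob), 1, tolerance = 1e-10)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  # u -> 0 with r >> |s|: neutral per-epoch probabilities
  prn <- epoch_coalescence_probabilities(dem, 1e-14, -0.01, 0.4)
  cp <- coalescence_profile(dem)
  expect_close(prn$prob, cp$prob, 1e-7)
})

test_that("expected TMRCA under selection: constant size and neutral limit", {
  # constant N: E[T] = 2N/lambda
  m <- structured_model(1e-6, -0.01, 1e-4)
  ET <- expected_tmrca_selected(demography(1e4), 1e-6, -0.01, 1e-4)
  expect_equal(ET, 2e4 / m$lambda, tolerance = 1e-5)
  # u -> 0: neutral piecewise E[TMRCA], relative 1e-10
  dem <- demography(c(1e4, 1e3), c(Inf, 5000))
  ETs <- expected_tmrca_selected(dem, 1e-15, -0.01, 1e-3)
  ETn <- bgsmap:::neutral_tmrca(dem, discrete = FALSE)
  expect_equal(ETs / ETn, 1, tolerance = 1e-8)
})

test_that("non-equilibrium strong-selection B behaves correctly", {
  # u = 0 -> B = 1 for any demography
  dem <- demography(c(1e4, 1e3), c(Inf, 5000))
  expect_equal(nonequilibrium_B_strong(dem, 0, -0.01, 1e-4), 1)
  # constant N: B = 1/lambda, equal to classic_B up to O(p^2)
  Bc0 <- classic_B(1e-6, -0.01, 1e-4)
  B <- nonequilibrium_B_strong(demography(1e4), 1e-6, -0.01, 1e-4)
  expect_lt(abs(B - Bc0), 0.02 * (1 - Bc0))
  m <- structured_model(1e-6, -0.01, 1e-4)
  expect_equal(B, 1 / m$lambda, tolerance = 1e-10)
  # B is transiently perturbed after a size change and re-approaches the
  # equilibrium value as t -> infinity
  Bcl <- classic_B(1e-6, -0.01, 1e-4)
  B5k <- nonequilibrium_B_strong(demography(c(1e4, 1e3), c(Inf, 5000)),
                                 1e-6, -0.01, 1e-4)
  Blong <- nonequilibrium_B_strong(demography(c(1e4, 1e3), c(Inf, 2e5)),
                                   1e-6, -0.01, 1e-4)
  expect_gt(abs(B5k - Bcl), abs(Blong - Bcl))
  expect_lt(abs(Blong - Bcl), 1e-6)
  # monotone in r, non-increasing in u at equilibrium
  Bs <- vapply(c(0, 1e-4, 1e-2), function(r)
    nonequilibrium_B_strong(demography(1e4), 1e-6, -0.01, r), numeric(1))
  expect_true(all(diff(Bs) > 0))
  Bu <- vapply(c(1e-7, 1e-6, 1e-5), function(u)
    nonequilibrium_B_strong(demography(1e4), u, -0.01, 1e-4), numeric(1))
  expect_true(all(diff(Bu) < 0))
})
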