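# Equilibrium and time-dependent solutions of the moment system.

test_that("B = 1 whenever u_left = 0 or s = 0", {
  for (r in c(0, 1e-4)) {
    p1 <- two_locus_params(s = 0, u_left = 1e-8, u_right = 1e-8, r = r)
    expect_equal(two_locus_B(p1, demography(1e4)), 1)
    p2 <- two_locus_params(s = -1e-3, u_left = 0, u_right = 1e-8, r = r)
    expect_equal(two_locus_B(p2, demography(1e4)), 1)
  }
  # the solver itself handles the neutral fixed point (conserved y-block)
  pn <- two_locus_params(0, 0, u_right = 1e-8, r = 0)
  v <- equilibrium_state(bgsmap:::epoch_operator(pn, 1e4, build_basis(0)))
  expect_equal(unname(v$values["piR"]), 4e4 * 1e-8, tolerance = 1e-9)
  expect_equal(unname(v$values["one"]), 1)
})

test_that("equilibrium fixed point has a small residual", {
  pp <- two_locus_params(s = -2e-4, u_left = 1e-8, u_right = 1e-8, r = 1e-6)
  M <- bgsmap:::epoch_operator(pp, 1e4, build_basis(25))
  v <- equilibrium_state(M)
  res <- max(abs(v$mono - as.numeric(M %*% v$mono)))
  expect_lt(res, 1e-12 * max(abs(v$mono)))
})

test_that("equilibrium B is non-decreasing in r", {
  Bs <- vapply(c(0, 1e-6, 1e-4, 1e-2, 0.5), function(r) {
    pp <- two_locus_params(s = -3e-4, u_left = 1e-8, u_right = 1e-8, r = r)
    two_locus_B_equilibrium(pp, 1e4, j_max = 40)
  }, numeric(1))
  expect_true(all(diff(Bs) >= -1e-12))
  expect_lt(Bs[1], Bs[5])
})

test_that("B(j_max) converges (Cauchy) and auto_truncation finds it", {
  pp <- two_locus_params(s = -1e-4, u_left = 1e-8, u_right = 1e-8, r = 1e-7)
  js <- c(10, 15, 20, 25, 30, 35)
  Bs <- vapply(js, function(j) two_locus_B_equilibrium(pp, 1e4, j_max = j),
               numeric(1))
  d <- abs(diff(Bs))
  expect_lt(d[length(d)], d[1])        # differences shrink
  expect_lt(d[length(d)], 1e-7)
  j_auto <- auto_truncation(pp, 1e4)
  expect_lt(abs(two_locus_B_equilibrium(pp, 1e4, j_max = j_auto) -
                Bs[length(Bs)]), 5e-6)
  # stronger selection needs higher order at equal accuracy
  p10 <- two_locus_params(s = -5e-4, u_left = 1e-8, u_right = 1e-8, r = 1e-7)
  expect_gt(auto_truncation(p10, 1e4), j_auto)
  # truncation requirement is insensitive to the deleterious rate
  expect_equal(auto_truncation(two_locus_params(-1e-4, 5e-9, 1e-8, 1e-7), 1e4),
               j_auto)
  expect_error(auto_truncation(two_locus_params(-0.01, 1e-8, 1e-8, 0), 1e4),
               "structured")
})

test_that("B is invariant to joint mutation-rate rescaling", {
  pp <- two_locus_params(s = -3e-4, u_left = 1e-8, u_right = 1e-8, r = 1e-6)
  B1 <- two_locus_B_equilibrium(pp, 1e4, j_max = 40)
  B2 <- two_locus_B_equilibrium(pp, 1e4, j_max = 40, mutation_scale = 100)
  expect_lt(abs(B1 - B2), 1e-6)
})

test_that("moment system agrees with strong-selection theory at the handoff", {
  # s = -0.005, N = 1e4, u = 1e-8: the two routes agree within 10% of (1-B)
  pp <- two_locus_params(s = -5e-3, u_left = 1e-8, u_right = 1e-8, r = 1e-6)
  Bm <- two_locus_B_equilibrium(pp, 1e4, j_max = 250)
  Bc <- classic_B(1e-8, -5e-3, 1e-6)
  expect_lt(abs(Bm - Bc), 0.1 * (1 - Bc))
})

test_that("evolve: t = 0 identity, neutral convergence, bottleneck diversity", {
  pp <- two_locus_params(0, 0, u_right = 1e-8, r = 0)
  b <- build_basis(0)
  M1 <- bgsmap:::epoch_operator(pp, 10000, b)
  v <- equilibrium_state(M1)
  expect_equal(evolve(v, M1, 0)$values, v$values)

  # N: 10,000 -> 1,000 for 5,000 generations: drift-effective Ne ~ 2,000
  M2 <- bgsmap:::epoch_operator(pp, 1000, b)
  v5 <- evolve(v, M2, 5000)
  expect_equal(round(unname(v5$values["piR"]) / (4 * 1e-8) / 1000) * 1000, 2000)

  # convergence to the new equilibrium from any start after t >> 2N
  v0 <- bgsmap:::state_moments(b, 0.25, 0.25, 0.25, 0.25)
  vlong <- evolve(v0, M2, 60000)
  expect_equal(unname(vlong$values["piR"]), 4 * 1000 * 1e-8, tolerance = 1e-8)
})
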