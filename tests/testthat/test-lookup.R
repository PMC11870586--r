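test_that("default grids match the documented design", {
  expect_equal(length(default_s_grid(extend = FALSE)), 35L) # 0 to -0.001
  expect_equal(length(default_r_grid()), 72L)               # 0 to 0.5
  expect_equal(default_r_grid()[1], 0)
  expect_equal(max(default_r_grid()), 0.5)
  expect_equal(default_s_grid()[1], 0)
  expect_equal(min(default_s_grid()), -1)
})

test_that("lookup table: B(0, r) = 1, bounds, and free recombination", {
  tab <- lookup_weak()
  expect_true(all(tab$B[1, ] == 1))                  # s = 0 row
  expect_true(all(tab$B > 0 & tab$B <= 1))
  # free recombination: column r = 0.5 within 1e-3 of 1 for |s| <= 1e-3
  expect_true(all(abs(tab$B[, ncol(tab$B)] - 1) < 1e-3))
  # B non-decreasing in r along every s row
  expect_true(all(apply(tab$B, 1, function(x) all(diff(x) >= -1e-12))))
})

test_that("interpolation is exact on nodes, bracketed, monotone and guarded", {
  tab <- lookup_weak()
  for (i in c(2, 5)) for (j in c(1, 7, 20)) {
    expect_equal(interp_B(tab, tab$s_grid[i], tab$r_grid[j]), tab$B[i, j],
                 tolerance = 1e-12)
  }
  expect_equal(interp_B(tab, 0, c(0, 0.3)), c(1, 1))
  # interpolated values lie within the bracketing node values
  for (i in c(2, 5, 8)) {
    for (j in 1:(length(tab$r_grid) - 1)) {
      rmid <- sqrt(max(tab$r_grid[j], 1e-12) * tab$r_grid[j + 1])
      B <- interp_B(tab, tab$s_grid[i], rmid)
      lo <- min(tab$B[i, j:(j + 1)]); hi <- max(tab$B[i, j:(j + 1)])
      expect_true(B >= lo - 1e-12 && B <= hi + 1e-12)
    }
  }
  # off-grid s lies between the bracketing s-gridline values
  s_mid <- -sqrt(abs(tab$s_grid[3] * tab$s_grid[4]))
  B <- interp_B(tab, s_mid, 1e-5)
  b3 <- interp_B(tab, tab$s_grid[3], 1e-5)
  b4 <- interp_B(tab, tab$s_grid[4], 1e-5)
  expect_true(B >= min(b3, b4) - 1e-12 && B <= max(b3, b4) + 1e-12)
  expect_error(interp_B(tab, -1, 0.1), "outside")
  expect_error(interp_B(tab, tab$s_grid[2], 0.7), "0.5")
})

test_that("handoff continuity: the two methods overlap at moderate s", {
  # at |s| = 2e-3 (the strongest row of the coarse full-range table built
  # with handoff below it) the structured coalescent agrees with a
  # moment-system computation within 10% of (1 - B)
  pp <- two_locus_params(s = -2e-3, u_left = 1e-8, u_right = 1e-8, r = 1e-6)
  Bm <- two_locus_B_equilibrium(pp, 1e4, j_max = 120)
  Bc <- nonequilibrium_B_strong(demography(1e4), 1e-8, -2e-3, 1e-6)
  expect_lt(abs(Bm - Bc), 0.1 * (1 - Bc))
})

test_that("non-equilibrium lookup slices vary over time and start at equilibrium", {
  dem <- demography(c(1e4, 1e3), c(Inf, 25000))
  sg <- c(0, -1e-4, -1e-2)
  rg <- c(0, 1e-6, 1e-3, 0.5)
  tab <- build_lookup(dem, sg, rg, u_ref = 1e-8,
                      sample_times = c(0, 5000, 25000), handoff = 5e-3)
  expect_equal(dim(tab$B), c(3L, 4L, 3L))
  eq <- build_lookup(demography(1e4), sg, rg, u_ref = 1e-8, handoff = 5e-3)
  # t = 0 slice equals the ancestral equilibrium table
  expect_close(tab$B[, , 1], eq$B, 1e-6)
  # transient B differs from the ancestral equilibrium for selected cells,
  # on the scale of the reduction itself
  rel <- abs(tab$B[2:3, 1:3, 2] - eq$B[2:3, 1:3]) / (1 - eq$B[2:3, 1:3])
  expect_gt(max(rel), 0.05)
})

test_that("lookup serialization round-trips", {
  tab <- lookup_weak()
  path <- tempfile(fileext = ".tsv")
  write_lookup(tab, path)
  tab2 <- read_lookup(path)
  expect_equal(tab2$s_grid, tab$s_grid)
  expect_equal(tab2$r_grid, tab$r_grid)
  expect_equal(tab2$B, tab$B, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(tab2$u_ref, tab$u_ref)
  expect_equal(tab2$demography_id, tab$demography_id)
  expect_match(tab2$version, "bgsmap-lookup")
})
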