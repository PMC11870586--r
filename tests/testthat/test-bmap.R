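# Multi-locus B-map composition: DFE weights, element effects, mutation
# adjustment and map-level properties.

test_that("DFE weights: normalization, point mass, refinement stability", {
  sg <- lookup_full()$s_grid
  w <- dfe_weights(dfe_gamma(0.215, 0.028105), sg)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  # point mass lands on the nearest grid point
  wp <- dfe_weights(dfe_point(sg[4] * 1.01), sg)
  expect_equal(which(wp == 1), 4L)
  expect_equal(sum(wp), 1)
})

test_that("mutation adjustment: identity, zero and first-order linearity", {
  expect_equal(mutation_adjust(0.9, 1e-8, 1e-8), 0.9)
  expect_equal(mutation_adjust(0.9, 0, 1e-8), 1)
  # for B = 1 - eps, 1 - B scales linearly in u_site/u_ref to O(eps^2)
  eps <- 1e-4
  out <- 1 - mutation_adjust(1 - eps, 3e-8, 1e-8)
  expect_equal(out, 3 * eps, tolerance = 1e-3)
  # doubling u_site doubles -log(B)
  expect_equal(log(mutation_adjust(0.9, 2e-8, 1e-8)), 2 * log(0.9),
               tolerance = 1e-12)
})

test_that("element effects: trivial cases and chunking consistency", {
  tab <- lookup_weak()
  dfe <- dfe_point(-1e-3)
  # zero mutation rate or zero constrained fraction: contribution 1
  lay0 <- chromosome_layout(1e6, data.frame(start = 5e5, end = 5e5 + 1000,
                                            u_site = 0, constrained_fraction = 1))
  ch <- bgsmap:::chunk_elements(lay0)
  expect_equal(element_effect(1000, ch[1, ], tab, dfe, lay0), 1)
  lay1 <- chromosome_layout(1e6, data.frame(start = 5e5, end = 5e5 + 1000,
                                            u_site = 1e-8, constrained_fraction = 0))
  ch1 <- bgsmap:::chunk_elements(lay1)
  expect_equal(element_effect(1000, ch1[1, ], tab, dfe, lay1), 1)

  # two adjacent 500 bp chunks ~ one 1000 bp chunk at distant focal sites
  el1 <- chromosome_layout(1e6, data.frame(start = 5e5, end = 5e5 + 1000,
                                           u_site = 1e-8, constrained_fraction = 1))
  B1 <- compose_bmap(el1, tab, dfe, focal_positions = c(4e5, 52e4, 9e5))
  ch2 <- bgsmap:::chunk_elements(el1, max_len = 500L)
  expect_equal(nrow(ch2), 2L)
  B2 <- compose_bmap(el1, tab, dfe, focal_positions = c(4e5, 52e4, 9e5),
                     chunks = ch2)
  expect_close(B2$B / B1$B, 1, 1e-4)

  # doubling u_site doubles -log(B contribution)
  elA <- bgsmap:::chunk_elements(el1)[1, ]
  bA <- element_effect(6e5, elA, tab, dfe, el1)
  elB <- elA; elB$u_site <- 2e-8
  bB <- element_effect(6e5, elB, tab, dfe, el1)
  expect_equal(log(bB), 2 * log(bA), tolerance = 1e-10)
})

test_that("B-maps: empty layout, recovery with distance, density contrast", {
  tab <- lookup_weak()
  dfe <- dfe_point(-1e-3)
  empty <- chromosome_layout(1e6, data.frame(start = numeric(0), end = numeric(0),
                                             u_site = numeric(0),
                                             constrained_fraction = numeric(0)))
  bm <- compose_bmap(empty, tab, dfe, focal_positions = c(1e5, 5e5))
  expect_equal(bm$B, c(1, 1))

  # single element: B dips at the element and recovers monotonically
  lay <- chromosome_layout(2e6, data.frame(start = 1e6 - 500, end = 1e6 + 500,
                                           u_site = 1e-8, constrained_fraction = 1))
  fp <- 1e6 + c(0, 1e4, 1e5, 5e5, 9e5)
  bm <- compose_bmap(lay, tab, dfe, focal_positions = fp)
  expect_true(all(diff(bm$B) > 0))
  expect_lt(bm$B[1], 1)

  # element-dense region has lower mean B than an element-free region
  els <- data.frame(start = seq(1e5, 4e5, by = 5e4),
                    end = seq(1e5, 4e5, by = 5e4) + 1000,
                    u_site = 1e-8, constrained_fraction = 1)
  lay2 <- chromosome_layout(1e6, els)
  dense <- compose_bmap(lay2, tab, dfe, focal_positions = seq(1e5, 4e5, by = 2e4))
  free <- compose_bmap(lay2, tab, dfe, focal_positions = seq(7e5, 9.5e5, by = 2e4))
  expect_lt(mean(dense$B), mean(free$B))
})

test_that("uniform constrained segment: concavity and the multiplicative
           strong-selection limit", {
  # strong point DFE: mid-segment B matches the product of classic two-locus
  # B-values over constrained sites within 10% of (1 - B)
  sg <- c(0, -10^seq(-3, 0, length.out = 10))
  rg <- c(0, 10^seq(-8, log10(0.5), length.out = 40))
  tabS <- build_lookup(demography(1e4), sg, rg, u_ref = 1e-8, handoff = 1e-3)
  s0 <- sg[7] # a strong-selection grid node (~ -0.046), no s-interpolation
  lay <- layout_100kb(dfe = dfe_point(s0))
  mid <- 5e4
  bm <- compose_bmap(lay, tabS, focal_positions = c(500, mid))
  # closed-form multiplicative cBGS over all sites
  pos <- seq(0.5, 1e5 - 0.5, by = 1)
  Bexp <- exp(sum(log(classic_B(1e-8, s0, pmin(0.5, abs(pos - mid) * 1e-8)))))
  expect_lt(abs(bm$B[2] - Bexp), 0.1 * (1 - Bexp))
  # edge sites have higher B than the midpoint
  expect_gt(bm$B[1], bm$B[2])
})
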