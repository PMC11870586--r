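# Iterative interference correction.

test_that("a single isolated element converges immediately with no change", {
  tab <- lookup_weak()
  lay <- chromosome_layout(1e6, data.frame(start = 5e5, end = 5e5 + 800,
                                           u_site = 1e-8, constrained_fraction = 1),
                           dfe = dfe_point(-1e-3))
  res <- correct_interference(lay, tab)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  expect_equal(res$element_B, 1)
})

test_that("self-B: symmetry, distance decay and the far-apart limit", {
  tab <- lookup_weak()
  mk <- function(gap) {
    st <- c(1e5, 1e5 + 1000 + gap)
    chromosome_layout(5e7, data.frame(start = st, end = st + 1000,
                                      u_site = 1e-8, constrained_fraction = 1),
                      dfe = dfe_point(-1e-3))
  }
  # two identical adjacent elements: equal self-B below 1, by symmetry
  lay <- mk(0)
  b1 <- element_self_B(lay, tab, element_index = 1)
  b2 <- element_self_B(lay, tab, element_index = 2)
  expect_equal(b1, b2, tolerance = 1e-12)
  expect_lt(b1, 1)
  # self-B decreases as the elements approach
  gaps <- c(4e7, 1e6, 1e4, 0)
  bs <- vapply(gaps, function(g) element_self_B(mk(g), tab, element_index = 1),
               numeric(1))
  expect_true(all(diff(bs) < 0))
  # far apart (r_mid ~ 0.5): self-B ~ 1
  expect_gt(bs[1], 1 - 1e-6)
})

test_that("dense 100 kb benchmark: fast convergence, corrected >= naive,
           mirror symmetry", {
  tab <- lookup_weak()
  lay <- layout_100kb(dfe = dfe_point(-1e-3))
  fp <- seq(500, 1e5 - 500, by = 1000) # mirror-symmetric grid
  res <- correct_interference(lay, tab, focal_positions = fp, tol = 1e-4)
  expect_true(res$converged)
  expect_lte(res$iterations, 10L)
  naive <- compose_bmap(lay, tab, focal_positions = fp)
  expect_true(all(res$bmap$B >= naive$B - 1e-12))
  expect_gt(max(res$bmap$B - naive$B), 0)
  # symmetric layout -> mirror-symmetric corrected map
  expect_close(res$bmap$B, rev(res$bmap$B), 1e-9)
  expect_close(res$element_B, rev(res$element_B), 1e-9)
  # fixed-point residual: one more round moves no element B by > tol
  res2 <- suppressWarnings(
    correct_interference(lay, tab, focal_positions = fp, tol = 1e-12,
                         max_iter = res$iterations + 1L))
  expect_lt(max(abs(res2$element_B - res$element_B)), 1e-4)
})

test_that("non-equilibrium tables are refused unless forced", {
  dem <- demography(c(1e4, 1e3), c(Inf, 5000))
  sg <- c(0, -1e-4)
  rg <- c(0, 1e-5, 0.5)
  tab <- build_lookup(dem, sg, rg, u_ref = 1e-8)
  lay <- chromosome_layout(1e6, data.frame(start = 5e5, end = 5e5 + 500,
                                           u_site = 1e-8, constrained_fraction = 1),
                           dfe = dfe_point(-1e-4))
  expect_error(correct_interference(lay, tab), "equilibrium")
  expect_warning(res <- correct_interference(lay, tab, force = TRUE),
                 "non-equilibrium")
  expect_true(res$converged)
})
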