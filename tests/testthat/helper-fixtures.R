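# Shared fixtures, built lazily and memoized for the whole run.

.fix <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# coarse grids used throughout the suite
test_r_grid <- function() c(0, 10^seq(-8, log10(0.5), length.out = 20))

# equilibrium lookup at N = 1e4 for weak-to-moderate point DFEs
lookup_weak <- function() memo("lookup_weak", function() {
  build_lookup(demography(1e4),
               s_grid = c(0, -10^seq(-5, -3, length.out = 7)),
               r_grid = test_r_grid(), u_ref = 1e-8, handoff = 5e-3)
})

# equilibrium lookup spanning the full DFE range (coarse), N = 1e4
lookup_full <- function() memo("lookup_full", function() {
  sg <- unique(c(0, default_s_grid()[seq(2, 68, by = 4)]))
  build_lookup(demography(1e4), s_grid = sg, r_grid = test_r_grid(),
               u_ref = 1e-8, handoff = 2e-3)
})

layout_10mb <- function(dfe = dfe_gamma(0.215, 0.028105))
  make_fixture("paper10mb", dfe = dfe)

layout_100kb <- function(dfe = dfe_point(-1e-3))
  make_fixture("uniform100kb", dfe = dfe)

# bottleneck + expansion DFE-fit sign experiment (shared between the DFE
# module tests and the acceptance property suite)
bias_signs_results <- function() memo("bias_signs", function() {
  dfe <- dfe_gamma(0.215, 0.028105)
  lay <- layout_10mb(dfe)
  fp <- seq(5e5, 9.5e6, by = 2e5)
  rg <- c(0, 10^seq(-7, log10(0.5), length.out = 8))
  run <- function(dem) bias_experiment(
    dem, lay, dfe, u = 1e-8, sampling_stride = 5000L, horizon = 5000L,
    r_grid = rg, focal_positions = fp, fit_times = 5000L)
  list(bot = run(demography(c(1e4, 1e3), c(Inf, 5000))),
       exp = run(demography(c(1e4, 1e5), c(Inf, 5000))))
})

# forward-simulation vs moment-system B comparison (shared).  The rescaled
# regime N = 300, 2Ns = -12, with recurrent right-locus mutation in BOTH the
# simulator and the operator (the matched finite-alleles model) makes
# 1 - B ~ 4%, well above the Monte-Carlo error of per-replicate
# time-averaged pi_R over 5,000 independent replicates.
sim_B_check <- function() memo("sim_B", function() {
  N <- 300L; s <- -0.02; uL <- 1e-3; uR <- 4e-4; r <- 3e-4
  pars <- two_locus_params(s = s, u_left = uL, u_right = uR, r = r,
                           right_recurrent = TRUE)
  piR_sel <- unname(equilibrium_state(
    bgsmap:::epoch_operator(pars, N, build_basis(40)))$values["piR"])
  pars0 <- two_locus_params(0, 0, u_right = uR, r = r, right_recurrent = TRUE)
  piR_neu <- unname(equilibrium_state(
    bgsmap:::epoch_operator(pars0, N, build_basis(0)))$values["piR"])
  sim <- two_locus_forward(pars, demography(N), n_reps = 5000L, t = 12000L,
                           seed = 11L, record_every = 150L, burn = 3000L,
                           keep_reps = TRUE)
  rm_ <- attr(sim, "rep_means")[, "piR"]
  est <- mean(rm_)
  se <- stats::sd(rm_) / sqrt(length(rm_))
  list(Bpred = piR_sel / piR_neu, Bsim = est / piR_neu, relse = se / est,
       piR_neu = piR_neu)
})

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %.3e (tol %.3e)",
                              max(abs(object - expected)), tol))
}
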