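# Operator matrices vs the exact two-locus Wright-Fisher chain at 2N = 8,
# plus the structural properties of the single-force operators.

basis6 <- build_basis(6)

project_moments <- function(mono_vals, basis) {
  mono <- monomial_basis <- bgsmap:::monomial_basis(attr(basis, "j_max"))
  as.numeric(bgsmap:::moment_projection(basis, mono) %*% mono_vals)
}

one_step <- function(params, N, forces, op_order, x0, basis = basis6) {
  chain <- exact_wf_chain(params, N, forces = forces)
  exact <- chain_moment_step(chain, basis, x0)
  v0 <- bgsmap:::state_moments(basis, x0[1], x0[2], x0[3], x0[4])
  M <- Reduce(`%*%`, lapply(op_order, function(f)
    build_operator(f, params, N = N, basis = basis)))
  pred <- project_moments(as.numeric(M %*% v0$mono), basis)
  list(err = abs(pred - exact)[basis$j <= 4], exact = exact)
}

x0 <- c(2, 1, 3, 2) / 8

test_that("drift and recombination match the exact chain to machine precision", {
  p0 <- two_locus_params(0, 0, 0, 0)
  expect_lt(max(one_step(p0, 4, character(0), "drift", x0)$err), 1e-12)
  pr <- two_locus_params(0, 0, 0, r = 0.3)
  expect_lt(max(one_step(pr, 4, "recombination",
                         c("drift", "recombination"), x0)$err), 1e-12)
  # several initial states
  for (n0 in list(c(1, 2, 2, 3), c(0, 4, 4, 0), c(5, 1, 1, 1))) {
    expect_lt(max(one_step(pr, 4, "recombination",
                           c("drift", "recombination"), n0 / 8)$err), 1e-12)
  }
})

test_that("mutation operator (symmetric recurrent) matches the exact chain", {
  for (u in c(0.02, 0.003)) {
    pu <- two_locus_params(0, u_left = u, u_right = 0, r = 0)
    expect_lt(max(one_step(pu, 4, "mutation",
                           c("drift", "mutation"), x0)$err), 1e-12)
  }
})

test_that("selection operator error decays quadratically in s", {
  errs <- vapply(c(-0.02, -0.01, -0.005), function(s) {
    ps <- two_locus_params(s = s, u_left = 0, u_right = 0, r = 0)
    max(one_step(ps, 4, "selection", c("drift", "selection"), x0)$err)
  }, numeric(1))
  # halving s should quarter the error (allow 20% slack on the ratio)
  expect_lt(errs[2] / errs[1], 0.25 * 1.2)
  expect_lt(errs[3] / errs[2], 0.25 * 1.2)
})

test_that("single-force neutral reductions give the identity", {
  p0 <- two_locus_params(0, 0, 0, 0)
  for (f in c("selection", "recombination", "mutation")) {
    M <- build_operator(f, p0, basis = basis6)
    expect_equal(max(abs(M - Matrix::Diagonal(nrow(M)))), 0)
  }
  # drift at N -> infinity approaches the identity
  Dr <- build_operator("drift", p0, N = 1e9, basis = build_basis(2))
  expect_lt(max(abs(Dr - Matrix::Diagonal(nrow(Dr)))), 1e-7)
})

test_that("documented operator rows hold: selection and drift on pi_R", {
  b <- build_basis(4)
  TT <- bgsmap:::moment_projection(b, bgsmap:::monomial_basis(4))
  s <- -1e-3
  ps <- two_locus_params(s = s, u_left = 0, u_right = 0, r = 0)
  S <- build_operator("selection", ps, basis = b)
  # Delta_s E[pi_R] = 2 s E[D(1-2q)] for a generic state
  v <- bgsmap:::state_moments(b, 0.3, 0.2, 0.4, 0.1)
  after <- as.numeric(TT %*% as.numeric(S %*% v$mono))
  names(after) <- b$id
  dpiR <- after["piR"] - v$values["piR"]
  expect_equal(unname(dpiR), 2 * s * unname(v$values["Dz_0"]), tolerance = 1e-10)
  # drift decays E[pi_R] by exactly 1 - 1/(2N)
  for (N in c(10, 1000)) {
    Dr <- build_operator("drift", ps, N = N, basis = b)
    after <- as.numeric(TT %*% as.numeric(Dr %*% v$mono))
    names(after) <- b$id
    expect_equal(unname(after["piR"]),
                 (1 - 1 / (2 * N)) * unname(v$values["piR"]), tolerance = 1e-12)
  }
})

test_that("composite operator: identity composition and factor reordering", {
  p0 <- two_locus_params(0, 0, 0, 0)
  b2 <- build_basis(2)
  ops <- lapply(c("selection", "recombination", "mutation"), function(f)
    build_operator(f, p0, basis = b2))
  M <- compose_operators(ops[[1]], ops[[2]], ops[[3]],
                         build_operator("drift", p0, N = 1e12, basis = b2))
  expect_lt(max(abs(M - Matrix::Diagonal(nrow(M)))), 1e-10)

  # neutral case: equilibrium E[pi_R] = 4 N u_right to first order
  pn <- two_locus_params(0, 0, u_right = 1e-8, r = 0.1)
  Mn <- bgsmap:::epoch_operator(pn, 5000, b2)
  vn <- equilibrium_state(Mn)
  expect_equal(unname(vn$values["piR"]) / (4 * 5000 * 1e-8), 1, tolerance = 1e-6)

  # reordering the life cycle changes B by a relative amount < 1e-3 of
  # (1 - B); each ordering is normalized by its own neutral reference since
  # a cyclic shift also moves the point in the cycle where pi_R is read off
  pp <- two_locus_params(s = -1e-3, u_left = 1e-8, u_right = 1e-8, r = 1e-8)
  p0n <- two_locus_params(0, 0, u_right = 1e-8, r = 1e-8)
  bas <- build_basis(60)
  Bfun <- function(ord) {
    Msel <- bgsmap:::epoch_operator(pp, 1e4, bas, order = ord)
    Mneu <- bgsmap:::epoch_operator(p0n, 1e4, build_basis(0), order = ord)
    unname(equilibrium_state(Msel)$values["piR"]) /
      unname(equilibrium_state(Mneu)$values["piR"])
  }
  B1 <- Bfun(c("S", "R", "U", "D"))
  B2 <- Bfun(c("D", "U", "R", "S"))
  expect_lt(abs(B1 - B2) / abs(1 - B1), 1e-3)
  expect_error(compose_operators(ops[[1]], ops[[2]], ops[[3]],
                                 build_operator("drift", p0, N = 10,
                                                basis = build_basis(3))),
               "share one moment basis")
})
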