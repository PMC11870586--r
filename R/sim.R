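# Simulation oracles: an exact two-locus Wright-Fisher Markov chain for tiny
# populations, and a forward-in-time two-locus simulator with deterministic
# selection/recombination/mutation and multinomial drift.

# deterministic one-generation maps on haplotype frequencies (exact forms)
deterministic_step <- function(x, params, forces = c("selection", "recombination", "mutation")) {
  # x: 4 x k matrix of (x_AB, x_Ab, x_aB, x_ab) columns
  s <- params$s; r <- params$r; u <- params$u_left
  if ("selection" %in% forces && s != 0) {
    w <- 1 + s * (x[1L, ] + x[2L, ])
    x[1L, ] <- x[1L, ] * (1 + s) / w
    x[2L, ] <- x[2L, ] * (1 + s) / w
    x[3L, ] <- x[3L, ] / w
    x[4L, ] <- x[4L, ] / w
  }
  if ("recombination" %in% forces && r != 0) {
    D <- x[1L, ] * x[4L, ] - x[2L, ] * x[3L, ]
    x[1L, ] <- x[1L, ] - r * D
    x[2L, ] <- x[2L, ] + r * D
    x[3L, ] <- x[3L, ] + r * D
    x[4L, ] <- x[4L, ] - r * D
  }
  if ("mutation" %in% forces && u != 0) {
    # recurrent symmetric mutation at the left locus (A <-> a)
    x1 <- x[1L, ] * (1 - u) + u * x[3L, ]
    x2 <- x[2L, ] * (1 - u) + u * x[4L, ]
    x3 <- x[3L, ] * (1 - u) + u * x[1L, ]
    x4 <- x[4L, ] * (1 - u) + u * x[2L, ]
    x[1L, ] <- x1; x[2L, ] <- x2; x[3L, ] <- x3; x[4L, ] <- x4
  }
  x
}

#' Exact two-locus Wright-Fisher chain for tiny populations
#'
#' Enumerates all haplotype-count states (n_AB, n_Ab, n_aB, n_ab) summing to
#' 2N, applies the deterministic selection/recombination/mutation maps to
#' the frequencies and builds the exact multinomial transition kernel.
#' Serves as the independent oracle for the operator matrices.
#'
#' @param params \code{\link{two_locus_params}}.
#' @param N_small Diploid size with 2*N_small <= 12.
#' @param forces Which deterministic forces to apply before resampling.
#' @return A list with \code{states} (matrix of counts), \code{M} (=2N) and
#'   \code{transition} (dense row-stochastic matrix).
#' @export
exact_wf_chain <- function(params, N_small,
                           forces = c("selection", "recombination", "mutation")) {
  M <- as.integer(round(2 * N_small))
  if (M > 12L) stop("2N must be <= 12 for exact enumeration")
  grid <- expand.grid(n1 = 0:M, n2 = 0:M, n3 = 0:M)
  grid <- grid[grid$n1 + grid$n2 + grid$n3 <= M, , drop = FALSE]
  states <- cbind(grid$n1, grid$n2, grid$n3, M - grid$n1 - grid$n2 - grid$n3)
  ns <- nrow(states)
  lgam <- lgamma(seq_len(M + 1L))          # lgamma(n+1) for n = 0..M
  lmult <- lgamma(M + 1) - (lgam[states[, 1L] + 1L] + lgam[states[, 2L] + 1L] +
                            lgam[states[, 3L] + 1L] + lgam[states[, 4L] + 1L])
  TR <- matrix(0, ns, ns)
  xs <- deterministic_step(t(states) / M, params, forces)
  for (i in seq_len(ns)) {
    pr <- xs[, i]
    lp <- log(ifelse(pr > 0, pr, 1))
    bad <- pr <= 0
    lrow <- lmult + states %*% lp
    if (any(bad))
      lrow[rowSums(states[, bad, drop = FALSE]) > 0] <- -Inf
    TR[i, ] <- exp(lrow)
  }
  list(states = states, M = M, transition = TR)
}

#' One-generation expectations of basis moments under the exact chain
#'
#' @param chain Result of \code{\link{exact_wf_chain}}.
#' @param basis A moment basis.
#' @param x0 Initial haplotype frequencies (length 4, multiples of 1/2N).
#' @return Named numeric vector of exact one-generation expectations
#'   E[f(x')] for every basis moment f.
#' @export
chain_moment_step <- function(chain, basis, x0) {
  M <- chain$M
  n0 <- round(x0 * M)
  if (any(abs(n0 - x0 * M) > 1e-9)) stop("x0 must be multiples of 1/(2N)")
  i0 <- which(apply(chain$states, 1L, function(s) all(s == n0)))
  pr <- chain$transition[i0, ]
  xs <- chain$states / M
  vapply(basis$id, function(id) {
    f <- moment_polynomial(id)
    sum(pr * f(xs[, 1L], xs[, 2L], xs[, 3L], xs[, 4L]))
  }, numeric(1L))
}

#' Forward-in-time two-locus simulator
#'
#' Recombination, selection and one-way mutation operate deterministically
#' on haplotype frequencies; drift is multinomial resampling of 2N
#' haplotypes each generation (sampled as a chain of binomials, vectorized
#' over replicates).  Neutral diversity at the right locus accrues by
#' recurrent symmetric low-rate mutation, matching the moment model's
#' influx assumption.
#'
#' @param params \code{\link{two_locus_params}}.
#' @param dem A \code{\link{demography}} (piecewise-constant sizes).
#' @param n_reps Number of replicate populations.
#' @param t Number of generations to simulate (defaults to the demography's
#'   finite span, or 10N for a single-epoch model).
#' @param seed RNG seed; fixed seed gives bitwise-reproducible output.
#' @param record_every Generations between recorded ensemble statistics.
#' @param x0 Initial haplotype frequencies (default: ancestral-equilibrium
#'   frequencies with the derived alleles absent, q = 0.5 at the right
#'   locus so pi_R starts at its maximum; see details in the vignette).
#' @param burn Generations to discard from the per-replicate time averages.
#' @param keep_reps Attach per-replicate time averages (over the recorded
#'   generations after \code{burn}) as attribute \code{"rep_means"} — the
#'   basis for honest Monte-Carlo standard errors, since replicates are
#'   independent while consecutive snapshots are not.
#' @return A data frame time series of ensemble means and Monte-Carlo
#'   standard errors for E[pi_L], E[pi_R], E[D], E[D^2], E[D(1-2q)].
#' @export
two_locus_forward <- function(params, dem, n_reps = 100L, t = NULL,
                              seed = 1L, record_every = 100L,
                              x0 = c(0, 0, 0.5, 0.5), burn = 0L,
                              keep_reps = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  sizes <- epoch_sizes_forward(dem, t)
  t <- length(sizes)
  x <- matrix(x0, nrow = 4L, ncol = n_reps)
  recs <- list()
  rep_acc <- matrix(0, n_reps, 5L,
                    dimnames = list(NULL, c("piL", "piR", "D", "D2", "Dz")))
  n_acc <- 0L
  u_r <- params$u_right
  for (g in seq_len(t)) {
    x <- deterministic_step(x, params)
    if (u_r > 0) { # symmetric recurrent mutation at the right locus
      x1 <- x[1L, ] * (1 - u_r) + x[2L, ] * u_r
      x2 <- x[2L, ] * (1 - u_r) + x[1L, ] * u_r
      x3 <- x[3L, ] * (1 - u_r) + x[4L, ] * u_r
      x4 <- x[4L, ] * (1 - u_r) + x[3L, ] * u_r
      x[1L, ] <- x1; x[2L, ] <- x2; x[3L, ] <- x3; x[4L, ] <- x4
    }
    M <- 2L * sizes[g]
    # multinomial via a chain of binomials, vectorized across replicates
    n1 <- rbinom(n_reps, M, pmin(pmax(x[1L, ], 0), 1))
    p2 <- ifelse(x[1L, ] < 1, x[2L, ] / (1 - x[1L, ]), 0)
    n2 <- rbinom(n_reps, M - n1, pmin(pmax(p2, 0), 1))
    p3 <- ifelse(x[3L, ] + x[4L, ] > 0, x[3L, ] / (x[3L, ] + x[4L, ]), 0)
    n3 <- rbinom(n_reps, M - n1 - n2, pmin(pmax(p3, 0), 1))
    x <- rbind(n1, n2, n3, M - n1 - n2 - n3) / M
    if (g %% record_every == 0L || g == t) {
      p <- x[1L, ] + x[2L, ]; q <- x[1L, ] + x[3L, ]
      D <- x[1L, ] * x[4L, ] - x[2L, ] * x[3L, ]
      stats <- rbind(piL = 2 * p * (1 - p), piR = 2 * q * (1 - q),
                     D = D, D2 = D^2, Dz = D * (1 - 2 * q))
      recs[[length(recs) + 1L]] <- data.frame(
        generation = g,
        statistic = rownames(stats),
        mean = rowMeans(stats),
        se = apply(stats, 1L, stats::sd) / sqrt(n_reps),
        row.names = NULL)
      if (keep_reps && g > burn) {
        rep_acc <- rep_acc + t(stats)
        n_acc <- n_acc + 1L
      }
    }
  }
  out <- do.call(rbind, recs)
  attr(out, "seed") <- seed
  if (keep_reps && n_acc > 0L) attr(out, "rep_means") <- rep_acc / n_acc
  out
}

# expand a demography into a per-generation vector of sizes (forward view)
epoch_sizes_forward <- function(dem, t = NULL) {
  ep <- dem$epochs
  finite <- ep$duration[is.finite(ep$duration)]
  if (is.null(t)) t <- if (length(finite)) sum(finite) else 10L * ep$N[1L]
  t <- as.integer(t)
  # ancestral epoch absorbs any remainder at the start
  durs <- ep$duration
  durs[1L] <- max(0L, t - sum(durs[-1L][is.finite(durs[-1L])], 0))
  sizes <- unlist(lapply(seq_len(nrow(ep)), function(i)
    rep(as.integer(round(ep$N[i])), as.integer(durs[i]))))
  if (length(sizes) > t) sizes <- sizes[(length(sizes) - t + 1L):length(sizes)]
  sizes
}
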