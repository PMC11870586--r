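# Equilibrium and time-dependent solutions of the moment system.

#' Equilibrium moment vector of a composite operator
#'
#' Solves the fixed point v = M v with the constant coordinate pinned to 1,
#' i.e. the linear system (I - M') v' = m where M' is the non-constant block
#' and m the affine (constant) column.  A condition-number estimate guards
#' against the near-singularity that high truncation orders induce under
#' strong selection.
#'
#' @param M Composite operator matrix (see \code{\link{compose_operators}}).
#' @param cond_max Conditioning threshold above which a numerical-stability
#'   error is raised.
#' @return A \code{moment_vector}.
#' @export
equilibrium_state <- function(M, cond_max = 1e12) {
  basis <- attr(M, "basis")
  mono <- attr(M, "mono")
  n <- nrow(M)
  ione <- which(mono$id == "y.0")
  idx <- setdiff(seq_len(n), ione)
  A <- Matrix::Diagonal(n - 1L) - M[idx, idx, drop = FALSE]
  b <- M[idx, ione]
  # with no deleterious input (u_left = 0) the pure-y block is exactly
  # conserved (E[y'] = y) and those coordinates are undetermined by the
  # fixed point; pin them to the no-deleterious boundary y^a = 1
  rmax <- apply(abs(A), 1L, max)
  pin <- which(rmax == 0)
  if (length(pin)) {
    if (!all(mono$family[idx[pin]] == "y"))
      stop("unexpected conserved coordinates outside the pure-y family")
    keep <- setdiff(seq_len(n - 1L), pin)
    b2 <- b[keep] + as.numeric(M[idx[keep], idx[pin], drop = FALSE] %*%
                                 rep(1, length(pin)))
    A <- A[keep, keep, drop = FALSE]
    kappa <- tryCatch(Matrix::condest(A)$est, error = function(e) Inf)
    if (!is.finite(kappa) || kappa > cond_max)
      stop("moment system is ill-conditioned at this truncation order; ",
           "lower j_max or enable mutation-rate scaling", call. = FALSE)
    v <- numeric(n - 1L)
    v[pin] <- 1
    v[keep] <- as.numeric(Matrix::solve(A, b2))
    vals <- numeric(n)
    vals[idx] <- v
    vals[ione] <- 1
    return(moment_vector(vals, mono, basis))
  }
  kappa <- tryCatch(Matrix::condest(A)$est, error = function(e) Inf)
  if (!is.finite(kappa) || kappa > cond_max)
    stop("moment system is ill-conditioned at this truncation order ",
         sprintf("(condition estimate %.3g); ", kappa),
         "lower j_max or enable mutation-rate scaling", call. = FALSE)
  v <- as.numeric(Matrix::solve(A, b))
  vals <- numeric(n)
  vals[idx] <- v
  vals[ione] <- 1
  out <- moment_vector(vals, mono, basis)
  res <- max(abs(vals - as.numeric(M %*% vals)))
  if (res > 1e-10 * max(1, max(abs(vals))))
    warning(sprintf("equilibrium residual %.3e exceeds tolerance", res))
  out
}

#' Iterate the moment system forward in time
#'
#' Computes v(t) = M^t v0 by sparse iteration, optionally recording the
#' state at intermediate generations.
#'
#' @param v0 Initial \code{moment_vector}.
#' @param M Composite operator matrix on the same basis.
#' @param t Number of generations (non-negative integer).
#' @param record At which generations (0..t) to record the full state.
#' @return If \code{record} is NULL, the final \code{moment_vector};
#'   otherwise a list with \code{final} and a matrix \code{states} (one
#'   column per recorded generation).
#' @export
evolve <- function(v0, M, t, record = NULL) {
  stopifnot(t >= 0, t == round(t))
  v <- v0$mono
  basis <- v0$basis
  mono <- v0$mono_basis
  rec <- NULL
  if (!is.null(record)) {
    record <- sort(unique(as.integer(record)))
    rec <- matrix(NA_real_, length(v), length(record),
                  dimnames = list(mono$id, record))
  }
  ri <- 1L
  for (g in 0:t) {
    if (!is.null(rec) && ri <= length(record) && record[ri] == g) {
      rec[, ri] <- v
      ri <- ri + 1L
    }
    if (g < t) {
      v <- as.numeric(M %*% v)
      if (!all(is.finite(v)))
        stop("moment iteration lost numerical precision ",
             "(high-order moments under/overflowed); ",
             "scaling up the mutation rate restores numerical precision",
             call. = FALSE)
    }
  }
  out <- moment_vector(v, mono, basis)
  if (is.null(rec)) out else list(final = out, states = rec)
}

# value of one moment from a moment_vector
moment_value <- function(v, id) v$values[match(id, v$basis$id)]

#' Equilibrium B-value of the pure two-locus moment system
#'
#' B = E[pi_R]/(4 N u_right): the neutral recurrent-influx equilibrium of
#' the same system is exactly 4 N u_right, so the ratio needs no second
#' solve.
#'
#' @param params \code{\link{two_locus_params}}.
#' @param N Diploid population size.
#' @param j_max Truncation order; use \code{\link{auto_truncation}} if NULL.
#' @param mutation_scale Optional multiplier k applied to both mutation
#'   rates to restore numerical precision in hard regimes; the resulting
#'   log B is divided by k (the per-unit-mutation reduction is what the
#'   B-value measures), so the returned B is invariant to k up to
#'   O(k (1-B)^2).
#' @return B in (0, 1].
#' @export
two_locus_B_equilibrium <- function(params, N, j_max = NULL,
                                    mutation_scale = 1) {
  if (is.null(j_max)) j_max <- auto_truncation(params, N)
  if (mutation_scale != 1)
    params <- two_locus_params(params$s, params$u_left * mutation_scale,
                               params$u_right * mutation_scale, params$r)
  basis <- build_basis(j_max)
  M <- epoch_operator(params, N, basis)
  v <- equilibrium_state(M)
  piR <- moment_value(v, "piR")
  B <- piR / (4 * N * params$u_right)
  if (mutation_scale != 1) B <- max(B, 1e-300)^(1 / mutation_scale)
  B
}

#' Choose the (1-2p)^j truncation order automatically
#'
#' Increases j_max in steps of 5 until the predicted equilibrium B changes
#' by less than \code{tol} (absolute), subject to the conditioning check.
#' The required order grows supra-linearly with |2 N s|.
#'
#' @param params \code{\link{two_locus_params}}; requires |s| <= 0.005, the
#'   moment system's supported range (use the structured-coalescent model
#'   beyond).
#' @param N Diploid population size used for the convergence assessment
#'   (for multi-epoch models, the largest size the system will traverse).
#' @param tol Absolute tolerance on B between successive steps.
#' @param step Step size in j_max.
#' @param j_cap Upper bound; exceeding it raises an error recommending the
#'   structured-coalescent path.
#' @return The selected j_max (integer).
#' @export
auto_truncation <- function(params, N, tol = 1e-6, step = 5L, j_cap = 400L) {
  if (abs(params$s) > 0.005)
    stop("|s| > 0.005 is outside the moment system's supported range; ",
         "use the structured-coalescent model", call. = FALSE)
  if (params$s == 0 || params$u_left == 0) return(0L)
  # start above the scaled strength; convergence requires j of order
  # 2-3x |2Ns| and is supra-linear in |2Ns|
  j <- max(5L, as.integer(ceiling(2.5 * abs(2 * N * params$s))))
  B_prev <- two_locus_B_equilibrium(params, N, j_max = j)
  repeat {
    j2 <- j + step
    if (j2 > j_cap)
      stop("no stable adequate truncation order found below ", j_cap,
           "; use the structured-coalescent model for this regime",
           call. = FALSE)
    B_new <- two_locus_B_equilibrium(params, N, j_max = j2)
    if (abs(B_new - B_prev) < tol) return(j)
    j <- j2
    B_prev <- B_new
  }
}
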