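# Per-generation operator matrices on the moment basis.
#
# Selection, recombination and mutation act deterministically on haplotype
# frequencies; their action on a moment is obtained by substituting the
# one-generation map into the moment polynomial (selection linearized to
# first order in s; recombination and mutation exact).  Drift is
# the exact expectation under multinomial resampling of 2N haplotypes,
# computed channel by channel with a stable recursion on the factorial
# moment generating function (see the methods vignette): in the coordinates
# y = 1-2p, z = 1-2q, D every coefficient that enters the recursion lies in
# [-1, 1] up to small eigenvalue shifts, so no catastrophic cancellation
# occurs even at high (1-2p)^j truncation orders.

# ---- drift ----------------------------------------------------------------

# Sweep engine.  One "channel" is an invariant factor P with A/B eigenvalues
# (ly, lz) left by differentiating the mgf h^M (h = sum x_i e^{theta_i});
# the remaining state is a combination of h^{M-d0-j} h_y^{k1} h_z^{k2}
# h_yz^{k3}, evolved by the normalized operators A/M and B/M, where A and B
# pull down M*y' and M*z'.  Evaluating at theta = 0 maps a state to a
# polynomial via h -> 1, h_y -> y, h_z -> z, h_yz -> yz + 4D.
.drift_cfgs <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L),
                     c(2L, 0L), c(1L, 1L), c(0L, 2L))
.cfg_idx <- function(k2, k3) {
  for (i in seq_len(nrow(.drift_cfgs)))
    if (.drift_cfgs[i, 1L] == k2 && .drift_cfgs[i, 2L] == k3) return(i)
  stop("bad drift state configuration")
}

.drift_stepA <- function(ST, M, d0, ly) {
  Kp1 <- nrow(ST)
  NEW <- matrix(0, Kp1, 6L)
  k1 <- 0:(Kp1 - 1L)
  for (ci in 1:6) {
    v <- ST[, ci]
    if (!any(v != 0)) next
    k2 <- .drift_cfgs[ci, 1L]; k3 <- .drift_cfgs[ci, 2L]
    wup <- (M - d0 - (k1 + k2 + k3)) / M
    NEW[2:Kp1, ci] <- NEW[2:Kp1, ci] + v[1:(Kp1 - 1L)] * wup[1:(Kp1 - 1L)]
    NEW[1:(Kp1 - 1L), ci] <- NEW[1:(Kp1 - 1L), ci] + v[2:Kp1] * (k1[2:Kp1] / M)
    if (k2 > 0L) {
      cj <- .cfg_idx(k2 - 1L, k3 + 1L)
      NEW[, cj] <- NEW[, cj] + v * (k2 / M)
    }
    if (k3 > 0L) {
      cj <- .cfg_idx(k2 + 1L, k3 - 1L)
      NEW[, cj] <- NEW[, cj] + v * (k3 / M)
    }
    if (ly != 0) NEW[, ci] <- NEW[, ci] + v * (ly / M)
  }
  NEW
}

.drift_stepB <- function(ST, M, d0, lz) {
  Kp1 <- nrow(ST)
  NEW <- matrix(0, Kp1, 6L)
  k1 <- 0:(Kp1 - 1L)
  for (ci in 1:6) {
    v <- ST[, ci]
    if (!any(v != 0)) next
    k2 <- .drift_cfgs[ci, 1L]; k3 <- .drift_cfgs[ci, 2L]
    wup <- (M - d0 - (k1 + k2 + k3)) / M
    if (k2 + k3 < 2L) {
      cj <- .cfg_idx(k2 + 1L, k3)
      NEW[, cj] <- NEW[, cj] + v * wup
    }
    if (k2 > 0L) {
      cj <- .cfg_idx(k2 - 1L, k3)
      NEW[, cj] <- NEW[, cj] + v * (k2 / M)
    }
    # h_y -> h_yz lowers k1 by one
    if (k2 + k3 < 2L) {
      cj <- .cfg_idx(k2, k3 + 1L)
      NEW[1:(Kp1 - 1L), cj] <- NEW[1:(Kp1 - 1L), cj] + v[2:Kp1] * (k1[2:Kp1] / M)
    }
    if (k3 > 0L) {
      cj <- .cfg_idx(k2, k3 - 1L)
      NEW[2:Kp1, cj] <- NEW[2:Kp1, cj] + v[1:(Kp1 - 1L)] * (k3 / M)
    }
    if (lz != 0) NEW[, ci] <- NEW[, ci] + v * (lz / M)
  }
  NEW
}

# run one channel: returns list of polynomials, entry a+1 = contribution to
# E[y'^a z'^b D'^c] for a = 0..amax
.drift_run <- function(ay, M, d0, nB, pre, Pval, ly = 0, lz = 0, amax) {
  Kp1 <- amax + 4L
  ST <- matrix(0, Kp1, 6L)
  ST[1L, 1L] <- pre
  for (b in seq_len(nB)) ST <- .drift_stepB(ST, M, d0, lz)

  # per-configuration polynomial z^{k2} (yz + 4D)^{k3} * Pval
  w <- p_new(ay); w[2L, 2L, 1L] <- 1; w[1L, 1L, 2L] <- 4
  zp <- p_mono(ay, 0L, 1L, 0L)
  polyc <- vector("list", 6L)
  for (ci in 1:6) {
    k2 <- .drift_cfgs[ci, 1L]; k3 <- .drift_cfgs[ci, 2L]
    if (k2 + k3 > nB) next # state never populated
    Q <- Pval
    for (i in seq_len(k2)) Q <- p_mul(Q, zp)
    for (i in seq_len(k3)) Q <- p_mul(Q, w)
    polyc[[ci]] <- Q
  }

  out <- vector("list", amax + 1L)
  for (a in 0:amax) {
    P <- p_new(ay)
    for (ci in 1:6) {
      v <- ST[, ci]
      nzv <- which(v != 0)
      if (!length(nzv) || is.null(polyc[[ci]])) next
      pc <- polyc[[ci]]
      nzp <- which(pc != 0, arr.ind = TRUE)
      for (r in seq_len(nrow(nzp))) {
        a0 <- nzp[r, 1L] - 1L
        cf <- pc[nzp[r, 1L], nzp[r, 2L], nzp[r, 3L]]
        rows <- nzv - 1L + a0 + 1L
        P[rows, nzp[r, 2L], nzp[r, 3L]] <- P[rows, nzp[r, 2L], nzp[r, 3L]] +
          cf * v[nzv]
      }
    }
    out[[a + 1L]] <- P
    if (a < amax) ST <- .drift_stepA(ST, M, d0, ly)
  }
  out
}

# exact multinomial expectations of the four monomial channels the basis
# needs: E[y'^a], E[y'^a z'^2], E[y'^a z' D'], E[y'^a D'^2], a = 0..amax
drift_channel_images <- function(ay, M, amax) {
  one <- p_mono(ay, 0L, 0L, 0L)
  Dp <- p_mono(ay, 0L, 0L, 1L)
  D2 <- p_mono(ay, 0L, 0L, 2L)

  x1 <- p_hap(ay, "AB"); x2 <- p_hap(ay, "Ab")
  x3 <- p_hap(ay, "aB"); x4 <- p_hap(ay, "ab")
  x14 <- p_mul(x1, x4)
  x23 <- p_mul(x2, x3)

  b0c0 <- .drift_run(ay, M, 0L, 0L, 1, one, amax = amax)
  b2c0 <- .drift_run(ay, M, 0L, 2L, 1, one, amax = amax)
  b1c1 <- .drift_run(ay, M, 2L, 1L, (M - 1) / M, Dp, amax = amax)

  f1 <- (M - 1) / M; f2 <- (M - 2) / M; f3 <- (M - 3) / M
  term1 <- .drift_run(ay, M, 4L, 0L, f1 * f2 * f3, D2, amax = amax)
  pre2 <- f1 * f2 / M
  tA <- .drift_run(ay, M, 3L, 0L, pre2, p_mul(x1, x14), ly = -1, amax = amax)
  tB <- .drift_run(ay, M, 3L, 0L, pre2, p_mul(x4, x14), ly = +1, amax = amax)
  tC <- .drift_run(ay, M, 3L, 0L, pre2, p_mul(x2, x23), ly = -1, amax = amax)
  tD <- .drift_run(ay, M, 3L, 0L, pre2, p_mul(x3, x23), ly = +1, amax = amax)
  term3 <- .drift_run(ay, M, 2L, 0L, f1 / M^2, p_add(x14, x23), amax = amax)
  b0c2 <- lapply(seq_len(amax + 1L), function(i)
    term1[[i]] + tA[[i]] + tB[[i]] + tC[[i]] + tD[[i]] + term3[[i]])

  list(b0c0 = b0c0, b2c0 = b2c0, b1c1 = b1c1, b0c2 = b0c2)
}

# drift image of an arbitrary basis polynomial (z-degree <= 2, D-degree <= 2)
drift_image_poly <- function(P, ch) {
  ay <- p_ay(P)
  out <- p_new(ay)
  nz <- which(P != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    a <- nz[r, 1L] - 1L; b <- nz[r, 2L] - 1L; c <- nz[r, 3L] - 1L
    cf <- P[nz[r, 1L], nz[r, 2L], nz[r, 3L]]
    key <- if (b == 0L && c == 0L) "b0c0"
      else if (b == 2L && c == 0L) "b2c0"
      else if (b == 1L && c == 1L) "b1c1"
      else if (b == 0L && c == 2L) "b0c2"
      else stop("monomial y^a z^", b, " D^", c, " is outside the drift channels")
    out <- out + cf * ch[[key]][[a + 1L]]
  }
  out
}

# ---- deterministic forces (first-order images) ----------------------------

# selection, linear term in s: dy = -s(1-y^2)/2, dz = -2sD, dD = s y D
sel_image_poly <- function(P) {
  ay <- p_ay(P)
  out <- p_new(ay)
  nz <- which(P != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    a <- nz[r, 1L] - 1L; b <- nz[r, 2L] - 1L; c <- nz[r, 3L] - 1L
    cf <- P[nz[r, 1L], nz[r, 2L], nz[r, 3L]]
    if (a > 0L) { # a * y^(a-1) * dy/s = -(a/2)(y^{a-1} - y^{a+1})
      out[a, b + 1L, c + 1L] <- out[a, b + 1L, c + 1L] - cf * a / 2
      out[a + 2L, b + 1L, c + 1L] <- out[a + 2L, b + 1L, c + 1L] + cf * a / 2
    }
    if (b > 0L) # b * z^(b-1) * dz/s = -2b D z^{b-1}
      out[a + 1L, b, c + 2L] <- out[a + 1L, b, c + 2L] - 2 * b * cf
    if (c > 0L) # c * D^(c-1) * dD/s = c y D^c
      out[a + 2L, b + 1L, c + 1L] <- out[a + 2L, b + 1L, c + 1L] + c * cf
  }
  out
}

# recurrent (symmetric) mutation at the left locus, exact image:
# y' = (1-2u) y, z' = z, D' = (1-2u) D, so a monomial y^a z^b D^c simply
# scales by (1-2u)^(a+c).  This is the mutation model under which the
# (1-2p)^j-augmented basis closes exactly; the mutation-selection balance it
# implies, p = u/(|s|+2u), matches the one-way balance u/|s| to O(p^2).
mutation_image_poly <- function(P, u) {
  ay <- p_ay(P)
  out <- p_new(ay)
  nz <- which(P != 0, arr.ind = TRUE)
  f <- 1 - 2 * u
  for (r in seq_len(nrow(nz))) {
    a <- nz[r, 1L] - 1L; c <- nz[r, 3L] - 1L
    out[nz[r, 1L], nz[r, 2L], nz[r, 3L]] <-
      P[nz[r, 1L], nz[r, 2L], nz[r, 3L]] * f^(a + c)
  }
  out
}

# ---- operator construction ------------------------------------------------

.op_cache <- new.env(parent = emptyenv())

#' Build a per-generation operator matrix for one evolutionary force
#'
#' Returns the sparse matrix acting on moment-vector expectations for one of
#' the forces (or see \code{\link{compose_operators}} for their product).
#' Affine terms (the neutral mutational influx 2u into E[pi_R]) are carried
#' in the constant-coordinate column, so all operators are square.  Each
#' single-force operator reduces to the identity when its parameter is
#' switched off.
#'
#' @param force One of \code{"selection"}, \code{"recombination"},
#'   \code{"mutation"}, \code{"drift"}.
#' @param params A \code{\link{two_locus_params}} object.
#' @param N Diploid population size (required for drift).
#' @param basis A \code{\link{build_basis}} result.
#' @details The matrix acts on the internal monomial representation
#'   (families y^a, y^a z^2, y^a z D, y^a D^2 with a = 0..j_max+2, y = 1-2p,
#'   z = 1-2q), on which the system closes exactly; moment-basis values are
#'   exact linear projections of that state.  Drift and the (symmetric
#'   recurrent) mutation operator are exact; recombination is exact; the
#'   selection operator is linearized to first order in s.
#' @return A sparse \code{\link[Matrix]{dgCMatrix-class}} matrix with
#'   attributes \code{force}, \code{basis} (the reporting moment basis) and
#'   \code{mono} (the monomial basis indexing rows/columns).
#' @export
build_operator <- function(force, params, N = NULL, basis) {
  force <- match.arg(force, c("selection", "recombination", "mutation", "drift"))
  j_max <- attr(basis, "j_max")
  mono <- monomial_basis(j_max)
  n <- nrow(mono)
  A <- attr(mono, "A")
  ay <- A + 8L

  wrap <- function(M) {
    M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    dimnames(M) <- list(mono$id, mono$id)
    structure(M, force = force, basis = basis, mono = mono)
  }

  if (force == "recombination") {
    r <- params$r
    d <- rep(1, n)
    d[mono$family == "Dz"] <- 1 - r
    d[mono$family == "D2"] <- (1 - r)^2
    return(wrap(Matrix::Diagonal(n, d)))
  }

  if (force == "mutation") {
    # exact left-locus action: y' = (1-2u) y, z' = z, D' = (1-2u) D
    f <- 1 - 2 * params$u_left
    cD <- ifelse(mono$family == "Dz", 1L, ifelse(mono$family == "D2", 2L, 0L))
    diagf <- f^(mono$a + cD)
    if (isTRUE(params$right_recurrent)) {
      # symmetric recurrent mutation at the right locus too:
      # z' = (1-2u_R) z, D' = (1-2u_R) D (finite-alleles model)
      fr <- 1 - 2 * params$u_right
      bz <- ifelse(mono$family == "z2", 2L, ifelse(mono$family == "Dz", 1L, 0L))
      diagf <- diagf * fr^(bz + cD)
      return(wrap(Matrix::Diagonal(n, diagf)))
    }
    M <- as.matrix(Matrix::Diagonal(n, diagf))
    # infinite-sites influx at the neutral right locus: for every a,
    # E[pi_R y^a] gains 2 u_right E[y^a], i.e. E[z^2 y^a] loses 4 u_right E[y^a]
    if (params$u_right > 0) {
      iz <- which(mono$family == "z2")
      iy <- match(sprintf("y.%d", mono$a[iz]), mono$id)
      M[cbind(iz, iy)] <- M[cbind(iz, iy)] - 4 * params$u_right
    }
    return(wrap(M))
  }

  rows <- vector("list", n)
  if (force == "drift") {
    if (is.null(N) || N < 1) stop("drift requires a diploid size N >= 1")
    key <- sprintf("drift|%d|%.17g", j_max, N)
    cached <- .op_cache[[key]]
    if (!is.null(cached)) return(cached)
    ch <- drift_channel_images(ay, 2 * N, amax = A)
    for (i in seq_len(n)) {
      P <- mono_element_poly(mono$family[i], mono$a[i], ay)
      rows[[i]] <- poly_to_mono(drift_image_poly(P, ch), mono)
    }
  } else { # selection, first order in s
    s <- params$s
    for (i in seq_len(n)) {
      P <- mono_element_poly(mono$family[i], mono$a[i], ay)
      img <- P + s * sel_image_poly(P)
      rows[[i]] <- poly_to_mono(img, mono)
    }
  }

  M <- do.call(rbind, rows)
  M[abs(M) < 1e-300] <- 0
  out <- wrap(M)
  if (force == "drift") .op_cache[[key]] <- out
  out
}

#' Compose the four single-force operators into one generation
#'
#' The composite transition matrix is the product M = S R U D acting on the
#' moment vector (drift applied first within a generation, selection last);
#' the multiplicative composition retains cross-terms as small as
#' O(u r s / 2N).  Re-ordering the factors amounts to permuting the life
#' cycle and has negligible impact on predictions.
#'
#' @param S,R,U,D Operator matrices from \code{\link{build_operator}}
#'   sharing one basis.
#' @return The composite sparse operator matrix.
#' @export
compose_operators <- function(S, R, U, D) {
  b <- attr(S, "basis")
  for (x in list(R, U, D)) {
    bb <- attr(x, "basis")
    if (is.null(bb) || nrow(bb) != nrow(b) || attr(bb, "j_max") != attr(b, "j_max"))
      stop("operators must share one moment basis")
  }
  M <- S %*% R %*% U %*% D
  structure(methods::as(M, "CsparseMatrix"), force = "composite", basis = b,
            mono = attr(S, "mono"))
}

# build the composite one-generation operator for one epoch
epoch_operator <- function(params, N, basis, order = c("S", "R", "U", "D")) {
  ops <- list(
    S = build_operator("selection", params, basis = basis),
    R = build_operator("recombination", params, basis = basis),
    U = build_operator("mutation", params, basis = basis),
    D = build_operator("drift", params, N = N, basis = basis)
  )
  M <- ops[[order[1L]]] %*% ops[[order[2L]]] %*% ops[[order[3L]]] %*% ops[[order[4L]]]
  structure(methods::as(M, "CsparseMatrix"), force = "composite", basis = basis,
            mono = attr(ops$S, "mono"))
}
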