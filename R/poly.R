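# Internal polynomial algebra over the two-locus coordinates
#   y = 1 - 2p,  z = 1 - 2q,  D = x_AB x_ab - x_Ab x_aB,
# where p and q are derived-allele frequencies at the selected (left) and
# neutral (right) locus.  Every moment the system tracks is a polynomial in
# (y, z, D); working in these coordinates keeps all coefficients O(1), which
# is what makes high truncation orders numerically viable.
#
# A polynomial is stored as a dense 3-d array coef[a+1, b+1, c+1] giving the
# coefficient of y^a z^b D^c.  z-degree <= 6 and D-degree <= 3 bound every
# intermediate quantity the operator derivations produce.

.PZ <- 7L # z powers 0..6
.PD <- 4L # D powers 0..3

p_new <- function(ay) array(0, dim = c(ay + 1L, .PZ, .PD))

p_mono <- function(ay, a, b, c, coef = 1) {
  P <- p_new(ay)
  P[a + 1L, b + 1L, c + 1L] <- coef
  P
}

p_ay <- function(P) dim(P)[1L] - 1L

p_add <- function(P, Q) P + Q

# multiply two polynomials; error (rather than silently drop) on overflow
p_mul <- function(P, Q) {
  R <- p_new(p_ay(P))
  nzP <- which(P != 0, arr.ind = TRUE)
  nzQ <- which(Q != 0, arr.ind = TRUE)
  if (nrow(nzP) == 0L || nrow(nzQ) == 0L) return(R)
  for (i in seq_len(nrow(nzP))) {
    cfP <- P[nzP[i, 1L], nzP[i, 2L], nzP[i, 3L]]
    a <- nzP[i, 1L] + nzQ[, 1L] - 2L
    b <- nzP[i, 2L] + nzQ[, 2L] - 2L
    c <- nzP[i, 3L] + nzQ[, 3L] - 2L
    if (any(a > p_ay(R)) || any(b >= .PZ) || any(c >= .PD))
      stop("internal polynomial overflow (degree bounds exceeded)")
    for (k in seq_len(nrow(nzQ))) {
      R[a[k] + 1L, b[k] + 1L, c[k] + 1L] <- R[a[k] + 1L, b[k] + 1L, c[k] + 1L] +
        cfP * Q[nzQ[k, 1L], nzQ[k, 2L], nzQ[k, 3L]]
    }
  }
  R
}

# multiply by y^k (shift along the first dimension)
p_shift_y <- function(P, k) {
  if (k == 0L) return(P)
  ay <- p_ay(P)
  R <- p_new(ay)
  if (any(P[(ay - k + 2L):(ay + 1L), , ] != 0))
    stop("internal polynomial overflow in y-degree")
  R[(k + 1L):(ay + 1L), , ] <- P[1L:(ay + 1L - k), , ]
  R
}

# evaluate at numeric (y, z, D)
p_eval <- function(P, y, z, D) {
  nz <- which(P != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(0)
  sum(P[nz] * y^(nz[, 1L] - 1L) * z^(nz[, 2L] - 1L) * D^(nz[, 3L] - 1L))
}

# haplotype-frequency polynomials in (y, z, D):
#   x_AB = (1-y)(1-z)/4 + D   x_Ab = (1-y)(1+z)/4 - D
#   x_aB = (1+y)(1-z)/4 - D   x_ab = (1+y)(1+z)/4 + D
p_hap <- function(ay, which) {
  sy <- if (which %in% c("AB", "Ab")) -1 else 1
  sz <- if (which %in% c("AB", "aB")) -1 else 1
  sD <- if (which %in% c("AB", "ab")) 1 else -1
  P <- p_new(ay)
  P[1L, 1L, 1L] <- 1 / 4
  P[2L, 1L, 1L] <- sy / 4
  P[1L, 2L, 1L] <- sz / 4
  P[2L, 2L, 1L] <- sy * sz / 4
  P[1L, 1L, 2L] <- sD
  P
}
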