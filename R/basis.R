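#' Build the truncated Hill-Robertson moment basis with selection
#'
#' The two-locus system with selection at the left locus closes on four
#' families of moments augmented by powers of (1 - 2p): E[D^2 (1-2p)^j],
#' E[D (1-2p)^j (1-2q)], E[p(1-p)(1-2p)^j q(1-q)] and E[pi_L (1-2p)^j]
#' for 0 <= j <= j_max, plus E[pi_R] and a constant-1 coordinate that carries
#' affine terms (mutational influx).  Ordering is family-major with j
#' ascending and the constant coordinate last.
#'
#' @param j_max Maximum order of the (1-2p)^j augmentation (integer >= 0).
#' @return An object of class \code{moment_basis}: a data frame with columns
#'   \code{id}, \code{family}, \code{j}, with \code{j_max} stored as an
#'   attribute.  It has \code{4 * (j_max + 1) + 2} rows.
#' @examples
#' b <- build_basis(0)
#' nrow(b) # 6
#' @export
build_basis <- function(j_max) {
  if (length(j_max) != 1L || is.na(j_max) || j_max < 0 || j_max != round(j_max))
    stop("'j_max' must be a single non-negative integer")
  j_max <- as.integer(j_max)
  jj <- 0L:j_max
  df <- rbind(
    data.frame(family = "D2",  j = jj),
    data.frame(family = "Dz",  j = jj),
    data.frame(family = "pi2", j = jj),
    data.frame(family = "piL", j = jj),
    data.frame(family = c("piR", "one"), j = c(0L, 0L))
  )
  df$id <- ifelse(df$family %in% c("piR", "one"), df$family,
                  sprintf("%s_%d", df$family, df$j))
  df <- df[, c("id", "family", "j")]
  attr(df, "j_max") <- j_max
  class(df) <- c("moment_basis", "data.frame")
  df
}

# polynomial (in y, z, D) of one basis element
basis_element_poly <- function(family, j, ay) {
  P <- p_new(ay)
  switch(family,
    D2 = { P[j + 1L, 1L, 3L] <- 1 },
    Dz = { P[j + 1L, 2L, 2L] <- 1 },
    pi2 = { # p(1-p)q(1-q) y^j = (1-y^2)(1-z^2) y^j / 16
      P[j + 1L, 1L, 1L] <- 1 / 16; P[j + 3L, 1L, 1L] <- -1 / 16
      P[j + 1L, 3L, 1L] <- -1 / 16; P[j + 3L, 3L, 1L] <- 1 / 16
    },
    piL = { # 2p(1-p) y^j = (1-y^2) y^j / 2
      P[j + 1L, 1L, 1L] <- 1 / 2; P[j + 3L, 1L, 1L] <- -1 / 2
    },
    piR = { P[1L, 1L, 1L] <- 1 / 2; P[1L, 3L, 1L] <- -1 / 2 },
    one = { P[1L, 1L, 1L] <- 1 },
    stop("unknown moment family: ", family)
  )
  P
}

#' Polynomial representation of a moment identifier
#'
#' Maps a basis identifier to its exact polynomial in the haplotype
#' frequencies (x_AB, x_Ab, x_aB, x_ab), using p = x_AB + x_Ab,
#' q = x_AB + x_aB, D = x_AB x_ab - x_Ab x_aB, pi_L = 2p(1-p),
#' pi_R = 2q(1-q).
#'
#' @param id A basis identifier such as \code{"Dz_0"} or \code{"piR"} (see
#'   \code{\link{build_basis}}).
#' @return A function of \code{(xAB, xAb, xaB, xab)} evaluating the moment
#'   polynomial exactly; the identifier is kept in attribute \code{"id"} so
#'   the identifier -> polynomial -> identifier round trip is the identity.
#' @examples
#' f <- moment_polynomial("piR")
#' f(0.5, 0, 0.5, 0) # 2q(1-q) with q = 1
#' @export
moment_polynomial <- function(id) {
  parsed <- parse_moment_id(id)
  fam <- parsed$family
  j <- parsed$j
  fn <- function(xAB, xAb, xaB, xab) {
    tot <- xAB + xAb + xaB + xab
    if (any(abs(tot - 1) > 1e-9))
      stop("haplotype frequencies must sum to 1")
    p <- xAB + xAb
    q <- xAB + xaB
    D <- xAB * xab - xAb * xaB
    yp <- (1 - 2 * p)^j
    switch(fam,
      D2  = D^2 * yp,
      Dz  = D * yp * (1 - 2 * q),
      pi2 = p * (1 - p) * yp * q * (1 - q),
      piL = 2 * p * (1 - p) * yp,
      piR = 2 * q * (1 - q),
      one = rep(1, length(xAB))
    )
  }
  attr(fn, "id") <- id
  fn
}

parse_moment_id <- function(id) {
  if (id %in% c("piR", "one")) return(list(family = id, j = 0L))
  m <- regmatches(id, regexec("^(D2|Dz|pi2|piL)_([0-9]+)$", id))[[1L]]
  if (length(m) != 3L) stop("unknown moment identifier: ", id)
  list(family = m[2L], j = as.integer(m[3L]))
}

# ---- internal computational (monomial) basis ------------------------------
#
# The recursion system closes exactly on the four monomial families
#   y^a, y^a z^2, y^a z D, y^a D^2,   a = 0..A  (A = j_max + 2),
# with y^0 = 1 serving as the constant coordinate.  The spec'd moment basis
# (D^2 y^j, D y^j z, p(1-p)q(1-q) y^j, piL y^j, piR, 1) is an exact linear
# image of this representation and is used for reporting; the monomial form
# is what the operators act on.  Truncation drops y-powers above A (naive
# truncation of the (1-2p)^j hierarchy).
monomial_basis <- function(j_max) {
  A <- as.integer(j_max) + 2L
  aa <- 0L:A
  df <- rbind(
    data.frame(family = "y",  a = aa),
    data.frame(family = "z2", a = aa),
    data.frame(family = "Dz", a = aa),
    data.frame(family = "D2", a = aa)
  )
  df$id <- sprintf("%s.%d", df$family, df$a)
  df <- df[, c("id", "family", "a")]
  attr(df, "j_max") <- as.integer(j_max)
  attr(df, "A") <- A
  class(df) <- c("monomial_basis", "data.frame")
  df
}

mono_element_poly <- function(family, a, ay) {
  switch(family,
    y  = p_mono(ay, a, 0L, 0L),
    z2 = p_mono(ay, a, 2L, 0L),
    Dz = p_mono(ay, a, 1L, 1L),
    D2 = p_mono(ay, a, 0L, 2L),
    stop("unknown monomial family: ", family))
}

# read a polynomial off into monomial coordinates, truncating y-powers > A;
# channels outside the four families must vanish (up to cancellation noise)
poly_to_mono <- function(P, mono, tol = 1e-9) {
  A <- attr(mono, "A")
  ay <- p_ay(P)
  resid <- 0
  for (b in 0:(.PZ - 1L)) for (c in 0:(.PD - 1L)) {
    ok <- (b == 0L && c == 0L) || (b == 2L && c == 0L) ||
      (b == 1L && c == 1L) || (b == 0L && c == 2L)
    if (!ok) resid <- max(resid, max(abs(P[, b + 1L, c + 1L])))
  }
  if (resid > tol)
    stop(sprintf("operator image leaves the closed system (residual %.3e)", resid))
  k <- min(A, ay)
  sel <- seq_len(k + 1L)
  n1 <- A + 1L
  coords <- numeric(4L * n1)
  coords[sel] <- P[sel, 1L, 1L]
  coords[n1 + sel] <- P[sel, 3L, 1L]
  coords[2L * n1 + sel] <- P[sel, 2L, 2L]
  coords[3L * n1 + sel] <- P[sel, 1L, 3L]
  coords
}

# exact projection matrix: moment-basis values = T %*% monomial-state values
moment_projection <- function(basis, mono) {
  n <- nrow(basis)
  m <- nrow(mono)
  A <- attr(mono, "A")
  TT <- matrix(0, n, m, dimnames = list(basis$id, mono$id))
  col <- function(fam, a) which(mono$family == fam & mono$a == a)
  for (i in seq_len(n)) {
    fam <- basis$family[i]; j <- basis$j[i]
    if (fam == "D2") TT[i, col("D2", j)] <- 1
    else if (fam == "Dz") TT[i, col("Dz", j)] <- 1
    else if (fam == "pi2") { # (y^j - y^{j+2} - y^j z^2 + y^{j+2} z^2)/16
      TT[i, col("y", j)] <- 1 / 16; TT[i, col("y", j + 2L)] <- -1 / 16
      TT[i, col("z2", j)] <- -1 / 16; TT[i, col("z2", j + 2L)] <- 1 / 16
    } else if (fam == "piL") {
      TT[i, col("y", j)] <- 1 / 2; TT[i, col("y", j + 2L)] <- -1 / 2
    } else if (fam == "piR") {
      TT[i, col("y", 0L)] <- 1 / 2; TT[i, col("z2", 0L)] <- -1 / 2
    } else TT[i, col("y", 0L)] <- 1
  }
  TT
}

# moment vector: reported moment-basis values plus the internal monomial
# state the operators act on
moment_vector <- function(mono_values, mono, basis) {
  stopifnot(length(mono_values) == nrow(mono))
  TT <- moment_projection(basis, mono)
  vals <- as.numeric(TT %*% mono_values)
  names(vals) <- basis$id
  structure(list(values = vals, basis = basis,
                 mono = as.numeric(mono_values), mono_basis = mono),
            class = "moment_vector")
}

#' @export
print.moment_vector <- function(x, ...) {
  cat(sprintf("moment vector (j_max = %d):\n", attr(x$basis, "j_max")))
  print(utils::head(x$values, 12L))
  if (length(x$values) > 12L) cat("  ...\n")
  invisible(x)
}

# monomial state of a point-mass population given haplotype frequencies
state_moments <- function(basis, xAB, xAb, xaB, xab) {
  mono <- monomial_basis(attr(basis, "j_max"))
  p <- xAB + xAb; q <- xAB + xaB
  y <- 1 - 2 * p; z <- 1 - 2 * q
  D <- xAB * xab - xAb * xaB
  vals <- numeric(nrow(mono))
  for (i in seq_len(nrow(mono))) {
    a <- mono$a[i]
    vals[i] <- switch(mono$family[i],
      y = y^a, z2 = y^a * z^2, Dz = y^a * z * D, D2 = y^a * D^2)
  }
  moment_vector(vals, mono, basis)
}
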