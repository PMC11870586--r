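# Lookup tables of pure two-locus B-values on an (s, r) grid, for a fixed
# demography and reference mutation rate, with spline interpolation in r and
# log-linear interpolation in s.

#' Default selection-coefficient grid
#'
#' 35 values spanning 0 to -0.001 (0 plus 34 log-spaced magnitudes), served
#' by the moment system, extended with further log-spaced values down to -1
#' for the structured-coalescent regime.
#'
#' @param extend Extend beyond -0.001 down to -1 (default TRUE).
#' @return Numeric vector of s values (0 first, then increasingly negative).
#' @export
default_s_grid <- function(extend = TRUE) {
  lo <- 10^seq(-6, -3, length.out = 34)
  hi <- if (extend) 10^seq(-3 + 3 / 33, 0, by = 3 / 33) else numeric(0)
  c(0, -lo, -hi)
}

#' Default recombination-fraction grid
#'
#' 72 values from 0 to 0.5, 0 plus 71 roughly log-spaced values.
#'
#' @return Numeric vector of r values.
#' @export
default_r_grid <- function() c(0, 10^seq(-8, log10(0.5), length.out = 71))

#' Predict the pure two-locus B-value for one parameter combination
#'
#' Dispatches between the moment system (weak to moderate selection,
#' |s| < handoff) and the structured-coalescent model (strong selection).
#'
#' @param params \code{\link{two_locus_params}}.
#' @param dem \code{\link{demography}}.
#' @param t_sample Sampling time (generations after the ancestral epoch's
#'   end; NULL = end of the listed epochs).
#' @param handoff |s| at and above which the structured coalescent is used
#'   (default 0.005).
#' @param j_max Moment-system truncation order (NULL = automatic).
#' @return B in (0, 1].
#' @export
two_locus_B <- function(params, dem, t_sample = NULL, handoff = 5e-3,
                        j_max = NULL) {
  if (params$s == 0 || params$u_left == 0) return(1)
  if (!is.null(t_sample)) dem <- demography_at(dem, t_sample)
  if (abs(params$s) >= handoff)
    return(nonequilibrium_B_strong(dem, params$u_left, params$s, params$r))
  ep <- dem$epochs
  if (is.null(j_max))
    j_max <- auto_truncation(params, max(ep$N))
  if (nrow(ep) == 1L)
    return(min(1, two_locus_B_equilibrium(params, ep$N[1L], j_max = j_max)))
  basis <- build_basis(j_max)
  v <- equilibrium_state(epoch_operator(params, ep$N[1L], basis))
  for (i in 2L:nrow(ep)) {
    M <- epoch_operator(params, ep$N[i], basis)
    v <- evolve(v, M, ep$duration[i])
  }
  piR <- moment_value(v, "piR")
  pi0 <- neutral_pi0(dem, params$u_right, discrete = TRUE)
  min(1, piR / pi0)
}

#' Precompute a lookup table of two-locus B-values on an (s, r) grid
#'
#' For each grid cell the pure two-locus prediction is computed for the
#' prescribed demography and sampling time(s): the moment system for
#' |s| < handoff, the phase-type structured coalescent beyond.  For
#' non-equilibrium demographies with several sampling times, the moment
#' system is iterated once per cell, recording all times in a single pass.
#'
#' @param dem \code{\link{demography}}.
#' @param s_grid Selection grid including 0 (default
#'   \code{\link{default_s_grid}}).
#' @param r_grid Recombination grid including 0 (default
#'   \code{\link{default_r_grid}}).
#' @param u_ref Reference (deleterious) mutation rate per site.
#' @param u_right Neutral mutation rate used internally (cancels in B).
#' @param sample_times Vector of sampling times (generations after the
#'   ancestral epoch's end) for non-equilibrium tables; NULL = one table at
#'   the end of the listed epochs.
#' @param handoff Moment-system/structured-coalescent handoff on |s|.
#' @param j_max Truncation order(s) for the moment system: NULL (automatic
#'   per s-row), a single value, or a vector aligned with \code{s_grid}
#'   (NA entries = automatic).
#' @param verbose Print per-row progress.
#' @return An object of class \code{lookup_table}: grids, u_ref, B (matrix
#'   s x r, or 3-d array s x r x time), per-row j_max, demography and a
#'   content hash.
#' @export
build_lookup <- function(dem, s_grid = default_s_grid(),
                         r_grid = default_r_grid(), u_ref = 1e-8,
                         u_right = 1e-8, sample_times = NULL,
                         handoff = 5e-3, j_max = NULL, verbose = FALSE) {
  stopifnot(any(s_grid == 0), any(r_grid == 0))
  if (!is.null(j_max) && length(j_max) == 1L)
    j_max <- rep(j_max, length(s_grid))
  o <- order(s_grid, decreasing = TRUE)
  if (!is.null(j_max)) j_max <- j_max[o][!duplicated(s_grid[o])]
  s_grid <- unique(s_grid[o]) # 0 first
  r_grid <- unique(sort(r_grid))
  if (any(s_grid > 0)) stop("selection grid must be non-positive")
  nt <- if (is.null(sample_times)) 1L else length(sample_times)
  B <- array(NA_real_, dim = c(length(s_grid), length(r_grid), nt))
  jmax_used <- rep(NA_integer_, length(s_grid))
  equilibrium <- nrow(dem$epochs) == 1L && is.null(sample_times)
  N_anc <- dem$epochs$N[1L]
  N_max <- max(dem$epochs$N)

  for (is in seq_along(s_grid)) {
    s <- s_grid[is]
    if (s == 0) { B[is, , ] <- 1; next }
    if (abs(s) >= handoff * (1 - 1e-9)) {
      for (ir in seq_along(r_grid)) {
        if (is.null(sample_times)) {
          B[is, ir, 1L] <- nonequilibrium_B_strong(dem, u_ref, s, r_grid[ir])
        } else {
          for (it in seq_len(nt))
            B[is, ir, it] <- nonequilibrium_B_strong(
              demography_at(dem, sample_times[it]), u_ref, s, r_grid[ir])
        }
      }
      if (verbose) message(sprintf("s = %g: structured coalescent", s))
      next
    }
    pars0 <- two_locus_params(s = s, u_left = u_ref, u_right = u_right,
                              r = min(r_grid[r_grid > 0], 0.5))
    jm <- if (!is.null(j_max) && !is.na(j_max[is])) as.integer(j_max[is])
          else auto_truncation(pars0, N_max)
    jmax_used[is] <- jm
    basis <- build_basis(jm)
    for (ir in seq_along(r_grid)) {
      pars <- two_locus_params(s = s, u_left = u_ref, u_right = u_right,
                               r = r_grid[ir])
      cell <- function(expr) tryCatch(expr, error = function(e)
        stop(sprintf("lookup cell (s = %g, r = %g): %s", s, r_grid[ir],
                     conditionMessage(e)), call. = FALSE))
      if (equilibrium) {
        B[is, ir, 1L] <- cell(min(1, two_locus_B_equilibrium(pars, N_anc,
                                                             j_max = jm)))
      } else {
        v <- cell(equilibrium_state(epoch_operator(pars, N_anc, basis)))
        ep <- dem$epochs
        if (is.null(sample_times)) {
          for (k in 2L:nrow(ep))
            v <- cell(evolve(v, epoch_operator(pars, ep$N[k], basis),
                             ep$duration[k]))
          piR <- moment_value(v, "piR")
          B[is, ir, 1L] <- min(1, piR / neutral_pi0(dem, u_right))
        } else {
          piRt <- cell(moment_series_piR(v, pars, dem, sample_times, basis))
          pi0t <- vapply(sample_times, function(tt)
            neutral_pi0(dem, u_right, t_sample = tt), numeric(1L))
          B[is, ir, ] <- pmin(1, piRt / pi0t)
        }
      }
    }
    if (verbose) message(sprintf("s = %g: moment system (j_max = %d)", s, jm))
  }
  if (is.null(sample_times)) B <- B[, , 1L, drop = TRUE]
  structure(list(s_grid = s_grid, r_grid = r_grid, u_ref = u_ref,
                 B = B, sample_times = sample_times, handoff = handoff,
                 jmax_used = jmax_used, demography = dem,
                 demography_id = demography_id(dem),
                 version = "bgsmap-lookup-1",
                 cache = new.env(parent = emptyenv())),
            class = "lookup_table")
}

# iterate the epochs after the ancestral one, recording pi_R at the given
# sampling times (measured from the first size change)
moment_series_piR <- function(v, pars, dem, sample_times, basis) {
  ep <- dem$epochs
  out <- numeric(length(sample_times))
  done <- sample_times <= 0
  out[done] <- moment_value(v, "piR")
  offset <- 0
  for (k in 2L:nrow(ep)) {
    M <- epoch_operator(pars, ep$N[k], basis)
    dur <- ep$duration[k]
    if (k == nrow(ep)) dur <- max(dur, max(sample_times) - offset)
    local_t <- sample_times - offset
    rec <- local_t[local_t > 0 & local_t <= dur]
    res <- evolve(v, M, dur, record = if (length(rec)) rec else NULL)
    if (length(rec)) {
      st <- res$states
      piRs <- (1 - st["z2.0", ]) / 2
      out[match(rec + offset, sample_times)] <- piRs
      v <- res$final
    } else v <- res
    offset <- offset + dur
  }
  out
}

demography_id <- function(dem) {
  paste0("dem:", paste(sprintf("%g@%g", dem$epochs$N, dem$epochs$duration),
                       collapse = ","), ";ref=", dem$N_ref)
}

#' @export
print.lookup_table <- function(x, ...) {
  d <- dim(x$B)
  cat(sprintf("two-locus B lookup table: %d s-values x %d r-values%s\n",
              length(x$s_grid), length(x$r_grid),
              if (length(d) == 3L) sprintf(" x %d times", d[3L]) else ""))
  cat(sprintf("  u_ref = %g, handoff |s| = %g, %s\n", x$u_ref, x$handoff,
              x$demography_id))
  invisible(x)
}

# extract an s x r matrix for one sampling time
lookup_slice <- function(table, time_index = NULL) {
  if (length(dim(table$B)) == 2L) return(table)
  stopifnot(!is.null(time_index))
  out <- table
  out$B <- table$B[, , time_index]
  out$sample_times <- NULL
  out$cache <- new.env(parent = emptyenv())
  out
}

# r-interpolators (monotone cubic Hermite in log-shifted r), memoized in the
# table's own cache environment (each table/slice carries its own)
lookup_splines <- function(table) {
  env <- table$cache
  if (!is.null(env) && !is.null(env$splines)) return(env$splines)
  r0 <- min(table$r_grid[table$r_grid > 0]) / 2
  xs <- log(table$r_grid + r0)
  sp <- list(r0 = r0, funs = lapply(seq_along(table$s_grid), function(i)
    stats::splinefun(xs, table$B[i, ], method = "monoH.FC")))
  if (!is.null(env)) env$splines <- sp
  sp
}

#' Interpolate a lookup table at arbitrary (s, r)
#'
#' Monotone cubic Hermite splines in log-shifted r along each s gridline
#' (exact on the nodes and bracketed by neighboring node values), combined
#' with linear interpolation in log|s| across gridlines (linear in |s|
#' below the weakest nonzero gridline); clamped to (0, 1].  No
#' extrapolation in s is allowed.
#'
#' @param table A \code{lookup_table} (single sampling time).
#' @param s Selection coefficient (scalar, within the grid range).
#' @param r Recombination fraction(s) in [0, 0.5] (vectorized).
#' @return B value(s).
#' @export
interp_B <- function(table, s, r) {
  if (length(dim(table$B)) == 3L)
    stop("time-resolved table: extract one sampling time first")
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  if (s > 0) stop("s must be <= 0")
  sg <- table$s_grid
  if (s < min(sg)) stop("s outside the lookup grid (no extrapolation in s)")
  if (s == 0) return(rep(1, length(r)))
  sp <- lookup_splines(table)
  x <- log(r + sp$r0)
  sa <- abs(s)
  mags <- abs(sg)
  hit <- which(sg == s)
  if (length(hit) == 1L) {
    B <- sp$funs[[hit]](x)
  } else {
    neg <- which(sg < 0)
    below <- neg[mags[neg] < sa]
    above <- neg[mags[neg] > sa]
    if (!length(below)) { # between 0 and the weakest gridline: linear in |s|
      i1 <- neg[which.min(mags[neg])]
      w <- sa / mags[i1]
      B <- (1 - w) + w * sp$funs[[i1]](x)
    } else {
      i0 <- below[which.max(mags[below])]
      i1 <- above[which.min(mags[above])]
      w <- (log(sa) - log(mags[i0])) / (log(mags[i1]) - log(mags[i0]))
      B <- (1 - w) * sp$funs[[i0]](x) + w * sp$funs[[i1]](x)
    }
  }
  pmin(1, pmax(B, 1e-12))
}
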