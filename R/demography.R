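#' Piecewise-constant population-size history
#'
#' Epochs are listed ancestral-first (forward-time view); the ancestral
#' epoch has unbounded duration.  The coalescent (backward-time) view simply
#' reverses the order.  Time is in generations, sizes are diploid N, and the
#' pairwise coalescence rate within an epoch is 1/(2N) per generation.
#'
#' @param N Vector of diploid sizes, ancestral first.
#' @param duration Vector of epoch durations in generations; the first
#'   (ancestral) entry must be \code{Inf}, all others finite and positive.
#' @param N_ref Reference size for rate scaling (defaults to the ancestral
#'   size).
#' @return An object of class \code{demography}.
#' @examples
#' demography(N = c(10000, 1000), duration = c(Inf, 5000))
#' @export
demography <- function(N, duration = Inf, N_ref = N[1L]) {
  stopifnot(length(N) == length(duration), length(N) >= 1L)
  if (any(N <= 0)) stop("population sizes must be positive")
  if (!is.infinite(duration[1L]))
    stop("the ancestral (first) epoch must have unbounded duration")
  if (length(duration) > 1L && any(!is.finite(duration[-1L]) | duration[-1L] <= 0))
    stop("non-ancestral epochs must have finite positive durations")
  if (N_ref <= 0) stop("N_ref must be positive")
  structure(list(epochs = data.frame(N = as.numeric(N), duration = as.numeric(duration)),
                 N_ref = as.numeric(N_ref)),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("piecewise-constant demography (ancestral first):\n")
  print(x$epochs)
  invisible(x)
}

# backward-time (coalescent) view: most recent epoch first
coalescent_view <- function(dem) {
  ep <- dem$epochs[rev(seq_len(nrow(dem$epochs))), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

# truncate/extend the present-most epoch so that sampling happens t_sample
# generations after the end of the ancestral epoch
demography_at <- function(dem, t_sample) {
  ep <- dem$epochs
  if (nrow(ep) == 1L) return(dem)
  span <- cumsum(ep$duration[-1L])
  tot <- span[length(span)]
  if (t_sample <= 0) return(demography(ep$N[1L], Inf, dem$N_ref))
  if (t_sample >= tot) {
    ep$duration[nrow(ep)] <- ep$duration[nrow(ep)] + (t_sample - tot)
    return(demography(ep$N, ep$duration, dem$N_ref))
  }
  keep <- which(c(0, span[-length(span)]) < t_sample)
  ep2 <- ep[c(1L, keep + 1L), , drop = FALSE]
  ep2$duration[nrow(ep2)] <- t_sample - c(0, span)[keep[length(keep)]]
  demography(ep2$N, ep2$duration, dem$N_ref)
}

#' Expected neutral diversity under a piecewise-constant history
#'
#' pi0(t) = 2 u E[TMRCA] for a pair sampled \code{t_sample} generations
#' after the first size change (default: at the end of the modeled span).
#' With \code{discrete = TRUE} the per-epoch survival is the exact geometric
#' (1 - 1/2N)^t of the discrete-time model, which matches the neutral
#' moment-system iteration to machine precision; with \code{FALSE} it is the
#' piecewise-exponential exp(-t/2N) of the continuous coalescent, which
#' matches the phase-type machinery.  The two differ by O(t/N^2).
#'
#' @param dem A \code{\link{demography}}.
#' @param u Per-site neutral mutation rate.
#' @param t_sample Sampling time (generations after the ancestral epoch's
#'   end); NULL = end of the listed epochs.
#' @param discrete Use the discrete-time geometric survival (default TRUE).
#' @return Expected pairwise diversity pi0.
#' @export
neutral_pi0 <- function(dem, u, t_sample = NULL, discrete = TRUE) {
  if (!is.null(t_sample)) dem <- demography_at(dem, t_sample)
  2 * u * neutral_tmrca(dem, discrete = discrete)
}

# expected pairwise TMRCA, summing per-epoch survival in the coalescent view
neutral_tmrca <- function(dem, discrete = TRUE) {
  ep <- coalescent_view(dem)
  surv <- 1
  ET <- 0
  for (i in seq_len(nrow(ep))) {
    N <- ep$N[i]; dt <- ep$duration[i]
    if (discrete) {
      c1 <- 1 / (2 * N)
      hold <- if (is.finite(dt)) (1 - (1 - c1)^dt) / c1 else 1 / c1
      ET <- ET + surv * hold
      if (is.finite(dt)) surv <- surv * (1 - c1)^dt else surv <- 0
    } else {
      hold <- if (is.finite(dt)) 2 * N * (1 - exp(-dt / (2 * N))) else 2 * N
      ET <- ET + surv * hold
      if (is.finite(dt)) surv <- surv * exp(-dt / (2 * N)) else surv <- 0
    }
  }
  ET
}

#' Per-epoch coalescence probabilities and conditional times (neutral)
#'
#' For each epoch of the coalescent view: P(coalesce within the epoch) =
#' P(no coalescence before) * (1 - exp(-t/2N)), and the conditional expected
#' TMRCA given coalescence in that epoch (exact truncated-exponential mean,
#' offset by the epoch's start).
#'
#' @param dem A \code{\link{demography}}.
#' @return A data frame (coalescent view, most recent epoch first) with
#'   columns \code{N}, \code{duration}, \code{prob}, \code{t_cond}; probs
#'   sum to 1 and sum(prob * t_cond) equals the continuous-time E[TMRCA].
#' @export
coalescence_profile <- function(dem) {
  ep <- coalescent_view(dem)
  surv <- 1
  t0 <- 0
  out <- data.frame(N = ep$N, duration = ep$duration, prob = NA_real_,
                    t_cond = NA_real_)
  for (i in seq_len(nrow(ep))) {
    N <- ep$N[i]; dt <- ep$duration[i]
    if (is.finite(dt)) {
      pin <- 1 - exp(-dt / (2 * N))
      out$prob[i] <- surv * pin
      out$t_cond[i] <- t0 + 2 * N - dt * exp(-dt / (2 * N)) / pin
      surv <- surv * exp(-dt / (2 * N))
      t0 <- t0 + dt
    } else {
      out$prob[i] <- surv
      out$t_cond[i] <- t0 + 2 * N
      surv <- 0
    }
  }
  out
}

#' Drift-effective population size trajectory
#'
#' Ne(t) = pi0(t)/(4u), the constant size that would produce the observed
#' neutral diversity at each sampling time.
#'
#' @param dem A \code{\link{demography}}.
#' @param u Neutral mutation rate.
#' @param sample_times Generations after the ancestral epoch's end.
#' @param discrete Passed to \code{\link{neutral_pi0}}.
#' @return Numeric vector of Ne(t).
#' @export
ne_trajectory <- function(dem, u, sample_times, discrete = TRUE) {
  vapply(sample_times, function(t)
    neutral_pi0(dem, u, t_sample = t, discrete = discrete) / (4 * u),
    numeric(1L))
}
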