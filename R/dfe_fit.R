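# Gamma-DFE inference from B-maps: least-squares fitting of (shape, scale)
# and/or the deleterious mutation rate under the equilibrium assumption, and
# the equilibrium-assumption bias experiments.

# design matrix for fast objective evaluation: L[f, i] such that for DFE
# weights w, log B(focal f) = u_mult * (L %*% w); the lookup is evaluated
# once per s-gridline, not once per optimizer step
bmap_design <- function(layout, table, focal_positions, chunks = NULL) {
  if (is.null(chunks)) chunks <- chunk_elements(layout)
  sg <- table$s_grid
  L <- matrix(0, length(focal_positions), length(sg))
  for (k in seq_len(nrow(chunks))) {
    r_mid <- genetic_distance(layout, focal_positions, chunks$mid[k])
    fac <- chunks$n_sel[k] * chunks$u_site[k] / table$u_ref
    for (i in seq_along(sg)) {
      if (sg[i] == 0) next
      L[, i] <- L[, i] + fac * log(interp_B(table, sg[i], r_mid))
    }
  }
  L
}

#' Fit DFE parameters to a target B-map
#'
#' Minimizes the mean squared difference between the equilibrium-predicted
#' and target B over focal positions, by derivative-free simplex search in
#' log-parameter space with jittered restarts.  Free parameters are any
#' subset of Gamma shape, Gamma scale and a multiplier on the deleterious
#' mutation rate.
#'
#' @param target Numeric vector of target B-values at the focal positions.
#' @param layout \code{\link{chromosome_layout}}.
#' @param table Equilibrium lookup table built at the assumed Ne.
#' @param focal_positions Positions of \code{target}.
#' @param free Character subset of c("shape", "scale", "u_mult").
#' @param start Named list of starting values (defaults: shape 0.2,
#'   scale 0.02, u_mult 1); fixed parameters keep their start value.
#' @param objective \code{"b"} (squared B difference) or \code{"logb"}.
#' @param restarts Number of jittered restarts (first start is unjittered).
#' @param seed Seed for the restart jitter.
#' @param reltol Convergence tolerance passed to \code{\link[stats]{optim}}.
#' @return A list: \code{estimates} (named vector), \code{objective},
#'   \code{n_evals}, \code{converged}.
#' @export
fit_dfe <- function(target, layout, table, focal_positions,
                    free = c("shape", "scale"),
                    start = list(shape = 0.2, scale = 0.02, u_mult = 1),
                    objective = c("b", "logb"), restarts = 3L, seed = 1L,
                    reltol = 1e-12) {
  objective <- match.arg(objective)
  stopifnot(length(free) >= 1L, all(free %in% c("shape", "scale", "u_mult")))
  L <- bmap_design(layout, table, focal_positions)
  sg <- table$s_grid
  tgt <- if (objective == "b") target else log(target)
  n_evals <- 0L
  obj <- function(theta) {
    n_evals <<- n_evals + 1L
    par <- as.list(exp(theta))
    names(par) <- free
    pp <- utils::modifyList(start, par)
    w <- dfe_weights(dfe_gamma(pp$shape, pp$scale), sg)
    lb <- pp$u_mult * as.numeric(L %*% w)
    pred <- if (objective == "b") pmin(1, exp(lb)) else pmin(0, lb)
    mean((pred - tgt)^2)
  }
  th0 <- log(unlist(start[free]))
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (k in seq_len(max(1L, restarts))) {
    th <- if (k == 1L) th0 else th0 + stats::rnorm(length(th0), sd = 0.3)
    if (length(th0) == 1L) {
      fit <- stats::optim(th, obj, method = "Brent",
                          lower = th0 - 8, upper = th0 + 8)
    } else {
      fit <- stats::optim(th, obj, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = 2000L))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # simplex polish from the best point
  if (length(th0) > 1L) {
    fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 2000L))
    if (fit$value <= best$value) best <- fit
  }
  est <- exp(best$par)
  names(est) <- free
  list(estimates = est, objective = best$value, n_evals = n_evals,
       converged = is.null(best$convergence) || best$convergence == 0L)
}

#' Equilibrium-assumption bias experiment
#'
#' Builds demography-aware B-maps at a series of sampling times after the
#' first size change, contrasts each with the steady-state B-map predicted
#' at the drift-effective size Ne(t) = pi0(t)/(4 mu), and (optionally) fits
#' Gamma-DFE parameters to the demography-aware map under the equilibrium
#' assumption.
#'
#' @param dem \code{\link{demography}} with at least two epochs.
#' @param layout \code{\link{chromosome_layout}}.
#' @param dfe_truth Generating DFE (see \code{\link{dfe_gamma}}).
#' @param u Neutral/deleterious reference mutation rate.
#' @param sampling_stride Generations between sampling times.
#' @param horizon Total generations followed after the first size change.
#' @param s_grid,r_grid Lookup grids (reduced grids keep runtime modest).
#' @param handoff Moment/structured handoff on |s| (chosen so that the
#'   largest |2 N s| the moment system must resolve stays tractable).
#' @param focal_positions Focal sites for the maps (default: 1 kb stride).
#' @param fit_times Sampling times at which to run the equilibrium-assumed
#'   DFE fit (NULL = none; fits are the expensive part).
#' @param fit_free Free parameters for those fits.
#' @param verbose Progress messages.
#' @return A list: \code{series} (data frame with t, Ne, mean |Delta B|),
#'   \code{fits} (data frame of fitted parameters at \code{fit_times}),
#'   \code{aware} (matrix of demography-aware B-maps, one column per time).
#' @export
bias_experiment <- function(dem, layout, dfe_truth, u = 1e-8,
                            sampling_stride = 500L, horizon = 25000L,
                            s_grid = NULL, r_grid = NULL, handoff = NULL,
                            focal_positions = NULL, fit_times = NULL,
                            fit_free = c("shape", "scale"), verbose = FALSE) {
  if (nrow(dem$epochs) < 2L) stop("bias experiment needs >= 2 epochs")
  times <- seq(0L, horizon, by = sampling_stride)
  N_max <- max(dem$epochs$N)
  if (is.null(handoff)) handoff <- min(5e-3, 20 / (2 * N_max))
  if (is.null(s_grid)) {
    # structured-coalescent rows must be strongly selected in the ancestral
    # epoch, where their mutation-selection-balance initialization is set
    strong_min <- max(handoff, 20 / (2 * dem$epochs$N[1L]))
    s_grid <- reduced_s_grid(handoff, strong_min)
  }
  if (is.null(r_grid)) r_grid <- c(0, 10^seq(-8, log10(0.5), length.out = 15))
  if (is.null(focal_positions))
    focal_positions <- seq(500, layout$length - 500, by = 1000)

  # settle the truncation order per weak s-row once, at the largest size it
  # must traverse; the same orders are reused for every equilibrium table
  s_sorted <- unique(sort(s_grid, decreasing = TRUE))
  jvec <- rep(NA_integer_, length(s_sorted))
  for (i in seq_along(s_sorted)) {
    s <- s_sorted[i]
    if (s == 0 || abs(s) >= handoff) next
    jvec[i] <- auto_truncation(two_locus_params(s = s, u_left = u,
                                                u_right = u, r = 1e-8), N_max)
  }

  if (verbose) message("building demography-aware lookup (all times)...")
  tab_aware <- build_lookup(dem, s_sorted, r_grid, u_ref = u, u_right = u,
                            sample_times = times, handoff = handoff,
                            j_max = jvec, verbose = verbose)
  Ne_t <- ne_trajectory(dem, u, times)

  chunks <- chunk_elements(layout)
  aware <- matrix(NA_real_, length(focal_positions), length(times))
  series <- data.frame(t = times, Ne = Ne_t, mean_abs_dB = NA_real_)
  fits <- NULL
  for (it in seq_along(times)) {
    slice <- lookup_slice(tab_aware, it)
    bm_aw <- compose_bmap(layout, slice, dfe_truth, focal_positions,
                          chunks = chunks)
    aware[, it] <- bm_aw$B
    if (verbose && it %% 10L == 1L)
      message(sprintf("t = %d: equilibrium table at Ne = %.1f", times[it], Ne_t[it]))
    tab_eq <- build_lookup(demography(Ne_t[it]), s_sorted, r_grid, u_ref = u,
                           u_right = u, handoff = handoff, j_max = jvec)
    bm_eq <- compose_bmap(layout, tab_eq, dfe_truth, focal_positions,
                          chunks = chunks)
    series$mean_abs_dB[it] <- mean(abs(bm_eq$B - bm_aw$B))
    if (!is.null(fit_times) && times[it] %in% fit_times) {
      fit <- fit_dfe(bm_aw$B, layout, tab_eq, focal_positions,
                     free = fit_free,
                     start = list(shape = dfe_truth$shape,
                                  scale = dfe_truth$scale, u_mult = 1))
      row <- data.frame(t = times[it], objective = fit$objective)
      for (nm in names(fit$estimates)) row[[nm]] <- fit$estimates[[nm]]
      fits <- rbind(fits, row)
    }
  }
  list(series = series, fits = fits, aware = aware,
       focal_positions = focal_positions, times = times)
}

# a coarse s-grid for bias experiments: moment-system points up to weak_max
# and structured-coalescent points from strong_min down to -1.  The band in
# between (where neither engine is comfortable when the two bounds differ)
# carries no gridline; the geometric-midpoint DFE cells of the flanking
# points absorb its probability mass.
reduced_s_grid <- function(weak_max, strong_min = weak_max) {
  weak <- -10^seq(-6, log10(weak_max), length.out = 6)
  strong <- -10^seq(log10(strong_min), 0, length.out = 7)
  unique(signif(c(0, weak, strong), 10))
}

#' Generation of maximal B-map discrepancy
#'
#' @param series The \code{series} data frame from
#'   \code{\link{bias_experiment}}.
#' @return The sampled generation at which the mean absolute difference
#'   between equilibrium-assumed and demography-aware B-maps peaks.
#' @export
bias_peak_time <- function(series) series$t[which.max(series$mean_abs_dB)]
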