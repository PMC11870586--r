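# Multi-locus B-map composition: per-site B-values are products of pure
# two-locus effects over all constrained chunks, with DFE weighting,
# midpoint genetic distances and mutation-rate adjustment.

#' DFE specifications
#'
#' \code{dfe_gamma} describes a Gamma distribution of |s| (deleterious
#' selection coefficients); \code{dfe_point} a point mass at one s.
#'
#' @param shape,scale Gamma shape and scale of |s|.
#' @param s Point selection coefficient (<= 0).
#' @return A DFE specification list.
#' @export
dfe_gamma <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  list(type = "gamma", shape = shape, scale = scale)
}

#' @rdname dfe_gamma
#' @export
dfe_point <- function(s) {
  stopifnot(s <= 0)
  list(type = "point", s = s)
}

#' Probability weights of a DFE on the lookup s-grid
#'
#' Each nonzero grid point receives the Gamma probability mass of the cell
#' around it, with cell edges at geometric midpoints of |s|; the weakest
#' cell extends to 0 (its near-neutral tail assigned to the s = 0 point is
#' zero-width there, so the first nonzero point absorbs the [0, edge) mass
#' only up to its lower edge), and the strongest grid point takes the
#' open-ended upper tail.  A point DFE places weight 1 on the nearest grid
#' point in log|s|.
#'
#' @param dfe A \code{\link{dfe_gamma}} or \code{\link{dfe_point}}.
#' @param s_grid Lookup selection grid (includes 0).
#' @return Numeric weights (same order as \code{s_grid}), summing to 1.
#' @export
dfe_weights <- function(dfe, s_grid) {
  w <- numeric(length(s_grid))
  neg <- which(s_grid < 0)
  mags <- abs(s_grid[neg])
  o <- order(mags)
  neg <- neg[o]; mags <- mags[o]
  if (dfe$type == "point") {
    if (dfe$s == 0) { w[s_grid == 0] <- 1; return(w) }
    i <- which.min(abs(log(mags) - log(abs(dfe$s))))
    w[neg[i]] <- 1
    return(w)
  }
  k <- length(mags)
  # geometric-midpoint cell edges; first lower edge continues the grid's
  # geometric spacing toward 0, strongest cell is open-ended
  inner <- sqrt(mags[-k] * mags[-1L])
  lo0 <- mags[1L]^2 / inner[1L]
  edges <- c(lo0, inner, Inf)
  pm <- stats::pgamma(edges, shape = dfe$shape, scale = dfe$scale)
  w[neg] <- diff(c(stats::pgamma(edges[1L], dfe$shape, scale = dfe$scale), pm[-1L]))
  w[neg[1L]] <- w[neg[1L]] + pm[1L] # [0, first edge) mass to the weakest point
  w[s_grid == 0] <- 0
  w / sum(w)
}

#' Mutation-rate adjustment of a B-value
#'
#' Element-specific mutation rates scale the per-site effect on the log-B
#' scale: B = B_ref^(u_site/u_ref), which equals the linear scaling of
#' (1 - B) to first order.
#'
#' @param B_ref B at the reference mutation rate.
#' @param u_site,u_ref Element-specific and reference mutation rates.
#' @return Adjusted B.
#' @export
mutation_adjust <- function(B_ref, u_site, u_ref) {
  stopifnot(u_ref > 0, u_site >= 0)
  B_ref^(u_site / u_ref)
}

# log B-value contribution of one source chunk at focal position(s):
# n_sel * (u eff / u_ref) * sum_i w_i log B(s_i * scale, r_mid * scale)
chunk_log_effect <- function(table, sw, r_mid, n_sel, u_site, scale = 1) {
  if (n_sel <= 0 || u_site <= 0) return(numeric(length(r_mid)))
  sg <- table$s_grid
  acc <- numeric(length(r_mid))
  rs <- pmin(0.5, r_mid * scale)
  s_min <- min(sg)
  for (i in seq_along(sg)) {
    if (sw[i] <= 0 || sg[i] == 0) next
    s_eff <- max(sg[i] * scale, s_min) # clamp rescaled s to the grid edge
    acc <- acc + sw[i] * log(interp_B(table, s_eff, rs))
  }
  acc * n_sel * (u_site * scale / table$u_ref)
}

#' Per-element B contribution at a focal position
#'
#' The element (already chunked to <= 1000 bp) contributes the product over
#' the DFE grid of interp_B(s_i, r_mid)^(w_i n_sel), where r_mid is the
#' genetic distance from the focal site to the chunk midpoint and n_sel its
#' number of constrained sites, with the mutation-rate adjustment for
#' u_site != u_ref.  A focal site inside the element uses the distance to
#' the midpoint like any other.
#'
#' @param focal_pos Focal position(s), bp.
#' @param elem One row of a chunked element table (list or data frame row
#'   with \code{mid}, \code{n_sel}, \code{u_site}).
#' @param table Lookup table.
#' @param dfe DFE specification.
#' @param layout \code{\link{chromosome_layout}} (for the recombination map).
#' @return B contribution(s) in (0, 1].
#' @export
element_effect <- function(focal_pos, elem, table, dfe, layout) {
  sw <- dfe_weights(dfe, table$s_grid)
  r_mid <- genetic_distance(layout, focal_pos, elem$mid)
  exp(chunk_log_effect(table, sw, r_mid, elem$n_sel, elem$u_site))
}

#' Compose a multi-locus B-map
#'
#' B(x) is the product over all element chunks of their two-locus effects;
#' the total reduction from many pairwise interactions is multiplicative.
#'
#' @param layout \code{\link{chromosome_layout}}.
#' @param table Lookup table (single sampling time).
#' @param dfe DFE specification (defaults to the layout's).
#' @param focal_positions Positions at which to evaluate B (default: a
#'   1 kb-stride grid along the chromosome).
#' @param element_scale Optional per-chunk rescaling factors (the
#'   interference correction passes each chunk's own B here).
#' @param chunks Pre-chunked element table (internal reuse).
#' @return Object of class \code{bmap}: data frame with \code{pos} and
#'   \code{B} plus metadata attributes.
#' @export
compose_bmap <- function(layout, table, dfe = layout$dfe,
                         focal_positions = NULL, element_scale = NULL,
                         chunks = NULL) {
  if (is.null(dfe)) stop("no DFE given (neither argument nor layout default)")
  if (is.null(chunks)) chunks <- chunk_elements(layout)
  if (is.null(focal_positions))
    focal_positions <- seq(500, layout$length - 500, by = 1000)
  sw <- dfe_weights(dfe, table$s_grid)
  logB <- numeric(length(focal_positions))
  if (nrow(chunks)) {
    if (is.null(element_scale)) element_scale <- rep(1, nrow(chunks))
    for (k in seq_len(nrow(chunks))) {
      r_mid <- genetic_distance(layout, focal_positions, chunks$mid[k])
      logB <- logB + chunk_log_effect(table, sw, r_mid, chunks$n_sel[k],
                                      chunks$u_site[k], element_scale[k])
    }
  }
  out <- data.frame(pos = focal_positions, B = pmin(1, exp(logB)))
  attr(out, "demography_id") <- table$demography_id
  attr(out, "u_ref") <- table$u_ref
  attr(out, "interference_corrected") <- !is.null(element_scale) &&
    any(element_scale != 1)
  class(out) <- c("bmap", "data.frame")
  out
}
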