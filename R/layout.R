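# Chromosome layouts: constrained elements in 0-based half-open (BED)
# coordinates, a piecewise-constant per-bp recombination map, per-element
# mutation rates and DFE assignments.

#' Define a constrained element
#'
#' @param start,end 0-based half-open coordinates (bp).
#' @param u_site Per-site deleterious mutation rate.
#' @param constrained_fraction Fraction of sites under selection (e.g.
#'   2.31/3.31 within exons, the human nonsynonymous:synonymous ratio).
#' @param dfe A DFE specification (see \code{\link{dfe_point}} /
#'   \code{\link{dfe_gamma}}); elements may share one.
#' @return A one-row data frame.
#' @export
element <- function(start, end, u_site = 1e-8, constrained_fraction = 1,
                    dfe = NULL) {
  stopifnot(end > start, constrained_fraction >= 0, constrained_fraction <= 1)
  data.frame(start = start, end = end, u_site = u_site,
             constrained_fraction = constrained_fraction)
}

#' Assemble a chromosome layout
#'
#' @param length Chromosome length in bp.
#' @param elements Data frame with columns \code{start}, \code{end},
#'   \code{u_site}, \code{constrained_fraction}; rows must be sorted and
#'   non-overlapping within [0, length).
#' @param recmap Data frame with columns \code{pos} (0-based interval start)
#'   and \code{rate} (per-bp recombination rate applying from \code{pos} to
#'   the next entry); must start at 0 and cover [0, length).
#' @param dfe DFE shared by all elements (see \code{\link{dfe_gamma}},
#'   \code{\link{dfe_point}}).
#' @return Object of class \code{chromosome_layout}.
#' @export
chromosome_layout <- function(length, elements, recmap = NULL, dfe = NULL) {
  if (is.null(recmap))
    recmap <- data.frame(pos = 0, rate = 1e-8)
  stopifnot(all(c("start", "end") %in% names(elements)))
  if (is.null(elements$u_site)) elements$u_site <- 1e-8
  if (is.null(elements$constrained_fraction)) elements$constrained_fraction <- 1
  o <- order(elements$start)
  elements <- elements[o, , drop = FALSE]
  rownames(elements) <- NULL
  if (nrow(elements)) {
    if (any(elements$start < 0) || any(elements$end > length))
      stop("elements must lie within [0, length)")
    if (nrow(elements) > 1L &&
        any(elements$start[-1L] < elements$end[-nrow(elements)]))
      stop("elements overlap")
  }
  if (recmap$pos[1L] != 0) stop("recombination map must start at position 0")
  if (any(diff(recmap$pos) <= 0)) stop("recombination map positions must increase")
  if (any(recmap$pos >= length)) stop("recombination map runs past the chromosome")
  if (any(recmap$rate < 0)) stop("recombination rates must be >= 0")
  structure(list(length = as.numeric(length), elements = elements,
                 recmap = recmap, dfe = dfe),
            class = "chromosome_layout")
}

#' @export
print.chromosome_layout <- function(x, ...) {
  cat(sprintf("chromosome layout: %.6g bp, %d constrained elements, %d recmap intervals\n",
              x$length, nrow(x$elements), nrow(x$recmap)))
  invisible(x)
}

# cumulative genetic position (Morgans) at physical positions x
cumulative_map <- function(layout, x) {
  rm <- layout$recmap
  brk <- c(rm$pos, layout$length)
  cum <- c(0, cumsum(rm$rate * diff(brk)))
  i <- findInterval(x, brk, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i > nrow(rm)] <- nrow(rm)
  cum[i] + (x - rm$pos[i]) * rm$rate[i]
}

#' Genetic distance between positions, capped at free recombination
#'
#' Sum of per-bp recombination rates between the positions (cumulative
#' map distance), capped at r = 0.5.
#'
#' @param layout A \code{\link{chromosome_layout}}.
#' @param a,b Physical positions (bp); vectorized.
#' @return Recombination fraction(s) in [0, 0.5].
#' @export
genetic_distance <- function(layout, a, b) {
  pmin(0.5, abs(cumulative_map(layout, a) - cumulative_map(layout, b)))
}

# split elements into chunks of at most max_len bp (the within-chunk,
# no-interference + midpoint-distance approximations hold to ~1 kb)
chunk_elements <- function(layout, max_len = 1000L) {
  el <- layout$elements
  if (!nrow(el)) return(cbind(el, data.frame(mid = numeric(0), n_sel = numeric(0),
                                             element = integer(0))))
  out <- do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
    len <- el$end[i] - el$start[i]
    k <- ceiling(len / max_len)
    edges <- round(seq(el$start[i], el$end[i], length.out = k + 1L))
    data.frame(start = edges[-(k + 1L)], end = edges[-1L],
               u_site = el$u_site[i],
               constrained_fraction = el$constrained_fraction[i],
               element = i)
  }))
  out$mid <- (out$start + out$end) / 2
  out$n_sel <- (out$end - out$start) * out$constrained_fraction
  rownames(out) <- NULL
  out
}
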