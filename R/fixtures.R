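# Synthetic chromosome layouts used throughout the benchmarks and tests.

#' Synthetic benchmark layouts
#'
#' \describe{
#'   \item{paper10mb}{A 10 Mb chromosome with 20 evenly spaced 1 kb
#'     constrained elements, uniform per-bp mutation and recombination
#'     rates of 1e-8, and a nonsynonymous:synonymous ratio of 2.31:1
#'     (constrained_fraction 2.31/3.31) within elements.}
#'   \item{uniform100kb}{A fully constrained 100 kb segment with uniform
#'     mu = r = 1e-8 per bp, the dense equilibrium benchmark.}
#'   \item{random}{A seeded random layout (element count, lengths and
#'     positions drawn reproducibly) for property tests.}
#' }
#'
#' @param kind One of \code{"paper10mb"}, \code{"uniform100kb"},
#'   \code{"random"}.
#' @param seed Seed for \code{kind = "random"}.
#' @param dir If non-NULL, also write the BED/annotation/recmap files there
#'   (see \code{\link{write_layout}}).
#' @param dfe Optional DFE to attach to the layout.
#' @return A \code{\link{chromosome_layout}}; if \code{dir} is given, the
#'   file paths are attached as attribute \code{"files"}.
#' @export
make_fixture <- function(kind = c("paper10mb", "uniform100kb", "random"),
                         seed = 1L, dir = NULL, dfe = NULL) {
  kind <- match.arg(kind)
  if (kind == "paper10mb") {
    len <- 1e7
    n_el <- 20L
    # evenly distributed: element i centered at (i - 1/2) * length / 20
    centers <- (seq_len(n_el) - 0.5) * len / n_el
    el <- data.frame(start = round(centers - 500), end = round(centers + 500),
                     u_site = 1e-8, constrained_fraction = 2.31 / 3.31)
    lay <- chromosome_layout(len, el,
                             data.frame(pos = 0, rate = 1e-8), dfe = dfe)
  } else if (kind == "uniform100kb") {
    len <- 1e5
    el <- data.frame(start = 0, end = len, u_site = 1e-8,
                     constrained_fraction = 1)
    lay <- chromosome_layout(len, el,
                             data.frame(pos = 0, rate = 1e-8), dfe = dfe)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    len <- 1e6
    n_el <- sample(3:12, 1L)
    starts <- sort(sample.int(len - 2000L, n_el))
    lens <- sample(200:1500, n_el, replace = TRUE)
    ends <- pmin(starts + lens, len)
    keep <- c(TRUE, starts[-1L] >= ends[-n_el])
    el <- data.frame(start = starts[keep], end = ends[keep],
                     u_site = 1e-8, constrained_fraction = runif(sum(keep), 0.3, 1))
    rec <- data.frame(pos = c(0, sort(sample.int(len - 1L, 3L))),
                      rate = 10^runif(4L, -8.5, -7.5))
    lay <- chromosome_layout(len, el, rec, dfe = dfe)
  }
  if (!is.null(dir)) {
    files <- write_layout(lay, dir, prefix = kind)
    attr(lay, "files") <- files
  }
  lay
}
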