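#' Two-locus model parameters
#'
#' Parameters of the pure two-locus background-selection model: a constrained
#' (left) locus under genic selection with one-way recurrent mutation, and a
#' neutral focal (right) locus at recombination distance r.
#'
#' @param s Selection coefficient at the left locus (dimensionless, <= 0);
#'   the haplotype carrying the derived allele has relative fitness 1 + s.
#' @param u_left Per-generation deleterious mutation rate at the left locus.
#' @param u_right Per-generation neutral mutation rate at the right locus.
#' @param r Per-generation recombination probability between the loci,
#'   in [0, 0.5].
#' @param right_recurrent Model the neutral (right) locus with symmetric
#'   recurrent mutation at rate \code{u_right} instead of the default
#'   infinite-sites influx 2 u_right into E[pi_R].  The recurrent variant
#'   matches the forward simulator's finite-alleles model exactly and is
#'   used for oracle comparisons; the infinite-sites influx is the model
#'   underlying B-map prediction.
#' @return An object of class \code{two_locus_params}.
#' @examples
#' two_locus_params(s = -1e-3, u_left = 1e-8, u_right = 1e-8, r = 1e-8)
#' @export
two_locus_params <- function(s = 0, u_left = 0, u_right = 1e-8, r = 0,
                             right_recurrent = FALSE) {
  stopifnot(length(s) == 1L, length(u_left) == 1L,
            length(u_right) == 1L, length(r) == 1L)
  if (is.na(s) || s > 0) stop("'s' must be <= 0 (negative selection)")
  if (r < 0 || r > 0.5) stop("'r' must lie in [0, 0.5]")
  if (u_left < 0 || u_right < 0) stop("mutation rates must be >= 0")
  structure(list(s = s, u_left = u_left, u_right = u_right, r = r,
                 right_recurrent = isTRUE(right_recurrent)),
            class = "two_locus_params")
}

#' @export
print.two_locus_params <- function(x, ...) {
  cat(sprintf("two-locus parameters: s = %g, u_left = %g, u_right = %g, r = %g\n",
              x$s, x$u_left, x$u_right, x$r))
  invisible(x)
}
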