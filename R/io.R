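# File formats: BED3 + annotation TSV + recombination-map TSV layouts,
# bedGraph/TSV B-maps, and versioned TSV lookup-table containers.

#' Read a chromosome layout from BED + annotation + recombination map files
#'
#' Coordinates are 0-based half-open (BED convention).  The annotation TSV
#' has columns \code{u_site} and \code{constrained_fraction}, one row per
#' BED element (in file order).  The recombination map TSV has columns
#' \code{pos} and \code{rate} (per-bp rate from \code{pos} to the next
#' position; HapMap-like, must start at 0).
#'
#' @param bed_path BED3(+) file of constrained elements.
#' @param annot_path Annotation TSV (NULL: defaults u_site = 1e-8,
#'   constrained_fraction = 1).
#' @param recmap_path Recombination map TSV (NULL: uniform 1e-8 per bp).
#' @param length Chromosome length in bp (NULL: taken from a \code{track}
#'   comment line \code{# length=<bp>} in the BED, else the last element
#'   end).
#' @return A \code{\link{chromosome_layout}}.
#' @export
read_layout <- function(bed_path, annot_path = NULL, recmap_path = NULL,
                        length = NULL) {
  lines <- readLines(bed_path)
  if (is.null(length)) {
    m <- grep("^#\\s*length=", lines, value = TRUE)
    if (base::length(m)) length <- as.numeric(sub("^#\\s*length=", "", m[1L]))
  }
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(body)]
  if (base::length(body)) {
    parts <- strsplit(body, "\t")
    bad <- which(vapply(parts, base::length, 1L) < 3L)
    if (base::length(bad))
      stop("malformed BED line(s): ", paste(bad, collapse = ", "))
    el <- data.frame(
      start = as.numeric(vapply(parts, `[[`, "", 2L)),
      end = as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(el$start) || anyNA(el$end))
      stop("non-numeric BED coordinates")
    o <- order(el$start)
    el <- el[o, , drop = FALSE]
    ov <- which(el$start[-1L] < el$end[-nrow(el)])
    if (base::length(ov))
      stop("overlapping elements at BED lines ",
           paste(sprintf("%d/%d", ov, ov + 1L), collapse = ", "))
  } else {
    el <- data.frame(start = numeric(0), end = numeric(0))
    o <- integer(0)
  }
  if (!is.null(annot_path)) {
    an <- utils::read.delim(annot_path)
    if (nrow(an) != nrow(el))
      stop("annotation rows (", nrow(an), ") != BED elements (", nrow(el), ")")
    an <- an[o, , drop = FALSE]
    el$u_site <- an$u_site
    el$constrained_fraction <- an$constrained_fraction
  }
  recmap <- if (!is.null(recmap_path)) utils::read.delim(recmap_path) else NULL
  if (is.null(length))
    length <- if (nrow(el)) max(el$end) else stop("chromosome length unknown")
  chromosome_layout(length, el, recmap)
}

#' Write a layout's files (BED + annotation + recombination map)
#'
#' @param layout \code{\link{chromosome_layout}}.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths (bed, annot, recmap).
#' @export
write_layout <- function(layout, dir, prefix = "layout") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, paste0(prefix, ".bed"))
  annot <- file.path(dir, paste0(prefix, "_annot.tsv"))
  rec <- file.path(dir, paste0(prefix, "_recmap.tsv"))
  el <- layout$elements
  con <- file(bed, "w")
  writeLines(sprintf("# length=%.0f", layout$length), con)
  if (nrow(el))
    writeLines(sprintf("chr1\t%.0f\t%.0f\telement_%d",
                       el$start, el$end, seq_len(nrow(el))), con)
  close(con)
  utils::write.table(el[, c("u_site", "constrained_fraction"), drop = FALSE],
                     annot, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(layout$recmap, rec, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(bed = bed, annot = annot, recmap = rec))
}

#' Write a B-map to bedGraph or TSV
#'
#' B-values are written with 10 significant digits so that a write/read
#' round trip is exact at that precision.  In bedGraph each focal position
#' is a 1-bp interval.
#'
#' @param bmap A \code{bmap} (from \code{\link{compose_bmap}}).
#' @param path Output path.
#' @param format \code{"bedgraph"} or \code{"tsv"}.
#' @param chrom Chromosome label (pass-through).
#' @return Invisibly, \code{path}.
#' @export
write_bmap <- function(bmap, path, format = c("bedgraph", "tsv"),
                       chrom = "chr1") {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bedgraph") {
    writeLines(sprintf("track type=bedGraph name=bgsmap_B"), con)
    if (nrow(bmap)) {
      # contiguous tiling: each interval runs to the next focal position
      ends <- c(bmap$pos[-1L], bmap$pos[nrow(bmap)] +
                  if (nrow(bmap) > 1L) stats::median(diff(bmap$pos)) else 1)
      writeLines(sprintf("%s\t%.0f\t%.0f\t%.10g", chrom, bmap$pos,
                         ends, bmap$B), con)
    }
  } else {
    writeLines("pos\tB", con)
    if (nrow(bmap))
      writeLines(sprintf("%.0f\t%.10g", bmap$pos, bmap$B), con)
  }
  invisible(path)
}

#' Read a B-map written by \code{\link{write_bmap}}
#'
#' @param path File path.
#' @param format \code{"bedgraph"} or \code{"tsv"}.
#' @return A \code{bmap} data frame with \code{pos}, \code{B}.
#' @export
read_bmap <- function(path, format = c("bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "bedgraph") {
    df <- utils::read.delim(path, skip = 1L, header = FALSE)
    out <- data.frame(pos = df[[2L]], B = df[[4L]])
  } else {
    df <- utils::read.delim(path)
    out <- data.frame(pos = df$pos, B = df$B)
  }
  class(out) <- c("bmap", "data.frame")
  out
}

#' Serialize a lookup table to a versioned TSV container
#'
#' Header lines (\code{#key=value}) carry the version, reference mutation
#' rate, handoff and demography; the body is the (s, r, B) grid in long
#' format, with full double precision.
#'
#' @param table A \code{lookup_table} (single sampling time).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_lookup <- function(table, path) {
  if (length(dim(table$B)) == 3L)
    stop("time-resolved tables are not file-serialized; slice first")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#version=%s", table$version),
    sprintf("#u_ref=%.17g", table$u_ref),
    sprintf("#handoff=%.17g", table$handoff),
    sprintf("#demography=%s", table$demography_id)), con)
  writeLines("s\tr\tB", con)
  grid <- expand.grid(ir = seq_along(table$r_grid), is = seq_along(table$s_grid))
  writeLines(sprintf("%.17g\t%.17g\t%.17g",
                     table$s_grid[grid$is], table$r_grid[grid$ir],
                     table$B[cbind(grid$is, grid$ir)]), con)
  invisible(path)
}

#' Read a lookup table written by \code{\link{write_lookup}}
#'
#' @param path File path.
#' @return A \code{lookup_table} (without the demography object; the
#'   demography id from the header is retained for cache keys).
#' @export
read_lookup <- function(path) {
  lines <- readLines(path)
  hd <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(paste0("^#", key, "="), "",
                            grep(paste0("^#", key, "="), hd, value = TRUE)[1L])
  df <- utils::read.delim(text = lines[!grepl("^#", lines)])
  s_grid <- unique(df$s)
  r_grid <- sort(unique(df$r))
  B <- matrix(NA_real_, length(s_grid), length(r_grid))
  B[cbind(match(df$s, s_grid), match(df$r, r_grid))] <- df$B
  structure(list(s_grid = s_grid, r_grid = r_grid,
                 u_ref = as.numeric(getv("u_ref")), B = B,
                 sample_times = NULL, handoff = as.numeric(getv("handoff")),
                 jmax_used = NULL, demography = NULL,
                 demography_id = getv("demography"),
                 version = getv("version"),
                 cache = new.env(parent = emptyenv())),
            class = "lookup_table")
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' A run configuration collects the inputs of a B-map run: the demography
#' (list of records with \code{N} and \code{duration}, \code{"inf"} allowed
#' for the ancestral epoch), layout file paths, grids, reference mutation
#' rate, DFE, sample times, interference settings, seed and output path.
#' Unknown keys are rejected; the demography and DFE blocks are parsed into
#' their package objects.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A named list with parsed \code{demography} and \code{dfe}
#'   entries plus the remaining settings.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml/.yml or .json file")

  known <- c("demography", "layout", "s_grid", "r_grid", "u_ref", "dfe",
             "sample_times", "interference", "seed", "out", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$demography)) stop("configuration lacks a 'demography' block")

  dm <- cfg$demography
  if (is.data.frame(dm)) dm <- split(dm, seq_len(nrow(dm)))
  # YAML 1.1 readers coerce a bare key `N` to boolean FALSE; accept both
  getN <- function(e) {
    v <- e$N
    if (is.null(v)) v <- e[["FALSE"]]
    if (is.null(v)) stop("demography record lacks 'N'")
    as.numeric(v)
  }
  N <- vapply(dm, getN, numeric(1L))
  dur <- vapply(dm, function(e) {
    d <- e$duration
    if (is.character(d) && tolower(d) == "inf") Inf else as.numeric(d)
  }, numeric(1L))
  cfg$demography <- demography(N, dur)

  if (!is.null(cfg$dfe)) {
    cfg$dfe <- if (!is.null(cfg$dfe$s)) dfe_point(as.numeric(cfg$dfe$s))
               else dfe_gamma(as.numeric(cfg$dfe$shape), as.numeric(cfg$dfe$scale))
  }
  if (!is.null(cfg$interference)) {
    ik <- setdiff(names(cfg$interference), c("enabled", "tol", "max_iter"))
    if (length(ik))
      stop("unknown interference key(s): ", paste(ik, collapse = ", "))
  }
  cfg
}
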