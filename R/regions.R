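#' Construct a genomic-region tibble
#'
#' Regions are the universal coordinate currency of the package: a tibble with
#' columns `chrom`, `start`, `end`. All coordinates are 0-based, half-open
#' `[start, end)` in memory regardless of the source file's convention;
#' converters live at the I/O boundary (see [read_regions()]).
#'
#' @param chrom Chromosome name(s). Passed through verbatim — no implicit
#'   "chr" prefix munging.
#' @param start,end Integer base positions, 0-based half-open. `end > start`
#'   and `start >= 0` are enforced.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' region("chr1", 100, 200)
#' @export
region <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) abort("region start must be >= 0")
  if (any(end <= start)) abort("region end must be > start (0-based half-open)")
  tibble(chrom = as.character(chrom), start = start, end = end)
}

#' Region lengths in base pairs
#' @param regions A region tibble (columns `chrom`, `start`, `end`).
#' @return Numeric vector of lengths, `end - start`.
#' @export
region_length <- function(regions) {
  regions$end - regions$start
}

check_regions <- function(regions, what = "regions") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  invisible(regions)
}

#' Fraction of a query gene set found in a reference set
#'
#' Computes `|query ∩ reference| / |query|` over case-normalized gene
#' symbols, the overlap percentage used to validate curated fusion gene sets
#' against external driver-gene and fusion whitelists.
#'
#' @param query,reference Character vectors of gene symbols; duplicates are
#'   collapsed. Comparison is exact after uppercasing (no alias expansion).
#' @return A single number in `[0, 1]`.
#' @examples
#' overlap_fraction(c("A", "B", "C", "D"), c("A", "B", "C", "X")) # 0.75
#' @export
overlap_fraction <- function(query, reference) {
  q <- unique(toupper(as.character(query)))
  r <- unique(toupper(as.character(reference)))
  q <- q[!is.na(q) & nzchar(q)]
  r <- r[!is.na(r) & nzchar(r)]
  if (length(q) == 0) abort("overlap_fraction: empty query set (fraction undefined)")
  length(intersect(q, r)) / length(q)
}
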