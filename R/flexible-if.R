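# The flexible interaction-frequency statistic: a containment ratio of the
# contact signal inside a core region rectangle to the signal over a
# background rectangle obtained by extending each region by its matched
# resolution times an extension coefficient.

#' Pick the stored resolution nearest to a region length
#'
#' Returns the available bin size minimizing `|region_length - R|`; ties are
#' broken toward the smaller resolution (preserving detail).
#'
#' @param region_length Region length in bp.
#' @param available Numeric vector of available bin sizes, nonempty.
#' @return One element of `available`.
#' @examples
#' select_resolution(12000, c(1000, 5000, 10000, 50000, 100000, 500000)) # 10000
#' select_resolution(3000, c(1000, 5000)) # tie -> 1000
#' @export
select_resolution <- function(region_length, available) {
  if (length(available) == 0) abort("no resolutions available")
  available <- sort(as.numeric(available))
  d <- abs(region_length - available)
  available[which.min(d)] # sort + which.min => ties go to the smaller bin size
}

#' Extension coefficient for background regions
#'
#' The ratio of the larger to the smaller of the two matched resolutions
#' (1 when they are equal), so the coarser-resolution side is extended
#' proportionally more.
#'
#' @param Ra,Rb Matched resolutions (bp), positive.
#' @return A number `>= 1`.
#' @examples
#' extension_coefficient(10000, 5000) # 2
#' @export
extension_coefficient <- function(Ra, Rb) {
  if (any(c(Ra, Rb) <= 0)) abort("resolutions must be positive")
  max(Ra, Rb) / min(Ra, Rb)
}

#' Flexible interaction frequency between two regions
#'
#' For core regions `C_a = [S_a, E_a)` and `C_b = [S_b, E_b)`:
#' resolutions `R_a`, `R_b` are matched to the region lengths with
#' [select_resolution()], the query window is `W_ab = min(R_a, R_b)`, and the
#' extension coefficient `alpha` is [extension_coefficient()]. Background
#' regions extend each side by its resolution times `alpha`
#' (`[S - R*alpha, E + R*alpha)`), clamped to the chromosome; clamping can
#' shrink the background but never the core. The statistic is
#'
#'   `flexible_if = IF(core) / IF(background)`
#'
#' with both interaction frequencies computed by [query_if()] at `W_ab`.
#' When the core signal is zero (including 0/0) the statistic is defined as
#' 0: no-signal region pairs score as no interaction. With the default
#' symmetric extension the background rectangle contains the core rectangle,
#' so the result lies in `[0, 1]`.
#'
#' @param store A [contact_store()].
#' @param region_a,region_b Single-row region tibbles (the core regions).
#' @param strict_extension If `TRUE`, the b-side background end point is
#'   `E_b - R_b*alpha` instead of `E_b + R_b*alpha`, reproducing an
#'   asymmetric variant of the extension; the default symmetric form is
#'   recommended (see the methods vignette). With the asymmetric form the
#'   containment bound no longer holds.
#' @param aggregate Passed to [query_if()] (`"sum"` default).
#' @return A one-row tibble: `Ra`, `Rb`, `Wab`, `alpha`, core and extended
#'   region coordinates, `core_if`, `extended_if`, `flexible_if`.
#' @export
flexible_if <- function(store, region_a, region_b,
                        strict_extension = FALSE, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  check_regions(region_a, "region_a")
  check_regions(region_b, "region_b")
  check_store_chrom(store, region_a$chrom)
  check_store_chrom(store, region_b$chrom)
  len_a <- region_a$end - region_a$start
  len_b <- region_b$end - region_b$start
  if (len_a <= 0 || len_b <= 0) abort("degenerate (length 0) region")
  Ra <- select_resolution(len_a, store$resolutions)
  Rb <- select_resolution(len_b, store$resolutions)
  Wab <- min(Ra, Rb)
  alpha <- extension_coefficient(Ra, Rb)

  clamp <- function(chrom, s, e) {
    lim <- store$chrom_sizes[[chrom]]
    c(max(0, s), min(e, lim))
  }
  ext_a <- clamp(region_a$chrom, region_a$start - Ra * alpha, region_a$end + Ra * alpha)
  eb_end <- if (strict_extension) region_b$end - Rb * alpha else region_b$end + Rb * alpha
  ext_b <- clamp(region_b$chrom, region_b$start - Rb * alpha, eb_end)

  core_if <- query_if(store, region_a, region_b, Wab, aggregate)
  ext_region_a <- tibble(chrom = region_a$chrom, start = ext_a[1], end = ext_a[2])
  ext_region_b <- tibble(chrom = region_b$chrom, start = ext_b[1], end = ext_b[2])
  extended_if <- if (ext_a[2] > ext_a[1] && ext_b[2] > ext_b[1]) {
    query_if(store, ext_region_a, ext_region_b, Wab, aggregate)
  } else {
    0 # strict (asymmetric) extension can empty the background rectangle
  }
  fif <- if (core_if == 0) 0 else core_if / extended_if

  tibble(
    chromA = region_a$chrom, startA = region_a$start, endA = region_a$end,
    chromB = region_b$chrom, startB = region_b$start, endB = region_b$end,
    Ra = Ra, Rb = Rb, Wab = Wab, alpha = alpha,
    ext_startA = ext_a[1], ext_endA = ext_a[2],
    ext_startB = ext_b[1], ext_endB = ext_b[2],
    core_if = core_if, extended_if = extended_if, flexible_if = fif
  )
}

#' Flexible IF for a table of region pairs
#'
#' Applies [flexible_if()] row-wise to a pair table (columns
#' `chromA/startA/endA/chromB/startB/endB`; extra columns are carried
#' through).
#'
#' @param pairs Pair tibble.
#' @inheritParams flexible_if
#' @return `pairs` with the [flexible_if()] result columns appended.
#' @export
flexible_if_pairs <- function(store, pairs, strict_extension = FALSE,
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  res <- purrr::pmap(
    pairs[, c("chromA", "startA", "endA", "chromB", "startB", "endB")],
    function(chromA, startA, endA, chromB, startB, endB) {
      flexible_if(
        store,
        region(chromA, startA, endA),
        region(chromB, startB, endB),
        strict_extension = strict_extension, aggregate = aggregate
      )[, c(
        "Ra", "Rb", "Wab", "alpha", "ext_startA", "ext_endA",
        "ext_startB", "ext_endB", "core_if", "extended_if", "flexible_if"
      )]
    }
  )
  bind_cols(pairs, bind_rows(res))
}
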