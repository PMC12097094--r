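# Multi-resolution sparse contact store.
#
# Contacts are held per resolution as a canonicalized COO tibble
# (chromA, binA, chromB, binB, value): each unordered bin pair is stored once
# with (chromA, binA) <= (chromB, binB) lexicographically, and every query
# treats the matrix as symmetric. Matrices are assumed pre-normalized
# (e.g. ICE-balanced) upstream; no balancing is performed here.

canonicalize_coo <- function(coo) {
  flip <- coo$chromB < coo$chromA | (coo$chromB == coo$chromA & coo$binB < coo$binA)
  out <- coo
  out$chromA <- ifelse(flip, coo$chromB, coo$chromA)
  out$binA <- ifelse(flip, coo$binB, coo$binA)
  out$chromB <- ifelse(flip, coo$chromA, coo$chromB)
  out$binB <- ifelse(flip, coo$binA, coo$binB)
  dup <- duplicated(out[, c("chromA", "binA", "chromB", "binB", "value")])
  out <- out[!dup, ]
  key <- paste(out$chromA, out$binA, out$chromB, out$binB)
  if (anyDuplicated(key)) {
    abort("conflicting duplicate contact entries (same bin pair, different values)")
  }
  out
}

#' Build a multi-resolution Hi-C contact store
#'
#' @param contacts Named list, one element per resolution (names are bin sizes
#'   in bp), each a tibble/data frame with columns
#'   `chromA, binA, chromB, binB, value` (bin indices 0-based, values
#'   normalized non-negative contact counts). Symmetric duplicates are
#'   collapsed; conflicting duplicates are an error.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A `contact_store` object.
#' @export
contact_store <- function(contacts, chrom_sizes) {
  if (is.null(names(contacts)) || any(!nzchar(names(contacts)))) {
    abort("contacts must be a named list keyed by resolution (bp)")
  }
  resolutions <- sort(as.numeric(names(contacts)))
  if (any(is.na(resolutions)) || any(resolutions <= 0)) abort("resolutions must be positive bin sizes")
  chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  maps <- list()
  for (res in resolutions) {
    coo <- as_tibble(contacts[[as.character(res)]])
    need <- c("chromA", "binA", "chromB", "binB", "value")
    if (!all(need %in% names(coo))) abort("contact tibbles need chromA, binA, chromB, binB, value")
    coo <- coo[coo$value != 0, need]
    if (any(coo$value < 0)) abort("contact values must be non-negative")
    chroms <- unique(c(coo$chromA, coo$chromB))
    missing <- setdiff(chroms, names(chrom_sizes))
    if (length(missing)) abort(paste0("contacts reference unknown chromosome: ", missing[1]))
    nb <- ceiling(chrom_sizes / res)
    if (any(coo$binA < 0 | coo$binB < 0) ||
      any(coo$binA >= nb[coo$chromA]) || any(coo$binB >= nb[coo$chromB])) {
      abort(sprintf("bin index out of range for resolution %d", as.integer(res)))
    }
    maps[[as.character(res)]] <- canonicalize_coo(coo)
  }
  structure(
    list(resolutions = resolutions, chrom_sizes = chrom_sizes, maps = maps),
    class = "contact_store"
  )
}

#' @export
print.contact_store <- function(x, ...) {
  cat("<contact_store>\n")
  cat("  chromosomes:", paste0(names(x$chrom_sizes), " (", x$chrom_sizes, " bp)", collapse = ", "), "\n")
  cat("  resolutions:", paste(x$resolutions, collapse = ", "), "bp\n")
  n <- vapply(x$maps, nrow, 0L)
  cat("  nonzero entries:", paste(paste0(names(n), ":", n), collapse = ", "), "\n")
  invisible(x)
}

check_store_window <- function(store, window) {
  if (!window %in% store$resolutions) {
    abort(sprintf(
      "window %s is not a stored resolution (available: %s)",
      format(window, scientific = FALSE), paste(store$resolutions, collapse = ", ")
    ))
  }
}

check_store_chrom <- function(store, chrom) {
  if (!chrom %in% names(store$chrom_sizes)) {
    abort(sprintf("chromosome '%s' not present in store", chrom))
  }
}

# 0-based inclusive bin index range covered by a region after clamping to the
# chromosome; bins touching the region boundary count fully. NULL if empty.
region_bins <- function(store, chrom, start, end, window) {
  len <- store$chrom_sizes[[chrom]]
  s <- max(0, start)
  e <- min(end, len)
  if (e <= s) {
    return(NULL)
  }
  c(floor(s / window), min(floor((e - 1) / window), ceiling(len / window) - 1))
}

#' Interaction frequency over a region rectangle
#'
#' Sums the normalized contact values over all bin pairs `(i, j)` at
#' resolution `window` such that bin `i` intersects `region_a` and bin `j`
#' intersects `region_b`. The result is symmetric in the two regions and
#' regions are clamped to the chromosome bounds. With `aggregate = "mean"`
#' the sum is divided by the number of bin pairs in the rectangle (zeros
#' included).
#'
#' @param store A [contact_store()].
#' @param region_a,region_b Single-row region tibbles (see [region()]).
#' @param window Bin size in bp; must be one of the store's resolutions.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return A non-negative number.
#' @export
query_if <- function(store, region_a, region_b, window, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  check_regions(region_a, "region_a")
  check_regions(region_b, "region_b")
  check_store_window(store, window)
  check_store_chrom(store, region_a$chrom)
  check_store_chrom(store, region_b$chrom)
  ba <- region_bins(store, region_a$chrom, region_a$start, region_a$end, window)
  bb <- region_bins(store, region_b$chrom, region_b$start, region_b$end, window)
  if (is.null(ba) || is.null(bb)) {
    return(0)
  }
  coo <- store$maps[[as.character(window)]]
  in_a <- function(chrom, bin) chrom == region_a$chrom & bin >= ba[1] & bin <= ba[2]
  in_b <- function(chrom, bin) chrom == region_b$chrom & bin >= bb[1] & bin <= bb[2]
  diag_entry <- coo$chromA == coo$chromB & coo$binA == coo$binB
  mult <- ifelse(
    diag_entry,
    as.numeric(in_a(coo$chromA, coo$binA) & in_b(coo$chromA, coo$binA)),
    as.numeric(in_a(coo$chromA, coo$binA) & in_b(coo$chromB, coo$binB)) +
      as.numeric(in_a(coo$chromB, coo$binB) & in_b(coo$chromA, coo$binA))
  )
  total <- sum(coo$value * mult)
  if (aggregate == "mean") {
    npairs <- (ba[2] - ba[1] + 1) * (bb[2] - bb[1] + 1)
    total <- total / npairs
  }
  total
}

#' Virtual 4C profile from a fixed viewpoint
#'
#' For every bin `b` along the viewpoint chromosome, sums the contacts
#' between the bins intersecting the viewpoint and bin `b` (the viewpoint's
#' own bins included), producing a one-vs-all contact profile.
#'
#' @param store A [contact_store()].
#' @param viewpoint Single-row region tibble on a chromosome in the store.
#' @param resolution Bin size in bp; must be one of the store's resolutions.
#' @return Tibble with one row per bin: `chrom`, `start`, `end`, `bin`,
#'   `value`; `nrow == ceiling(chrom_length / resolution)`.
#' @export
virtual_4c <- function(store, viewpoint, resolution) {
  check_regions(viewpoint, "viewpoint")
  check_store_window(store, resolution)
  check_store_chrom(store, viewpoint$chrom)
  chrom <- viewpoint$chrom
  len <- store$chrom_sizes[[chrom]]
  if (viewpoint$start >= len) abort("viewpoint lies beyond the chromosome end")
  vb <- region_bins(store, chrom, viewpoint$start, viewpoint$end, resolution)
  if (is.null(vb)) abort("viewpoint covers no bins")
  nbins <- ceiling(len / resolution)
  prof <- numeric(nbins)
  coo <- store$maps[[as.character(resolution)]]
  coo <- coo[coo$chromA == chrom & coo$chromB == chrom, ]
  if (nrow(coo) > 0) {
    in_v <- function(bin) bin >= vb[1] & bin <= vb[2]
    a_in <- in_v(coo$binA)
    b_in <- in_v(coo$binB)
    same <- coo$binA == coo$binB
    # p in viewpoint -> contributes at q; q in viewpoint -> contributes at p
    add_a <- coo$value * as.numeric(a_in)
    add_b <- coo$value * as.numeric(b_in & !same)
    for (k in which(add_a > 0)) prof[coo$binB[k] + 1] <- prof[coo$binB[k] + 1] + add_a[k]
    for (k in which(add_b > 0)) prof[coo$binA[k] + 1] <- prof[coo$binA[k] + 1] + add_b[k]
  }
  bins <- seq_len(nbins) - 1
  tibble(
    chrom = chrom,
    start = bins * resolution,
    end = pmin((bins + 1) * resolution, len),
    bin = bins,
    value = prof
  )
}

#' Read / write the native multi-resolution COO store
#'
#' The on-disk layout is a JSON manifest (`chrom_sizes`, `resolutions`,
#' `files` mapping resolution to a COO file path relative to the manifest)
#' plus one whitespace-delimited COO file per resolution with columns
#' `chromA binA chromB binB value` and no header.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A [contact_store()].
#' @export
read_contact_store <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  contacts <- lapply(man$files, function(f) {
    readr::read_table(file.path(dir, f),
      col_names = c("chromA", "binA", "chromB", "binB", "value"),
      col_types = "cdcdn", progress = FALSE
    )
  })
  names(contacts) <- names(man$files)
  contact_store(contacts, unlist(man$chrom_sizes))
}

#' @rdname read_contact_store
#' @param store A [contact_store()].
#' @param dir Output directory (created if needed).
#' @return `write_contact_store()`: the manifest path, invisibly.
#' @export
write_contact_store <- function(store, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (res in store$resolutions) {
    key <- as.character(res)
    f <- sprintf("contacts_%s.coo.tsv", format(res, scientific = FALSE))
    coo <- store$maps[[key]]
    out <- coo
    out$binA <- format(out$binA, scientific = FALSE, trim = TRUE)
    out$binB <- format(out$binB, scientific = FALSE, trim = TRUE)
    readr::write_tsv(out, file.path(dir, f), col_names = FALSE, progress = FALSE)
    files[[key]] <- f
  }
  man <- list(
    chrom_sizes = as.list(store$chrom_sizes),
    resolutions = store$resolutions,
    files = files
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
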