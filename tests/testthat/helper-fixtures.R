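# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's query machinery: they expand
# the sparse entries to a full symmetric list and test rectangle membership
# bin by bin, so agreement with query_if()/flexible_if() is a genuine
# cross-check.

# random sparse multi-resolution store; returns the store plus the raw
# symmetric entry list per resolution for the oracle
random_store <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1)
  chrom_sizes <- setNames(
    sample(4:10, n_chrom, replace = TRUE) * 10000,
    paste0("c", seq_len(n_chrom))
  )
  resolutions <- sort(sample(c(1000, 5000, 10000), sample(2:3, 1)))
  contacts <- list()
  full <- list()
  for (r in resolutions) {
    rows <- list()
    for (ca in names(chrom_sizes)) {
      for (cb in names(chrom_sizes)) {
        if (cb < ca) next
        na <- ceiling(chrom_sizes[[ca]] / r)
        nb <- ceiling(chrom_sizes[[cb]] / r)
        n_entry <- sample(5:25, 1)
        ba <- sample.int(na, n_entry, replace = TRUE) - 1
        bb <- sample.int(nb, n_entry, replace = TRUE) - 1
        if (ca == cb) { # keep upper triangle
          lo <- pmin(ba, bb)
          hi <- pmax(ba, bb)
          ba <- lo
          bb <- hi
        }
        tb <- tibble::tibble(
          chromA = ca, binA = ba, chromB = cb, binB = bb,
          value = round(runif(n_entry, 0.1, 5), 3)
        )
        tb <- tb[!duplicated(tb[, 1:4]), ]
        rows[[length(rows) + 1]] <- tb
      }
    }
    coo <- dplyr::bind_rows(rows)
    contacts[[as.character(r)]] <- coo
    # symmetric expansion for the oracle
    swapped <- coo[coo$chromA != coo$chromB | coo$binA != coo$binB, ]
    swapped <- tibble::tibble(
      chromA = swapped$chromB, binA = swapped$binB,
      chromB = swapped$chromA, binB = swapped$binA, value = swapped$value
    )
    full[[as.character(r)]] <- dplyr::bind_rows(coo, swapped)
  }
  list(
    store = contact_store(contacts, chrom_sizes),
    full = full,
    chrom_sizes = chrom_sizes,
    resolutions = resolutions
  )
}

random_region <- function(chrom_sizes) {
  chrom <- sample(names(chrom_sizes), 1)
  len <- chrom_sizes[[chrom]]
  s <- sample.int(len - 1000, 1) - 1
  e <- min(len, s + sample.int(30000, 1))
  region(chrom, s, e)
}

# does bin b (at width w, on chrom bc) intersect the clamped region?
oracle_bin_in_region <- function(bc, b, w, reg, chrom_sizes) {
  s <- max(0, reg$start)
  e <- min(reg$end, chrom_sizes[[reg$chrom]])
  if (e <= s) {
    return(FALSE)
  }
  bc == reg$chrom && (b * w) < e && (b + 1) * w > s
}

# brute-force rectangle sum over the full symmetric entry list
oracle_query_if <- function(fix, rega, regb, w) {
  entries <- fix$full[[as.character(w)]]
  total <- 0
  for (k in seq_len(nrow(entries))) {
    if (oracle_bin_in_region(entries$chromA[k], entries$binA[k], w, rega, fix$chrom_sizes) &&
      oracle_bin_in_region(entries$chromB[k], entries$binB[k], w, regb, fix$chrom_sizes)) {
      total <- total + entries$value[k]
    }
  }
  total
}

# independent re-derivation of the flexible IF chain
oracle_flexible_if <- function(fix, rega, regb) {
  nearest <- function(len) {
    best <- fix$resolutions[1]
    for (r in fix$resolutions) {
      if (abs(len - r) < abs(len - best)) best <- r
    }
    best
  }
  Ra <- nearest(rega$end - rega$start)
  Rb <- nearest(regb$end - regb$start)
  w <- min(Ra, Rb)
  alpha <- if (Ra == Rb) 1 else max(Ra, Rb) / min(Ra, Rb)
  exta <- region(
    rega$chrom,
    max(0, rega$start - Ra * alpha),
    min(fix$chrom_sizes[[rega$chrom]], rega$end + Ra * alpha)
  )
  extb <- region(
    regb$chrom,
    max(0, regb$start - Rb * alpha),
    min(fix$chrom_sizes[[regb$chrom]], regb$end + Rb * alpha)
  )
  core <- oracle_query_if(fix, rega, regb, w)
  ext <- oracle_query_if(fix, exta, extb, w)
  if (core == 0) 0 else core / ext
}

# minimal handmade store: one chromosome, 60 kb, three resolutions
tiny_store <- function(entries_10k = NULL) {
  sizes <- c(chrT = 60000)
  empty <- tibble::tibble(
    chromA = character(), binA = numeric(),
    chromB = character(), binB = numeric(), value = numeric()
  )
  contacts <- list(
    "1000" = empty, "5000" = empty,
    "10000" = if (is.null(entries_10k)) empty else entries_10k
  )
  contact_store(contacts, sizes)
}

# textbook Welch one-sided CDF, independent of expression_change()
oracle_welch_ec <- function(x_cancer, x_normal) {
  nc <- length(x_cancer)
  nn <- length(x_normal)
  vc <- var(x_cancer)
  vn <- var(x_normal)
  t_stat <- (mean(x_cancer) - mean(x_normal)) / sqrt(vc / nc + vn / nn)
  df <- (vc / nc + vn / nn)^2 / ((vc / nc)^2 / (nc - 1) + (vn / nn)^2 / (nn - 1))
  pt(t_stat, df)
}
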