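# Mapping curated variants onto the four layers of 3D genome organization
# (territory, compartment, TAD, loop) and classifying the disruption types.

# All overlapping (x_row, y_row) index pairs between two interval tables,
# half-open [start, end) semantics.
ivl_overlap_pairs <- function(x, y) {
  x2 <- tibble(.xrow = seq_len(nrow(x)), chrom = x$chrom, xs = x$start, xe = x$end)
  y2 <- tibble(.yrow = seq_len(nrow(y)), chrom = y$chrom, ys = y$start, ye = y$end)
  inner_join(x2, y2, by = join_by("chrom", xs < ye, xe > ys))[, c(".xrow", ".yrow")]
}

# logical: does each x interval overlap any y interval
ivl_hits_any <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(rep(FALSE, nrow(x)))
  }
  seq_len(nrow(x)) %in% ivl_overlap_pairs(x, y)$.xrow
}

# index of the interval containing each position (NA if none); intervals
# must be non-overlapping within a chromosome
ivl_locate <- function(chrom, pos, ivls) {
  q <- tibble(chrom = chrom, start = pos, end = pos + 1)
  hit <- ivl_overlap_pairs(q, ivls)
  out <- rep(NA_integer_, length(pos))
  out[hit$.xrow] <- hit$.yrow
  out
}

#' Filter structural variants by length and population frequency
#'
#' Retains SVs with length between `min_length` and `max_length` bp
#' (inclusive) and population frequency strictly greater than
#' `min_frequency`. Input order is preserved; per-rule drop counts (a record
#' failing both rules increments both) are attached as the `drop_counts`
#' attribute.
#'
#' @param svs SV tibble (needs `start`, `end`, `frequency`).
#' @param min_length,max_length Inclusive length bounds in bp
#'   (defaults 10 kb and 10 Mb).
#' @param min_frequency Exclusive lower frequency bound (default 0.01,
#'   i.e. > 1%).
#' @return The retained rows, with `attr(, "drop_counts")` =
#'   `c(length = ..., frequency = ...)`.
#' @export
filter_svs <- function(svs, min_length = 1e4, max_length = 1e7, min_frequency = 0.01) {
  len <- svs$end - svs$start
  ok_len <- len >= min_length & len <= max_length
  ok_freq <- svs$frequency > min_frequency
  out <- svs[ok_len & ok_freq, ]
  attr(out, "drop_counts") <- c(length = sum(!ok_len), frequency = sum(!ok_freq))
  out
}

compartment_transitions <- function(track) {
  track %>%
    arrange(.data$chrom, .data$start) %>%
    group_by(.data$chrom) %>%
    reframe(
      pos = {
        n <- dplyr::n()
        if (n < 2) {
          numeric()
        } else {
          # boundary between abutting bins with different labels
          e <- .data$end[-n]
          s <- .data$start[-1]
          lab_change <- .data$label[-n] != .data$label[-1]
          e[e == s & lab_change]
        }
      }
    )
}

nearest_transition_dist <- function(chrom, pos, transitions) {
  vapply(seq_along(pos), function(i) {
    t <- transitions$pos[transitions$chrom == chrom[i]]
    if (length(t) == 0) NA_real_ else min(abs(pos[i] - t))
  }, 0)
}

#' Classify compartment disruption of structural variants
#'
#' Looks up the A/B compartment label at each SV breakpoint (left breakpoint
#' at `start`, right breakpoint at `end - 1` under the half-open convention,
#' so an SV ending exactly at a compartment transition belongs to the left
#' bin) and reports the ordered pair: `A-A` and `B-B` are stable
#' disruptions, `A-B` and `B-A` are switching. A breakpoint falling in a
#' track gap gives `unmapped`. The distance from each breakpoint to the
#' nearest compartment transition (abutting bins with different labels) is
#' also reported.
#'
#' @param svs SV tibble (`sv_id`, `chrom`, `start`, `end`).
#' @param track Compartment track from [read_compartments()] (`chrom`,
#'   `start`, `end`, `label`).
#' @return `svs` with columns `category` (`A-A`, `A-B`, `B-A`, `B-B`,
#'   `unmapped`), `dist_left`, `dist_right` appended.
#' @export
classify_compartment_disruption <- function(svs, track) {
  left <- svs$start
  right <- svs$end - 1
  li <- ivl_locate(svs$chrom, left, track)
  ri <- ivl_locate(svs$chrom, right, track)
  lab_l <- ifelse(is.na(li), NA_character_, track$label[li])
  lab_r <- ifelse(is.na(ri), NA_character_, track$label[ri])
  category <- ifelse(is.na(lab_l) | is.na(lab_r), "unmapped", paste0(lab_l, "-", lab_r))
  trans <- compartment_transitions(track)
  svs %>% mutate(
    category = category,
    dist_left = nearest_transition_dist(svs$chrom, left, trans),
    dist_right = nearest_transition_dist(svs$chrom, right, trans)
  )
}

#' Classify TAD disruption of structural variants
#'
#' Assigns each breakpoint (left at `start`, right at `end - 1`) to a TAD
#' domain or a boundary interval and maps the pair to: `intra-TAD` (both in
#' the same domain), `inter-TAD1` (one in a boundary, the other in a
#' domain), `inter-TAD2` (both in boundary intervals, not necessarily the
#' same one), `inter-TAD3` (two different domains). An SV longer than 50% of
#' the local TAD size is `excluded` (local TAD = the domain containing the
#' left breakpoint, falling back to the right breakpoint's domain when the
#' left sits in a boundary; for `inter-TAD3`, the mean of the two containing
#' domains). A breakpoint outside all domains and boundaries gives
#' `unmapped`.
#'
#' @param svs SV tibble (`sv_id`, `chrom`, `start`, `end`).
#' @param domains,boundaries Region tibbles of TAD domains and boundary
#'   intervals.
#' @param max_tad_fraction Exclusion threshold as a fraction of the local
#'   TAD size (default 0.5).
#' @return `svs` with a `category` column appended (`intra-TAD`,
#'   `inter-TAD1`, `inter-TAD2`, `inter-TAD3`, `excluded`, `unmapped`).
#' @export
classify_tad_disruption <- function(svs, domains, boundaries, max_tad_fraction = 0.5) {
  left <- svs$start
  right <- svs$end - 1
  ld <- ivl_locate(svs$chrom, left, domains)
  rd <- ivl_locate(svs$chrom, right, domains)
  lb <- ivl_locate(svs$chrom, left, boundaries)
  rb <- ivl_locate(svs$chrom, right, boundaries)
  dsize <- domains$end - domains$start
  sv_len <- svs$end - svs$start

  category <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    l_dom <- ld[i]
    r_dom <- rd[i]
    l_bnd <- lb[i]
    r_bnd <- rb[i]
    l_in <- !is.na(l_dom) || !is.na(l_bnd)
    r_in <- !is.na(r_dom) || !is.na(r_bnd)
    if (!l_in || !r_in) {
      category[i] <- "unmapped"
      next
    }
    cat_i <- if (!is.na(l_dom) && !is.na(r_dom)) {
      if (l_dom == r_dom) "intra-TAD" else "inter-TAD3"
    } else if (is.na(l_dom) && is.na(r_dom)) {
      "inter-TAD2"
    } else {
      "inter-TAD1"
    }
    local_size <- if (cat_i == "inter-TAD3") {
      mean(dsize[c(l_dom, r_dom)])
    } else if (!is.na(l_dom)) {
      dsize[l_dom]
    } else if (!is.na(r_dom)) {
      dsize[r_dom]
    } else {
      NA_real_ # inter-TAD2: no containing domain, exclusion not applicable
    }
    if (!is.na(local_size) && sv_len[i] > max_tad_fraction * local_size) {
      cat_i <- "excluded"
    }
    category[i] <- cat_i
  }
  svs %>% mutate(category = category)
}

#' Merge interchromosomal translocations into unique fusion gene pairs
#'
#' Removes exact duplicate records (same breakpoints and genes), collapses
#' the remainder into unordered gene pairs (`(X, Y)` and `(Y, X)` are the
#' same pair; symbols compared after uppercasing) and counts occurrences.
#' Pairs seen more than `high_frequency_min` times (strictly) are flagged
#' `high_frequency`. Records missing a gene symbol are skipped; their count
#' is attached as the `n_skipped` attribute (with a warning).
#'
#' @param icts ICT tibble from [read_icts()].
#' @param high_frequency_min Strict count threshold (default 10).
#' @return Tibble: `gene1`, `gene2` (alphabetical within pair), `count`,
#'   `high_frequency`, sorted by decreasing count.
#' @export
merge_fusion_pairs <- function(icts, high_frequency_min = 10) {
  has_genes <- !is.na(icts$geneA) & nzchar(icts$geneA) &
    !is.na(icts$geneB) & nzchar(icts$geneB)
  n_skipped <- sum(!has_genes)
  if (n_skipped > 0) warn(sprintf("%d ICT records missing gene symbols were skipped", n_skipped))
  tb <- icts[has_genes, ]
  tb <- tb[!duplicated(tb[, c("chromA", "posA", "chromB", "posB", "geneA", "geneB")]), ]
  ga <- toupper(tb$geneA)
  gb <- toupper(tb$geneB)
  out <- tibble(gene1 = pmin(ga, gb), gene2 = pmax(ga, gb)) %>%
    count(.data$gene1, .data$gene2, name = "count") %>%
    mutate(high_frequency = .data$count > high_frequency_min) %>%
    arrange(desc(.data$count), .data$gene1, .data$gene2)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Categorize a fusion pair's 3D interaction strength
#'
#' Averages the per-cell-line flexible IF values of a gene pair and bins the
#' mean: exactly 0 is `none`, below `t_strong` is `weak`, at or above
#' `t_strong` is `strong`.
#'
#' @param values Non-negative flexible IF values, one per cell line.
#' @param t_strong Strong-interaction threshold on the flexible-IF scale
#'   (default 0.5).
#' @return `"strong"`, `"weak"` or `"none"`.
#' @export
categorize_fusion_if <- function(values, t_strong = 0.5) {
  if (length(values) == 0) abort("need at least one cell-line value")
  if (any(values < 0)) abort("flexible IF values must be non-negative")
  if (t_strong <= 0) abort("t_strong must be positive")
  m <- mean(values)
  if (m == 0) "none" else if (m < t_strong) "weak" else "strong"
}

#' Count dosage-sensitive genes hit by compartment-disrupting SVs
#'
#' Crosses classified SVs with a dosage-sensitive gene set: each (SV, gene)
#' interval overlap counts once (a gene overlapping two SVs counts in each
#' pair). Categories `A-A` and `B-B` are `stable`, `A-B` and `B-A` are
#' `switching`.
#'
#' @param calls Output of [classify_compartment_disruption()] (needs
#'   `sv_id`, `chrom`, `start`, `end`, `category`).
#' @param genes Dosage-sensitive gene tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @return Tibble: `category`, `class` (`stable`/`switching`), `n_pairs` —
#'   one row per classified category, zero-filled.
#' @export
count_dosage_sensitive <- function(calls, genes) {
  classed <- calls %>% filter(.data$category %in% c("A-A", "A-B", "B-A", "B-B"))
  base <- tibble(
    category = c("A-A", "B-B", "A-B", "B-A"),
    class = c("stable", "stable", "switching", "switching")
  )
  if (nrow(classed) == 0 || nrow(genes) == 0) {
    return(base %>% mutate(n_pairs = 0L))
  }
  hits <- ivl_overlap_pairs(classed, genes)
  counts <- tibble(category = classed$category[hits$.xrow]) %>%
    count(.data$category, name = "n_pairs")
  base %>%
    left_join(counts, by = "category") %>%
    mutate(n_pairs = tidyr::replace_na(.data$n_pairs, 0L))
}

#' Map SNPs to genes through chromatin loops
#'
#' Each SNP is extended by 1 kb on both sides (interval
#' `[pos - 1000, pos + 1001)`, clamped at 0). A (SNP, gene) pair is emitted
#' when some loop has one anchor intersecting the extended SNP interval and
#' the other anchor intersecting the gene's region, in either orientation;
#' the supporting loop is recorded.
#'
#' @param snps SNP tibble (`snp_id`, `chrom`, `pos`; 0-based positions).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param loops Loop tibble from [read_loops()].
#' @param extend Extension in bp on each side (default 1000).
#' @return Tibble: `snp_id`, `gene_id`, `loop_id`, one row per supporting
#'   loop, duplicates removed.
#' @export
map_snp_to_loops <- function(snps, genes, loops, extend = 1000) {
  snp_iv <- tibble(
    snp_id = snps$snp_id, chrom = snps$chrom,
    start = pmax(0, snps$pos - extend), end = snps$pos + extend + 1
  )
  gene_iv <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start, end = genes$end
  )
  anchor <- function(side) {
    tibble(
      loop_id = loops$loop_id,
      chrom = loops[[paste0("chrom", side)]],
      start = loops[[paste0("start", side)]],
      end = loops[[paste0("end", side)]]
    )
  }
  one_orientation <- function(snp_anchor, gene_anchor) {
    sh <- ivl_overlap_pairs(snp_iv, snp_anchor)
    gh <- ivl_overlap_pairs(gene_iv, gene_anchor)
    inner_join(
      tibble(snp_id = snp_iv$snp_id[sh$.xrow], loop_id = snp_anchor$loop_id[sh$.yrow]),
      tibble(gene_id = gene_iv$gene_id[gh$.xrow], loop_id = gene_anchor$loop_id[gh$.yrow]),
      by = "loop_id", relationship = "many-to-many"
    )
  }
  bind_rows(
    one_orientation(anchor("A"), anchor("B")),
    one_orientation(anchor("B"), anchor("A"))
  ) %>%
    distinct(.data$snp_id, .data$gene_id, .data$loop_id) %>%
    arrange(.data$snp_id, .data$gene_id, .data$loop_id)
}

#' Classify loops by cancer-SNP content across tissues
#'
#' A loop containing at least one cancer-related SNP of every tissue within
#' either anchor is a cancer-specific loop (`CSL`); a loop containing none
#' in any tissue is a normal-specific loop (`NSL`); everything else is an
#' overlap loop (`OL`). The three categories are mutually exclusive and
#' exhaustive.
#'
#' @param loops Loop tibble from [read_loops()].
#' @param cancer_snps Tibble with `chrom`, `pos` (0-based) and `tissue`, one
#'   row per SNP-tissue assignment.
#' @param tissues Tissue universe; defaults to the tissues present in
#'   `cancer_snps`.
#' @return `loops` with `cancer_class` and `n_tissues_hit` appended.
#' @export
classify_loop_cancer_status <- function(loops, cancer_snps, tissues = NULL) {
  tissues <- tissues %||% sort(unique(cancer_snps$tissue))
  if (length(tissues) == 0) abort("tissue list must be nonempty")
  snp_iv <- tibble(
    chrom = cancer_snps$chrom, start = cancer_snps$pos,
    end = cancer_snps$pos + 1, tissue = cancer_snps$tissue
  )
  anchors <- bind_rows(
    tibble(.loop = seq_len(nrow(loops)), chrom = loops$chromA, start = loops$startA, end = loops$endA),
    tibble(.loop = seq_len(nrow(loops)), chrom = loops$chromB, start = loops$startB, end = loops$endB)
  )
  hits <- ivl_overlap_pairs(anchors, snp_iv)
  hit_tb <- distinct(tibble(
    .loop = anchors$.loop[hits$.xrow],
    tissue = snp_iv$tissue[hits$.yrow]
  ))
  hit_tb <- hit_tb[hit_tb$tissue %in% tissues, ]
  n_hit <- integer(nrow(loops))
  agg <- hit_tb %>% count(.data$.loop)
  n_hit[agg$.loop] <- agg$n
  n_tissues <- length(tissues)
  loops %>% mutate(
    n_tissues_hit = n_hit,
    cancer_class = dplyr::case_when(
      n_hit == n_tissues ~ "CSL",
      n_hit == 0 ~ "NSL",
      TRUE ~ "OL"
    )
  )
}

#' Classify loops as enhancer-promoter, CTCF or other
#'
#' Enhancer-promoter (`EP`) classification has priority: a loop with one
#' anchor intersecting an enhancer interval and the other a promoter
#' interval (either orientation) is `EP` even if its anchors also carry
#' CTCF peaks. Otherwise a loop with at least one anchor overlapping a CTCF
#' peak is `CTCF`; the rest are `other`.
#'
#' @param loops Loop tibble from [read_loops()].
#' @param ctcf_peaks,enhancers,promoters Region tibbles.
#' @return `loops` with a `loop_type` column appended.
#' @export
classify_loop_type <- function(loops, ctcf_peaks, enhancers, promoters) {
  aA <- tibble(chrom = loops$chromA, start = loops$startA, end = loops$endA)
  aB <- tibble(chrom = loops$chromB, start = loops$startB, end = loops$endB)
  a_enh <- ivl_hits_any(aA, enhancers)
  b_enh <- ivl_hits_any(aB, enhancers)
  a_pro <- ivl_hits_any(aA, promoters)
  b_pro <- ivl_hits_any(aB, promoters)
  a_ctcf <- ivl_hits_any(aA, ctcf_peaks)
  b_ctcf <- ivl_hits_any(aB, ctcf_peaks)
  is_ep <- (a_enh & b_pro) | (b_enh & a_pro)
  loops %>% mutate(
    loop_type = dplyr::case_when(
      is_ep ~ "EP",
      a_ctcf | b_ctcf ~ "CTCF",
      TRUE ~ "other"
    )
  )
}

#' Annotate SNPs as coding or noncoding
#'
#' A SNP is `coding` when its position falls inside any CDS interval or
#' lies within `splice_margin` bp (inclusive) of any annotated splice-site
#' coordinate; otherwise `noncoding`.
#'
#' @param snps SNP tibble (`chrom`, `pos`, 0-based).
#' @param genes Gene models from [read_gene_models()] (with `cds` and
#'   `splice_sites` list-columns).
#' @param splice_margin Inclusive distance in bp (default 10).
#' @return `snps` with an `annotation` column appended.
#' @export
annotate_snp_coding <- function(snps, genes, splice_margin = 10) {
  cds_tb <- purrr::map2_dfr(genes$chrom, genes$cds, function(chrom, m) {
    if (is.null(m) || nrow(m) == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    tibble(chrom = chrom, start = m[, "start"], end = m[, "end"])
  })
  splice_tb <- purrr::map2_dfr(genes$chrom, genes$splice_sites, function(chrom, s) {
    tibble(chrom = rep(chrom, length(s)), site = as.numeric(s))
  })
  snp_iv <- tibble(chrom = snps$chrom, start = snps$pos, end = snps$pos + 1)
  in_cds <- ivl_hits_any(snp_iv, cds_tb)
  near_splice <- vapply(seq_len(nrow(snps)), function(i) {
    s <- splice_tb$site[splice_tb$chrom == snps$chrom[i]]
    length(s) > 0 && min(abs(snps$pos[i] - s)) <= splice_margin
  }, TRUE)
  snps %>% mutate(annotation = ifelse(in_cds | near_splice, "coding", "noncoding"))
}
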