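# Deterministic synthetic-data generators. They emulate the statistical
# structure the analysis assumes -- distance-decay contact matrices with
# compartment checkerboard, TAD blocks and planted loop peaks; log-normal
# expression with planted differential genes; variant sets placed at known
# layout positions so classifier truth is exact -- at a toy scale where
# every downstream result can be checked against planted truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators. The same config and seed
#' always produce bit-identical outputs.
#'
#' @param seed Integer seed driving all randomness.
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param resolutions Bin sizes (bp) at which contact matrices are built.
#' @param decay_exponent Distance-decay exponent for contacts
#'   (`(d + 1)^exponent`, d in bins); -1 is the canonical interphase
#'   scaling.
#' @param decay_scale Contact value at distance 0 before structure factors.
#' @param compartment_block Checkerboard block size in bp (A/B alternate).
#' @param compartment_strength Contact multiplier for same-phase bin pairs.
#' @param domain_sizes Cycle of TAD domain sizes in bp.
#' @param boundary_width TAD boundary width in bp.
#' @param tad_strength Contact multiplier within a domain.
#' @param loop_strength Added contact at planted loop anchor pairs.
#' @param noise_max Upper bound of the non-negative uniform contact noise.
#' @param trans_density Fraction of cross-chromosome bin pairs given
#'   background contact.
#' @param trans_value Contact value of cross-chromosome background entries.
#' @param hotspot_value Contact value planted on cross-chromosome fusion
#'   hotspot rectangles.
#' @param n_genes,n_cancer,n_normal Expression matrix dimensions (the
#'   default 20 cancer / 15 normal matches the cell-line design the EC
#'   statistic is built for).
#' @param expr_meanlog,expr_sdlog Log-normal baseline of per-gene mean
#'   expression.
#' @param expr_noise_sdlog Multiplicative (log-scale) sample noise SD.
#' @param frac_diff Fraction of genes planted as differential.
#' @param effect_log Log-scale up-shift of planted genes in cancer samples.
#' @param n_score_pairs Number of variant-gene pairs for the scoring truth
#'   set.
#' @param curve_A,curve_tau Parameters of the EC~IC decay the pairs are
#'   generated on.
#' @param pair_noise_sd Gaussian EC noise around the curve.
#' @param frac_causal Fraction of pairs displaced off the curve (planted
#'   causal pairs).
#' @param displacement Absolute EC displacement of planted causal pairs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_sizes = c(chrS1 = 3e6, chrS2 = 2.5e6, chrS3 = 2e6),
                       resolutions = c(10000, 50000),
                       decay_exponent = -1,
                       decay_scale = 10,
                       compartment_block = 250e3,
                       compartment_strength = 2,
                       domain_sizes = c(100e3, 150e3, 120e3),
                       boundary_width = 20e3,
                       tad_strength = 3,
                       loop_strength = 20,
                       noise_max = 0.2,
                       trans_density = 0.002,
                       trans_value = 0.1,
                       hotspot_value = 5,
                       n_genes = 300,
                       n_cancer = 20,
                       n_normal = 15,
                       expr_meanlog = 4,
                       expr_sdlog = 1,
                       expr_noise_sdlog = 0.2,
                       frac_diff = 0.1,
                       effect_log = 2,
                       n_score_pairs = 200,
                       curve_A = 0.9,
                       curve_tau = 0.5,
                       pair_noise_sd = 0.02,
                       frac_causal = 0.05,
                       displacement = 0.4) {
  stopifnot(
    all(chrom_sizes > 0), all(resolutions > 0), boundary_width > 0,
    all(domain_sizes > 0), frac_diff >= 0, frac_diff <= 1,
    frac_causal >= 0, frac_causal <= 1, n_score_pairs >= 3
  )
  structure(as.list(environment()), class = "sim_config")
}

#' Deterministic compartment / TAD layouts of a simulation
#'
#' The checkerboard compartment track (blocks of `compartment_block` bp,
#' labels alternating A, B, A, ... from the chromosome start) and the TAD
#' layout (domains cycling through `domain_sizes`, separated by
#' `boundary_width` boundaries) are pure functions of the config, shared by
#' the contact generator and the variant-truth generator.
#'
#' @param config A [sim_config()].
#' @return `sim_compartment_track()`: a compartment track tibble
#'   (`chrom`, `start`, `end`, `label`, `eigen`).
#' @export
sim_compartment_track <- function(config) {
  purrr::imap_dfr(as.list(config$chrom_sizes), function(len, chrom) {
    starts <- seq(0, len - 1, by = config$compartment_block)
    ends <- pmin(starts + config$compartment_block, len)
    lab <- ifelse((seq_along(starts) - 1) %% 2 == 0, "A", "B")
    tibble(
      chrom = chrom, start = starts, end = ends, label = lab,
      eigen = ifelse(lab == "A", 1, -1)
    )
  })
}

#' @rdname sim_compartment_track
#' @return `sim_tad_layout()`: list of two region tibbles, `domains` and
#'   `boundaries`.
#' @export
sim_tad_layout <- function(config) {
  doms <- list()
  bnds <- list()
  for (chrom in names(config$chrom_sizes)) {
    len <- config$chrom_sizes[[chrom]]
    pos <- 0
    k <- 0
    while (TRUE) {
      ds <- config$domain_sizes[(k %% length(config$domain_sizes)) + 1]
      if (pos + ds > len) break
      doms[[length(doms) + 1]] <- tibble(chrom = chrom, start = pos, end = pos + ds)
      pos <- pos + ds
      if (pos + config$boundary_width > len) break
      bnds[[length(bnds) + 1]] <- tibble(chrom = chrom, start = pos, end = pos + config$boundary_width)
      pos <- pos + config$boundary_width
      k <- k + 1
    }
  }
  list(domains = bind_rows(doms), boundaries = bind_rows(bnds))
}

#' Planted loops of a simulation
#'
#' Two intra-chromosomal loops per chromosome at fixed fractional
#' positions, with anchors one finest-resolution bin wide.
#'
#' @param config A [sim_config()].
#' @return Loop tibble (`loop_id`, anchor columns, `tissues` list-column).
#' @export
sim_loops <- function(config) {
  r <- min(config$resolutions)
  out <- purrr::imap_dfr(as.list(config$chrom_sizes), function(len, chrom) {
    anchor <- function(frac) floor(len * frac / r) * r
    tibble(
      chromA = chrom,
      startA = c(anchor(0.10), anchor(0.55)),
      chromB = chrom,
      startB = c(anchor(0.35), anchor(0.80))
    )
  })
  out %>% mutate(
    endA = .data$startA + r, endB = .data$startB + r,
    loop_id = paste0("loop", dplyr::row_number()),
    tissues = rep(list(character()), dplyr::n())
  ) %>%
    select("loop_id", "chromA", "startA", "endA", "chromB", "startB", "endB", "tissues")
}

# fusion hotspot rectangles joining the first two chromosomes
sim_hotspots <- function(config) {
  ch <- names(config$chrom_sizes)
  r <- min(config$resolutions)
  al <- function(len, frac) floor(len * frac / r) * r
  l1 <- config$chrom_sizes[[ch[1]]]
  l2 <- config$chrom_sizes[[ch[2]]]
  tibble(
    chromA = ch[1],
    startA = c(al(l1, 0.2), al(l1, 0.6)),
    endA = c(al(l1, 0.2), al(l1, 0.6)) + 2 * r,
    chromB = ch[2],
    startB = c(al(l2, 0.3), al(l2, 0.7)),
    endB = c(al(l2, 0.3), al(l2, 0.7)) + 2 * r
  )
}

#' Generate a synthetic multi-resolution contact store
#'
#' Intra-chromosomal contact for bins `i, j` is
#' `decay_scale * (|i - j| + 1)^decay_exponent`, multiplied by
#' `compartment_strength` when both bins fall in the same checkerboard
#' phase and by `tad_strength` when both fall in the same TAD domain, with
#' `loop_strength` added at planted loop anchor pairs and non-negative
#' uniform noise on every pair. Cross-chromosome contact is sparse uniform
#' background plus elevated fusion-hotspot rectangles. Matrices are built
#' independently at every configured resolution; same seed, same store.
#'
#' @param config A [sim_config()].
#' @return A [contact_store()].
#' @export
gen_hic <- function(config) {
  set.seed(config$seed)
  track <- sim_compartment_track(config)
  tads <- sim_tad_layout(config)
  loops <- sim_loops(config)
  hot <- sim_hotspots(config)
  chroms <- names(config$chrom_sizes)
  contacts <- list()
  for (r in config$resolutions) {
    coo <- list()
    for (chrom in chroms) {
      len <- config$chrom_sizes[[chrom]]
      nb <- ceiling(len / r)
      bin_start <- (seq_len(nb) - 1) * r
      phase <- floor(bin_start / config$compartment_block) %% 2
      dom <- ivl_locate(rep(chrom, nb), bin_start, tads$domains)
      idx <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
      i <- idx[, 1] - 1
      j <- idx[, 2] - 1
      d <- j - i
      v <- config$decay_scale * (d + 1)^config$decay_exponent
      v <- v * ifelse(phase[i + 1] == phase[j + 1], config$compartment_strength, 1)
      same_dom <- !is.na(dom[i + 1]) & !is.na(dom[j + 1]) & dom[i + 1] == dom[j + 1]
      v <- v * ifelse(same_dom, config$tad_strength, 1)
      v <- v + runif(length(v), 0, config$noise_max)
      tb <- tibble(chromA = chrom, binA = i, chromB = chrom, binB = j, value = v)
      lp <- loops[loops$chromA == chrom, ]
      if (nrow(lp) > 0) {
        la <- floor(lp$startA / r)
        lb <- floor(lp$startB / r)
        key <- paste(pmin(la, lb), pmax(la, lb))
        hitk <- match(paste(tb$binA, tb$binB), key)
        tb$value <- tb$value + ifelse(is.na(hitk), 0, config$loop_strength)
      }
      coo[[length(coo) + 1]] <- tb
    }
    # sparse cross-chromosome background
    for (ci in seq_along(chroms)) {
      for (cj in seq_along(chroms)) {
        if (cj <= ci) next
      ca <- chroms[ci]
      cb <- chroms[cj]
      na <- ceiling(config$chrom_sizes[[ca]] / r)
      nbb <- ceiling(config$chrom_sizes[[cb]] / r)
      n_bg <- max(1, round(config$trans_density * na * nbb))
      tb <- tibble(
        chromA = ca,
        binA = sample.int(na, n_bg, replace = TRUE) - 1,
        chromB = cb,
        binB = sample.int(nbb, n_bg, replace = TRUE) - 1,
        value = config$trans_value + runif(n_bg, 0, config$noise_max)
      )
      tb <- tb[!duplicated(tb[, c("binA", "binB")]), ]
      coo[[length(coo) + 1]] <- tb
      }
    }
    # fusion hotspot rectangles
    for (h in seq_len(nrow(hot))) {
      ba <- floor(hot$startA[h] / r):floor((hot$endA[h] - 1) / r)
      bb <- floor(hot$startB[h] / r):floor((hot$endB[h] - 1) / r)
      grid <- expand.grid(binA = ba, binB = bb)
      coo[[length(coo) + 1]] <- tibble(
        chromA = hot$chromA[h], binA = grid$binA,
        chromB = hot$chromB[h], binB = grid$binB,
        value = config$hotspot_value
      )
    }
    all_coo <- bind_rows(coo)
    # later entries (hotspots) override background duplicates
    all_coo <- all_coo[!duplicated(
      all_coo[, c("chromA", "binA", "chromB", "binB")],
      fromLast = TRUE
    ), ]
    contacts[[as.character(r)]] <- all_coo
  }
  contact_store(contacts, config$chrom_sizes)
}

#' Generate a synthetic expression matrix with planted differential genes
#'
#' Per-gene baseline means are log-normal
#' (`meanlog = expr_meanlog`, `sdlog = expr_sdlog`); each sample value is
#' the baseline times multiplicative log-normal noise
#' (`sdlog = expr_noise_sdlog`). A fraction `frac_diff` of genes is shifted
#' up by `effect_log` (log scale) in cancer samples.
#'
#' @param config A [sim_config()].
#' @param effect_log Override of the planted effect (e.g. 0 for a null
#'   calibration run).
#' @return List: `expression` (gene-by-sample tibble), `metadata`
#'   (`sample_id`, `condition`, `aliquot`), `truth` (`gene_id`,
#'   `differential`, `effect_log`).
#' @export
gen_expression <- function(config, effect_log = config$effect_log) {
  set.seed(config$seed + 1L)
  n_g <- config$n_genes
  n_c <- config$n_cancer
  n_n <- config$n_normal
  genes <- sprintf("GSIM%03d", seq_len(n_g))
  samples <- c(sprintf("cancer_%02d", seq_len(n_c)), sprintf("normal_%02d", seq_len(n_n)))
  condition <- rep(c("cancer", "normal"), c(n_c, n_n))
  baseline <- rlnorm(n_g, config$expr_meanlog, config$expr_sdlog)
  n_diff <- round(config$frac_diff * n_g)
  diff_idx <- if (n_diff > 0) sample.int(n_g, n_diff) else integer()
  eff <- numeric(n_g)
  eff[diff_idx] <- effect_log
  noise <- matrix(rnorm(n_g * (n_c + n_n), 0, config$expr_noise_sdlog), n_g)
  shift <- outer(eff, as.numeric(condition == "cancer"))
  vals <- baseline * exp(shift + noise)
  mat <- as_tibble(as.data.frame(vals))
  names(mat) <- samples
  list(
    expression = bind_cols(tibble(gene_id = genes), mat),
    metadata = tibble(sample_id = samples, condition = condition, aliquot = paste0("aliq_", samples)),
    truth = tibble(gene_id = genes, differential = eff != 0, effect_log = eff)
  )
}

# helper: an SV row
sv_row <- function(chrom, start, end, truth, sv_type = "deletion", frequency = 0.05) {
  tibble(
    chrom = chrom, start = start, end = end,
    sv_type = sv_type, frequency = frequency, truth = truth
  )
}

#' Generate variant sets with exact classifier truth
#'
#' Places SVs at known positions of the simulated compartment checkerboard
#' and TAD layout so the compartment labels (`A-A`, `A-B`, `B-A`, `B-B`)
#' and TAD categories (`intra-TAD`, `inter-TAD1/2/3`, plus an `excluded`
#' oversize case) are known by construction; plants SNPs inside loop
#' anchors paired with genes at the partner anchors (and decoy SNPs outside
#' all anchors); emits ICT records for the fusion hotspots, one pair at
#' high frequency; and draws variant-gene score pairs on the EC~IC decay
#' curve with a planted fraction displaced off it (the causal truth).
#'
#' @param config A [sim_config()].
#' @return List of tibbles: `comp_svs`, `tad_svs` (with `truth` columns),
#'   `snps`, `genes`, `loops`, `snp_pair_truth` (`snp_id`, `gene_id`),
#'   `icts`, `score_pairs` (`pair_id`, `ic`, `ec`, `ci`, `ni`, `causal`).
#' @export
gen_variant_truth <- function(config) {
  set.seed(config$seed + 2L)
  track <- sim_compartment_track(config)
  tads <- sim_tad_layout(config)
  loops <- sim_loops(config)
  blk <- config$compartment_block

  # --- compartment SVs: blocks alternate A,B,A,... from 0 on every chrom
  comp <- list()
  for (chrom in names(config$chrom_sizes)) {
    # inside first A block / second (B) block; spanning each transition
    comp[[length(comp) + 1]] <- bind_rows(
      sv_row(chrom, 0.1 * blk, 0.6 * blk, "A-A"),
      sv_row(chrom, 1.2 * blk, 1.7 * blk, "B-B"),
      sv_row(chrom, 0.7 * blk, 1.4 * blk, "A-B"),
      sv_row(chrom, 1.6 * blk, 2.3 * blk, "B-A")
    )
  }
  comp_svs <- bind_rows(comp) %>% mutate(sv_id = paste0("csv", dplyr::row_number()))

  # --- TAD SVs from the realized layout of the first chromosome
  ch1 <- names(config$chrom_sizes)[1]
  dom <- tads$domains %>% filter(.data$chrom == ch1)
  bnd <- tads$boundaries %>% filter(.data$chrom == ch1)
  d1 <- dom[1, ]
  d2 <- dom[2, ]
  d3 <- dom[3, ]
  b1 <- bnd[1, ]
  b2 <- bnd[2, ]
  intra_len <- 0.3 * (d1$end - d1$start)
  tad_svs <- bind_rows(
    # both breakpoints inside domain 1, well under the 50% size cap
    sv_row(ch1, d1$start + 0.1 * (d1$end - d1$start), d1$start + 0.1 * (d1$end - d1$start) + intra_len, "intra-TAD"),
    # left in boundary 1, right inside domain 2 (short)
    sv_row(ch1, b1$start + 2, d2$start + 0.2 * (d2$end - d2$start), "inter-TAD1"),
    # left in boundary 1, right in boundary 2 (spans domain 2; no containing domain, never excluded)
    sv_row(ch1, b1$start + 2, b2$start + 2, "inter-TAD2"),
    # facing edges of domains 1 and 2: short enough to pass the 50% rule
    sv_row(ch1, d1$end - 0.1 * (d1$end - d1$start), d2$start + 0.1 * (d2$end - d2$start), "inter-TAD3"),
    # domain 1 start to domain 2 end: longer than 50% of the mean domain size
    sv_row(ch1, d1$start + 2, d3$start - config$boundary_width - 2, "excluded")
  ) %>% mutate(sv_id = paste0("tsv", dplyr::row_number()))

  # --- SNPs and genes around planted loops
  genes <- loops %>%
    transmute(
      gene_id = paste0("G_", .data$loop_id),
      chrom = .data$chromB, start = .data$startB, end = .data$endB,
      strand = "+"
    )
  snp_in <- loops %>%
    transmute(
      snp_id = paste0("S_", .data$loop_id),
      chrom = .data$chromA,
      pos = floor((.data$startA + .data$endA) / 2),
      ref = "A", alt = "G"
    )
  # decoys: midway between the two anchors, > 1 kb from either
  snp_out <- loops %>%
    transmute(
      snp_id = paste0("Sout_", .data$loop_id),
      chrom = .data$chromA,
      pos = floor((.data$endA + .data$startB) / 2),
      ref = "C", alt = "T"
    )
  snps <- bind_rows(snp_in, snp_out) %>%
    mutate(tissues = rep(list(character()), dplyr::n()), is_cancer_related = FALSE)
  snp_pair_truth <- tibble(
    snp_id = snp_in$snp_id,
    gene_id = paste0("G_", loops$loop_id),
    loop_id = loops$loop_id
  )

  # --- ICTs at the fusion hotspots; first pair recurrent (> 10), second rare
  hot <- sim_hotspots(config)
  mk_ict <- function(h, geneA, geneB, n) {
    tibble(
      chromA = hot$chromA[h],
      posA = hot$startA[h] + seq_len(n), # distinct breakpoints -> no dedup loss
      chromB = hot$chromB[h],
      posB = hot$startB[h] + seq_len(n),
      geneA = geneA, geneB = geneB, source = "sim"
    )
  }
  icts <- bind_rows(
    mk_ict(1, "FUSA", "FUSB", 12),
    mk_ict(2, "FUSC", "FUSD", 3)
  ) %>% mutate(ict_id = paste0("ict", dplyr::row_number()))

  # --- variant-gene score pairs on the decay curve, a fraction displaced
  n <- config$n_score_pairs
  ic <- runif(n, 0, 2)
  ec_curve <- config$curve_A * exp(-ic / config$curve_tau)
  ec <- ec_curve + rnorm(n, 0, config$pair_noise_sd)
  n_causal <- round(config$frac_causal * n)
  causal <- rep(FALSE, n)
  if (n_causal > 0) {
    idx <- sample.int(n, n_causal)
    causal[idx] <- TRUE
    # displace away from the curve, direction keeping EC inside (0, 1)
    dir <- ifelse(ec_curve[idx] > 0.5, -1, 1)
    ec[idx] <- ec_curve[idx] + dir * config$displacement
  }
  ec <- pmin(pmax(ec, 1e-6), 1 - 1e-6)
  ni <- runif(n, 0, 0.5)
  score_pairs <- tibble(
    pair_id = sprintf("vp%03d", seq_len(n)),
    variant = sprintf("var%03d", seq_len(n)),
    gene = sprintf("GSIM%03d", sample.int(config$n_genes, n, replace = TRUE)),
    cell_line = "simCL1",
    ni = ni, ci = ni + ic, ic = ic, ec = ec, causal = causal
  )

  list(
    comp_svs = comp_svs, tad_svs = tad_svs,
    snps = snps, genes = genes, loops = loops,
    snp_pair_truth = snp_pair_truth,
    icts = icts, score_pairs = score_pairs,
    track = track, domains = tads$domains, boundaries = tads$boundaries
  )
}
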