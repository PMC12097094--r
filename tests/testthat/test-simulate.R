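small_sim <- function(seed = 5) {
  sim_config(
    seed = seed,
    chrom_sizes = c(chrS1 = 1.2e6, chrS2 = 1e6),
    resolutions = c(10000, 50000),
    n_genes = 60,
    n_score_pairs = 60
  )
}

test_that("generated stores satisfy the contact-store invariants and are reproducible", {
  cfg <- small_sim()
  store1 <- gen_hic(cfg)
  store2 <- gen_hic(cfg)
  expect_equal(store1$maps, store2$maps) # same seed, same store
  other <- gen_hic(small_sim(seed = 6))
  expect_false(isTRUE(all.equal(store1$maps, other$maps)))
  for (r in names(store1$maps)) {
    coo <- store1$maps[[r]]
    expect_true(all(coo$value >= 0))
    nb <- ceiling(store1$chrom_sizes / as.numeric(r))
    expect_true(all(coo$binA < nb[coo$chromA]))
    expect_true(all(coo$binB < nb[coo$chromB]))
  }
})

test_that("planted TAD structure elevates intra-domain over cross-domain contact", {
  cfg <- small_sim()
  store <- gen_hic(cfg)
  tads <- sim_tad_layout(cfg)
  d <- tads$domains[tads$domains$chrom == "chrS1", ]
  r <- 10000
  # same genomic separation, within domain 2 vs straddling domains 1/2
  d2 <- d[2, ]
  within <- query_if(
    store,
    region("chrS1", d2$start, d2$start + r),
    region("chrS1", d2$start + 3 * r, d2$start + 4 * r), r
  )
  across <- query_if(
    store,
    region("chrS1", d2$start - 2 * r, d2$start - r),
    region("chrS1", d2$start + 2 * r, d2$start + 3 * r), r
  )
  expect_gt(within, across)
})

test_that("planted loops produce a local virtual-4C maximum at the partner anchor", {
  cfg <- small_sim()
  store <- gen_hic(cfg)
  loops <- sim_loops(cfg)
  lp <- loops[1, ]
  prof <- virtual_4c(store, region(lp$chromA, lp$startA, lp$endA), 10000)
  peak_bin <- lp$startB / 10000
  peak <- prof$value[prof$bin == peak_bin]
  flank <- prof$value[prof$bin %in% c(peak_bin - 2, peak_bin + 2)]
  expect_true(all(peak > flank))
})

test_that("expression generator plants recoverable differential genes", {
  cfg <- small_sim()
  ge <- gen_expression(cfg)
  expect_equal(ge$expression, gen_expression(cfg)$expression) # determinism
  meta <- ge$metadata
  ec <- expression_change(
    ge$expression,
    meta$sample_id[meta$condition == "cancer"],
    meta$sample_id[meta$condition == "normal"]
  )
  planted <- ge$truth$gene_id[ge$truth$differential]
  expect_gt(length(planted), 0)
  expect_true(all(ec$ec[ec$gene_id %in% planted] > 0.99))
  # null run: no planted effects
  ec0 <- expression_change(
    gen_expression(cfg, effect_log = 0)$expression,
    meta$sample_id[meta$condition == "cancer"],
    meta$sample_id[meta$condition == "normal"]
  )
  expect_lt(max(ec0$ec[ge$truth$differential]), 1) # no degenerate values
})

test_that("variant truth generator places classifiable variants", {
  cfg <- small_sim()
  truth <- gen_variant_truth(cfg)
  # compartment truth recovered exactly
  comp <- classify_compartment_disruption(truth$comp_svs, truth$track)
  expect_equal(comp$category, truth$comp_svs$truth)
  # TAD truth recovered exactly
  tad <- classify_tad_disruption(truth$tad_svs, truth$domains, truth$boundaries)
  expect_equal(tad$category, truth$tad_svs$truth)
  # SNP-loop truth: planted pairs emitted, decoys not
  hits <- map_snp_to_loops(truth$snps, truth$genes, truth$loops)
  expect_equal(
    dplyr::arrange(hits[, c("snp_id", "gene_id")], snp_id),
    dplyr::arrange(truth$snp_pair_truth[, c("snp_id", "gene_id")], snp_id)
  )
  # fusion counts: first pair recurrent, strict threshold
  pairs <- merge_fusion_pairs(truth$icts)
  expect_equal(pairs$count[pairs$gene1 == "FUSA"], 12)
  expect_true(pairs$high_frequency[pairs$gene1 == "FUSA"])
  expect_false(pairs$high_frequency[pairs$gene1 == "FUSC"])
  # score pairs: displaced fraction flagged causal
  expect_equal(sum(truth$score_pairs$causal), round(0.05 * cfg$n_score_pairs))
  expect_equal(truth$score_pairs$ic, abs(truth$score_pairs$ci - truth$score_pairs$ni))
})

test_that("fusion hotspots give recurrent pairs stronger flexible IF than random cross-chromosome regions", {
  cfg <- small_sim()
  store <- gen_hic(cfg)
  truth <- gen_variant_truth(cfg)
  ict1 <- truth$icts[1, ]
  r <- 10000
  hot_fif <- flexible_if(
    store,
    region(ict1$chromA, ict1$posA - r, ict1$posA + r),
    region(ict1$chromB, ict1$posB - r, ict1$posB + r)
  )
  expect_gt(hot_fif$flexible_if, 0)
})
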