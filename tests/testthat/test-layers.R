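toy_track <- function() {
  # checkerboard: 100 bp blocks A,B,A,B on chrT
  tibble::tibble(
    chrom = "chrT",
    start = c(0, 100, 200, 300),
    end = c(100, 200, 300, 400),
    label = c("A", "B", "A", "B")
  )
}

sv_tb <- function(start, end, frequency = 0.05) {
  tibble::tibble(
    sv_id = paste0("sv", seq_along(start)), chrom = "chrT",
    start = start, end = end, sv_type = "deletion", frequency = frequency
  )
}

test_that("filter_svs applies the 10 kb-10 Mb and >1% rules with inclusive length bounds", {
  svs <- tibble::tibble(
    sv_id = paste0("s", 1:5), chrom = "c1",
    start = 0,
    end = c(5e3, 5e4, 2e7, 5e4, 1e4),
    sv_type = "deletion",
    frequency = c(0.05, 0.05, 0.05, 0.001, 0.02)
  )
  kept <- filter_svs(svs)
  expect_equal(kept$sv_id, c("s2", "s5")) # s5: length exactly 10 kb is retained
  expect_equal(attr(kept, "drop_counts"), c(length = 2, frequency = 1))
  empty <- filter_svs(svs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("compartment disruption reports the ordered breakpoint label pair", {
  track <- toy_track()
  calls <- classify_compartment_disruption(
    sv_tb(start = c(10, 110, 10, 110, 10), end = c(90, 190, 190, 290, 300)),
    track
  )
  # sv5 ends exactly at the 300 transition: right breakpoint 299 stays in the A bin
  expect_equal(calls$category, c("A-A", "B-B", "A-B", "B-A", "A-A"))
  # gap handling
  gap_track <- track[-2, ]
  calls2 <- classify_compartment_disruption(sv_tb(10, 190), gap_track)
  expect_equal(calls2$category, "unmapped")
  # invariant to track interval order
  calls3 <- classify_compartment_disruption(
    sv_tb(start = c(10, 110), end = c(90, 190)), track[sample(1:4), ]
  )
  expect_equal(calls3$category, c("A-A", "B-B"))
  # distance to the nearest label transition
  expect_equal(calls$dist_left[1], 90) # pos 10, transitions at 100,200,300
  expect_equal(calls$dist_right[2], 11) # pos 189 vs 200
})

test_that("TAD disruption covers the four categories, exclusion and unmapped", {
  domains <- tibble::tibble(chrom = "chrT", start = c(0, 1200, 2400), end = c(1000, 2200, 3400))
  bounds <- tibble::tibble(chrom = "chrT", start = c(1000, 2200), end = c(1200, 2400))
  svs <- sv_tb(
    start = c(100, 1050, 1050, 900, 100, 3500),
    end = c(400, 1500, 2300, 1500, 2000, 3600)
  )
  calls <- classify_tad_disruption(svs, domains, bounds)
  expect_equal(calls$category, c(
    "intra-TAD", # both in domain 1, len 300 <= 50% of 1000
    "inter-TAD1", # boundary + domain, len 450 under the cap
    "inter-TAD2", # two different boundary intervals; exclusion not applicable
    "excluded", # domains 1-2 but len 600 > 50% of mean domain size
    "excluded", # domains 1-2, len 1900
    "unmapped" # breakpoint beyond all domains/boundaries
  ))
})

test_that("TAD 50% exclusion boundary arithmetic is exact", {
  domains <- tibble::tibble(chrom = "chrT", start = c(0, 1200), end = c(1000, 2200))
  bounds <- tibble::tibble(chrom = "chrT", start = 1000, end = 1200)
  # inter-TAD3 with mean domain size 1000: threshold is length 500
  ok <- classify_tad_disruption(sv_tb(900, 1400), domains, bounds) # len 500 == 50%
  expect_equal(ok$category, "inter-TAD3")
  over <- classify_tad_disruption(sv_tb(899, 1400), domains, bounds) # len 501
  expect_equal(over$category, "excluded")
  # intra-TAD uses the containing domain
  expect_equal(classify_tad_disruption(sv_tb(0, 500), domains, bounds)$category, "intra-TAD")
  expect_equal(classify_tad_disruption(sv_tb(0, 501), domains, bounds)$category, "excluded")
})

test_that("fusion pairs are deduplicated, unordered, and >10 is strict", {
  base <- tibble::tibble(
    chromA = "chr1", posA = 1:12 * 10, chromB = "chr2", posB = 1:12 * 10,
    geneA = "X", geneB = "Y", source = "db"
  )
  base$posA[12] <- base$posA[11] # exact duplicate of record 11
  base$posB[12] <- base$posB[11]
  flipped <- tibble::tibble(
    chromA = "chr2", posA = 500, chromB = "chr1", posB = 600,
    geneA = "y", geneB = "x", source = "db" # (Y,X) lowercase: same unordered pair
  )
  pairs <- merge_fusion_pairs(dplyr::bind_rows(base, flipped))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$count, 12) # 13 records - 1 exact duplicate
  expect_true(pairs$high_frequency)
  # count exactly 10 -> not high frequency (strict >10); 11 -> high
  ten <- merge_fusion_pairs(base[1:10, ])
  expect_false(ten$high_frequency)
  eleven <- merge_fusion_pairs(base[1:11, ])
  expect_true(eleven$high_frequency)
  # records without gene symbols are skipped with a warning
  nog <- base
  nog$geneA[1] <- NA
  expect_warning(res <- merge_fusion_pairs(nog), "skipped")
  expect_equal(attr(res, "n_skipped"), 1)
})

test_that("fusion IF categories split at zero and at t_strong", {
  expect_equal(categorize_fusion_if(c(0, 0, 0)), "none")
  expect_equal(categorize_fusion_if(c(0.6, 0.8), t_strong = 0.5), "strong")
  expect_equal(categorize_fusion_if(c(0.1, 0.3), t_strong = 0.5), "weak")
  expect_equal(categorize_fusion_if(0.5, t_strong = 0.5), "strong") # >= threshold
  expect_error(categorize_fusion_if(c(-0.1, 0.2)), "non-negative")
})

test_that("dosage-sensitive counting is per (SV, gene) overlap", {
  calls <- tibble::tibble(
    sv_id = c("s1", "s2"), chrom = "chrT",
    start = c(0, 500), end = c(300, 600),
    category = c("A-B", "A-A")
  )
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chrT",
    start = c(50, 250), end = c(80, 320)
  )
  counts <- count_dosage_sensitive(calls, genes)
  expect_equal(sum(counts$n_pairs[counts$class == "switching"]), 2)
  expect_equal(sum(counts$n_pairs[counts$class == "stable"]), 0)
  # a gene overlapping two SVs counts once per pair
  calls2 <- tibble::tibble(
    sv_id = c("s1", "s2"), chrom = "chrT", start = c(0, 100), end = c(300, 400),
    category = c("A-B", "B-A")
  )
  counts2 <- count_dosage_sensitive(calls2, genes[2, ])
  expect_equal(sum(counts2$n_pairs), 2)
  expect_equal(sum(count_dosage_sensitive(calls, genes[0, ])$n_pairs), 0)
})

test_that("SNP-loop mapping extends by 1 kb, clamps at 0 and requires the gene side", {
  loops <- tibble::tibble(
    loop_id = "L1",
    chromA = "chrT", startA = 5000, endA = 6000,
    chromB = "chrT", startB = 20000, endB = 21000
  )
  genes <- tibble::tibble(gene_id = "g1", chrom = "chrT", start = 20500, end = 22000)
  snps <- tibble::tibble(snp_id = c("in", "near", "far"), chrom = "chrT", pos = c(5500, 6900, 10000))
  hits <- map_snp_to_loops(snps, genes, loops)
  # pos 6900 - 1000 = 5900 < 6000: the extended interval reaches the anchor
  expect_equal(sort(hits$snp_id), c("in", "near"))
  # both anchors overlapping only the SNP side emit nothing
  no_gene <- map_snp_to_loops(snps[1, ], genes[0, ], loops)
  expect_equal(nrow(no_gene), 0)
  # clamp: pos 300 gives [0, 1301)
  loops0 <- tibble::tibble(
    loop_id = "L0", chromA = "chrT", startA = 0, endA = 100,
    chromB = "chrT", startB = 20000, endB = 21000
  )
  hit0 <- map_snp_to_loops(
    tibble::tibble(snp_id = "s0", chrom = "chrT", pos = 300), genes, loops0
  )
  expect_equal(hit0$gene_id, "g1")
  # either orientation works
  flipped <- loops[, c("loop_id", "chromB", "startB", "endB", "chromA", "startA", "endA")]
  names(flipped) <- c("loop_id", "chromA", "startA", "endA", "chromB", "startB", "endB")
  expect_equal(nrow(map_snp_to_loops(snps[1, ], genes, flipped)), 1)
})

test_that("CSL/OL/NSL classification is exclusive and exhaustive", {
  loops <- tibble::tibble(
    loop_id = c("all", "one", "none"),
    chromA = "chrT", startA = c(0, 1000, 2000), endA = c(100, 1100, 2100),
    chromB = "chrT", startB = c(5000, 6000, 7000), endB = c(5100, 6100, 7100)
  )
  snps <- tibble::tibble(
    chrom = "chrT",
    pos = c(50, 5050, 50, 1050),
    tissue = c("t1", "t2", "t3", "t1")
  )
  cls <- classify_loop_cancer_status(loops, snps, tissues = c("t1", "t2", "t3"))
  expect_equal(cls$cancer_class, c("CSL", "OL", "NSL"))
  expect_true(all(cls$cancer_class %in% c("CSL", "OL", "NSL")))
  expect_error(classify_loop_cancer_status(loops, snps, tissues = character()), "nonempty")
})

test_that("E-P classification has priority over CTCF", {
  loops <- tibble::tibble(
    loop_id = c("ep", "ctcf", "other"),
    chromA = "chrT", startA = c(0, 1000, 2000), endA = c(100, 1100, 2100),
    chromB = "chrT", startB = c(5000, 6000, 7000), endB = c(5100, 6100, 7100)
  )
  enhancers <- tibble::tibble(chrom = "chrT", start = 0, end = 100)
  promoters <- tibble::tibble(chrom = "chrT", start = 5000, end = 5100)
  ctcf <- tibble::tibble(chrom = "chrT", start = c(0, 6000), end = c(100, 6100))
  cls <- classify_loop_type(loops, ctcf, enhancers, promoters)
  # the EP loop's anchor also overlaps a CTCF peak: EP wins
  expect_equal(cls$loop_type, c("EP", "CTCF", "other"))
})

test_that("SNPs are coding inside CDS or within 10 bp of a splice site", {
  genes <- tibble::tibble(
    gene_id = "g", chrom = "chrT", start = 0, end = 1000, strand = "+",
    cds = list(cbind(start = 100, end = 200)),
    splice_sites = list(c(200, 300))
  )
  snps <- tibble::tibble(
    snp_id = c("in_cds", "at_10bp", "at_11bp"),
    chrom = "chrT", pos = c(150, 310, 311)
  )
  ann <- annotate_snp_coding(snps, genes)
  expect_equal(ann$annotation, c("coding", "coding", "noncoding"))
})
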