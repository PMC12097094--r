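# End-to-end pipeline: simulate -> flexible IF -> layer disruption ->
# expression change -> decay fit -> scoring -> ranking evaluation.
# Every stage writes a TSV (with a version/config-hash header comment) and
# a JSON run log; outputs are deterministic functions of the config.

pkg_version <- function() as.character(utils::packageVersion("threedfunc"))

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the simulation.
#' @param t_strong Strong-interaction threshold for fusion IF categories
#'   (in `(0, 1]`).
#' @param high_score High-score threshold on the 3DFunc score scale
#'   (default 0.9).
#' @param score_filter Filtering threshold used for reporting candidate
#'   pairs (default 0.5).
#' @param p_cutoff Significance cutoff (default 0.05).
#' @param strict_extension,aggregate Passed to [flexible_if()].
#' @param sim Named list of [sim_config()] overrides.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, t_strong = 0.5, high_score = 0.9,
                       score_filter = 0.5, p_cutoff = 0.05,
                       strict_extension = FALSE, aggregate = "sum",
                       sim = list()) {
  if (t_strong <= 0 || t_strong > 1) abort("t_strong must be in (0, 1]")
  if (high_score < 0) abort("high_score must be non-negative")
  if (p_cutoff <= 0 || p_cutoff > 1) abort("p_cutoff must be in (0, 1]")
  if (!aggregate %in% c("sum", "mean")) abort("aggregate must be 'sum' or 'mean'")
  unknown <- setdiff(names(sim), names(formals(sim_config)))
  if (length(unknown)) abort(paste0("unknown sim_config key: ", unknown[1]))
  structure(
    list(
      out_dir = out_dir, seed = seed, t_strong = t_strong,
      high_score = high_score, score_filter = score_filter,
      p_cutoff = p_cutoff, strict_extension = strict_extension,
      aggregate = aggregate, sim = sim
    ),
    class = "run_config"
  )
}

# hash of everything that determines the outputs (the output location and
# the input file paths do not)
config_hash <- function(config) {
  x <- unclass(config)
  rlang::hash(x[setdiff(names(x), "out_dir")])
}

write_stage_tsv <- function(tb, path, hash) {
  out <- tb
  for (cl in names(out)) {
    if (is.list(out[[cl]])) {
      out[[cl]] <- vapply(out[[cl]], function(x) paste(x, collapse = ";"), "")
    }
  }
  writeLines(sprintf("# threedfunc %s config=%s", pkg_version(), hash), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

write_run_log <- function(dir, stage, params, inputs = character()) {
  ck <- tools::md5sum(inputs)
  names(ck) <- basename(inputs)
  log <- list(
    tool = "threedfunc", version = pkg_version(), stage = stage,
    parameters = params,
    input_checksums = as.list(ck)
  )
  path <- file.path(dir, paste0(stage, ".log.json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the full synthetic fixture tree
#'
#' Materializes a simulation (contact store, compartment/TAD/loop tracks,
#' variant TSVs, annotation BEDs, expression matrix, truth tables) under
#' `dir`, in the plain-text formats the readers consume.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a named list of file paths plus the in-memory
#'   objects (`store`, `expr`, `truth`).
#' @export
write_simulation <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  store <- gen_hic(config)
  expr <- gen_expression(config)
  truth <- gen_variant_truth(config)
  p <- list()
  p$manifest <- write_contact_store(store, file.path(dir, "hic"))

  wt <- function(tb, name) {
    out <- tb
    for (cl in names(out)) {
      if (is.list(out[[cl]])) out[[cl]] <- vapply(out[[cl]], paste, "", collapse = ";")
    }
    path <- file.path(dir, name)
    readr::write_tsv(out, path, progress = FALSE)
    path
  }
  svs <- bind_rows(
    truth$comp_svs %>% mutate(layer = "compartment"),
    truth$tad_svs %>% mutate(layer = "TAD")
  )
  p$svs <- wt(svs %>% select("sv_id", "chrom", "start", "end", "sv_type", "frequency"), "svs.tsv")
  p$sv_truth <- wt(svs %>% select("sv_id", "layer", "truth"), "sv_truth.tsv")
  icts_out <- truth$icts %>% mutate(posA = .data$posA + 1, posB = .data$posB + 1) # 1-based on disk
  p$icts <- wt(icts_out %>% select("chromA", "posA", "chromB", "posB", "geneA", "geneB", "source"), "icts.tsv")
  snps_out <- truth$snps %>% mutate(pos = .data$pos + 1)
  p$snps <- wt(snps_out %>% select("snp_id", "chrom", "pos", "ref", "alt"), "snps.tsv")
  p$genes <- wt(truth$genes, "genes.tsv")
  p$snp_pair_truth <- wt(truth$snp_pair_truth, "snp_pair_truth.tsv")
  p$score_pairs <- wt(truth$score_pairs, "score_pairs.tsv")
  p$compartments <- write_bed(
    truth$track %>% select("chrom", "start", "end", "label", "eigen"),
    file.path(dir, "compartments.bed")
  )
  p$domains <- write_bed(truth$domains, file.path(dir, "tads.bed"))
  p$boundaries <- write_bed(truth$boundaries, file.path(dir, "boundaries.bed"))
  loops_out <- truth$loops %>% mutate(tags = "t1;t2;t3")
  p$loops <- write_bedpe(
    loops_out %>% select("chromA", "startA", "endA", "chromB", "startB", "endB", "tags"),
    file.path(dir, "loops.bedpe")
  )
  # annotation tracks derived from the planted loop anchors: A anchors are
  # enhancer-like, B anchors promoter-like (they hold the paired genes)
  p$enhancers <- write_bed(
    truth$loops %>% transmute(chrom = .data$chromA, start = .data$startA, end = .data$endA),
    file.path(dir, "enhancers.bed")
  )
  p$promoters <- write_bed(
    truth$loops %>% transmute(chrom = .data$chromB, start = .data$startB, end = .data$endB),
    file.path(dir, "promoters.bed")
  )
  p$ctcf <- write_bed(
    truth$loops %>% transmute(chrom = .data$chromA, start = .data$startA, end = .data$endA),
    file.path(dir, "ctcf.bed")
  )
  # cancer SNPs: the planted in-anchor SNPs, tagged in all three tissues
  cancer_snps <- truth$snps %>%
    filter(startsWith(.data$snp_id, "S_")) %>%
    tidyr::crossing(tissue = c("t1", "t2", "t3")) %>%
    select("snp_id", "chrom", "pos", "tissue")
  p$cancer_snps <- wt(cancer_snps, "cancer_snps.tsv")
  p$expression <- wt(expr$expression, "expression.tsv")
  p$metadata <- wt(expr$metadata, "sample_metadata.tsv")
  p$expr_truth <- wt(expr$truth, "expression_truth.tsv")
  invisible(list(paths = p, store = store, expr = expr, truth = truth))
}

#' Run the full pipeline on a self-generated fixture
#'
#' Stages run in order: `simulate` (fixture tree), `flexif` (flexible IF of
#' the merged fusion pairs and a virtual-4C profile of the first planted
#' loop), `layers` (SV filtering, compartment and TAD disruption calls,
#' SNP-loop mapping, loop cancer-status and type classification), `ec`
#' (expression change for every gene), `fit` (EC~IC decay), `score`
#' (3DFunc scores + significance), `evaluate` (ranking metrics against the
#' planted causal truth). Each stage emits a TSV with a version/config-hash
#' header and a JSON run log; rerunning with the same config reproduces
#' every output byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list with the stage result tibbles and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hash <- config_hash(config)

  # -- simulate
  simc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  fixture_dir <- file.path(dir, "fixture")
  sim <- write_simulation(simc, fixture_dir)
  write_run_log(dir, "simulate", list(seed = config$seed, config_hash = hash),
    inputs = character()
  )
  store <- sim$store
  truth <- sim$truth

  # -- flexif: merged fusion pairs queried at their first breakpoints
  icts <- read_icts(file.path(fixture_dir, "icts.tsv"))
  fusions <- merge_fusion_pairs(icts)
  first_bp <- icts %>%
    mutate(gene1 = pmin(toupper(.data$geneA), toupper(.data$geneB)),
           gene2 = pmax(toupper(.data$geneA), toupper(.data$geneB))) %>%
    group_by(.data$gene1, .data$gene2) %>%
    slice(1) %>%
    ungroup()
  half <- min(store$resolutions)
  fus_pairs <- first_bp %>% transmute(
    gene1 = .data$gene1, gene2 = .data$gene2,
    chromA = .data$chromA, startA = pmax(0, .data$posA - half), endA = .data$posA + half,
    chromB = .data$chromB, startB = pmax(0, .data$posB - half), endB = .data$posB + half
  )
  flexif_tb <- flexible_if_pairs(store, fus_pairs,
    strict_extension = config$strict_extension, aggregate = config$aggregate
  ) %>%
    left_join(fusions, by = c("gene1", "gene2")) %>%
    mutate(if_category = purrr::map_chr(.data$flexible_if, categorize_fusion_if,
      t_strong = config$t_strong
    ))
  write_stage_tsv(flexif_tb, file.path(dir, "flexif.tsv"), hash)
  v4c <- virtual_4c(
    store,
    region(truth$loops$chromA[1], truth$loops$startA[1], truth$loops$endA[1]),
    min(store$resolutions)
  )
  write_bedgraph(v4c, file.path(dir, "virtual4c.bedgraph"))
  write_run_log(dir, "flexif",
    list(
      t_strong = config$t_strong, strict_extension = config$strict_extension,
      aggregate = config$aggregate, config_hash = hash
    ),
    inputs = c(file.path(fixture_dir, "icts.tsv"), sim$paths$manifest)
  )

  # -- layers
  svs <- read_svs(file.path(fixture_dir, "svs.tsv"))
  svs_kept <- filter_svs(svs)
  track <- read_compartments(file.path(fixture_dir, "compartments.bed"))
  domains <- read_regions(file.path(fixture_dir, "tads.bed"), "bed")
  boundaries <- read_regions(file.path(fixture_dir, "boundaries.bed"), "bed")
  comp_calls <- classify_compartment_disruption(svs_kept, track) %>%
    mutate(layer = "compartment")
  tad_calls <- classify_tad_disruption(svs_kept, domains, boundaries) %>%
    mutate(layer = "TAD")
  snps <- read_snps(file.path(fixture_dir, "snps.tsv"), "tsv")
  genes <- read_regions(file.path(fixture_dir, "genes.tsv"), "tsv")
  loops <- read_loops(file.path(fixture_dir, "loops.bedpe"))
  snp_loops <- map_snp_to_loops(snps, genes, loops)
  cancer_snps <- readr::read_tsv(file.path(fixture_dir, "cancer_snps.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  loops_cls <- loops %>%
    classify_loop_cancer_status(cancer_snps, tissues = c("t1", "t2", "t3")) %>%
    classify_loop_type(
      read_regions(file.path(fixture_dir, "ctcf.bed"), "bed"),
      read_regions(file.path(fixture_dir, "enhancers.bed"), "bed"),
      read_regions(file.path(fixture_dir, "promoters.bed"), "bed")
    )
  calls <- bind_rows(
    comp_calls %>% select("sv_id", "layer", "category"),
    tad_calls %>% select("sv_id", "layer", "category")
  )
  write_stage_tsv(calls, file.path(dir, "disruption_calls.tsv"), hash)
  write_stage_tsv(snp_loops, file.path(dir, "snp_loop_pairs.tsv"), hash)
  write_stage_tsv(
    loops_cls %>% select("loop_id", "n_tissues_hit", "cancer_class", "loop_type"),
    file.path(dir, "loop_classes.tsv"), hash
  )
  write_run_log(dir, "layers", list(config_hash = hash),
    inputs = unlist(sim$paths[c("svs", "compartments", "domains", "boundaries", "snps", "loops")])
  )

  # -- ec
  expr <- read_expression(file.path(fixture_dir, "expression.tsv"))
  meta <- read_sample_metadata(file.path(fixture_dir, "sample_metadata.tsv"))
  ec_tb <- expression_change(
    expr,
    meta$sample_id[meta$condition == "cancer"],
    meta$sample_id[meta$condition == "normal"]
  )
  write_stage_tsv(ec_tb, file.path(dir, "ec.tsv"), hash)
  write_run_log(dir, "ec", list(config_hash = hash),
    inputs = unlist(sim$paths[c("expression", "metadata")])
  )

  # -- fit / score / evaluate on the variant-gene pair set
  pairs <- truth$score_pairs
  fit <- fit_ec_ic(pairs)
  write_stage_tsv(glance(fit), file.path(dir, "fit.tsv"), hash)
  scored <- score_pairs(fit, pairs, force = TRUE) %>% score_significance(fit)
  scored <- scored %>% mutate(
    high_score = .data$score >= config$high_score & .data$p_value < config$p_cutoff,
    candidate = .data$score > config$score_filter & .data$p_value < config$p_cutoff
  )
  write_stage_tsv(scored, file.path(dir, "scored.tsv"), hash)
  metrics <- evaluate_ranking(scored, pairs$causal)
  write_stage_tsv(metrics, file.path(dir, "evaluate.tsv"), hash)
  write_run_log(dir, "score",
    list(
      high_score = config$high_score, score_filter = config$score_filter,
      p_cutoff = config$p_cutoff, config_hash = hash
    ),
    inputs = unlist(sim$paths["score_pairs"])
  )

  invisible(list(
    out_dir = dir, flexif = flexif_tb, calls = calls, snp_loops = snp_loops,
    loop_classes = loops_cls, ec = ec_tb, fit = fit, scored = scored,
    metrics = metrics
  ))
}
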