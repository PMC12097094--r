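# Readers and writers for the standard interval/variant/expression formats.
# Everything is converted to 0-based half-open coordinates on the way in and
# back to the source convention on the way out. Chromosome names pass through
# verbatim. All readers accept gzip (readr decompresses transparently).

read_table_raw <- function(path, col_names = FALSE) {
  readr::read_tsv(path,
    col_names = col_names, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

# hard error naming the offending (1-based, comment lines excluded) line
check_numeric_cols <- function(tb, cols, path, offset = 0L) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(tb[[cl]]))
    bad <- which(is.na(v) & !is.na(tb[[cl]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "unparseable line %d in %s: field '%s' = '%s' is not numeric",
        bad[1] + offset, path, cl, tb[[cl]][bad[1]]
      ))
    }
    tb[[cl]] <- v
  }
  tb
}

#' Read genomic intervals from BED, BEDPE or headered TSV
#'
#' @param path Path to a (optionally gzipped) interval file.
#' @param format `"bed"` (3+ columns, already 0-based half-open), `"bedpe"`
#'   (6+ columns, two regions per line, kept in file order as
#'   `chromA/startA/endA/chromB/startB/endB`), or `"tsv"` (header row with at
#'   least `chrom`, `start`, `end`; coordinates taken as 0-based half-open).
#' @return A tibble of regions (plus any extra columns, named `X4`, `X5`, ...
#'   for BED/BEDPE), input order preserved.
#' @export
read_regions <- function(path, format = c("bed", "bedpe", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tb <- read_table_raw(path, col_names = TRUE)
    check_regions(tb, paste0("TSV file ", path))
    tb <- check_numeric_cols(tb, c("start", "end"), path, offset = 1L)
    return(as_tibble(tb))
  }
  tb <- read_table_raw(path)
  if (format == "bed") {
    if (ncol(tb) < 3) abort(sprintf("BED file %s has fewer than 3 columns", path))
    names(tb)[1:3] <- c("chrom", "start", "end")
    tb <- check_numeric_cols(tb, c("start", "end"), path)
  } else {
    if (ncol(tb) < 6) abort(sprintf("BEDPE file %s has fewer than 6 columns", path))
    names(tb)[1:6] <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
    tb <- check_numeric_cols(tb, c("startA", "endA", "startB", "endB"), path)
  }
  as_tibble(tb)
}

#' Write regions to BED / region pairs to BEDPE
#'
#' Coordinates are written back unchanged (BED is natively 0-based half-open),
#' so `write_bed(read_regions(p, "bed"), p2)` round-trips bit-exactly.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, extra columns kept).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  check_regions(regions)
  out <- regions
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param pairs Tibble with `chromA/startA/endA/chromB/startB/endB` (+ extras).
#' @export
write_bedpe <- function(pairs, path) {
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  if (!all(need %in% names(pairs))) abort("BEDPE needs chromA/startA/endA/chromB/startB/endB")
  out <- pairs
  for (cl in need[c(2, 3, 5, 6)]) {
    out[[cl]] <- format(out[[cl]], scientific = FALSE, trim = TRUE)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read SNP records from VCF (sites) or TSV
#'
#' Positions are 1-based in both source dialects and are stored 0-based.
#' A `tissues` column (semicolon-separated tags in TSV, `TISSUES=` key in the
#' VCF INFO field) is split into a list-column of character vectors.
#'
#' @param path VCF (`##` headers skipped) or TSV with header
#'   `chrom, pos, ref, alt[, tissues][, is_cancer_related]`.
#' @param format `"vcf"` or `"tsv"`.
#' @return Tibble: `snp_id`, `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `tissues` (list-column), `is_cancer_related`.
#' @export
read_snps <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    lines <- readr::read_lines(path, progress = FALSE)
    body <- lines[!startsWith(lines, "#")]
    if (length(body) == 0) abort(sprintf("VCF %s has no variant lines", path))
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 5)) {
      abort(sprintf("unparseable line %d in %s: fewer than 5 VCF fields", which(nf < 5)[1], path))
    }
    tb <- tibble(
      chrom = vapply(fields, `[[`, "", 1),
      pos = vapply(fields, `[[`, "", 2),
      snp_id = vapply(fields, `[[`, "", 3),
      ref = vapply(fields, `[[`, "", 4),
      alt = vapply(fields, `[[`, "", 5),
      info = vapply(fields, function(f) if (length(f) >= 8) f[8] else ".", "")
    )
    tb <- check_numeric_cols(tb, "pos", path)
    tiss <- stringr::str_match(tb$info, "TISSUES=([^;]+)")[, 2]
    tb$tissues <- lapply(tiss, function(x) if (is.na(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]])
    tb$is_cancer_related <- grepl("CANCER", tb$info, fixed = TRUE)
    tb$info <- NULL
  } else {
    tb <- read_table_raw(path, col_names = TRUE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tb))) abort("SNP TSV needs columns chrom, pos, ref, alt")
    tb <- check_numeric_cols(tb, "pos", path, offset = 1L)
    if (!"snp_id" %in% names(tb)) tb$snp_id <- paste0("snp", seq_len(nrow(tb)))
    tb$tissues <- if ("tissues" %in% names(tb)) {
      lapply(tb$tissues, function(x) if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]])
    } else {
      rep(list(character()), nrow(tb))
    }
    tb$is_cancer_related <- if ("is_cancer_related" %in% names(tb)) {
      as.logical(tb$is_cancer_related)
    } else {
      FALSE
    }
  }
  if (any(tb$pos < 1)) abort("SNP positions must be >= 1 (1-based input)")
  if (any(!nzchar(tb$ref)) || any(!nzchar(tb$alt))) abort("SNP alleles must be nonempty")
  tb$pos <- tb$pos - 1 # store 0-based
  select(tb, "snp_id", "chrom", "pos", "ref", "alt", "tissues", "is_cancer_related")
}

#' Read interchromosomal translocation (ICT) records
#'
#' TSV with header `chromA, posA, chromB, posB, geneA, geneB[, source]`;
#' positions are 1-based single-base breakpoints, stored as 0-based
#' point-like regions. Intrachromosomal rows are rejected (an ICT joins two
#' different chromosomes by definition).
#'
#' @param path TSV path.
#' @return Tibble: `ict_id`, `chromA`, `posA`, `chromB`, `posB`, `geneA`,
#'   `geneB`, `source` (positions 0-based).
#' @export
read_icts <- function(path) {
  tb <- read_table_raw(path, col_names = TRUE)
  need <- c("chromA", "posA", "chromB", "posB", "geneA", "geneB")
  if (!all(need %in% names(tb))) abort("ICT TSV needs chromA, posA, chromB, posB, geneA, geneB")
  tb <- check_numeric_cols(tb, c("posA", "posB"), path, offset = 1L)
  if (any(tb$chromA == tb$chromB)) {
    abort(sprintf(
      "line %d in %s: ICT breakpoints on the same chromosome (%s)",
      which(tb$chromA == tb$chromB)[1] + 1L, path, tb$chromA[which(tb$chromA == tb$chromB)[1]]
    ))
  }
  if (!"source" %in% names(tb)) tb$source <- NA_character_
  tb$posA <- tb$posA - 1
  tb$posB <- tb$posB - 1
  tb$ict_id <- paste0("ict", seq_len(nrow(tb)))
  select(tb, "ict_id", "chromA", "posA", "chromB", "posB", "geneA", "geneB", "source")
}

#' Read structural-variant (SV) records
#'
#' TSV with header `chrom, start, end, sv_type, frequency`; coordinates are
#' 0-based half-open (the two breakpoints are `start` and `end`), frequency a
#' population fraction in `[0, 1]`.
#'
#' @param path TSV path.
#' @return Tibble: `sv_id`, `chrom`, `start`, `end`, `sv_type`, `frequency`.
#' @export
read_svs <- function(path) {
  tb <- read_table_raw(path, col_names = TRUE)
  need <- c("chrom", "start", "end", "sv_type", "frequency")
  if (!all(need %in% names(tb))) abort("SV TSV needs chrom, start, end, sv_type, frequency")
  tb <- check_numeric_cols(tb, c("start", "end", "frequency"), path, offset = 1L)
  if (any(tb$end <= tb$start)) abort("SV end must be > start")
  if (any(tb$frequency < 0 | tb$frequency > 1)) abort("SV frequency must be in [0, 1]")
  if (!"sv_id" %in% names(tb)) tb$sv_id <- paste0("sv", seq_len(nrow(tb)))
  select(tb, "sv_id", "chrom", "start", "end", "sv_type", "frequency")
}

#' Read gene models from BED12 or TSV
#'
#' Gene models carry the fields the coding/noncoding SNP annotation and the
#' loop mapping need: the gene span, CDS intervals and splice-site
#' coordinates (exon-intron junctions).
#'
#' For BED12, exons come from the block fields, CDS intervals are exons
#' intersected with `[thickStart, thickEnd)`, and splice sites are the
#' internal exon boundaries. For TSV, the header is
#' `gene_id, chrom, start, end, strand, cds, splice_sites` with `cds` a
#' comma-separated list of `start-end` pairs (0-based half-open) and
#' `splice_sites` a comma-separated list of positions; both may be empty.
#'
#' @param path File path.
#' @param format `"bed12"` or `"tsv"`.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cds` (list-column of two-column matrices), `splice_sites` (list-column
#'   of numeric vectors).
#' @export
read_gene_models <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (format == "bed12") {
    tb <- read_table_raw(path)
    if (ncol(tb) < 12) abort(sprintf("BED12 file %s has fewer than 12 columns", path))
    names(tb)[1:12] <- c(
      "chrom", "start", "end", "gene_id", "score", "strand",
      "thickStart", "thickEnd", "rgb", "blockCount", "blockSizes", "blockStarts"
    )
    tb <- check_numeric_cols(tb, c("start", "end", "thickStart", "thickEnd", "blockCount"), path)
    models <- purrr::pmap(
      list(tb$start, tb$thickStart, tb$thickEnd, tb$blockSizes, tb$blockStarts),
      function(start, ts, te, sizes, offs) {
        sz <- as.numeric(strsplit(sizes, ",")[[1]])
        of <- as.numeric(strsplit(offs, ",")[[1]])
        ex_s <- start + of
        ex_e <- ex_s + sz
        cds_s <- pmax(ex_s, ts)
        cds_e <- pmin(ex_e, te)
        keep <- cds_e > cds_s
        n <- length(ex_s)
        splice <- if (n > 1) sort(c(ex_e[-n], ex_s[-1])) else numeric()
        list(cds = cbind(start = cds_s[keep], end = cds_e[keep]), splice = splice)
      }
    )
    return(tibble(
      gene_id = tb$gene_id, chrom = tb$chrom, start = tb$start, end = tb$end,
      strand = tb$strand,
      cds = purrr::map(models, "cds"),
      splice_sites = purrr::map(models, "splice")
    ))
  }
  tb <- read_table_raw(path, col_names = TRUE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tb))) abort("gene TSV needs gene_id, chrom, start, end, strand")
  tb <- check_numeric_cols(tb, c("start", "end"), path, offset = 1L)
  parse_iv <- function(x) {
    if (is.na(x) || !nzchar(x)) {
      return(cbind(start = numeric(), end = numeric()))
    }
    parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    cbind(
      start = vapply(parts, function(p) as.numeric(p[1]), 0),
      end = vapply(parts, function(p) as.numeric(p[2]), 0)
    )
  }
  cds_raw <- if ("cds" %in% names(tb)) tb$cds else rep(NA_character_, nrow(tb))
  sp_raw <- if ("splice_sites" %in% names(tb)) tb$splice_sites else rep(NA_character_, nrow(tb))
  tibble(
    gene_id = tb$gene_id, chrom = tb$chrom, start = tb$start, end = tb$end,
    strand = tb$strand,
    cds = lapply(cds_raw, parse_iv),
    splice_sites = lapply(sp_raw, function(x) {
      if (is.na(x) || !nzchar(x)) numeric() else as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
    })
  )
}

#' Read chromatin loops from BEDPE
#'
#' Columns 1-6 are the two anchors; column 7, when present, carries
#' semicolon-separated tissue tags.
#'
#' @param path BEDPE path.
#' @return Tibble: `loop_id`, anchors (`chromA/startA/endA/chromB/startB/endB`),
#'   `tissues` list-column.
#' @export
read_loops <- function(path) {
  tb <- read_regions(path, "bedpe")
  tb$tissues <- if (ncol(tb) >= 7 && "X7" %in% names(tb)) {
    lapply(tb$X7, function(x) if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]])
  } else {
    rep(list(character()), nrow(tb))
  }
  tb$loop_id <- paste0("loop", seq_len(nrow(tb)))
  select(tb, "loop_id", "chromA", "startA", "endA", "chromB", "startB", "endB", "tissues")
}

#' Read an A/B compartment track from BED
#'
#' Column 4 is the compartment label (`A`/`B`) or a signed eigenvalue
#' (positive = A, negative = B); column 5, when present and column 4 is a
#' label, is the eigenvalue. Label and eigenvalue sign must agree.
#'
#' @param path BED path.
#' @return Tibble: `chrom`, `start`, `end`, `label`, `eigen` (NA if absent).
#' @export
read_compartments <- function(path) {
  tb <- read_regions(path, "bed")
  if (!"X4" %in% names(tb)) abort(sprintf("compartment BED %s needs a 4th (label/eigen) column", path))
  v4 <- tb$X4
  num4 <- suppressWarnings(as.numeric(v4))
  if (all(!is.na(num4))) {
    tb$eigen <- num4
    tb$label <- ifelse(num4 >= 0, "A", "B")
  } else {
    if (!all(v4 %in% c("A", "B"))) abort(sprintf("compartment labels in %s must be A or B", path))
    tb$label <- v4
    tb$eigen <- if ("X5" %in% names(tb)) suppressWarnings(as.numeric(tb$X5)) else NA_real_
    bad <- !is.na(tb$eigen) & ((tb$label == "A") != (tb$eigen >= 0))
    if (any(bad)) abort(sprintf("line %d in %s: label disagrees with eigenvalue sign", which(bad)[1], path))
  }
  select(tb, "chrom", "start", "end", "label", "eigen")
}

#' Read an expression matrix and its sample metadata
#'
#' @param path Gene-by-sample TSV; header row of sample ids, first column
#'   `gene_id`.
#' @param metadata_path TSV with header `sample_id, condition[, aliquot]`,
#'   `condition` in `{cancer, normal}`.
#' @return `read_expression()`: tibble with `gene_id` plus one numeric column
#'   per sample. `read_sample_metadata()`: tibble
#'   `sample_id, condition, aliquot`.
#' @export
read_expression <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tb)[1] != "gene_id") abort("expression matrix must have gene_id as first column")
  if (anyDuplicated(tb$gene_id)) abort("gene ids must be unique")
  vals <- as.matrix(tb[, -1])
  if (!is.numeric(vals) || any(is.na(vals)) || any(vals < 0)) {
    abort("expression values must be non-negative numbers")
  }
  tb
}

#' @rdname read_expression
#' @export
read_sample_metadata <- function(metadata_path) {
  tb <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "condition") %in% names(tb))) {
    abort("sample metadata needs sample_id and condition columns")
  }
  if (!all(tb$condition %in% c("cancer", "normal"))) {
    abort("condition must be 'cancer' or 'normal'")
  }
  if (!"aliquot" %in% names(tb)) tb$aliquot <- tb$sample_id
  tb
}

#' Write a virtual-4C profile as BEDGraph
#'
#' @param profile Tibble from [virtual_4c()] (`chrom`, `start`, `end`,
#'   `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  out <- profile[, c("chrom", "start", "end", "value")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
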