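# Expression normalization and the expression-change (EC) statistic.

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

#' FPKM / FPKM-UQ normalization of a count matrix
#'
#' Standard FPKM divides each count by gene length (bp) and per-sample
#' library size:
#' `FPKM = counts * 1e9 / (length * total_counts)`.
#' The upper-quartile variant (`method = "fpkm_uq"`) replaces the library
#' size with the per-sample 75th percentile of nonzero gene counts:
#' `FPKM-UQ = counts * 1e9 / (length * UQ)`. Because the upper quartile of
#' per-gene counts is orders of magnitude smaller than the library total,
#' FPKM-UQ values sit on a correspondingly larger scale; only relative
#' comparisons within a normalization are meaningful.
#'
#' @param counts Count tibble: `gene_id` column plus one numeric column per
#'   sample (raw counts).
#' @param gene_lengths Named numeric vector of gene lengths in bp (names =
#'   gene ids), or unnamed in row order.
#' @param method `"fpkm"` or `"fpkm_uq"`.
#' @return A tibble of the same shape with normalized values.
#' @export
fpkm_normalize <- function(counts, gene_lengths, method = c("fpkm", "fpkm_uq")) {
  method <- match.arg(method)
  m <- expr_matrix(counts)
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(m), names(gene_lengths))
    if (length(missing)) abort(paste0("no length for gene ", missing[1]))
    len <- gene_lengths[rownames(m)]
  } else {
    if (length(gene_lengths) != nrow(m)) abort("gene_lengths must match the gene rows")
    len <- gene_lengths
  }
  if (any(len <= 0)) abort("gene lengths must be positive")
  denom <- if (method == "fpkm") {
    colSums(m)
  } else {
    apply(m, 2, function(x) {
      nz <- x[x > 0]
      if (length(nz) == 0) 0 else as.numeric(quantile(nz, 0.75, type = 7))
    })
  }
  if (any(denom == 0)) abort("zero library size / upper quartile in some sample")
  norm <- sweep(m / len, 2, denom, "/") * 1e9
  out <- as_tibble(norm)
  bind_cols(tibble(gene_id = counts$gene_id), out)
}

welch_ec <- function(mean_c, sd_c, n_c, mean_n, sd_n, n_n) {
  se2 <- sd_c^2 / n_c + sd_n^2 / n_n
  ec <- numeric(length(mean_c))
  zero <- se2 == 0
  # degenerate: both group variances zero -> decide by the sign of the shift
  ec[zero] <- ifelse(mean_c[zero] > mean_n[zero], 1,
    ifelse(mean_c[zero] < mean_n[zero], 0, 0.5)
  )
  if (any(!zero)) {
    t_stat <- (mean_c[!zero] - mean_n[!zero]) / sqrt(se2[!zero])
    df <- se2[!zero]^2 /
      ((sd_c[!zero]^2 / n_c)^2 / (n_c - 1) + (sd_n[!zero]^2 / n_n)^2 / (n_n - 1))
    ec[!zero] <- pt(t_stat, df)
  }
  ec
}

#' Expression change between cancer and normal samples
#'
#' For each gene, computes the Welch statistic
#' `t = (mean_cancer - mean_normal) / sqrt(s_c^2/n_c + s_n^2/n_n)`
#' (sample standard deviations, `n - 1` denominator) with
#' Welch-Satterthwaite degrees of freedom, and returns the lower-tail t CDF
#' at the statistic: `EC = P(T < t)`. EC near 1 means the gene is
#' up-regulated in cancer; swapping the groups maps EC to `1 - EC`. When
#' both group variances are zero, EC is 1 or 0 by the sign of the mean
#' difference (0.5 when the means are equal).
#'
#' @param expr Expression tibble (`gene_id` + sample columns), any
#'   non-negative value kind (FPKM recommended).
#' @param cancer_samples,normal_samples Character vectors of sample column
#'   names; at least 2 each.
#' @param genes Optional subset of gene ids (default: all).
#' @return Tibble: `gene_id`, `mean_cancer`, `mean_normal`, `t`, `df`, `ec`.
#' @export
expression_change <- function(expr, cancer_samples, normal_samples, genes = NULL) {
  if (length(cancer_samples) < 2 || length(normal_samples) < 2) {
    abort("need at least 2 samples per group")
  }
  missing <- setdiff(c(cancer_samples, normal_samples), names(expr))
  if (length(missing)) abort(paste0("sample column not found: ", missing[1]))
  m <- expr_matrix(expr)
  if (!is.null(genes)) {
    bad <- setdiff(genes, rownames(m))
    if (length(bad)) abort(paste0("unknown gene: ", bad[1]))
    m <- m[genes, , drop = FALSE]
  }
  mc <- m[, cancer_samples, drop = FALSE]
  mn <- m[, normal_samples, drop = FALSE]
  n_c <- ncol(mc)
  n_n <- ncol(mn)
  mean_c <- rowMeans(mc)
  mean_n <- rowMeans(mn)
  sd_c <- apply(mc, 1, sd)
  sd_n <- apply(mn, 1, sd)
  se2 <- sd_c^2 / n_c + sd_n^2 / n_n
  t_stat <- ifelse(se2 > 0, (mean_c - mean_n) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
    se2^2 / ((sd_c^2 / n_c)^2 / (n_c - 1) + (sd_n^2 / n_n)^2 / (n_n - 1)),
    NA_real_
  )
  tibble(
    gene_id = rownames(m),
    mean_cancer = unname(mean_c), mean_normal = unname(mean_n),
    t = unname(t_stat), df = unname(df),
    ec = unname(welch_ec(mean_c, sd_c, n_c, mean_n, sd_n, n_n))
  )
}
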