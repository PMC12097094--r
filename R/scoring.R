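# The two-phase variant-gene scoring algorithm (3DFunc): pair an
# expression-change statistic (EC) with an interaction-frequency change
# (IC), fit the exponential decay EC = A * exp(-IC / tau) per cell line by
# nonlinear least squares, and score each pair by its residual from the
# fitted curve.

#' Interaction-frequency change between cancer and normal
#'
#' `IC = |C_i - N_i|`: the absolute difference between the flexible IF of a
#' variant-gene pair in a cancer cell line and in the matched normal.
#'
#' @param ci,ni Non-negative flexible IF values.
#' @return `abs(ci - ni)`, vectorized.
#' @export
if_change <- function(ci, ni) {
  if (any(ci < 0) || any(ni < 0)) abort("flexible IF values must be non-negative")
  abs(ci - ni)
}

#' Fit the exponential decay between EC and IC
#'
#' Minimizes `sum((EC - A * exp(-IC / tau))^2)` over `A in (0, 1.5]` and
#' `tau in (0, tau_max]` by bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]). The default start is `A0 = max(EC)`,
#' `tau0 = mean(IC)`. `tau_max` caps the decay constant so the degenerate
#' flat-curve case (EC uncorrelated with IC) stays finite; a fit that runs
#' into the cap is flagged non-converged.
#'
#' @param pairs Tibble with columns `ec` and `ic` (one row per variant-gene
#'   pair in one cell line); at least 3 rows and at least 2 distinct IC
#'   values.
#' @param init Optional `c(A0, tau0)` start values.
#' @param tau_max Upper bound for `tau`; default `100 * max(ic)`.
#' @return An `ecic_fit` object: fields `A`, `tau`, `rss`, `n_points`,
#'   `converged`, `residual_sd` (`sqrt(rss / (n - 2))`), `tau_max`, `data`.
#' @export
fit_ec_ic <- function(pairs, init = NULL, tau_max = NULL) {
  if (!all(c("ec", "ic") %in% names(pairs))) abort("pairs must have columns ec and ic")
  ec <- pairs$ec
  ic <- pairs$ic
  if (length(ec) < 3) abort("need at least 3 pairs to fit the decay")
  if (length(unique(ic)) < 2) abort("all IC values identical: decay unidentifiable")
  if (any(ic < 0)) abort("IC must be non-negative")
  tau_max <- tau_max %||% (100 * max(ic))
  if (is.null(init)) {
    init <- c(A0 = max(ec), tau0 = mean(ic))
    if (init[2] <= 0) init[2] <- 1
  }
  A0 <- min(max(init[1], 1e-6), 1.5)
  tau0 <- min(max(init[2], 1e-6), tau_max)
  dat <- data.frame(ec = ec, ic = ic)
  fit <- minpack.lm::nlsLM(
    ec ~ A * exp(-ic / tau),
    data = dat,
    start = list(A = A0, tau = tau0),
    lower = c(1e-9, 1e-9),
    upper = c(1.5, tau_max),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  p <- coef(fit)
  rss <- sum(resid(fit)^2)
  at_cap <- p[["tau"]] >= tau_max * (1 - 1e-6)
  converged <- fit$convInfo$isConv && !at_cap
  structure(
    list(
      A = unname(p[["A"]]), tau = unname(p[["tau"]]),
      rss = rss, n_points = length(ec),
      converged = converged,
      residual_sd = sqrt(rss / max(length(ec) - 2, 1)),
      tau_max = tau_max,
      data = as_tibble(dat)
    ),
    class = "ecic_fit"
  )
}

#' @export
print.ecic_fit <- function(x, ...) {
  cat("<ecic_fit>  EC = A * exp(-IC / tau)\n")
  cat(sprintf("  A = %.6g, tau = %.6g\n", x$A, x$tau))
  cat(sprintf(
    "  n = %d, RSS = %.6g, residual SD = %.6g, converged = %s\n",
    x$n_points, x$rss, x$residual_sd, x$converged
  ))
  invisible(x)
}

#' Predicted EC at given IC values
#' @param object An `ecic_fit`.
#' @param newdata Optional tibble with an `ic` column (default: training data).
#' @param ... Unused.
#' @return Numeric vector of `A * exp(-ic / tau)`.
#' @export
predict.ecic_fit <- function(object, newdata = NULL, ...) {
  ic <- if (is.null(newdata)) object$data$ic else newdata$ic
  object$A * exp(-ic / object$tau)
}

#' Score variant-gene pairs against the fitted decay
#'
#' The score of a pair is the absolute residual
#' `|expected_EC - EC|` where `expected_EC = A * exp(-IC / tau)` from the
#' fitted model; the signed residual (`expected - observed`) is retained so
#' over- and under-expression relative to the 3D-contact expectation can be
#' distinguished. Pairs are ranked by descending score (ties broken by
#' stable input order) and the top `ceiling(0.10 * n)` are flagged
#' `top_decile`.
#'
#' @param fit An [fit_ec_ic()] model. A non-converged model is an error
#'   unless `force = TRUE`.
#' @param pairs Tibble with `ec` and `ic` columns (extra columns carried
#'   through).
#' @param force Score with a non-converged model anyway.
#' @param top_fraction Fraction of pairs flagged as top-ranked
#'   (default 0.10).
#' @return `pairs` with `expected_ec`, `signed_residual`, `score`, `rank`,
#'   `top_decile` appended (input row order preserved).
#' @export
score_pairs <- function(fit, pairs, force = FALSE, top_fraction = 0.10) {
  if (!inherits(fit, "ecic_fit")) abort("fit must be an ecic_fit")
  if (!fit$converged && !force) {
    abort("model did not converge; pass force = TRUE to score anyway")
  }
  expected <- fit$A * exp(-pairs$ic / fit$tau)
  signed <- expected - pairs$ec
  score <- abs(signed)
  ord <- order(-score) # stable: ties keep input order
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  n_top <- ceiling(top_fraction * length(score))
  pairs %>% mutate(
    expected_ec = expected,
    signed_residual = signed,
    score = score,
    rank = rank,
    top_decile = rank <= n_top
  )
}

#' Significance of 3DFunc scores
#'
#' Standardizes each signed residual by the fit's residual standard
#' deviation and refers its square to a 1-degree-of-freedom chi-square
#' distribution: `p = P(chi2_1 > (residual / sd)^2)`, in `(0, 1]`.
#'
#' @param scored Output of [score_pairs()].
#' @param fit The [fit_ec_ic()] model used for scoring.
#' @return `scored` with a `p_value` column appended. If the residual SD is
#'   zero every p-value is 1 (with a warning).
#' @export
score_significance <- function(scored, fit) {
  if (!inherits(fit, "ecic_fit")) abort("fit must be an ecic_fit")
  if (fit$residual_sd == 0) {
    warn("residual SD is zero; all p-values set to 1")
    return(scored %>% mutate(p_value = 1))
  }
  z2 <- (scored$signed_residual / fit$residual_sd)^2
  scored %>% mutate(p_value = pchisq(z2, df = 1, lower.tail = FALSE))
}

# Mann-Whitney AUROC with midranks for score ties
auroc_rank <- function(score, label) {
  r <- rank(score, ties.method = "average")
  n_pos <- sum(label)
  n_neg <- sum(!label)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# AUPRC by step integration of the precision-recall curve, descending
# score, ties broken by stable input order
auprc_step <- function(score, label) {
  ord <- order(-score)
  lab <- label[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  precision <- tp / (tp + fp)
  recall <- tp / sum(lab)
  prev_recall <- c(0, head(recall, -1))
  sum((recall - prev_recall) * precision)
}

#' Evaluate a scored ranking against causal truth labels
#'
#' Computes the fraction of verified causal pairs within the top decile of
#' the score ranking, the AUROC (Mann-Whitney rank statistic, midranks for
#' ties) and the AUPRC (precision-recall step integration; ties broken by
#' stable input order).
#'
#' @param scored Output of [score_pairs()] (needs `score`, `rank`,
#'   `top_decile`).
#' @param causal Logical vector, one flag per row of `scored`; at least one
#'   `TRUE` and one `FALSE`.
#' @return One-row tibble: `n`, `n_causal`, `top_decile_causal_fraction`,
#'   `auroc`, `auprc`.
#' @export
evaluate_ranking <- function(scored, causal) {
  causal <- as.logical(causal)
  if (length(causal) != nrow(scored)) abort("one truth label per scored pair required")
  if (!any(causal) || all(causal)) abort("need at least one causal and one non-causal label")
  top <- scored$top_decile
  tibble(
    n = nrow(scored),
    n_causal = sum(causal),
    top_decile_causal_fraction = sum(causal & top) / sum(top),
    auroc = auroc_rank(scored$score, causal),
    auprc = auprc_step(scored$score, causal)
  )
}
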