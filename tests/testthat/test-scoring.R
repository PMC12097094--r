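curve_pairs <- function(n, A = 0.9, tau = 0.5, noise = 0, seed = NULL, ic_max = 2) {
  if (!is.null(seed)) set.seed(seed)
  ic <- seq(0, ic_max, length.out = n)
  ec <- A * exp(-ic / tau) + (if (noise > 0) rnorm(n, 0, noise) else 0)
  tibble::tibble(ic = ic, ec = ec)
}

test_that("if_change is the absolute flexible-IF difference", {
  expect_equal(if_change(0.8, 0.3), 0.5)
  expect_equal(if_change(0.3, 0.8), 0.5)
  expect_equal(if_change(0.4, 0.4), 0)
  expect_error(if_change(-0.1, 0.2), "non-negative")
})

test_that("noiseless exponential decay is recovered to 1e-6", {
  fit <- fit_ec_ic(curve_pairs(50))
  expect_true(fit$converged)
  expect_equal(fit$A, 0.9, tolerance = 1e-6)
  expect_equal(fit$tau, 0.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fit reports RSS consistent with an independent recomputation", {
  pairs <- curve_pairs(100, noise = 0.05, seed = 11)
  fit <- fit_ec_ic(pairs)
  rss <- sum((pairs$ec - fit$A * exp(-pairs$ic / fit$tau))^2)
  expect_equal(fit$rss, rss, tolerance = 1e-9)
  expect_equal(fit$residual_sd, sqrt(rss / (nrow(pairs) - 2)))
  expect_error(fit_ec_ic(pairs[1:2, ]), "at least 3")
  expect_error(
    fit_ec_ic(tibble::tibble(ic = c(1, 1, 1), ec = c(0.1, 0.2, 0.3))),
    "identical"
  )
})

test_that("flat constant EC drives tau to its cap and is flagged non-converged", {
  pairs <- tibble::tibble(ic = seq(0, 2, length.out = 30), ec = 0.4)
  fit <- fit_ec_ic(pairs)
  expect_false(fit$converged)
  expect_equal(fit$tau, fit$tau_max, tolerance = 1e-4)
  expect_equal(fit$A, 0.4, tolerance = 0.01)
  expect_error(score_pairs(fit, pairs), "force")
  scored <- score_pairs(fit, pairs, force = TRUE)
  expect_true(all(scored$score < 0.01))
})

test_that("scores are absolute residuals with stable descending ranks", {
  fit <- fit_ec_ic(curve_pairs(20))
  pairs <- tibble::tibble(ic = c(0, 0.5, 1), ec = NA_real_)
  pairs$ec <- c(0.9, fit$A * exp(-0.5 / fit$tau) - 0.5, fit$A * exp(-1 / fit$tau))
  scored <- score_pairs(fit, pairs)
  expect_equal(scored$score[1], 0, tolerance = 1e-6) # on the curve
  expect_equal(scored$score[2], 0.5, tolerance = 1e-6)
  expect_equal(scored$signed_residual[2], 0.5, tolerance = 1e-6) # expected - observed
  expect_equal(sort(scored$rank), 1:3)
  expect_equal(scored$rank[2], 1)
  # invariant to input order; ranks are a permutation
  perm <- c(3, 1, 2)
  scored_perm <- score_pairs(fit, pairs[perm, ])
  expect_equal(scored_perm$score, scored$score[perm])
  # idempotent and side-effect free
  expect_equal(score_pairs(fit, pairs), scored)
})

test_that("top-decile flag covers ceil(0.1 n) pairs", {
  fit <- fit_ec_ic(curve_pairs(20))
  pairs <- curve_pairs(10)
  pairs$ec[4] <- pairs$ec[4] + 0.4
  scored <- score_pairs(fit, pairs)
  expect_equal(sum(scored$top_decile), 1) # ceiling(0.1 * 10)
  expect_true(scored$top_decile[4])
})

test_that("chi-square significance maps standardized residuals to upper-tail p", {
  pairs <- curve_pairs(100, noise = 0.05, seed = 3)
  fit <- fit_ec_ic(pairs)
  scored <- score_significance(score_pairs(fit, pairs), fit)
  expect_true(all(scored$p_value > 0 & scored$p_value <= 1))
  # z^2 = qchisq(0.95, 1) = 3.841 -> p = 0.05
  z <- sqrt(qchisq(0.95, 1))
  fake <- scored[1, ]
  fake$signed_residual <- z * fit$residual_sd
  expect_equal(score_significance(fake, fit)$p_value, 0.05, tolerance = 1e-9)
  # monotone: larger |residual| -> smaller p
  ord <- order(abs(scored$signed_residual))
  expect_true(all(diff(scored$p_value[ord]) <= 1e-12))
  # residual exactly 0 -> p = 1
  fake$signed_residual <- 0
  expect_equal(score_significance(fake, fit)$p_value, 1)
})

test_that("ranking metrics behave at the extremes and match pROC", {
  scored <- tibble::tibble(
    ic = 0, ec = 0,
    score = c(0.9, 0.8, 0.3, 0.2, 0.1, 0.05, 0.04, 0.03, 0.02, 0.01),
    rank = 1:10, top_decile = c(TRUE, rep(FALSE, 9))
  )
  causal <- c(TRUE, rep(FALSE, 9))
  m <- evaluate_ranking(scored, causal)
  expect_equal(m$auroc, 1) # perfect separation
  expect_equal(m$top_decile_causal_fraction, 1) # 1 causal in the 1-pair bucket
  expect_equal(m$auprc, 1)
  causal2 <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  m2 <- evaluate_ranking(scored, causal2)
  skip_if_not_installed("pROC")
  want <- as.numeric(pROC::auc(pROC::roc(causal2, scored$score,
    quiet = TRUE, direction = "<"
  )))
  expect_equal(m2$auroc, want)
  expect_error(evaluate_ranking(scored, rep(TRUE, 10)), "at least one")
})

test_that("label-independent scores give AUROC near 0.5", {
  set.seed(17)
  aurocs <- replicate(50, {
    scored <- tibble::tibble(
      score = runif(200), rank = 1:200, top_decile = FALSE
    )
    evaluate_ranking(scored, sample(c(TRUE, FALSE), 200, replace = TRUE))$auroc
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.02)
})

test_that("tidy and glance expose the fitted decay parameters", {
  fit <- fit_ec_ic(curve_pairs(30))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("A", "tau"))
  gl <- generics::glance(fit)
  expect_equal(gl$A, fit$A)
  expect_true(gl$converged)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
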