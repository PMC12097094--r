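# broom-style accessors for fitted EC~IC decay models

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an EC~IC decay fit
#'
#' @param x An [fit_ec_ic()] object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.ecic_fit <- function(x, ...) {
  tibble(term = c("A", "tau"), estimate = c(x$A, x$tau))
}

#' One-row model summary of an EC~IC decay fit
#'
#' @param x An [fit_ec_ic()] object.
#' @param ... Unused.
#' @return Tibble: `A`, `tau`, `rss`, `residual_sd`, `n_points`, `converged`.
#' @exportS3Method generics::glance
glance.ecic_fit <- function(x, ...) {
  tibble(
    A = x$A, tau = x$tau, rss = x$rss,
    residual_sd = x$residual_sd, n_points = x$n_points,
    converged = x$converged
  )
}
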