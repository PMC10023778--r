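#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted rate GAM
#'
#' @param x An `fs_gam` from [fit_rate_gam()].
#' @param ... Unused.
#' @return One row per smooth term: `term`, `edf`, `statistic`, `p.value`.
#' @export
tidy.fs_gam <- function(x, ...) {
  st <- summary(x$fit)$s.table
  tibble(term = c("Month", "Year"),
         edf = st[, "edf"],
         statistic = st[, "F"],
         p.value = st[, "p-value"])
}

#' @rdname tidy.fs_gam
#' @return `glance()`: one row with `response`, `deviance_explained`,
#'   `aic`, `n`.
#' @export
glance.fs_gam <- function(x, ...) {
  tibble(response = x$response,
         deviance_explained = x$deviance_explained,
         aic = stats::AIC(x$fit),
         n = x$n)
}

#' Tidy a rank-correlation result
#'
#' @param x An `fs_cor` from [correlate_with_sst()].
#' @param ... Unused.
#' @export
tidy.fs_cor <- function(x, ...) {
  tibble(response = x$response, statistic_s = x$statistic_s, rho = x$rho,
         p.value = x$p, strength = x$strength, n = x$n)
}

#' Tidy a rank-based group test
#'
#' @param x An `fs_grouptest` from [october_contrast()].
#' @param ... Unused.
#' @export
tidy.fs_grouptest <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p.value = x$p,
         group1 = x$groups[1], group2 = x$groups[2],
         n1 = x$n[1], n2 = x$n[2], method = x$method)
}
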