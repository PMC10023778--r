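#' Seasonal/trend GAM for weekly rates
#'
#' Fits `rate ~ s(month, bs = "cc") + s(year, bs = "cr")` with a Gaussian
#' family and identity link: a cyclic cubic spline over calendar month
#' (continuous in value and derivative across the December-January wrap)
#' and a cubic regression spline over year. Month is the calendar month of
#' the ISO week's Thursday; year is the ISO year. Smoothing parameters are
#' chosen by GCV; the month basis uses k = 12 and the year basis one knot
#' per distinct year. Missing-data weeks are dropped.
#'
#' @param bins Weekly bins from [weekly_rates()] (optionally with SST).
#' @param response `"pr"` or `"dr"`.
#' @return An `fs_gam` object: the mgcv fit plus tidy per-term curves.
#'   Use [tidy()][generics::tidy()], [glance()][generics::glance()] and
#'   [autoplot()][ggplot2::autoplot()].
#' @export
fit_rate_gam <- function(bins, response = c("pr", "dr")) {
  response <- match.arg(response)
  df <- bins |>
    mutate(thursday = .data$week_start + 3 * 86400,
           month = lubridate::month(.data$thursday),
           year = lubridate::isoyear(.data$week_start),
           y = .data[[response]]) |>
    filter(!is.na(.data$y))
  if (length(unique(df$year)) < 2) {
    abort("predictor year has insufficient spread (< 2 distinct years)")
  }
  if (length(unique(df$month)) < 6) {
    abort("predictor month has insufficient spread (< 6 distinct months)")
  }
  k_year <- max(3, length(unique(df$year)))
  fit <- mgcv::gam(
    y ~ s(month, bs = "cc", k = 12) + s(year, bs = "cr", k = k_year),
    data = df, family = stats::gaussian(),
    knots = list(month = c(0.5, 12.5)), method = "GCV.Cp"
  )
  sm <- summary(fit)
  month_grid <- tibble(month = seq(0.5, 12.5, by = 0.05),
                       year = median(df$year))
  year_grid <- tibble(month = 6.5,
                      year = seq(min(df$year), max(df$year), by = 0.05))
  term_curve <- function(grid, term) {
    pr <- mgcv::predict.gam(fit, newdata = grid, type = "terms",
                            se.fit = TRUE)
    col <- grep(term, colnames(pr$fit))
    tibble(term = term, x = grid[[term]],
           estimate = pr$fit[, col],
           lower = pr$fit[, col] - 1.96 * pr$se.fit[, col],
           upper = pr$fit[, col] + 1.96 * pr$se.fit[, col])
  }
  curves <- bind_rows(term_curve(month_grid, "month"),
                      term_curve(year_grid, "year"))
  structure(list(
    fit = fit,
    response = toupper(response),
    deviance_explained = unname(sm$dev.expl),
    term_pvalues = setNames(as.numeric(sm$s.table[, "p-value"]),
                            c("Month", "Year")),
    curves = curves,
    n = nrow(df)
  ), class = "fs_gam")
}

#' @export
print.fs_gam <- function(x, ...) {
  cat("<fs_gam> ", x$response, " ~ s(month, cc) + s(year, cr); n = ", x$n,
      "; deviance explained = ", sprintf("%.1f%%", 100 * x$deviance_explained),
      "\n  p(Month) = ", format.pval(x$term_pvalues["Month"], digits = 3),
      ", p(Year) = ", format.pval(x$term_pvalues["Year"], digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Spearman correlation of a weekly rate with SST
#'
#' Non-parametric rank correlation between a weekly rate and the weekly
#' mean sea-surface temperature, with the conventional strength labels:
#' weak when `|rho| < 0.39`, strong when `|rho| > 0.60`, moderate
#' otherwise.
#'
#' @param bins Weekly bins with `sst_mean_c` (see [attach_sst()]).
#' @param response `"pr"` or `"dr"`.
#' @param min_pairs Minimum complete (rate, SST) pairs required.
#' @return An `fs_cor` list: `response`, `statistic_s` (the rank statistic
#'   S), `rho`, `p`, `strength`, `n`.
#' @export
correlate_with_sst <- function(bins, response = c("pr", "dr"),
                               min_pairs = 10) {
  response <- match.arg(response)
  x <- bins[[response]]
  y <- bins[["sst_mean_c"]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) {
    abort(sprintf("need at least %d complete (rate, SST) pairs", min_pairs))
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("all-tied input: Spearman's rho is undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  rho <- unname(ct$estimate)
  structure(list(
    response = toupper(response),
    statistic_s = unname(ct$statistic),
    rho = rho,
    p = ct$p.value,
    strength = if (abs(rho) < 0.39) "WEAK"
               else if (abs(rho) > 0.60) "STRONG" else "MODERATE",
    n = length(x)
  ), class = "fs_cor")
}

#' @export
print.fs_cor <- function(x, ...) {
  cat("<fs_cor> ", x$response, " vs SST: S = ", format(x$statistic_s),
      ", rho = ", round(x$rho, 3), " (", x$strength, "), p = ",
      format.pval(x$p, digits = 3), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Two-sample rank-sum test with a normal-approximation Z
#'
#' Wilcoxon-Mann-Whitney comparison. For small samples (both groups at
#' most 20) without ties the p-value comes from the exact distribution;
#' otherwise from the normal approximation with continuity and tie
#' correction. The Z statistic is always reported from the (tie-corrected)
#' normal approximation, signed so that Z > 0 means `x` tends larger.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List: `z`, `p`, `u` (Mann-Whitney U for `x`), `method`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(all_v)
  n <- n1 + n2
  tie_term <- sum(nt^3 - nt) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  cc <- 0.5 * sign(u - mu)
  z <- if (sigma > 0) (u - mu - cc) / sigma else 0
  has_ties <- any(nt > 1)
  if (max(n1, n2) <= 20 && !has_ties) {
    p <- stats::wilcox.test(x, y, alternative = alternative,
                            exact = TRUE)$p.value
    method <- "exact"
  } else {
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z)
    )
    method <- "normal approximation (tie/continuity corrected)"
  }
  list(z = z, p = min(1, p), u = u, method = method)
}

#' October detection-rate contrast
#'
#' Two-sided rank-sum comparison of weekly rates in October against the
#' rest of the year, reported as a Z statistic (normal approximation with
#' tie correction) with October as the first group, so Z > 0 means
#' October rates tend higher.
#'
#' @param bins Weekly bins from [weekly_rates()].
#' @param response `"dr"` (default) or `"pr"`.
#' @param min_oct,min_rest Minimum weeks required in each group.
#' @return An `fs_grouptest` list: `test`, `statistic` (Z), `p`, `groups`,
#'   `n`, `method`.
#' @export
october_contrast <- function(bins, response = c("dr", "pr"),
                             min_oct = 3, min_rest = 10) {
  response <- match.arg(response)
  df <- bins |>
    mutate(month = lubridate::month(.data$week_start + 3 * 86400)) |>
    filter(!is.na(.data[[response]]))
  oct <- df[[response]][df$month == 10]
  rest <- df[[response]][df$month != 10]
  if (length(oct) < min_oct || length(rest) < min_rest) {
    abort("not enough October (or non-October) weeks for the contrast")
  }
  rs <- rank_sum_test(oct, rest, "two.sided")
  structure(list(test = "MANN_WHITNEY", statistic = rs$z, p = rs$p,
                 groups = c("October", "rest of year"),
                 n = c(length(oct), length(rest)), method = rs$method),
            class = "fs_grouptest")
}

#' Between-season INI comparison
#'
#' Kruskal-Wallis test of INI values across singing seasons, per note
#' class, with Holm-adjusted pairwise two-sided rank-sum post-hoc
#' comparisons.
#'
#' @param ini_table Long tibble with `season`, `note_class`, `ini_s`.
#' @param min_seasons Minimum seasons required per note class.
#' @param min_inis Minimum INIs per season (seasons below are dropped).
#' @return A tibble with one row per note class: `note_class`,
#'   `chi_square`, `df`, `p`, `n_seasons`, and a `pairwise` list-column of
#'   Holm-adjusted p-value matrices.
#' @export
season_ini_test <- function(ini_table, min_seasons = 2, min_inis = 7) {
  out <- list()
  for (cls in unique(ini_table$note_class)) {
    dat <- ini_table |>
      filter(.data$note_class == cls, !is.na(.data$season)) |>
      mutate(season = factor(.data$season))
    counts <- table(dat$season)
    keep <- names(counts)[counts >= min_inis]
    dat <- dat |> filter(.data$season %in% keep) |> droplevels()
    if (length(unique(dat$season)) < min_seasons) {
      abort(sprintf("note class %s has fewer than %d seasons with >= %d INIs",
                    cls, min_seasons, min_inis))
    }
    kw <- stats::kruskal.test(dat$ini_s, dat$season)
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(dat$ini_s, dat$season,
                                  p.adjust.method = "holm", exact = FALSE)
    )
    out[[cls]] <- tibble(
      note_class = cls,
      chi_square = unname(kw$statistic),
      df = unname(kw$parameter),
      p = kw$p.value,
      n_seasons = length(unique(dat$season)),
      pairwise = list(pw$p.value)
    )
  }
  list_rbind(out)
}

#' @export
print.fs_grouptest <- function(x, ...) {
  cat("<fs_grouptest> ", x$test, ": Z = ", round(x$statistic, 3),
      ", p = ", format.pval(x$p, digits = 3), " (", x$method, "); groups ",
      paste(x$groups, collapse = " vs "), " n = ",
      paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}
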