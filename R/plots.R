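#' Plot GAM smooth terms with 95% bands
#'
#' @param object An `fs_gam` from [fit_rate_gam()].
#' @param ... Unused.
#' @return A ggplot with one panel per smooth term.
#' @export
autoplot.fs_gam <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$x, y = .data$estimate)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey70", alpha = 0.6) +
    geom_line() +
    facet_wrap(~ .data$term, scales = "free_x") +
    labs(x = NULL, y = paste0("partial effect on ", object$response),
         title = paste0(object$response,
                        " ~ s(Month, cyclic) + s(Year), Gaussian/identity")) +
    theme_minimal()
}

#' Week-by-year heat map of a weekly rate
#'
#' Missing-data weeks (no recordings) are shown as blank tiles,
#' distinguishing absence of data from absence of whales.
#'
#' @param bins Weekly bins from [weekly_rates()].
#' @param response `"pr"` or `"dr"`.
#' @return A ggplot.
#' @export
plot_weekly_rates <- function(bins, response = c("pr", "dr")) {
  response <- match.arg(response)
  ggplot(bins, aes(x = .data$iso_week, y = factor(.data$iso_year),
                   fill = .data[[response]])) +
    geom_tile(color = "white") +
    scale_fill_viridis_c(na.value = "grey95") +
    labs(x = "ISO week", y = NULL, fill = toupper(response),
         title = paste0("Weekly ", toupper(response))) +
    theme_minimal()
}

#' INI distributions per singing season
#'
#' @param ini_table Long tibble with `season`, `note_class`, `ini_s`.
#' @param binwidth Histogram bin width, seconds.
#' @return A ggplot faceted by season.
#' @export
plot_ini_seasons <- function(ini_table, binwidth = 0.5) {
  ggplot(ini_table, aes(x = .data$ini_s, fill = .data$note_class)) +
    geom_histogram(binwidth = binwidth, position = "identity", alpha = 0.7) +
    facet_wrap(~ .data$season) +
    labs(x = "inter-note interval (s)", y = "count", fill = NULL) +
    theme_minimal()
}

#' Plot weekly rate against sea-surface temperature
#'
#' @param bins Weekly bins with `sst_mean_c` (see [attach_sst()]).
#' @param response `"pr"` or `"dr"`.
#' @return A ggplot.
#' @export
plot_rate_vs_sst <- function(bins, response = c("pr", "dr")) {
  response <- match.arg(response)
  ggplot(filter(bins, !is.na(.data[[response]]), !is.na(.data$sst_mean_c)),
         aes(x = .data$sst_mean_c, y = .data[[response]])) +
    geom_point(alpha = 0.6) +
    labs(x = "weekly mean SST (°C)", y = toupper(response)) +
    theme_minimal()
}
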