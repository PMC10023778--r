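#' Segment a note stream into songs, sequences and rests
#'
#' A song is a series of note sequences with a regular inter-note interval
#' (INI), separated by rests (silent gaps clearly longer than the song's
#' typical INI). Gaps of `song_break_min` minutes or more split the stream
#' into separate songs. Within a song, a gap counts as a rest when it
#' exceeds `gap_rest_min_factor` times the song's median INI; the median
#' is estimated over the song's sub-break gaps and refined once after
#' removing provisional rests, which keeps doublet songs (alternating
#' short/long INIs) from mislabelling their long mode as a rest. INIs are
#' start-to-start differences of consecutive same-class notes within a
#' sequence; rest-spanning intervals are never INIs.
#'
#' @param notes Tibble with `abs_time` (POSIXct) and `note_class`; a single
#'   class per call (filter first, or pass `note_class` to select one).
#' @param note_class Class to segment (`"LF20"` or `"HF130"`).
#' @param gap_rest_min_factor Rest threshold as a multiple of the song's
#'   median INI.
#' @param song_break_min Gap starting a new song, minutes.
#' @return Tibble of songs with list-columns: `song_id`, `note_class`,
#'   `start_time`, `n_notes`, `n_sequences`, `onsets` (seconds from song
#'   start), `inis` (within-sequence intervals), `rests` (tibble of
#'   `start_s`, `duration_s`), `season`.
#' @examples
#' notes <- tibble::tibble(
#'   abs_time = as.POSIXct("2015-10-01", tz = "UTC") +
#'     c(0, 15, 30, 45, 77, 92, 107),
#'   note_class = "LF20"
#' )
#' segment_songs(notes)$inis[[1]]
#' @export
segment_songs <- function(notes, note_class = NULL,
                          gap_rest_min_factor = 1.5, song_break_min = 20) {
  if (!is.null(note_class)) {
    notes <- notes |> filter(.data$note_class == !!note_class)
  }
  empty <- tibble(song_id = character(), note_class = character(),
                  start_time = as.POSIXct(character(), tz = "UTC"),
                  n_notes = integer(), n_sequences = integer(),
                  onsets = list(), inis = list(), rests = list(),
                  season = character())
  if (nrow(notes) < 2) return(empty)
  if (length(unique(notes$note_class)) > 1) {
    abort("segment_songs expects a single note class; pass note_class")
  }
  notes <- notes |> arrange(.data$abs_time)
  t_s <- as.numeric(notes$abs_time)
  gaps <- diff(t_s)
  break_s <- song_break_min * 60

  song_of <- cumsum(c(1, as.integer(gaps >= break_s)))
  out <- list()
  for (sid in unique(song_of)) {
    idx <- which(song_of == sid)
    if (length(idx) < 2) next
    g <- gaps[idx[-length(idx)]]
    med0 <- median(g)
    is_rest <- g > gap_rest_min_factor * med0
    if (any(!is_rest)) {
      med1 <- median(g[!is_rest])
      is_rest <- g > gap_rest_min_factor * med1
    }
    onsets <- t_s[idx] - t_s[idx[1]]
    rest_pos <- which(is_rest)
    rests <- tibble(start_s = onsets[rest_pos], duration_s = g[rest_pos])
    st <- notes$abs_time[idx[1]]
    out[[length(out) + 1]] <- tibble(
      song_id = NA_character_,
      note_class = notes$note_class[idx[1]],
      start_time = st,
      n_notes = length(idx),
      n_sequences = length(rest_pos) + 1L,
      onsets = list(onsets),
      inis = list(g[!is_rest]),
      rests = list(rests),
      season = season_assign(st)
    )
  }
  if (length(out) == 0) return(empty)
  list_rbind(out) |>
    arrange(.data$start_time) |>
    mutate(song_id = sprintf("%s_%03d", .data$note_class, row_number()))
}

#' Select songs and INIs under the standard analysis filters
#'
#' Keeps songs with strictly more than `min_notes` notes and at least
#' `min_inis` valid (within-sequence) INIs; retains at most `max_inis`
#' INIs per song, taking the first chronologically; and enforces
#' independence by rejecting any song starting less than `independence_h`
#' hours after the previously selected song (earliest song wins, scanning
#' chronologically).
#'
#' @param songs Songs tibble from [segment_songs()].
#' @param min_notes Song must have more than this many notes (strict).
#' @param min_inis Minimum number of valid INIs.
#' @param max_inis INIs retained per song.
#' @param independence_h Minimum spacing between selected songs, hours.
#' @return The selected songs with a `selected_inis` list-column and an
#'   `n_inis_selected` count; rejected songs are dropped, with the reasons
#'   tallied in the `rejections` attribute (a tibble of `song_id`,
#'   `reason`).
#' @export
select_song_inis <- function(songs, min_notes = 10, min_inis = 7,
                             max_inis = 20, independence_h = 24) {
  if (nrow(songs) == 0) return(songs |> mutate(selected_inis = list()))
  songs <- songs |> arrange(.data$start_time)
  reasons <- list()
  keep <- logical(nrow(songs))
  sel <- vector("list", nrow(songs))
  last_sel <- as.POSIXct(NA)
  for (i in seq_len(nrow(songs))) {
    inis <- songs$inis[[i]]
    if (songs$n_notes[i] <= min_notes) {
      reasons[[songs$song_id[i]]] <- sprintf("<= %d notes", min_notes)
      next
    }
    if (length(inis) < min_inis) {
      reasons[[songs$song_id[i]]] <- sprintf("< %d valid INIs", min_inis)
      next
    }
    if (!is.na(last_sel) &&
        difftime(songs$start_time[i], last_sel, units = "hours") <
          independence_h) {
      reasons[[songs$song_id[i]]] <- sprintf("< %g h after previous selected song",
                                             independence_h)
      next
    }
    keep[i] <- TRUE
    sel[[i]] <- head(inis, max_inis)
    last_sel <- songs$start_time[i]
  }
  out <- songs[keep, ] |>
    mutate(selected_inis = sel[keep],
           n_inis_selected = lengths(sel[keep]))
  attr(out, "rejections") <- tibble(
    song_id = names(reasons),
    reason = unlist(reasons, use.names = FALSE) %||% character()
  )
  out
}

#' Classify an INI sequence as unimodal or bimodal
#'
#' Fits one- and two-component Gaussian mixtures (equal variance) and
#' declares the pattern bimodal when the two-component model wins by at
#' least `ic_margin` BIC points and the fitted modes are separated by at
#' least `min_separation_s`. A secondary `doublet` flag reports whether
#' successive INIs alternate between the modes (lag-1 sign alternation of
#' the INI differences), since field bimodal songs are typically doublets.
#'
#' @param inis Numeric INI vector (at least 7 values).
#' @param ic_margin BIC margin required to prefer two components.
#' @param min_separation_s Minimum mode separation, seconds.
#' @return A `pattern_result` list: `kind` ("UNIMODAL"/"BIMODAL"),
#'   `modes_s`, `mean_s`, `sd_s`, `n_inis`, `evidence` (BIC difference,
#'   two-component minus one-component), `doublet`.
#' @examples
#' classify_pattern(rep(c(9, 14), 10))$kind
#' @export
classify_pattern <- function(inis, ic_margin = 2, min_separation_s = 2) {
  inis <- as.numeric(inis)
  if (length(inis) < 7) abort("pattern classification needs at least 7 INIs")
  res <- function(kind, modes, evidence) {
    structure(list(kind = kind, modes_s = modes, mean_s = mean(inis),
                   sd_s = sd(inis), n_inis = length(inis),
                   evidence = evidence, doublet = doublet_flag(inis)),
              class = "pattern_result")
  }
  if (sd(inis) < 1e-9) return(res("UNIMODAL", mean(inis), -Inf))
  # Mclust() resolves mclustBIC in the caller's frame; give it a binding
  mclustBIC <- mclust::mclustBIC
  b <- suppressWarnings(
    mclust::mclustBIC(inis, G = 1:2, modelNames = "E", verbose = FALSE)
  )
  b1 <- b["1", "E"]; b2 <- b["2", "E"]
  if (is.na(b2)) return(res("UNIMODAL", mean(inis), -Inf))
  fit2 <- suppressWarnings(
    mclust::Mclust(inis, G = 2, modelNames = "E", x = b, verbose = FALSE)
  )
  modes <- sort(fit2$parameters$mean)
  sep_ok <- diff(modes) >= min_separation_s
  if (b2 - b1 >= ic_margin && sep_ok) {
    res("BIMODAL", unname(modes), unname(b2 - b1))
  } else {
    res("UNIMODAL", mean(inis), unname(b2 - b1))
  }
}

doublet_flag <- function(inis) {
  if (length(inis) < 3) return(FALSE)
  d <- diff(inis)
  s <- sign(d[abs(d) > 1e-9])
  if (length(s) < 2) return(FALSE)
  mean(s[-1] * s[-length(s)] < 0) > 0.7
}

#' @export
print.pattern_result <- function(x, ...) {
  cat("<pattern_result> ", x$kind,
      " modes=", paste(round(x$modes_s, 2), collapse = "/"),
      " mean=", round(x$mean_s, 2), " sd=", round(x$sd_s, 2),
      " n=", x$n_inis,
      if (x$doublet) " (doublet alternation)" else "", "\n", sep = "")
  invisible(x)
}

#' Classify the INI pattern of every selected song
#'
#' @param songs Songs tibble with a `selected_inis` list-column (from
#'   [select_song_inis()]).
#' @param ... Passed to [classify_pattern()].
#' @return `songs` with columns `pattern`, `mode1_s`, `mode2_s`, `mean_s`,
#'   `sd_s`, `doublet` and a `pattern_result` list-column.
#' @export
classify_songs <- function(songs, ...) {
  pr <- map(songs$selected_inis, classify_pattern, ...)
  songs |>
    mutate(
      pattern_result = pr,
      pattern = map_chr(pr, "kind"),
      mode1_s = map_dbl(pr, function(p) p$modes_s[1]),
      mode2_s = map_dbl(pr, function(p) {
        if (length(p$modes_s) > 1) p$modes_s[2] else NA_real_
      }),
      mean_s = map_dbl(pr, "mean_s"),
      sd_s = map_dbl(pr, "sd_s"),
      doublet = purrr::map_lgl(pr, "doublet")
    )
}

#' Assign a timestamp to a singing season
#'
#' The singing season runs September through April. September-December
#' map to the season starting that year (`"2015/16"` for October 2015);
#' January-April map to the season that started the previous year
#' (`"2016/17"` for April 2017); May-August are outside the singing
#' season and return `NA`.
#'
#' @param timestamp POSIXct or Date (vectorized).
#' @return Character season labels, `NA` outside the singing season.
#' @examples
#' season_assign(as.Date(c("2015-10-10", "2017-04-02", "2016-06-01")))
#' @export
season_assign <- function(timestamp) {
  m <- lubridate::month(timestamp)
  y <- lubridate::year(timestamp)
  y0 <- dplyr::case_when(m >= 9 ~ y, m <= 4 ~ y - 1, .default = NA_real_)
  ifelse(is.na(y0), NA_character_,
         sprintf("%d/%02d", y0, (y0 + 1) %% 100))
}

#' Rest-duration statistics grouped by the song's modal INI
#'
#' Pools rest durations across songs, split into a short-INI and a
#' long-INI group by the song's modal INI (the median of its selected
#' INIs) against `short_long_split_s`. Groups with no rests are omitted
#' with a notice.
#'
#' @param songs Songs tibble carrying `rests` and `selected_inis`
#'   list-columns.
#' @param short_long_split_s Modal-INI split point, seconds.
#' @return Tibble with `group` ("SHORT_INI"/"LONG_INI"), `mean_s`, `sd_s`,
#'   `n`.
#' @export
rest_statistics <- function(songs, short_long_split_s = 12) {
  if (nrow(songs) == 0) {
    return(tibble(group = character(), mean_s = numeric(),
                  sd_s = numeric(), n = integer()))
  }
  ini_col <- if ("selected_inis" %in% names(songs)) "selected_inis" else "inis"
  rows <- songs |>
    mutate(modal_ini = map_dbl(.data[[ini_col]], median),
           group = ifelse(.data$modal_ini <= short_long_split_s,
                          "SHORT_INI", "LONG_INI")) |>
    select("group", "rests") |>
    tidyr::unnest("rests")
  out <- rows |>
    summarise(mean_s = mean(.data$duration_s), sd_s = sd(.data$duration_s),
              n = n(), .by = "group") |>
    arrange(.data$group != "SHORT_INI")
  missing <- setdiff(c("SHORT_INI", "LONG_INI"), out$group)
  for (g in missing) inform(paste0("no rests in group ", g, "; row omitted"))
  out
}
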