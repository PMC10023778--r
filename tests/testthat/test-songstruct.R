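test_that("segmentation separates sequences, rests and songs", {
  # one song: sequences 0..45, 77, 92..107; the 32 s gap is a rest
  notes <- note_table(c(0, 15, 30, 45, 77, 92, 107))
  s <- segment_songs(notes)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_sequences, 2)
  expect_equal(nrow(s$rests[[1]]), 1)
  expect_equal(s$rests[[1]]$duration_s, 32)
  expect_equal(s$inis[[1]], c(15, 15, 15, 15, 15))

  # oracle: brute-force gap classification of the same instance
  gaps <- diff(c(0, 15, 30, 45, 77, 92, 107))
  expect_equal(s$inis[[1]], gaps[gaps <= 1.5 * median(gaps)])

  # two trains 25 min apart are two songs
  two <- note_table(c(seq(0, 150, 15), seq(0, 150, 15) + 150 + 25 * 60))
  expect_equal(nrow(segment_songs(two)), 2)

  # uniform onsets: one song, one sequence, zero rests
  uni <- segment_songs(note_table(seq(0, 110, 10)))
  expect_equal(uni$n_sequences, 1)
  expect_equal(nrow(uni$rests[[1]]), 0)

  # fewer than 2 notes: empty result
  expect_equal(nrow(segment_songs(note_table(5))), 0)
})

test_that("doublet songs keep their long mode out of the rests", {
  notes <- note_table(cumsum(c(0, rep(c(9, 14), 10))))
  s <- segment_songs(notes)
  expect_equal(nrow(s$rests[[1]]), 0)
  expect_length(s$inis[[1]], 20)
})

test_that("song selection applies the note, INI and independence filters", {
  base <- utc("2015-10-01 00:00:00")
  mk_song <- function(n_notes, at_h) {
    segment_songs(note_table(seq(0, by = 12, length.out = n_notes),
                             base = base + at_h * 3600))
  }
  # exactly 10 notes: rejected (strictly more than 10 required)
  s10 <- select_song_inis(mk_song(10, 0))
  expect_equal(nrow(s10), 0)
  expect_match(attr(s10, "rejections")$reason, "notes")

  # 31 notes -> 30 INIs, truncated to the first 20
  s30 <- select_song_inis(mk_song(31, 0))
  expect_equal(s30$n_inis_selected, 20)
  expect_equal(s30$selected_inis[[1]], head(s30$inis[[1]], 20))

  # two qualifying songs 12 h apart: the second is rejected
  pair <- dplyr::bind_rows(mk_song(15, 0), mk_song(15, 12))
  sel <- select_song_inis(pair)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$start_time, base)
  # 25 h apart: both kept
  pair2 <- dplyr::bind_rows(mk_song(15, 0), mk_song(15, 25))
  expect_equal(nrow(select_song_inis(pair2)), 2)
})

test_that("tightening min_notes never admits more songs", {
  set.seed(31)
  songs <- purrr::map(1:6, function(k) {
    segment_songs(note_table(cumsum(c(0, finsong:::rtruncnorm3(5 + 3 * k, 11, 1))),
                             base = utc("2015-10-01") + k * 86400 * 2))
  }) |> purrr::list_rbind()
  counts <- purrr::map_int(c(5, 10, 15, 20),
                           function(mn) nrow(select_song_inis(songs,
                                                              min_notes = mn)))
  expect_true(all(diff(counts) <= 0))
})

test_that("pattern classification separates doublet from unimodal songs", {
  set.seed(8)
  bi <- classify_pattern(rep(c(9, 14), 10) + rnorm(20, 0, 0.3))
  expect_equal(bi$kind, "BIMODAL")
  expect_equal(bi$modes_s[1], 9, tolerance = 0.5 / 9)
  expect_equal(bi$modes_s[2], 14, tolerance = 0.5 / 14)
  expect_true(bi$doublet)

  un <- classify_pattern(rnorm(20, 15.08, 0.5))
  expect_equal(un$kind, "UNIMODAL")
  expect_equal(un$mean_s, 15.08, tolerance = 0.5 / 15)
  expect_false(un$doublet)

  const <- classify_pattern(rep(12, 9))
  expect_equal(const$kind, "UNIMODAL")
  expect_equal(const$sd_s, 0)

  expect_error(classify_pattern(c(9, 14, 9)), "at least 7")
})

test_that("paired HF130 songs recover the same per-song INI mean", {
  set.seed(12)
  sp <- song_spec(ini_model("unimodal", mean_s = 10.35, sd_s = 0.65),
                  n_notes = 15, with_hf130 = TRUE,
                  start_time = utc("2018-10-03 02:00:00"))
  rs <- realize_song(sp)
  notes <- tibble::tibble(abs_time = sp$start_time + rs$notes$onset_s,
                          note_class = rs$notes$note_class)
  m_lf <- mean(segment_songs(notes, "LF20")$inis[[1]])
  m_hf <- mean(segment_songs(notes, "HF130")$inis[[1]])
  expect_lt(abs(m_lf - m_hf), 0.1)
})

test_that("season assignment maps the singing season across new year", {
  expect_equal(season_assign(as.Date("2015-10-10")), "2015/16")
  expect_equal(season_assign(as.Date("2017-04-02")), "2016/17")
  expect_true(is.na(season_assign(as.Date("2016-06-01"))))
  expect_equal(season_assign(as.Date(c("2014-09-01", "2015-01-31"))),
               c("2014/15", "2014/15"))
})

test_that("rest statistics group by the song's modal INI", {
  mk <- function(modal, rests, at_days) {
    tibble::tibble(
      song_id = paste0("s", at_days), note_class = "LF20",
      start_time = utc("2015-10-01") + at_days * 86400,
      n_notes = 15L, n_sequences = length(rests) + 1L,
      onsets = list(numeric(0)),
      inis = list(rep(modal, 10)),
      rests = list(tibble::tibble(start_s = seq_along(rests) * 50,
                                  duration_s = rests)),
      season = "2015/16",
      selected_inis = list(rep(modal, 10))
    )
  }
  songs <- dplyr::bind_rows(mk(9, c(17, 18, 18), 1), mk(15, c(30, 33), 2))
  rs <- rest_statistics(songs)
  expect_equal(rs$mean_s[rs$group == "SHORT_INI"], mean(c(17, 18, 18)))
  expect_equal(rs$n[rs$group == "SHORT_INI"], 3L)
  expect_equal(rs$mean_s[rs$group == "LONG_INI"], 31.5)

  # only short-INI songs present: single row, with a notice
  expect_message(one <- rest_statistics(mk(9, c(17, 18), 1)), "LONG_INI")
  expect_equal(one$group, "SHORT_INI")
})

test_that("selected INIs always equal onset differences within sequences", {
  # property over random songs: brute-force verification from onsets
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(12:30, 1)
    sp <- song_spec(ini_model("unimodal", mean_s = runif(1, 9, 16),
                              sd_s = runif(1, 0, 0.8),
                              rest_mean_s = 40, rest_sd_s = 1),
                    n_notes = n, n_rests = sample(0:2, 1),
                    start_time = utc("2015-11-01 00:00:00"))
    rs <- realize_song(sp)
    notes <- tibble::tibble(abs_time = sp$start_time + rs$notes$onset_s,
                            note_class = "LF20")
    seg <- segment_songs(notes)
    expect_equal(nrow(seg), 1)
    onsets <- seg$onsets[[1]]
    all_gaps <- diff(onsets)
    expect_true(all(seg$inis[[1]] %in% all_gaps))
    expect_equal(sort(seg$inis[[1]]), sort(rs$inis), tolerance = 1e-6)
  }
})
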