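#' Run the full pipeline: generate, detect, rates, songs, stats
#'
#' Executes the stages in order against a single configuration document,
#' persisting the intermediate CSVs (annotations, detections, weekly bins,
#' songs, INI table, SST) under `out_dir`, and returns a run manifest
#' recording the configuration hash, seed, per-stage row counts and
#' statuses, and the package version. A stage that cannot run (for
#' example, the statistical layer on a deployment too short for a GAM)
#' is recorded as `"skipped"` with its reason; hard failures are recorded
#' as `"failed"` and stop subsequent dependent stages.
#'
#' @param cfg Config list from [read_pipeline_config()] /
#'   [validate_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run, in pipeline order.
#' @param skip_empty_audio Skip WAV synthesis for note-free recordings.
#' @return The manifest (list, class `fs_manifest`), invisibly also
#'   written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("generate", "detect", "rates", "songs",
                                    "stats"),
                         skip_empty_audio = FALSE) {
  cfg <- validate_pipeline_config(unclass(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("finsong")),
    stages = list()
  )
  note_stage <- function(name, status, counts = list(), reason = NULL) {
    manifest$stages[[name]] <<- c(list(status = status), counts,
                                  if (!is.null(reason)) list(reason = reason))
  }

  dep <- NULL; dets <- NULL; bins <- NULL; sst <- NULL

  if ("generate" %in% stages) {
    spec <- config_to_deployment(cfg)
    dep <- synth_deployment(spec, out_dir = file.path(out_dir, "audio"),
                            skip_empty = skip_empty_audio)
    write_annotations(dep$notes, file.path(out_dir, "annotations.csv"))
    sst <- with_preserved_rng(cfg$seed + 1L, {
      synth_sst(as.Date(spec$start), as.Date(spec$end) + 1)
    })
    write_sst(sst, file.path(out_dir, "sst.csv"))
    readr::write_csv(dep$recordings |>
                       mutate(start_time = fmt_utc(.data$start_time)),
                     file.path(out_dir, "recordings.csv"))
    note_stage("generate", "ok",
               list(recordings = nrow(dep$recordings),
                    notes = nrow(dep$notes), songs = length(dep$songs)))
  }

  if ("detect" %in% stages) {
    if (is.null(dep)) {
      note_stage("detect", "skipped", reason = "no generated deployment")
    } else {
      det_args <- as.list(cfg$detector %||% list())
      cfg_lf <- do.call(detector_config, det_args)
      cfg_hf <- do.call(hf130_config, det_args)
      sp_par <- do.call(spectrogram_params,
                        as.list(cfg$spectrogram %||% list()))
      dets <- detect_deployment(dep$recordings,
                                configs = list(cfg_lf, cfg_hf),
                                params = sp_par)
      write_detections(dets, file.path(out_dir, "detections.csv"))
      note_stage("detect", "ok", list(detections = nrow(dets)))
    }
  }

  if ("rates" %in% stages) {
    if (is.null(dets)) {
      note_stage("rates", "skipped", reason = "no detections stage output")
    } else {
      bins <- weekly_rates(dets, dep$recordings)
      if (!is.null(sst)) bins <- attach_sst(bins, sst)
      readr::write_csv(bins, file.path(out_dir, "weekly_rates.csv"))
      note_stage("rates", "ok", list(weeks = nrow(bins)))
    }
  }

  songs_sel <- NULL
  ini_table <- NULL
  if ("songs" %in% stages) {
    if (is.null(dets)) {
      note_stage("songs", "skipped", reason = "no detections stage output")
    } else {
      ss_opt <- cfg$songstruct %||% list()
      songs_by_class <- map(c("LF20", "HF130"), function(cl) {
        segment_songs(dets |> rename(note_class = "note_class_guess"),
                      note_class = cl,
                      gap_rest_min_factor = ss_opt$gap_rest_min_factor %||% 1.5,
                      song_break_min = ss_opt$song_break_min %||% 20)
      }) |> list_rbind()
      songs_sel <- select_song_inis(
        songs_by_class,
        min_notes = ss_opt$min_notes %||% 10,
        min_inis = ss_opt$min_inis %||% 7,
        max_inis = ss_opt$max_inis %||% 20,
        independence_h = ss_opt$independence_h %||% 24
      )
      if (nrow(songs_sel) > 0) songs_sel <- classify_songs(songs_sel)
      flat <- songs_sel |>
        select(any_of(c("song_id", "season", "note_class", "start_time",
                        "n_notes", "n_inis_selected", "pattern", "mode1_s",
                        "mode2_s", "mean_s", "sd_s", "doublet")))
      readr::write_csv(flat, file.path(out_dir, "songs.csv"))
      ini_table <- songs_sel |>
        select("song_id", "season", "note_class", "selected_inis") |>
        tidyr::unnest_longer("selected_inis", values_to = "ini_s") |>
        select("song_id", "season", "note_class", "ini_s")
      readr::write_csv(ini_table, file.path(out_dir, "inis.csv"))
      rests <- rest_statistics(songs_sel)
      readr::write_csv(rests, file.path(out_dir, "rest_stats.csv"))
      note_stage("songs", "ok",
                 list(songs_segmented = nrow(songs_by_class),
                      songs_selected = nrow(songs_sel),
                      inis_selected = if (is.null(ini_table)) 0L
                                      else nrow(ini_table)))
    }
  }

  if ("stats" %in% stages) {
    if (is.null(bins)) {
      note_stage("stats", "skipped", reason = "no weekly rates")
    } else {
      results <- list()
      for (resp in c("pr", "dr")) {
        g <- tryCatch(fit_rate_gam(bins, resp), error = function(e) e)
        results[[paste0("gam_", resp)]] <- if (inherits(g, "error")) {
          list(status = "skipped", reason = conditionMessage(g))
        } else {
          list(status = "ok",
               deviance_explained = g$deviance_explained,
               p_month = unname(g$term_pvalues["Month"]),
               p_year = unname(g$term_pvalues["Year"]))
        }
        ct <- tryCatch(correlate_with_sst(bins, resp), error = function(e) e)
        results[[paste0("spearman_", resp)]] <- if (inherits(ct, "error")) {
          list(status = "skipped", reason = conditionMessage(ct))
        } else {
          list(status = "ok", rho = ct$rho, p = ct$p, strength = ct$strength)
        }
      }
      oc <- tryCatch(october_contrast(bins), error = function(e) e)
      results$october_dr <- if (inherits(oc, "error")) {
        list(status = "skipped", reason = conditionMessage(oc))
      } else {
        list(status = "ok", z = oc$statistic, p = oc$p)
      }
      if (!is.null(ini_table) && nrow(ini_table) > 0) {
        kw <- tryCatch(season_ini_test(ini_table), error = function(e) e)
        results$season_ini <- if (inherits(kw, "error")) {
          list(status = "skipped", reason = conditionMessage(kw))
        } else {
          list(status = "ok",
               tests = purrr::map(seq_len(nrow(kw)), function(i) {
                 list(note_class = kw$note_class[i],
                      chi_square = kw$chi_square[i], p = kw$p[i])
               }))
        }
      }
      jsonlite::write_json(results, file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note_stage("stats", "ok", list(analyses = length(results)))
    }
  }

  manifest$row_counts <- purrr::map(manifest$stages, function(s) {
    s[setdiff(names(s), c("status", "reason"))]
  })
  class(manifest) <- "fs_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.fs_manifest <- function(x, ...) {
  cat("<fs_manifest> seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      "\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("  ", format(nm, width = 9), st$status,
        if (!is.null(st$reason)) paste0(" (", st$reason, ")"), "\n", sep = "")
  }
  invisible(x)
}
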