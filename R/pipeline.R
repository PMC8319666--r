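#' Pipeline configuration
#'
#' All knobs of the end-to-end workflow, defaulting to the assay constants
#' (1 frame/s, 30-minute sessions) and the package's documented defaults for
#' smoothing, gap handling, model fitting and screen statistics.
#'
#' @param frame_rate_hz Frames per second.
#' @param window_s Speed-smoothing window (s); 0 (default) disables smoothing,
#'   see [compute_speeds()].
#' @param max_gap_frames Longest invalid run bridged by interpolation.
#' @param epsilon Speed floor in the log transform (px/s).
#' @param hmm_tol,hmm_max_iter Baum-Welch convergence controls.
#' @param alpha Family-wise significance level.
#' @param family_size Bonferroni family size; `NULL` for 2 x n_genes.
#' @param rule,band,cutoffs Hit-classification rule, see [classify_hits()].
#' @param seed Master seed recorded in the run log.
#' @return List of class `quiescr_pipeline_config`.
#' @export
pipeline_config <- function(frame_rate_hz = 1, window_s = 0,
                            max_gap_frames = 5, epsilon = 0.01,
                            hmm_tol = 1e-6, hmm_max_iter = 500,
                            alpha = 0.05, family_size = NULL,
                            rule = "ratio_band", band = 0.20,
                            cutoffs = c(0.6, 1.7), seed = 1) {
  structure(
    list(frame_rate_hz = frame_rate_hz, window_s = window_s,
         max_gap_frames = max_gap_frames, epsilon = epsilon,
         hmm_tol = hmm_tol, hmm_max_iter = hmm_max_iter,
         alpha = alpha, family_size = family_size, rule = rule,
         band = band, cutoffs = cutoffs, seed = seed),
    class = "quiescr_pipeline_config"
  )
}

#' Run the full screen pipeline from track files
#'
#' Composes the whole workflow: read tracks, build smoothed speed series, fit
#' one shared HMM per gene on that gene's concurrent control animals, freeze
#' it, decode every animal of the experiment with the frozen model, summarize
#' per-animal metrics, and assemble the screen table. Fitting on controls only
#' guarantees treated/control comparability; the decoded states of both groups
#' come from the same model.
#'
#' Intermediates (speed CSVs, per-gene model JSON, decoded-state CSVs, the
#' per-animal summary TSV, the screen TSV and a JSON run log) are written
#' under `output_dir` when given.
#'
#' @param manifest Tibble with columns `gene`, `role`
#'   (`"control"`/`"treated"`), `animal_id`, `track_csv` (file path).
#' @param config A [pipeline_config()].
#' @param output_dir Directory for intermediates; `NULL` to skip writing.
#' @return The [screen_report()] table, with the per-animal summaries in
#'   attribute `"summaries"`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(all(c("gene", "role", "animal_id", "track_csv") %in% names(manifest)))
  missing_files <- manifest$track_csv[!file.exists(manifest$track_csv)]
  if (length(missing_files) > 0) {
    stop("stage track: missing track file(s): ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  all_summaries <- purrr::map_dfr(unique(manifest$gene), function(g) {
    rows <- manifest[manifest$gene == g, ]
    speeds <- purrr::map(seq_len(nrow(rows)), function(i) {
      trk <- stage("track", read_track_csv(rows$track_csv[i]))
      sp <- stage("speeds", compute_speeds(trk, window_s = config$window_s,
                                           max_gap_frames = config$max_gap_frames))
      sp$animal_id <- rows$animal_id[i]
      if (!is.null(output_dir)) {
        readr::write_csv(sp, file.path(output_dir,
                                       paste0(rows$animal_id[i], "_speeds.csv")),
                         progress = FALSE)
      }
      sp
    })
    ctl_idx <- which(rows$role == "control")
    if (length(ctl_idx) == 0) {
      stop("stage fit: gene '", g, "' has no concurrent control animals",
           call. = FALSE)
    }
    fit <- stage("fit", fit_hmm(dplyr::bind_rows(speeds[ctl_idx]),
                                max_iter = config$hmm_max_iter,
                                tol = config$hmm_tol,
                                epsilon = config$epsilon))
    if (!is.null(output_dir)) {
      write_hmm_json(fit, file.path(output_dir, paste0(g, "_hmm.json")))
    }
    decoded <- purrr::map_dfr(speeds, function(sp) {
      d <- stage("decode", decode_states(fit, sp))
      if (!is.null(output_dir)) {
        write_states_csv(d, file.path(output_dir,
                                      paste0(d$animal_id[1], "_states.csv")))
      }
      d
    })
    sm <- stage("metrics", behavior_summary(decoded, config$frame_rate_hz))
    sm$gene <- g
    sm$role <- rows$role[match(sm$animal_id, rows$animal_id)]
    sm
  })
  screen <- screen_report(all_summaries,
                          manifest = tibble(gene = unique(manifest$gene)),
                          alpha = config$alpha,
                          family_size = config$family_size,
                          rule = config$rule, band = config$band,
                          cutoffs = config$cutoffs)
  if (!is.null(output_dir)) {
    readr::write_tsv(all_summaries, file.path(output_dir, "animal_summaries.tsv"),
                     progress = FALSE)
    readr::write_tsv(screen, file.path(output_dir, "screen_table.tsv"),
                     progress = FALSE)
    log <- list(
      config = unclass(config),
      n_genes = length(unique(manifest$gene)),
      n_animals = nrow(manifest),
      package_version = as.character(utils::packageVersion("quiescr")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  attr(screen, "summaries") <- all_summaries
  screen
}
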