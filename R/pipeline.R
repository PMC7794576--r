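#' Measures analysed by the condition model
#'
#' Named list mapping each per-participant measure to the prior centre used
#' by [fit_condition_model()]: headway measures centre on 2 s, durations on
#' 0.4 s, weights on 0.5.
#'
#' @export
measure_priors <- function() {
  list(median_th = 2, gf_mean = 2, ef_mean = 2, launch_th = 2, land_th = 2,
       tracking_duration = 0.4, gf_weight = 0.5)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates generation, headway estimation, mixture decomposition, gaze
#' sequencing and Bayesian condition inference, failing fast with
#' stage-labelled errors. With `out_dir` set, all result tables are written
#' as CSV alongside a JSON run manifest holding the configuration snapshot,
#' seeds, package version and an md5 digest of every output file.
#'
#' @param cfg A [synth_config()] (its `seed` drives all randomness).
#' @param track A [track_config()].
#' @param cam A [camera_model()].
#' @param out_dir Optional output directory.
#' @param measures Character vector of measures to model, from
#'   `names(measure_priors())`.
#' @return List: `th`, `mixtures`, `sequencing`, `summaries`, `posteriors`
#'   (one [fit_condition_model()] result per measure), `manifest`.
#' @export
run_pipeline <- function(cfg = synth_config(), track = track_config(),
                         cam = camera_model(), out_dir = NULL,
                         measures = names(measure_priors())) {
  warnings_log <- character(0)
  ds <- stage("synth", simulate_dataset(cfg, track, cam))
  th <- stage("projection", estimate_th_dataset(ds))
  entry <- bend_entry(track, default_trial_window(track))
  mixtures <- stage("mixture", fit_all_mixtures(th, entry$time_s))
  bend_span <- c(entry$time_s,
                 entry$time_s + pi * track$bend_radius_m / track$speed_mps)
  seqr <- stage("segmentation", sequence_all_trials(th, cam, bend_span))
  summaries <- stage("summaries", withCallingHandlers(
    pipeline_summaries(th, mixtures, seqr),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  priors <- measure_priors()
  posteriors <- stage("inference", {
    out <- list()
    for (m in intersect(measures, unique(summaries$measure))) {
      s <- summaries[summaries$measure == m, , drop = FALSE]
      out[[m]] <- fit_condition_model(s, prior_center = priors[[m]],
                                      seed = cfg$seed)
    }
    out
  })
  res <- list(th = th, mixtures = mixtures, sequencing = seqr,
              summaries = summaries, posteriors = posteriors)
  res$manifest <- build_manifest(cfg, track, cam, res, out_dir, warnings_log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Estimate headway for every trial of a simulated dataset
#'
#' @param ds From [simulate_dataset()].
#' @param ... Passed to [estimate_th()].
#' @return Pooled tidy headway table.
#' @export
estimate_th_dataset <- function(ds, ...) {
  key <- unique(ds$vehicle[, c("participant", "mode", "trial")])
  out <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    sel_v <- ds$vehicle$participant == key$participant[i] &
      ds$vehicle$mode == key$mode[i] & ds$vehicle$trial == key$trial[i]
    sel_g <- ds$gaze$participant == key$participant[i] &
      ds$gaze$mode == key$mode[i] & ds$gaze$trial == key$trial[i]
    window <- default_trial_window(ds$track,
                                   participant = key$participant[i],
                                   trial = key$trial[i],
                                   mode = key$mode[i])
    out[[i]] <- estimate_th(ds$vehicle[sel_v, ], ds$gaze[sel_g, ],
                            ds$midline, ds$cam, window, ...)
  }
  do.call(rbind, out)
}

# Assemble the participant-level summary table across all measures.
pipeline_summaries <- function(th, mixtures, seqr) {
  inc <- th[!th$excluded, , drop = FALSE]
  pieces <- list(summarise_participants(inc, "th_s", "median_th"))
  mix_long <- rbind(
    data.frame(participant = mixtures$participant, mode = mixtures$mode,
               measure = "gf_mean", value = mixtures$gf_mean_th),
    data.frame(participant = mixtures$participant, mode = mixtures$mode,
               measure = "ef_mean", value = mixtures$ef_mean_th),
    data.frame(participant = mixtures$participant, mode = mixtures$mode,
               measure = "gf_weight", value = mixtures$gf_weight))
  mix_long <- mix_long[!is.na(mix_long$value), , drop = FALSE]
  pieces <- c(pieces, list(mix_long[, c("participant", "mode", "measure",
                                        "value")]))
  if (!is.null(seqr$events)) {
    pieces <- c(pieces,
                list(summarise_participants(seqr$events[seqr$events$forward, ],
                                            "launch_th_s", "launch_th"),
                     summarise_participants(seqr$events[seqr$events$forward, ],
                                            "land_th_s", "land_th")))
  }
  if (!is.null(seqr$tracking))
    pieces <- c(pieces, list(summarise_participants(seqr$tracking,
                                                    "duration_s",
                                                    "tracking_duration")))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

build_manifest <- function(cfg, track, cam, res, out_dir, warnings_log) {
  list(package = "gazeway",
       version = as.character(utils::packageVersion("gazeway")),
       seed = cfg$seed,
       config = list(synth = unclass(cfg), track = unclass(track),
                     camera = unclass(cam)[c("eye_height_m",
                                             "screen_distance_m",
                                             "fov_h_deg", "fov_v_deg")]),
       warnings = warnings_log,
       n_th_samples = nrow(res$th),
       created = NULL)   # timestamps omitted so manifests are reproducible
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(res$th, "th_table.csv")
  wr(res$mixtures, "mixture_fits.csv")
  if (!is.null(res$sequencing$segments)) wr(res$sequencing$segments,
                                            "segments.csv")
  if (!is.null(res$sequencing$events)) wr(res$sequencing$events,
                                          "saccade_events.csv")
  if (!is.null(res$sequencing$tracking)) wr(res$sequencing$tracking,
                                            "tracking_durations.csv")
  wr(res$summaries, "participant_summaries.csv")
  post <- do.call(rbind, lapply(names(res$posteriors), function(m)
    cbind(measure = m, res$posteriors[[m]]$contrasts)))
  if (!is.null(post)) wr(post, "posterior_contrasts.csv")
  cond <- do.call(rbind, lapply(names(res$posteriors), function(m)
    cbind(measure = m, res$posteriors[[m]]$conditions)))
  if (!is.null(cond)) wr(cond, "posterior_conditions.csv")
  res$manifest$files <- as.list(tools::md5sum(paths))
  names(res$manifest$files) <- basename(paths)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML
#'
#' Sections `synth`, `track` and `camera` override the respective defaults.
#'
#' @param path YAML file path.
#' @return List with `cfg`, `track`, `cam`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, if (is.null(args)) list() else args)
  syn <- y$synth
  if (!is.null(syn$mode_shift_s)) syn$mode_shift_s <- unlist(syn$mode_shift_s)
  list(cfg = build(synth_config, syn),
       track = build(track_config, y$track),
       cam = build(camera_model, y$camera))
}
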