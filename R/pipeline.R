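#' Per-recording feature extraction with calibrated segmentation
#'
#' Stage driver over a cohort: computes frame features for every
#' recording, calibrates threshold rules on the first `n_exemplars`
#' recordings using their ground-truth labels (or uses `rules` if
#' supplied), classifies and smooths frames into segments, and aggregates
#' the 23-feature recording vector plus biological covariates. When
#' ground-truth labels are available, per-recording segmentation quality
#' (frame accuracy, per-kind segment recall) is reported alongside.
#'
#' @param cohort A `voice_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param grid A [frame_grid()]; its sample rate must match the cohort's.
#' @param rules Optional pre-calibrated rules; otherwise calibrated from
#'   exemplars.
#' @param n_exemplars Recordings used for calibration (default 5).
#' @param min_votes Vote quorum for [classify_frames()].
#' @param median_width,min_gap_s,min_seg_s Smoothing constants for
#'   [frames_to_segments()].
#' @return List: `features` (tibble, one row per recording: ids, fev1_pct,
#'   26 feature columns), `rules`, `segments` (named list), `quality`
#'   (tibble or NULL).
#' @export
extract_cohort_features <- function(cohort, grid = frame_grid(),
                                    rules = NULL, n_exemplars = 5L,
                                    min_votes = 3L, median_width = 5L,
                                    min_gap_s = 0.10, min_seg_s = 0.15) {
  m <- cohort$manifest
  n <- nrow(m)
  has_truth <- !is.null(cohort$labels) && length(cohort$labels) == n
  cache <- vector("list", min(n_exemplars, n))
  if (is.null(rules)) {
    if (!has_truth)
      stop("no rules supplied and no ground-truth labels to calibrate on")
    ex <- lapply(seq_len(min(n_exemplars, n)), function(i) {
      fr <- frame_features(render_recording(cohort, i), grid)
      cache[[i]] <<- fr
      fr$kind <- kind_at_times(fr$times, cohort$labels[[m$recording_id[i]]])
      fr
    })
    rules <- calibrate_thresholds(do.call(rbind, ex))
  }
  if (min_votes > nrow(rules))
    stop("min_votes exceeds the number of calibrated rules")

  segments <- vector("list", n)
  quality <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- if (i <= length(cache) && !is.null(cache[[i]])) cache[[i]] else
      frame_features(render_recording(cohort, i), grid)
    kinds <- classify_frames(fr, rules, min_votes)
    seg <- frames_to_segments(kinds, grid, median_width = median_width,
                              min_gap_s = min_gap_s, min_seg_s = min_seg_s,
                              duration_s = cohort$params$recording_s)
    segments[[i]] <- seg
    v <- aggregate_recording_features(fr[, setdiff(names(fr), "kind")], seg)
    rows[[i]] <- attach_biological(v, m[i, ])
    if (has_truth) {
      truth <- cohort$labels[[m$recording_id[i]]]
      quality[[i]] <- tibble::tibble(
        recording_id = m$recording_id[i],
        frame_accuracy = mean(kinds == kind_at_times(fr$times, truth)),
        recall_breath = segment_recall(truth, seg, "breath"),
        recall_speech = segment_recall(truth, seg, "speech"))
    }
  }
  names(segments) <- m$recording_id
  features <- cbind(m[, c("recording_id", "subject_id", "fev1_pct")],
                    do.call(rbind, rows))
  list(features = tibble::as_tibble(features), rules = rules,
       segments = segments,
       quality = if (has_truth) do.call(rbind, quality) else NULL)
}

#' End-to-end in-memory analysis of one cohort
#'
#' Feature extraction with calibrated segmentation, balanced (or random)
#' partitioning over FEV1% bins, and the 18-report prediction suite.
#'
#' @inheritParams extract_cohort_features
#' @param partition_mode `"balanced"` or `"random"`.
#' @param train_fraction Training fraction.
#' @param seed Seed for partitioning, CV folds and stochastic fits.
#' @param ... Passed to [extract_cohort_features()].
#' @return List: `features`, `rules`, `segments`, `quality`, `partition`,
#'   `reports`, `summary` (tibble), `feature_sets` (regression comparison).
#' @export
analyze_cohort <- function(cohort, grid = frame_grid(),
                           partition_mode = "balanced",
                           train_fraction = 0.7, seed = 1L, ...) {
  ex <- extract_cohort_features(cohort, grid, ...)
  partition <- make_partition(ex$features$fev1_pct,
                              train_fraction = train_fraction,
                              mode = partition_mode, seed = seed)
  reports <- run_task_suite(ex$features, partition, seed = seed)
  c(ex, list(partition = partition, reports = reports,
             summary = summarise_reports(reports),
             feature_sets = compare_feature_sets(ex$features, partition,
                                                 seed = seed)))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown names are
#' rejected; every value is echoed into the run log.
#'
#' @param cohort_dir Directory of an existing cohort (`manifest.csv` +
#'   WAVs + label CSVs), or `NULL` to synthesise one.
#' @param out_dir Output directory for stage artifacts.
#' @param n_subjects,n_recordings Cohort size when synthesising.
#' @param params [generative_params()] for synthesis / rendering.
#' @param grid [frame_grid()] for feature extraction.
#' @param n_exemplars,min_votes,median_width,min_gap_s,min_seg_s
#'   Segmentation settings.
#' @param partition_mode,train_fraction Partition settings.
#' @param seed Global seed (overrides `params$seed`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, cohort_dir = NULL, n_subjects = 26,
                            n_recordings = 323,
                            params = generative_params(),
                            grid = frame_grid(), n_exemplars = 5L,
                            min_votes = 3L, median_width = 5L,
                            min_gap_s = 0.10, min_seg_s = 0.15,
                            partition_mode = "balanced",
                            train_fraction = 0.7, seed = 1L) {
  stopifnot(min_votes >= 1L, min_votes <= 5L, n_exemplars >= 1L,
            train_fraction > 0, train_fraction < 1,
            partition_mode %in% c("balanced", "random"))
  if (grid$sample_rate != params$sample_rate)
    stop("frame grid and generative params disagree on sample rate")
  params$seed <- as.integer(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline to disk
#'
#' Synthesises (or reads) the cohort, extracts features, partitions,
#' runs the 18-report suite, and writes each stage's artifacts under
#' `out_dir`: `features.csv`, `thresholds.json`, per-recording segment
#' CSVs under `segments/`, `partition.json`, `reports.json`,
#' `summary.csv`, `feature_sets.csv`, `correlations.csv` and a structured
#' `run_log.json` (configuration echo, package version, per-stage timing,
#' any skipped recordings). Re-running with the same configuration
#' reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = config[setdiff(names(config), c("params", "grid"))],
              params = unclass(config$params), grid = unclass(config$grid),
              package_version = as.character(utils::packageVersion("voicefev")),
              stages = list(), skipped = character())
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  if (is.null(config$cohort_dir)) {
    cohort <- generate_cohort(config$params, config$n_subjects,
                              config$n_recordings, audio = "none")
  } else {
    cohort <- read_cohort(config$cohort_dir, config$params)
    ok <- vapply(seq_len(nrow(cohort$manifest)), function(i)
      tryCatch({ render_recording(cohort, i); TRUE },
               error = function(e) FALSE), logical(1))
    if (!any(ok)) stop("all recordings failed to load from ",
                       config$cohort_dir)
    log$skipped <- cohort$manifest$recording_id[!ok]
    cohort$manifest <- cohort$manifest[ok, ]
    cohort$labels <- cohort$labels[ok]
  }
  log$stages$cohort <- list(n = nrow(cohort$manifest), seconds = lap(t0))

  t0 <- tic()
  res <- analyze_cohort(cohort, config$grid,
                        partition_mode = config$partition_mode,
                        train_fraction = config$train_fraction,
                        seed = config$seed,
                        n_exemplars = config$n_exemplars,
                        min_votes = config$min_votes,
                        median_width = config$median_width,
                        min_gap_s = config$min_gap_s,
                        min_seg_s = config$min_seg_s)
  log$stages$analysis <- list(seconds = lap(t0))

  out <- config$out_dir
  utils::write.csv(res$features, file.path(out, "features.csv"),
                   row.names = FALSE)
  write_threshold_rules(res$rules, file.path(out, "thresholds.json"))
  seg_dir <- file.path(out, "segments")
  dir.create(seg_dir, showWarnings = FALSE)
  for (id in names(res$segments))
    utils::write.csv(res$segments[[id]],
                     file.path(seg_dir, paste0(id, "_segments.csv")),
                     row.names = FALSE)
  write_partition(res$partition, file.path(out, "partition.json"))
  utils::write.csv(res$summary, file.path(out, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$feature_sets, file.path(out, "feature_sets.csv"),
                   row.names = FALSE)
  acoustic <- res$features[, feature_schema()]
  utils::write.csv(feature_fev1_correlations(
    impute_from_train(acoustic, seq_len(nrow(acoustic)))$x,
    res$features$fev1_pct),
    file.path(out, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(res$reports, function(r) {
      r$metrics$confusion <- if (!is.null(r$metrics$confusion))
        as.data.frame.matrix(r$metrics$confusion)
      r$predictions <- as.character(r$predictions)
      r
    }),
    file.path(out, "reports.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
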