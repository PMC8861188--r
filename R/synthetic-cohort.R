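#' Parameters of the synthetic voice-cohort generator
#'
#' The generator emulates ~30 s readings interleaved with audible breaths,
#' recorded once per spirometry measurement. Two mechanisms tie acoustics to
#' lung function (FEV1, percent predicted), both motivated by breathlessness
#' at reduced lung function: breath loudness rises as FEV1% falls
#' (`breath_gain_slope`), and the breath cycle shortens as FEV1% falls
#' because speech spans between breaths contract (`cycle_slope`). The
#' acoustic driver is the recording's FEV1% plus Gaussian noise of sd
#' `noise_sd`, so `noise_sd` is the irreducible error (in FEV1% points) of
#' any acoustics-based predictor.
#'
#' FEV1% values are drawn from a two-component truncated-normal mixture:
#' with probability `p_normal` from N(`fev1_normal_mean`, `fev1_normal_sd`)
#' truncated to (80, 125] (normal lung function), otherwise from
#' N(`fev1_abnormal_mean`, `fev1_abnormal_sd`) truncated to (50, 80]. The
#' normal-component count is fixed at `round(p_normal * n)`, so the cohort
#' reproduces the reference prevalence exactly: mode near 100, no values at
#' or below 50, ~72% above 80.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param recording_s Recording duration, seconds.
#' @param speech_dur_range Range of speech-span durations, seconds (before
#'   the FEV1-dependent shift).
#' @param breath_dur_range Range of breath durations, seconds.
#' @param f0_range Speaker fundamental-frequency range, Hz.
#' @param speech_rms Target RMS of speech spans.
#' @param breath_rms Baseline breath RMS at FEV1% = 100.
#' @param breath_gain_slope Relative breath-gain increase per FEV1% point
#'   below 100 (dimensionless).
#' @param cycle_slope Change in speech-span duration per FEV1% point above
#'   100, seconds (positive: lower FEV1% gives shorter spans, hence shorter
#'   breath cycles).
#' @param noise_sd Sd of the acoustic-driver noise, FEV1% points.
#' @param p_normal Mixture weight of the normal component.
#' @param fev1_normal_mean,fev1_normal_sd Normal component, FEV1% points.
#' @param fev1_abnormal_mean,fev1_abnormal_sd Abnormal component.
#' @param seed Master seed for [generate_cohort()].
#' @return A `generative_params` list.
#' @export
generative_params <- function(sample_rate = 22050,
                              recording_s = 30,
                              speech_dur_range = c(2, 5),
                              breath_dur_range = c(0.3, 1.2),
                              f0_range = c(110, 220),
                              speech_rms = 0.2,
                              breath_rms = 0.03,
                              breath_gain_slope = 0.012,
                              cycle_slope = 0.02,
                              noise_sd = 2.0,
                              p_normal = 0.7214,
                              fev1_normal_mean = 100, fev1_normal_sd = 8,
                              fev1_abnormal_mean = 70, fev1_abnormal_sd = 8,
                              seed = 1L) {
  stopifnot(sample_rate > 0, recording_s > 0,
            length(speech_dur_range) == 2, all(speech_dur_range > 0),
            diff(speech_dur_range) >= 0,
            length(breath_dur_range) == 2, all(breath_dur_range > 0),
            diff(breath_dur_range) >= 0,
            length(f0_range) == 2, all(f0_range > 0), diff(f0_range) >= 0,
            speech_rms > 0, breath_rms > 0, noise_sd >= 0,
            p_normal > 0, p_normal < 1)
  structure(as.list(environment()), class = "generative_params")
}

# Inverse-CDF draw from N(mean, sd) truncated to (lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Draw FEV1% values for a synthetic cohort
#'
#' @param n Number of values.
#' @param params A [generative_params()] list.
#' @return Numeric vector in (50, 125], in shuffled order, with exactly
#'   `round(p_normal * n)` values above 80.
#' @export
sample_fev1 <- function(n, params = generative_params()) {
  stopifnot(n >= 1)
  n_norm <- round(params$p_normal * n)
  v <- c(rtruncnorm(n_norm, params$fev1_normal_mean, params$fev1_normal_sd, 80, 125),
         rtruncnorm(n - n_norm, params$fev1_abnormal_mean, params$fev1_abnormal_sd, 50, 80))
  v[sample.int(n)]
}

#' Synthesise one speech span
#'
#' A harmonic source (12 harmonics with 1/h amplitudes and random phases)
#' under a slow amplitude modulation with short attack/decay ramps, scaled
#' to `params$speech_rms`.
#'
#' @param duration Span duration, seconds (> 0).
#' @param f0 Fundamental frequency, Hz.
#' @param params A [generative_params()] list.
#' @return Numeric waveform, `round(duration * sample_rate)` samples.
#' @export
synth_speech_segment <- function(duration, f0, params = generative_params()) {
  if (duration <= 0) stop("duration must be positive")
  sr <- params$sample_rate
  n <- max(1L, round(duration * sr))
  t <- (seq_len(n) - 1) / sr
  n_harm <- max(1L, min(12L, floor(0.45 * sr / f0)))
  phases <- stats::runif(n_harm, 0, 2 * pi)
  x <- numeric(n)
  for (h in seq_len(n_harm))
    x <- x + sin(2 * pi * h * f0 * t + phases[h]) / h
  mod <- 1 + 0.3 * sin(2 * pi * 3 * t + stats::runif(1, 0, 2 * pi))
  ramp <- pmin(1, t / 0.02, rev(t - t[1] + 1 / sr) / 0.02)
  x <- x * mod * ramp
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x * min(params$speech_rms / r, 0.95 / max(abs(x)))
  x
}

breath_gain <- function(fev1, params) {
  params$breath_rms * max(0.05, 1 + params$breath_gain_slope * (100 - fev1))
}

#' Synthesise one breath
#'
#' Broadband Gaussian noise with 10 ms edge ramps; RMS scales with
#' [generative_params()]'s `breath_gain_slope` so that, at a fixed seed and
#' duration, RMS is non-increasing in FEV1%.
#'
#' @param duration Breath duration, seconds (> 0).
#' @param fev1 FEV1% driving the gain, in (0, 150].
#' @param params A [generative_params()] list.
#' @return Numeric waveform, `round(duration * sample_rate)` samples.
#' @export
synth_breath_segment <- function(duration, fev1, params = generative_params()) {
  if (duration <= 0) stop("duration must be positive")
  stopifnot(fev1 > 0, fev1 <= 150)
  sr <- params$sample_rate
  n <- max(1L, round(duration * sr))
  t <- (seq_len(n) - 1) / sr
  ramp <- pmin(1, t / 0.01, rev(t - t[1] + 1 / sr) / 0.01)
  stats::rnorm(n) * breath_gain(fev1, params) * ramp
}

#' Assemble one labelled synthetic recording
#'
#' Alternates speech and breath spans, starting with speech, until
#' `recording_s` is filled; the final span is truncated at the recording
#' end (a truncated remnant shorter than 0.25 s is absorbed into the
#' previous span). Span durations, the speaker's f0 and the acoustic
#' driver are drawn from the current RNG state, or under `seed` if given.
#' The segment plan is drawn before any audio noise, so labels are
#' identical whether or not audio is rendered.
#'
#' @param fev1 Recording FEV1%, in (50, 125].
#' @param params A [generative_params()] list.
#' @param seed Optional integer seed for this recording.
#' @param audio Render the waveform (set `FALSE` for labels only).
#' @return List with `waveform` (or `NULL`), `labels` (tibble `start_s`,
#'   `end_s`, `kind`), `fev1_eff` (the noisy acoustic driver), `f0`.
#' @export
assemble_recording <- function(fev1, params = generative_params(),
                               seed = NULL, audio = TRUE) {
  stopifnot(fev1 > 50, fev1 <= 125)
  run <- function() {
    sr <- params$sample_rate
    fev1_eff <- min(max(fev1 + stats::rnorm(1, 0, params$noise_sd), 35), 140)
    f0 <- stats::runif(1, params$f0_range[1], params$f0_range[2])
    shift <- params$cycle_slope * (fev1_eff - 100)

    kinds <- character(); durs <- numeric(); f0s <- numeric()
    total <- 0
    while (total < params$recording_s) {
      kind <- if (length(kinds) %% 2 == 0) "speech" else "breath"
      d <- if (kind == "speech") {
        max(1.0, stats::runif(1, params$speech_dur_range[1],
                              params$speech_dur_range[2]) + shift)
      } else {
        stats::runif(1, params$breath_dur_range[1], params$breath_dur_range[2])
      }
      kinds <- c(kinds, kind); durs <- c(durs, d)
      f0s <- c(f0s, f0 * stats::runif(1, 0.97, 1.03))
      total <- total + d
    }
    overrun <- total - params$recording_s
    k <- length(durs)
    if (durs[k] - overrun < 0.25 && k > 1L) {
      durs <- durs[-k]; kinds <- kinds[-k]; f0s <- f0s[-k]
      k <- k - 1L
      durs[k] <- durs[k] + (params$recording_s - sum(durs))
    } else {
      durs[k] <- durs[k] - overrun
    }

    n_total <- round(params$recording_s * sr)
    ns <- round(durs * sr)
    ns[k] <- n_total - sum(ns[-k])
    ends <- cumsum(ns) / sr
    labels <- tibble::tibble(start_s = c(0, ends[-k]), end_s = ends,
                             kind = kinds)
    waveform <- NULL
    if (audio) {
      waveform <- unlist(lapply(seq_len(k), function(i) {
        x <- if (kinds[i] == "speech")
          synth_speech_segment(durs[i], f0s[i], params)
        else synth_breath_segment(durs[i], fev1_eff, params)
        length(x) <- ns[i]                      # pad/trim rounding slack
        x[is.na(x)] <- 0
        x
      }), use.names = FALSE)
    }
    list(waveform = waveform, labels = labels, fev1_eff = fev1_eff, f0 = f0)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

make_subjects <- function(n_subjects) {
  sex <- stats::rbinom(n_subjects, 1, 0.5)
  height <- ifelse(sex == 1, stats::rnorm(n_subjects, 176, 7),
                   stats::rnorm(n_subjects, 163, 7))
  weight <- ifelse(sex == 1, stats::rnorm(n_subjects, 76, 10),
                   stats::rnorm(n_subjects, 66, 10))
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    sex = sex,
    height_cm = round(pmin(pmax(height, 142), 198), 1),
    weight_kg = round(pmin(pmax(weight, 42), 118), 1))
}

#' Generate a seeded synthetic voice cohort
#'
#' Draws FEV1% values from the cohort mixture, deals them to subjects in
#' contiguous blocks sorted in decreasing order within each subject
#' (emulating repeated measurements under a progressive bronchial
#' challenge), and assembles one labelled recording per value. Each
#' recording gets its own derived seed (stored in the manifest), so
#' waveforms can be re-rendered lazily from the manifest alone.
#'
#' @param params A [generative_params()] list; `params$seed` drives all
#'   randomness.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_recordings Total recordings (>= `n_subjects`).
#' @param audio `"memory"` keeps waveforms in the returned object; `"none"`
#'   stores only manifest + labels (waveforms re-rendered on demand by
#'   [render_recording()]).
#' @param dir Optional directory: writes per-recording WAV files, the
#'   manifest CSV and per-recording ground-truth label CSVs.
#' @return A `voice_cohort` list: `params`, `manifest`, `subjects`,
#'   `labels` (named list of tibbles), `waveforms` (named list or NULL).
#' @export
generate_cohort <- function(params = generative_params(), n_subjects = 26,
                            n_recordings = 323,
                            audio = c("memory", "none"), dir = NULL) {
  audio <- match.arg(audio)
  if (n_subjects < 1 || n_recordings < n_subjects)
    stop("need n_subjects >= 1 and n_recordings >= n_subjects")
  cohort <- withr::with_seed(params$seed, {
    subjects <- make_subjects(n_subjects)
    fev1 <- sample_fev1(n_recordings, params)
    cuts <- floor(seq(0, n_recordings, length.out = n_subjects + 1))
    subj_idx <- rep(seq_len(n_subjects), times = diff(cuts))
    fev1 <- unlist(lapply(split(fev1, subj_idx), sort, decreasing = TRUE),
                   use.names = FALSE)
    rec_seed <- sample.int(.Machine$integer.max, n_recordings)
    manifest <- tibble::tibble(
      recording_id = sprintf("R%04d", seq_len(n_recordings)),
      subject_id = subjects$subject_id[subj_idx],
      sex = subjects$sex[subj_idx],
      height_cm = subjects$height_cm[subj_idx],
      weight_kg = subjects$weight_kg[subj_idx],
      fev1_pct = round(fev1, 2),
      rec_seed = rec_seed,
      wav_path = NA_character_)
    subjects$baseline_fev1 <- unname(vapply(split(manifest$fev1_pct, subj_idx),
                                            max, numeric(1)))
    recs <- lapply(seq_len(n_recordings), function(i)
      assemble_recording(manifest$fev1_pct[i], params, seed = rec_seed[i],
                         audio = audio == "memory"))
    labels <- lapply(recs, `[[`, "labels")
    names(labels) <- manifest$recording_id
    waveforms <- NULL
    if (audio == "memory") {
      waveforms <- lapply(recs, `[[`, "waveform")
      names(waveforms) <- manifest$recording_id
    }
    list(params = params, manifest = manifest, subjects = subjects,
         labels = labels, waveforms = waveforms)
  })
  class(cohort) <- "voice_cohort"
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

#' Waveform of one cohort recording
#'
#' Returns the in-memory waveform if present, reads the WAV file if the
#' manifest has a path, and otherwise re-renders the recording
#' deterministically from its stored seed.
#'
#' @param cohort A `voice_cohort`.
#' @param i Recording index or `recording_id`.
#' @return Numeric waveform.
#' @export
render_recording <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$manifest$recording_id)
  stopifnot(!is.na(i), i >= 1, i <= nrow(cohort$manifest))
  id <- cohort$manifest$recording_id[i]
  if (!is.null(cohort$waveforms)) return(cohort$waveforms[[id]])
  p <- cohort$manifest$wav_path[i]
  if (!is.na(p) && file.exists(p)) return(read_wav(p)$waveform)
  assemble_recording(cohort$manifest$fev1_pct[i], cohort$params,
                     seed = cohort$manifest$rec_seed[i])$waveform
}

#' Write a cohort to disk (WAV + manifest CSV + label CSVs)
#' @param cohort A `voice_cohort`.
#' @param dir Output directory (created if needed).
#' @return The cohort with `wav_path` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    id <- m$recording_id[i]
    wav <- file.path(dir, paste0(id, ".wav"))
    write_wav(render_recording(cohort, i), wav, cohort$params$sample_rate)
    m$wav_path[i] <- wav
    utils::write.csv(cohort$labels[[id]],
                     file.path(dir, paste0(id, "_labels.csv")),
                     row.names = FALSE)
  }
  cohort$manifest <- m
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(cohort)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory containing `manifest.csv`.
#' @param params The [generative_params()] used (for sample rate and
#'   re-rendering; defaults suffice for cohorts written with defaults).
#' @return A `voice_cohort` (waveforms read lazily from WAV files).
#' @export
read_cohort <- function(dir, params = generative_params()) {
  m <- tibble::as_tibble(utils::read.csv(file.path(dir, "manifest.csv"),
                                         stringsAsFactors = FALSE))
  labels <- lapply(m$recording_id, function(id)
    tibble::as_tibble(utils::read.csv(file.path(dir, paste0(id, "_labels.csv")),
                                      stringsAsFactors = FALSE)))
  names(labels) <- m$recording_id
  structure(list(params = params, manifest = m, subjects = NULL,
                 labels = labels, waveforms = NULL),
            class = "voice_cohort")
}

#' Segment kind at given times
#'
#' Looks up, for each time, the kind of the labelled interval containing it
#' (intervals are `[start_s, end_s)`; times past the last interval take its
#' kind). Used to turn ground-truth (or predicted) segment tables into
#' per-frame labels.
#'
#' @param times Numeric times, seconds.
#' @param segments Tibble with `start_s`, `end_s`, `kind`.
#' @return Character vector of kinds.
#' @export
kind_at_times <- function(times, segments) {
  idx <- findInterval(times, segments$start_s)
  segments$kind[pmax(idx, 1L)]
}
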