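test_that("speech spans are harmonic, bounded and pitched at f0", {
  p <- generative_params(seed = 1)
  expect_error(synth_speech_segment(0, 150, p), "positive")

  x <- withr::with_seed(5, synth_speech_segment(3, 150, p))
  expect_lte(max(abs(x)), 1.0)

  spec <- Mod(stats::fft(x))[1:(length(x) %/% 2)]
  peak_hz <- (which.max(spec) - 1) * p$sample_rate / length(x)
  bin_hz <- p$sample_rate / length(x)
  expect_lt(min(abs(peak_hz - 150 * (1:12))), bin_hz + 1e-9)

  g <- frame_grid()
  mean_spec <- rowMeans(stft_magnitude(x, g, centre = FALSE))
  fl <- frame_spectral_features(matrix(mean_spec), g)$flatness
  expect_lt(fl, 0.2)

  b <- withr::with_seed(5, synth_breath_segment(3, 100, p))
  expect_gte(sqrt(mean(x^2)), 3 * sqrt(mean(b^2)))
})

test_that("breath spans are broadband with FEV1-dependent gain", {
  p <- generative_params(seed = 1)
  expect_error(synth_breath_segment(-1, 100, p), "positive")
  expect_length(withr::with_seed(1, synth_breath_segment(0.5, 100, p)), 11025)

  r60 <- sqrt(mean(withr::with_seed(8, synth_breath_segment(1, 60, p))^2))
  r100 <- sqrt(mean(withr::with_seed(8, synth_breath_segment(1, 100, p))^2))
  r120 <- sqrt(mean(withr::with_seed(8, synth_breath_segment(1, 120, p))^2))
  expect_gt(r60, r100)
  expect_gte(r100, r120)

  x <- withr::with_seed(3, synth_breath_segment(3, 90, p))
  g <- frame_grid()
  sf <- frame_spectral_features(stft_magnitude(x, g, centre = FALSE), g)
  expect_gt(mean(sf$flatness), 0.5)
})

test_that("assembled recordings have valid alternating labels covering the duration", {
  p <- generative_params(seed = 2)
  for (s in 1:5) {
    rec <- assemble_recording(100, p, seed = s)
    lab <- rec$labels
    expect_equal(lab$start_s[1], 0)
    expect_equal(lab$end_s[nrow(lab)], p$recording_s)
    expect_true(all(lab$start_s < lab$end_s))
    expect_equal(lab$start_s[-1], lab$end_s[-nrow(lab)])
    expect_true(all(lab$kind[c(TRUE, FALSE)] == "speech"))
    n_breath <- sum(lab$kind == "breath")
    expect_gte(n_breath, 4)
    expect_lte(n_breath, 15)
    expect_length(rec$waveform, p$recording_s * p$sample_rate)
  }
})

test_that("breath cycles shorten and breath counts rise at lower FEV1", {
  p <- generative_params(seed = 2)
  stats_at <- function(fev1) {
    out <- vapply(1:20, function(s) {
      lab <- assemble_recording(fev1, p, seed = 7000 + s,
                                audio = FALSE)$labels
      st <- breath_cycle_stats(lab)
      c(st$mean_cycle_s, st$breath_count)
    }, numeric(2))
    rowMeans(out)
  }
  low <- stats_at(60); high <- stats_at(110)
  expect_lt(low[1], high[1])       # shorter cycle at low FEV1
  expect_gt(low[2], high[2])       # more breaths at low FEV1
})

test_that("cohort generation is seeded-deterministic and validates inputs", {
  p <- small_params(seed = 77)
  a <- generate_cohort(p, 4, 10, audio = "memory")
  b <- generate_cohort(p, 4, 10, audio = "memory")
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$labels, b$labels)
  expect_identical(a$waveforms, b$waveforms)
  expect_error(generate_cohort(p, 0, 10), "n_subjects")
  expect_error(generate_cohort(p, 5, 3), "n_subjects")
})

test_that("cohort FEV1% distribution matches the study shape", {
  m <- generate_cohort(generative_params(seed = 12), 26, 323,
                       audio = "none")$manifest
  expect_equal(nrow(m), 323)
  expect_equal(length(unique(m$subject_id)), 26)
  expect_equal(sum(m$fev1_pct <= 50), 0)
  frac <- mean(m$fev1_pct > 80)
  expect_gte(frac, 0.67); expect_lte(frac, 0.77)
  h <- hist(m$fev1_pct, breaks = seq(50, 125, 5), plot = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  expect_gte(mode_mid, 95.5); expect_lte(mode_mid, 105)
  expect_true(all(m$height_cm >= 140 & m$height_cm <= 200))
  expect_true(all(m$weight_kg >= 40 & m$weight_kg <= 120))
  expect_true(all(m$sex %in% c(0, 1)))
})

test_that("subjects carry repeated measurements trending down from baseline", {
  co <- small_cohort()
  for (sid in unique(co$manifest$subject_id)) {
    v <- co$manifest$fev1_pct[co$manifest$subject_id == sid]
    expect_true(!is.unsorted(rev(v)))          # decreasing within subject
    expect_equal(co$subjects$baseline_fev1[co$subjects$subject_id == sid],
                 max(v))
  }
})

test_that("WAV round-trip and on-disk cohort reload preserve the data", {
  p <- small_params(seed = 31)
  x <- withr::with_seed(4, stats::runif(4000, -0.8, 0.8))
  f <- tempfile(fileext = ".wav")
  write_wav(x, f, 8000)
  back <- read_wav(f)
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$waveform, x, tolerance = 1e-4)   # 16-bit quantisation

  d <- tempfile("cohort")
  co <- generate_cohort(p, 2, 4, audio = "memory", dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- read_cohort(d, p)
  expect_equal(back$manifest$fev1_pct, co$manifest$fev1_pct)
  expect_equal(back$labels[[1]]$kind, co$labels[[1]]$kind)
  expect_equal(render_recording(back, 1), co$waveforms[[1]],
               tolerance = 2e-4)
  # re-rendering from the stored seed reproduces the waveform exactly
  co2 <- generate_cohort(p, 2, 4, audio = "none")
  expect_identical(render_recording(co2, 3), co$waveforms[[3]])
  unlink(d, recursive = TRUE)
})
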