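# Small shared fixtures: an 8 kHz, 8 s cohort keeps unit tests fast while
# exercising every stage; full-rate cohorts are built where a test needs
# the default study conditions.

small_params <- function(seed = 101L, ...) {
  generative_params(sample_rate = 8000, recording_s = 8, seed = seed, ...)
}

small_grid <- function() frame_grid(sample_rate = 8000)

# Built once per test run and reused read-only.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(small_params(), n_subjects = 8,
                                n_recordings = 44, audio = "none")
    cache
  }
})

small_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- analyze_cohort(small_cohort(), small_grid(), seed = 11L)
    cache
  }
})

# Brute-force O(N^2) one-sided DFT magnitudes of a windowed frame.
dft_oracle <- function(frame, window) {
  n <- length(frame)
  xw <- frame * window
  k <- 0:(n %/% 2)
  vapply(k, function(kk)
    abs(sum(xw * exp(-2i * pi * kk * (0:(n - 1)) / n))), numeric(1))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Pooled segment recall over a list of truth/predicted segment pairs.
pooled_recall <- function(truths, preds, kind) {
  hits <- 0; total <- 0
  for (i in seq_along(truths)) {
    n_k <- sum(truths[[i]]$kind == kind)
    hits <- hits + segment_recall(truths[[i]], preds[[i]], kind) * n_k
    total <- total + n_k
  }
  hits / total
}
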