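#' Frame/hop analysis grid
#'
#' Defines the short-time analysis grid shared by all frame-level features.
#' Defaults (2048-sample Hann frames, 512-sample hop at 22050 Hz) give
#' ~93 ms frames every ~23 ms, the conventional grid for speech-band
#' spectral features.
#'
#' @param frame_length Frame length in samples.
#' @param hop_length Hop between successive frame starts, in samples.
#' @param sample_rate Sampling rate in Hz.
#' @param window Taper: `"hann"` or `"rect"`.
#' @return A `frame_grid` list.
#' @export
frame_grid <- function(frame_length = 2048L, hop_length = 512L,
                       sample_rate = 22050, window = c("hann", "rect")) {
  window <- match.arg(window)
  frame_length <- as.integer(frame_length)
  hop_length <- as.integer(hop_length)
  stopifnot(frame_length >= 2L, hop_length >= 1L, hop_length <= frame_length,
            sample_rate > 0)
  structure(list(frame_length = frame_length, hop_length = hop_length,
                 sample_rate = sample_rate, window = window),
            class = "frame_grid")
}

window_taper <- function(grid) {
  n <- grid$frame_length
  switch(grid$window,
         hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n),  # periodic Hann
         rect = rep(1, n))
}

# Slice a (centre-padded) waveform into a frame_length x n_frames matrix.
frame_matrix <- function(waveform, grid, centre = TRUE) {
  if (length(waveform) < 1) stop("empty waveform")
  if (!all(is.finite(waveform))) stop("waveform contains non-finite samples")
  fl <- grid$frame_length
  hop <- grid$hop_length
  if (centre) waveform <- c(numeric(fl %/% 2L), waveform, numeric(fl %/% 2L))
  n <- length(waveform)
  if (n < fl) waveform <- c(waveform, numeric(fl - n))
  n_frames <- 1L + (length(waveform) - fl) %/% hop
  idx <- rep.int(seq_len(fl), n_frames) +
    rep((seq_len(n_frames) - 1L) * hop, each = fl)
  matrix(waveform[idx], nrow = fl)
}

#' Short-time Fourier magnitude spectrogram
#'
#' Frames the waveform on `grid` (centre-padded with zeros by default, so
#' frame `i` is centred at `i * hop / sample_rate` seconds), applies the
#' window taper, and returns one-sided DFT magnitudes.
#'
#' @param waveform Numeric sample vector.
#' @param grid A [frame_grid()].
#' @param centre Centre-pad the waveform by half a frame on each side.
#' @return Numeric matrix, `frame_length/2 + 1` frequency bins (rows) by
#'   frames (columns).
#' @export
stft_magnitude <- function(waveform, grid = frame_grid(), centre = TRUE) {
  fr <- frame_matrix(waveform, grid, centre) * window_taper(grid)
  n_bins <- grid$frame_length %/% 2L + 1L
  abs(stats::mvfft(fr))[seq_len(n_bins), , drop = FALSE]
}

#' Bin centre frequencies for a grid's one-sided spectrum
#' @param grid A [frame_grid()].
#' @return Numeric vector of length `frame_length/2 + 1`, in Hz.
#' @export
grid_frequencies <- function(grid) {
  (0:(grid$frame_length %/% 2L)) * grid$sample_rate / grid$frame_length
}

#' Frame centre times
#' @param n_frames Number of frames.
#' @param grid A [frame_grid()].
#' @return Times in seconds: `(i - 1) * hop / sample_rate`.
#' @export
frame_times <- function(n_frames, grid) {
  (seq_len(n_frames) - 1L) * grid$hop_length / grid$sample_rate
}

#' Time-domain frame features: RMS, mean amplitude, zero-crossing rate
#'
#' Computed on unwindowed frames. The zero-crossing rate is the number of
#' strict sign changes between consecutive samples divided by
#' `frame_length - 1`.
#'
#' @inheritParams stft_magnitude
#' @return Tibble with columns `times`, `rms`, `mean_amp`, `zcr`.
#' @export
frame_time_features <- function(waveform, grid = frame_grid(), centre = TRUE) {
  fr <- frame_matrix(waveform, grid, centre)
  fl <- grid$frame_length
  rms <- sqrt(colMeans(fr^2))
  mean_amp <- colMeans(abs(fr))
  zcr <- colSums(fr[-1L, , drop = FALSE] * fr[-fl, , drop = FALSE] < 0) / (fl - 1L)
  tibble::tibble(times = frame_times(ncol(fr), grid),
                 rms = rms, mean_amp = mean_amp, zcr = zcr)
}

#' Spectral frame features from a magnitude spectrogram
#'
#' Per frame: spectral centroid, bandwidth (magnitude-weighted spread),
#' roll-off at 85% and 95% of total magnitude, spectral flatness
#' (geometric/arithmetic mean ratio of the power spectrum), and spectral
#' contrast (mean over octave sub-bands of the top-minus-bottom quantile
#' difference in dB magnitude).
#'
#' An all-zero frame yields centroid, bandwidth and roll-offs of 0 and
#' flatness 1 (the epsilon-floor convention for silence).
#'
#' @param spectrogram Non-negative matrix from [stft_magnitude()].
#' @param grid The [frame_grid()] the spectrogram was computed on.
#' @param rolloff_q Roll-off fractions.
#' @param contrast_alpha Quantile fraction of band bins averaged at each
#'   extreme (at least one bin).
#' @param contrast_fmin Lower edge of the first contrast octave band, Hz.
#' @param contrast_bands Number of octave sub-bands.
#' @param eps Amplitude floor used inside logarithms.
#' @return Tibble with columns `centroid`, `bandwidth`, `rolloff85`,
#'   `rolloff95`, `flatness`, `contrast` (one row per frame).
#' @export
frame_spectral_features <- function(spectrogram, grid = frame_grid(),
                                    rolloff_q = c(0.85, 0.95),
                                    contrast_alpha = 0.02,
                                    contrast_fmin = 200,
                                    contrast_bands = 6L,
                                    eps = 1e-10) {
  if (any(spectrogram < 0)) stop("spectrogram must be non-negative")
  S <- spectrogram
  f <- grid_frequencies(grid)
  stopifnot(nrow(S) == length(f))
  tot <- colSums(S)
  ok <- tot > 0
  safe_tot <- ifelse(ok, tot, 1)

  centroid <- ifelse(ok, colSums(S * f) / safe_tot, 0)
  m2 <- colSums(S * f^2) / safe_tot
  bandwidth <- ifelse(ok, sqrt(pmax(m2 - centroid^2, 0)), 0)

  v <- cumsum(as.vector(S))        # column-wise cumsum without per-column calls
  off <- c(0, v[seq_len(ncol(S) - 1L) * nrow(S)])
  cum <- matrix(v, nrow(S)) - rep(off, each = nrow(S))
  rolloff <- vapply(rolloff_q, function(q) {
    k <- colSums(cum < rep(q * tot, each = nrow(S))) + 1L
    ifelse(ok, f[pmin(k, length(f))], 0)
  }, numeric(ncol(S)))
  if (is.null(dim(rolloff))) rolloff <- matrix(rolloff, nrow = 1L)

  P <- S^2
  flatness <- pmin(exp(colMeans(log(P + eps^2))) / (colMeans(P) + eps^2), 1)

  edges <- contrast_fmin * 2^(0:contrast_bands)
  edges[length(edges)] <- max(edges[length(edges)], grid$sample_rate / 2)
  logS <- 20 * log10(S + eps)
  band_diffs <- lapply(seq_len(contrast_bands), function(b) {
    bins <- which(f > edges[b] & f <= edges[b + 1L])
    if (length(bins) < 2L) return(NULL)
    nb <- length(bins)
    k <- max(1L, ceiling(contrast_alpha * nb))
    sub <- logS[bins, , drop = FALSE]
    o <- order(rep(seq_len(ncol(sub)), each = nb), sub, method = "radix")
    srt <- matrix(sub[o], nb)        # each column sorted ascending
    colMeans(srt[(nb - k + 1L):nb, , drop = FALSE]) -
      colMeans(srt[seq_len(k), , drop = FALSE])
  })
  band_diffs <- band_diffs[!vapply(band_diffs, is.null, logical(1))]
  contrast <- if (length(band_diffs)) rowMeans(do.call(cbind, band_diffs)) else
    rep(0, ncol(S))

  tibble::tibble(centroid = centroid, bandwidth = bandwidth,
                 rolloff85 = rolloff[, 1L], rolloff95 = rolloff[, 2L],
                 flatness = flatness, contrast = contrast)
}

#' All frame-level features for one recording
#'
#' Combines [frame_time_features()] and [frame_spectral_features()] on a
#' shared centre-padded grid, so row `i` of the result describes the frame
#' centred at `times[i]` seconds.
#'
#' @inheritParams stft_magnitude
#' @param ... Passed on to [frame_spectral_features()].
#' @return Tibble with columns `times`, `rms`, `mean_amp`, `zcr`,
#'   `centroid`, `bandwidth`, `rolloff85`, `rolloff95`, `flatness`,
#'   `contrast`.
#' @export
frame_features <- function(waveform, grid = frame_grid(), centre = TRUE, ...) {
  fr <- frame_matrix(waveform, grid, centre)     # shared by both paths
  fl <- grid$frame_length
  tf <- tibble::tibble(
    times = frame_times(ncol(fr), grid),
    rms = sqrt(colMeans(fr^2)),
    mean_amp = colMeans(abs(fr)),
    zcr = colSums(fr[-1L, , drop = FALSE] * fr[-fl, , drop = FALSE] < 0) /
      (fl - 1L))
  S <- abs(stats::mvfft(fr * window_taper(grid)))[seq_len(fl %/% 2L + 1L), ,
                                                  drop = FALSE]
  sf <- frame_spectral_features(S, grid, ...)
  tibble::as_tibble(cbind(tf, sf))
}
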