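#' The five discriminative features used for breath/speech separation
#' @return Character vector of feature names.
#' @export
discriminative_features <- function() {
  c("contrast", "rolloff95", "rms", "bandwidth", "mean_amp")
}

#' Calibrate breath/speech threshold rules from labelled exemplar frames
#'
#' For each discriminative feature, the threshold is the midpoint of the
#' breath-class and speech-class medians, and the breath side records which
#' side of the threshold the breath median falls on. Median midpoints are
#' robust to the heavy-tailed amplitude features. A feature whose class
#' medians coincide carries no signal and is dropped with a warning; fewer
#' than three usable rules is a calibration failure.
#'
#' @param exemplar_frames Tibble of frame features (see [frame_features()])
#'   with an added `kind` column in `{"breath", "speech"}`; at least 3
#'   frames of each kind.
#' @param features Candidate features; defaults to the discriminative five.
#' @return Tibble of rules: `feature`, `threshold`, `breath_side`
#'   (`"below"` or `"above"`).
#' @export
calibrate_thresholds <- function(exemplar_frames,
                                 features = discriminative_features()) {
  stopifnot(all(c(features, "kind") %in% names(exemplar_frames)))
  kind <- exemplar_frames$kind
  if (sum(kind == "breath") < 3 || sum(kind == "speech") < 3)
    stop("need at least 3 breath-labelled and 3 speech-labelled frames")
  rules <- lapply(features, function(f) {
    mb <- stats::median(exemplar_frames[[f]][kind == "breath"])
    ms <- stats::median(exemplar_frames[[f]][kind == "speech"])
    if (mb == ms) {
      warning("feature '", f, "' has identical class medians; excluded")
      return(NULL)
    }
    tibble::tibble(feature = f, threshold = (mb + ms) / 2,
                   breath_side = if (mb < ms) "below" else "above")
  })
  rules <- do.call(rbind, rules[!vapply(rules, is.null, logical(1))])
  if (is.null(rules) || nrow(rules) < 3)
    stop("calibration failure: fewer than 3 usable threshold rules")
  rules
}

#' Classify frames as breath or speech by threshold vote
#'
#' A frame is labelled breath iff at least `min_votes` of the rules place
#' it strictly on their breath side; otherwise speech. The vote is monotone:
#' moving a frame's features toward the breath side of every rule can never
#' flip breath to speech.
#'
#' @param frames Tibble of frame features containing every rule's feature.
#' @param rules Rule tibble from [calibrate_thresholds()].
#' @param min_votes Vote quorum (default 3; at most `nrow(rules)`).
#' @return Character vector, `"breath"` or `"speech"` per frame.
#' @export
classify_frames <- function(frames, rules, min_votes = 3L) {
  if (nrow(frames) == 0) stop("empty frame matrix")
  if (min_votes > nrow(rules))
    stop("min_votes (", min_votes, ") exceeds the number of rules (",
         nrow(rules), ")")
  on_side <- vapply(seq_len(nrow(rules)), function(j) {
    x <- frames[[rules$feature[j]]]
    if (rules$breath_side[j] == "below") x < rules$threshold[j]
    else x > rules$threshold[j]
  }, logical(nrow(frames)))
  votes <- rowSums(matrix(on_side, nrow = nrow(frames)))
  ifelse(votes >= min_votes, "breath", "speech")
}

rle_segments <- function(kinds) {
  r <- rle(kinds)
  ends <- cumsum(r$lengths)
  tibble::tibble(first = c(1L, utils::head(ends, -1L) + 1L), last = ends,
                 kind = r$values)
}

#' Smooth frame labels into contiguous breath/speech segments
#'
#' Median-filters the frame labels, run-length encodes them, absorbs runs
#' shorter than `min_gap_s` flanked by the opposite kind, then merges any
#' remaining run shorter than `min_seg_s` into its preceding neighbour.
#' Segment boundaries fall on frame-start times (`(i-1) * hop /
#' sample_rate`); the final segment is extended to `duration_s`, so the
#' output always partitions `[0, duration_s]`.
#'
#' @param frame_kinds Character vector of per-frame kinds.
#' @param grid The [frame_grid()] the frames were computed on.
#' @param median_width Median filter width in frames (odd).
#' @param min_gap_s Gaps shorter than this are absorbed, seconds.
#' @param min_seg_s Minimum surviving segment duration, seconds.
#' @param duration_s Recording duration; defaults to the span of the grid.
#' @return Tibble of segments: `start_s`, `end_s`, `kind`, ordered,
#'   non-overlapping, alternating kinds.
#' @export
frames_to_segments <- function(frame_kinds, grid = frame_grid(),
                               median_width = 5L, min_gap_s = 0.10,
                               min_seg_s = 0.15, duration_s = NULL) {
  n <- length(frame_kinds)
  if (n == 0) stop("empty frame_kinds")
  spf <- grid$hop_length / grid$sample_rate       # seconds per frame hop
  if (is.null(duration_s)) duration_s <- n * spf
  x <- as.integer(frame_kinds == "breath")
  if (median_width > 1L && n > median_width)
    x <- as.integer(stats::runmed(x, k = 2L * (median_width %/% 2L) + 1L))
  kinds <- ifelse(x == 1L, "breath", "speech")

  runs <- rle_segments(kinds)
  repeat {
    len_s <- (runs$last - runs$first + 1L) * spf
    gap <- which(len_s < min_gap_s &
                   seq_len(nrow(runs)) > 1L & seq_len(nrow(runs)) < nrow(runs))
    gap <- gap[runs$kind[gap - 1L] == runs$kind[gap + 1L]]
    if (length(gap)) {
      kinds[runs$first[gap[1L]]:runs$last[gap[1L]]] <- runs$kind[gap[1L] - 1L]
    } else {
      short <- which(len_s < min_seg_s)
      if (!length(short) || nrow(runs) == 1L) break
      i <- short[1L]
      j <- if (i > 1L) i - 1L else i + 1L
      kinds[runs$first[i]:runs$last[i]] <- runs$kind[j]
    }
    runs <- rle_segments(kinds)
  }
  start <- (runs$first - 1L) * spf
  end <- c(start[-1L], duration_s)
  tibble::tibble(start_s = start, end_s = pmax(end, start), kind = runs$kind)
}

#' Breath-cycle statistics of a segment set
#'
#' The breath cycle duration is the interval between onsets of successive
#' breath segments; with fewer than two breath segments it is `NA`.
#'
#' @param segments Tibble with `start_s`, `end_s`, `kind`.
#' @return List: `mean_cycle_s`, `breath_count`, `speech_count`,
#'   `breath_total_s`, `speech_total_s`.
#' @export
breath_cycle_stats <- function(segments) {
  b <- segments$kind == "breath"
  onsets <- segments$start_s[b]
  durs <- segments$end_s - segments$start_s
  list(mean_cycle_s = if (sum(b) >= 2L) mean(diff(onsets)) else NA_real_,
       breath_count = sum(b),
       speech_count = sum(!b),
       breath_total_s = sum(durs[b]),
       speech_total_s = sum(durs[!b]))
}

#' Segment-level recall against a reference segmentation
#'
#' A reference segment counts as recovered when at least `coverage` of its
#' duration is overlapped by predicted segments of the same kind.
#'
#' @param truth,predicted Segment tibbles (`start_s`, `end_s`, `kind`).
#' @param kind Which kind to score.
#' @param coverage Minimum covered fraction (default 0.5).
#' @return Recall in `[0, 1]` (`NaN` if the reference has no such segment).
#' @export
segment_recall <- function(truth, predicted, kind, coverage = 0.5) {
  tr <- truth[truth$kind == kind, ]
  pr <- predicted[predicted$kind == kind, ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    ov <- pmax(0, pmin(tr$end_s[i], pr$end_s) - pmax(tr$start_s[i], pr$start_s))
    sum(ov) >= coverage * (tr$end_s[i] - tr$start_s[i])
  }, logical(1))
  mean(hit)
}

#' Serialise / read threshold rules as JSON
#' @param rules Rule tibble from [calibrate_thresholds()].
#' @param path JSON file path.
#' @return `path` (write) or the rule tibble (read).
#' @export
write_threshold_rules <- function(rules, path) {
  jsonlite::write_json(rules, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_threshold_rules
#' @export
read_threshold_rules <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
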