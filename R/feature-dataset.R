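#' Canonical recording-level feature schema
#'
#' The 23 acoustic features of one recording: mean over breath frames and
#' mean over speech frames of each of the nine frame-level descriptors
#' (18), plus breath/speech segment counts and total durations, plus the
#' mean breath cycle duration. With biological covariates appended the
#' vector has 26 entries.
#'
#' @param biological Include `sex`, `height_cm`, `weight_kg`.
#' @return Character vector of feature names in canonical order.
#' @export
feature_schema <- function(biological = FALSE) {
  base <- c("rms", "mean_amp", "zcr", "centroid", "bandwidth",
            "rolloff85", "rolloff95", "flatness", "contrast")
  nm <- c(paste0("breath_", base), paste0("speech_", base),
          "breath_count", "speech_count", "breath_total_s", "speech_total_s",
          "mean_breath_cycle_s")
  if (biological) nm <- c(nm, "sex", "height_cm", "weight_kg")
  nm
}

#' Aggregate frame features over a segmentation into one recording vector
#'
#' Each frame is assigned the kind of the segment containing its centre
#' time; per-kind means are taken over the nine frame descriptors, and
#' counts/durations come from [breath_cycle_stats()]. A kind with no frames
#' yields `NA` for its means (imputed downstream).
#'
#' @param frames Frame-feature tibble from [frame_features()].
#' @param segments Segment tibble for the same recording.
#' @return One-row tibble with the 23 columns of [feature_schema()].
#' @export
aggregate_recording_features <- function(frames, segments) {
  kind <- kind_at_times(frames$times, segments)
  base <- c("rms", "mean_amp", "zcr", "centroid", "bandwidth",
            "rolloff85", "rolloff95", "flatness", "contrast")
  means_for <- function(k) {
    sel <- kind == k
    vapply(base, function(f)
      if (any(sel)) mean(frames[[f]][sel]) else NA_real_, numeric(1))
  }
  st <- breath_cycle_stats(segments)
  out <- c(means_for("breath"), means_for("speech"),
           breath_count = st$breath_count, speech_count = st$speech_count,
           breath_total_s = st$breath_total_s,
           speech_total_s = st$speech_total_s,
           mean_breath_cycle_s = st$mean_cycle_s)
  names(out) <- feature_schema()
  tibble::as_tibble(as.list(out))
}

#' Append biological covariates to a recording feature vector
#' @param vector One-row tibble from [aggregate_recording_features()].
#' @param subject One-row tibble/list with `sex` (0/1), `height_cm`,
#'   `weight_kg`.
#' @return One-row tibble with 26 columns ([feature_schema()] with
#'   `biological = TRUE`).
#' @export
attach_biological <- function(vector, subject) {
  stopifnot(all(c("sex", "height_cm", "weight_kg") %in% names(subject)))
  vector$sex <- as.numeric(subject$sex)
  vector$height_cm <- as.numeric(subject$height_cm)
  vector$weight_kg <- as.numeric(subject$weight_kg)
  vector
}

#' Min-max normalisation fitted on training rows
#'
#' `minmax_fit()` records per-column minima and maxima from the training
#' rows only; `minmax_apply()` maps `x` to `(x - min) / (max - min)`
#' without clipping, so test values may fall outside `[0, 1]`. A constant
#' training column maps to 0 everywhere. `minmax_invert()` undoes the map.
#'
#' @param x Data frame or matrix of numeric features.
#' @param fit Fit object from `minmax_fit()`.
#' @return `minmax_fit()`: tibble `feature`, `min`, `max`; the others: a
#'   tibble shaped like `x`.
#' @export
minmax_fit <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) == 0) stop("empty training set")
  tibble::tibble(
    feature = names(x),
    min = unname(vapply(x, function(v) min(v, na.rm = TRUE), numeric(1))),
    max = unname(vapply(x, function(v) max(v, na.rm = TRUE), numeric(1))))
}

#' @rdname minmax_fit
#' @export
minmax_apply <- function(x, fit) {
  x <- as.data.frame(x)
  stopifnot(all(fit$feature %in% names(x)))
  for (j in seq_len(nrow(fit))) {
    rng <- fit$max[j] - fit$min[j]
    v <- x[[fit$feature[j]]]
    x[[fit$feature[j]]] <- if (rng > 0) (v - fit$min[j]) / rng else v * 0
  }
  tibble::as_tibble(x)
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(x, fit) {
  x <- as.data.frame(x)
  for (j in seq_len(nrow(fit))) {
    rng <- fit$max[j] - fit$min[j]
    if (rng > 0)
      x[[fit$feature[j]]] <- x[[fit$feature[j]]] * rng + fit$min[j]
    else x[[fit$feature[j]]] <- x[[fit$feature[j]]] + fit$min[j]
  }
  tibble::as_tibble(x)
}

#' Binary lung-function label
#'
#' Normal iff FEV1% is strictly greater than 80; 80.0 itself is abnormal.
#'
#' @param fev1_pct Numeric FEV1% values (finite, > 0).
#' @return Factor with levels `normal`, `abnormal`.
#' @export
label_binary <- function(fev1_pct) {
  if (any(!is.finite(fev1_pct)) || any(fev1_pct <= 0))
    stop("fev1_pct must be finite and positive")
  factor(ifelse(fev1_pct > 80, "normal", "abnormal"),
         levels = c("normal", "abnormal"))
}

#' Default severity boundary table
#'
#' Lower FEV1% bounds of each grade below normal; normal is FEV1% > 80,
#' mild is `[70, 80]`, then each grade is `[lower, next)` going down.
#'
#' @return Named numeric vector of lower bounds, decreasing.
#' @export
ats_boundaries <- function() {
  c(mild = 70, moderate = 60, moderately_severe = 50, severe = 35,
    very_severe = -Inf)
}

#' Ordinal severity grade of lung-function abnormality
#'
#' @param fev1_pct Numeric FEV1% values (finite, > 0).
#' @param boundaries Named decreasing lower bounds for the abnormal grades
#'   (see [ats_boundaries()]); values above 80 are `normal`.
#' @return Ordered factor from most severe to `normal`.
#' @export
label_ats_grade <- function(fev1_pct, boundaries = ats_boundaries()) {
  if (any(!is.finite(fev1_pct)) || any(fev1_pct <= 0))
    stop("fev1_pct must be finite and positive")
  stopifnot(!is.unsorted(rev(boundaries)))
  lv <- c(rev(names(boundaries)), "normal")
  grade <- ifelse(fev1_pct > 80, "normal",
                  names(boundaries)[pmax(1L,
                    length(boundaries) + 1L -
                      findInterval(fev1_pct, rev(boundaries)))])
  factor(grade, levels = lv, ordered = TRUE)
}

#' Pearson correlation of each feature with FEV1%
#'
#' @param x Data frame of features (rows = recordings).
#' @param fev1_pct FEV1% per row.
#' @return Tibble `feature`, `r`, `p` (two-sided); `NA` for constant
#'   features.
#' @export
feature_fev1_correlations <- function(x, fev1_pct) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(fev1_pct))
  rows <- lapply(names(x), function(f) {
    ok <- is.finite(x[[f]]) & is.finite(fev1_pct)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for feature ", f)
    if (stats::sd(x[[f]][ok]) == 0)
      return(tibble::tibble(feature = f, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x[[f]][ok], fev1_pct[ok])
    tibble::tibble(feature = f, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

fev1_bins <- function(fev1_pct, bin_width = 5, lo = 50, hi = 125) {
  if (any(fev1_pct <= lo) || any(fev1_pct > hi))
    warning("FEV1% values outside (", lo, ", ", hi, "] assigned to edge bins")
  edges <- seq(lo, hi, by = bin_width)
  b <- findInterval(pmin(pmax(fev1_pct, lo + 1e-9), hi), edges,
                    rightmost.closed = FALSE, left.open = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Train/test partition of recordings, balanced over FEV1% bins or random
#'
#' Balanced mode groups recordings into half-open 5-point FEV1% bins
#' ((50, 55], (55, 60], ... printed as "51-55", "56-60", ...) and splits
#' each bin separately, so train and test share the FEV1% distribution to
#' within one sample per bin. Within a bin of size n, `floor(0.7 n + 0.5)`
#' recordings go to train (ties toward train; singletons train). Random
#' mode is one global seeded shuffle at the same fraction.
#'
#' @param fev1_pct FEV1% per recording.
#' @param ids Recording identifiers (default row indices).
#' @param train_fraction Training fraction (default 0.7).
#' @param bin_width Bin width in FEV1% points (balanced mode).
#' @param mode `"balanced"` or `"random"`.
#' @param seed Integer seed for the shuffles.
#' @return A `partition_spec` list: `mode`, `seed`, `train_fraction`,
#'   `bin_width`, `bin` (per id), `train_ids`, `test_ids`.
#' @export
make_partition <- function(fev1_pct, ids = seq_along(fev1_pct),
                           train_fraction = 0.7, bin_width = 5,
                           mode = c("balanced", "random"), seed = 1L) {
  mode <- match.arg(mode)
  n <- length(fev1_pct)
  if (n == 0) stop("empty dataset")
  stopifnot(length(ids) == n)
  n_train_of <- function(m) as.integer(floor(train_fraction * m + 0.5))
  bins <- fev1_bins(fev1_pct, bin_width)
  train <- withr::with_seed(seed, {
    if (mode == "random") {
      ord <- sample.int(n)
      ids[ord[seq_len(n_train_of(n))]]
    } else {
      unlist(lapply(sort(unique(bins)), function(b) {
        member <- ids[bins == b]
        member <- member[sample.int(length(member))]
        member[seq_len(max(1L, n_train_of(length(member))))]
      }), use.names = FALSE)
    }
  })
  structure(list(mode = mode, seed = as.integer(seed),
                 train_fraction = train_fraction, bin_width = bin_width,
                 bin = bins, ids = ids,
                 train_ids = ids[ids %in% train],
                 test_ids = ids[!ids %in% train]),
            class = "partition_spec")
}

#' Serialise / read a partition as JSON
#' @param partition A `partition_spec` from [make_partition()].
#' @param path JSON file path.
#' @return `path` (write) or a `partition_spec` (read).
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "partition_spec")
}

#' Impute missing feature values from training-row medians
#'
#' Recordings in which no segment of one kind was detected have `NA` for
#' that kind's features; these are filled with the per-column median over
#' the training rows (an `NA`-free training column passes through).
#'
#' @param x Feature data frame.
#' @param train_rows Logical or integer index of training rows.
#' @return List: `x` (imputed tibble), `imputed` (named count of filled
#'   cells per column).
#' @export
impute_from_train <- function(x, train_rows) {
  x <- as.data.frame(x)
  counts <- integer(0)
  for (f in names(x)) {
    miss <- !is.finite(x[[f]])
    if (any(miss)) {
      med <- stats::median(x[[f]][train_rows], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      x[[f]][miss] <- med
      counts[f] <- sum(miss)
    }
  }
  list(x = tibble::as_tibble(x), imputed = counts)
}
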