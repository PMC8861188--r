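toy_frames <- function() {
  # 6 frames at 0.5 s spacing; constant blocks make hand averages easy
  tibble::tibble(
    times = seq(0, 2.5, by = 0.5),
    rms = c(1, 1, 4, 4, 4, 4) / 10,
    mean_amp = c(2, 2, 6, 6, 6, 6) / 10,
    zcr = c(0.5, 0.5, 0.1, 0.1, 0.1, 0.1),
    centroid = c(4000, 4000, 800, 800, 800, 800),
    bandwidth = c(3000, 3000, 500, 500, 500, 500),
    rolloff85 = c(7000, 7000, 1500, 1500, 1500, 1500),
    rolloff95 = c(9000, 9000, 2000, 2000, 2000, 2000),
    flatness = c(0.8, 0.8, 0.02, 0.02, 0.02, 0.02),
    contrast = c(20, 20, 60, 60, 60, 60))
}

toy_segments <- tibble::tibble(start_s = c(0, 0.8), end_s = c(0.8, 3),
                               kind = c("breath", "speech"))

test_that("recording aggregation means frames per segment kind", {
  v <- aggregate_recording_features(toy_frames(), toy_segments)
  expect_named(v, feature_schema())
  expect_equal(ncol(v), 23)
  expect_equal(v$breath_rms, 0.1)        # frames at 0.0, 0.5 s
  expect_equal(v$speech_rms, 0.4)        # frames at 1.0 .. 2.5 s
  expect_equal(v$breath_centroid, 4000)
  expect_equal(v$speech_contrast, 60)
  expect_equal(v$breath_count, 1)
  expect_equal(v$speech_count, 1)
  expect_equal(v$breath_total_s, 0.8)
  expect_equal(v$speech_total_s, 2.2)
  expect_true(is.na(v$mean_breath_cycle_s))   # single breath segment
})

test_that("a kind with no segments yields missing means", {
  seg <- tibble::tibble(start_s = 0, end_s = 3, kind = "speech")
  v <- aggregate_recording_features(toy_frames(), seg)
  expect_true(is.na(v$breath_rms))
  expect_equal(v$breath_count, 0)
  expect_equal(v$speech_rms, mean(toy_frames()$rms))
})

test_that("biological covariates append in fixed order", {
  v <- aggregate_recording_features(toy_frames(), toy_segments)
  subj <- list(sex = 1, height_cm = 178, weight_kg = 81)
  v26 <- attach_biological(v, subj)
  expect_named(v26, feature_schema(biological = TRUE))
  expect_equal(ncol(v26), 26)
  v26b <- attach_biological(v, list(sex = 1, height_cm = 150, weight_kg = 81))
  expect_equal(v26$weight_kg, v26b$weight_kg)
  expect_false(v26$height_cm == v26b$height_cm)
  expect_equal(v26[, 1:24], v26b[, 1:24])
})

test_that("min-max normalisation fits on train and never clips", {
  fit <- minmax_fit(data.frame(a = c(2, 4, 10), b = c(1, 1, 1)))
  expect_equal(fit$min[fit$feature == "a"], 2)
  expect_equal(fit$max[fit$feature == "a"], 10)
  out <- minmax_apply(data.frame(a = c(4, 12), b = c(1, 7)), fit)
  expect_equal(out$a, c(0.25, 1.25))        # test value unclipped
  expect_equal(out$b, c(0, 0))              # constant train column -> 0
  expect_error(minmax_fit(data.frame(a = numeric(0))), "empty")

  set.seed(2)
  x <- data.frame(u = rnorm(20), v = runif(20, 5, 9))
  fit <- minmax_fit(x)
  expect_equal(as.data.frame(minmax_invert(minmax_apply(x, fit), fit)), x,
               tolerance = 1e-12)
})

test_that("binary and severity labels agree across the boundary sweep", {
  sweep <- c(34.9, 35, 49.9, 50, 59.9, 60, 69.9, 70, 79.9, 80, 80.1)
  bin <- label_binary(sweep)
  expect_equal(as.character(bin),
               c(rep("abnormal", 10), "normal"))
  grade <- label_ats_grade(sweep)
  expect_equal(as.character(grade),
               c("very_severe", "severe", "severe", "moderately_severe",
                 "moderately_severe", "moderate", "moderate", "mild",
                 "mild", "mild", "normal"))
  expect_equal(grade == "normal", bin == "normal")
  expect_error(label_binary(c(90, NA)), "finite")
  expect_error(label_ats_grade(Inf), "finite")
})

test_that("feature-FEV1 correlations behave at the extremes", {
  set.seed(4)
  fev1 <- runif(323, 51, 125)
  x <- data.frame(same = fev1, flipped = -fev1, noise = rnorm(323),
                  const = rep(1, 323))
  ct <- feature_fev1_correlations(x, fev1)
  expect_equal(ct$r[ct$feature == "same"], 1)
  expect_equal(ct$r[ct$feature == "flipped"], -1)
  expect_lt(abs(ct$r[ct$feature == "noise"]), 0.15)
  expect_true(is.na(ct$r[ct$feature == "const"]))
  expect_error(feature_fev1_correlations(data.frame(a = 1:2), c(1, 2)),
               "fewer than 3")
})

test_that("balanced partitioning splits each FEV1 bin at 70:30", {
  fev1 <- c(runif(10, 50.5, 55), runif(20, 55.5, 60))
  part <- make_partition(fev1, mode = "balanced", seed = 9)
  expect_equal(length(part$train_ids), 21)     # 7 + 14
  expect_equal(length(part$test_ids), 9)       # 3 + 6
  for (b in unique(part$bin)) {
    ids_b <- which(part$bin == b)
    expect_equal(sum(part$train_ids %in% ids_b),
                 floor(0.7 * length(ids_b) + 0.5))
  }
  # 52 falls in the first bin, (50, 55]
  expect_equal(make_partition(c(52, 52, 57), seed = 1)$bin[1], 1L)

  # singleton bin goes to train
  p1 <- make_partition(c(52, runif(10, 60.5, 65)), seed = 2)
  expect_true(1 %in% p1$train_ids)
})

test_that("partitions are disjoint covers and seed-reproducible", {
  set.seed(10)
  fev1 <- sample_fev1(100)
  for (mode in c("balanced", "random")) {
    p <- make_partition(fev1, mode = mode, seed = 33)
    expect_length(intersect(p$train_ids, p$test_ids), 0)
    expect_setequal(c(p$train_ids, p$test_ids), seq_along(fev1))
    p2 <- make_partition(fev1, mode = mode, seed = 33)
    expect_identical(p$train_ids, p2$train_ids)
    p3 <- make_partition(fev1, mode = mode, seed = 34)
    expect_false(identical(p$train_ids, p3$train_ids))
  }
  expect_error(make_partition(numeric(0)), "empty")
  expect_warning(make_partition(c(45, 90, 130)), "edge bins")
})

test_that("partition JSON round trip is faithful", {
  p <- make_partition(sample_fev1(40), seed = 5)
  f <- tempfile(fileext = ".json")
  write_partition(p, f)
  back <- read_partition(f)
  expect_equal(back$train_ids, p$train_ids)
  expect_equal(back$test_ids, p$test_ids)
  expect_equal(back$mode, p$mode)
})

test_that("missing features impute from training medians only", {
  x <- data.frame(a = c(1, 2, 3, NA, 100), b = 1:5)
  out <- impute_from_train(x, train_rows = 1:3)
  expect_equal(out$x$a[4], 2)               # median of rows 1:3
  expect_equal(out$imputed[["a"]], 1L)
  expect_equal(out$x$b, 1:5)
})
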