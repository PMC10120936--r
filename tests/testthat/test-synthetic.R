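test_that("generators are pure functions of spec and seed", {
  s1 <- generate_squeal(squeal_spec(), seed = 7)
  s2 <- generate_squeal(squeal_spec(), seed = 7)
  expect_identical(s1$samples, s2$samples)
  s3 <- generate_squeal(squeal_spec(), seed = 8)
  expect_false(identical(s1$samples, s3$samples))

  p1 <- generate_fiber_phantom(fiber_phantom_spec(image_size_px = 128,
                                                  n_fibers = 30), seed = 3)
  p2 <- generate_fiber_phantom(fiber_phantom_spec(image_size_px = 128,
                                                  n_fibers = 30), seed = 3)
  expect_identical(p1$collagen, p2$collagen)
  expect_identical(p1$elastin, p2$elastin)

  # generation does not disturb the global RNG stream
  set.seed(123); before <- .Random.seed
  invisible(generate_squeal(squeal_spec(), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("squeals satisfy the squeal criteria and amplitude envelope", {
  sq <- generate_squeal(squeal_spec(duration_s = 0.8), seed = 4)
  rec_len <- length(sq$samples)
  expect_gte(rec_len / sq$sample_rate, 0.5)
  expect_true(validate_squeal(0, rec_len, sq))
  expect_lte(max(abs(sq$samples)), 32767)
  # sharp onset: peak of the first 50 ms exceeds the last 50 ms tail
  n <- round(0.05 * sq$sample_rate)
  expect_gt(max(abs(sq$samples[1:(4 * n)])), 4 * max(abs(sq$samples[(rec_len - n):rec_len])))
})

test_that("spectral tilt controls Q50/P60 and instability controls flux, monotonically", {
  fs <- 44100
  tilts <- c(-3, -6, -9, -12)
  q50s <- sapply(tilts, function(tl) {
    sq <- generate_squeal(squeal_spec(spectral_tilt_db_per_octave = tl), seed = 9)
    f <- compute_features(sq$samples, fs)
    c(f[["q50"]], f[["p60"]])
  })
  expect_true(all(diff(q50s[1, ]) < 0))   # q50 falls with steeper tilt
  expect_true(all(diff(q50s[2, ]) <= 0))  # p60 falls too

  insts <- c(0, 0.1, 0.35, 0.8)
  fx <- sapply(insts, function(ii) {
    sq <- generate_squeal(squeal_spec(frame_instability = ii), seed = 9)
    f <- compute_features(sq$samples, fs)
    c(f[["flux1"]], f[["flux2"]])
  })
  expect_true(all(diff(fx[1, ]) > 0))
  expect_true(all(diff(fx[2, ]) > 0))
})

test_that("cohorts carry the requested structure and segmentable audio", {
  spec <- cohort_spec(pig_ids = "pig_x",
                      recording_days = c(-14, -7, 1, 8),
                      squeals_per_day = 5)
  coh <- generate_cohort(spec, seed = 77)
  expect_equal(nrow(coh$labels), 20)
  expect_equal(sum(coh$labels$phase == "PRE"), 10)
  expect_equal(sum(coh$labels$phase == "POST_EARLY"), 10)
  expect_equal(length(coh$recordings), 4)

  # every labeled squeal validates and segmentation finds the bursts
  rec <- coh$recordings[[coh$labels$recording_id[1]]]
  lab1 <- coh$labels[coh$labels$recording_id == rec$source_id, ]
  for (i in seq_len(nrow(lab1))) {
    s0 <- round(lab1$start_s[i] * rec$sample_rate)
    s1 <- round(lab1$end_s[i] * rec$sample_rate)
    expect_true(validate_squeal(s0, s1, rec))
  }
  ev <- segment_events(rec, threshold = 500)
  expect_equal(nrow(ev), nrow(lab1))
})

test_that("recovery interpolation pulls late squeals back to the pre-surgery voice", {
  spec <- cohort_spec(pig_ids = "pig_r", recovery_model = "logistic",
                      recording_days = c(-16, -10, -3, 2, 8, 170, 190),
                      squeals_per_day = 8)
  coh <- generate_cohort(spec, seed = 88)
  ft <- cohort_feature_table(coh)
  med <- aggregate(q50 ~ phase, ft, median)
  q <- setNames(med$q50, med$phase)
  expect_lt(q[["POST_EARLY"]], q[["PRE"]])
  # POST_LATE back within the PRE interquartile range
  iqr <- quantile(ft$q50[ft$phase == "PRE"], c(0.25, 0.75))
  expect_gte(q[["POST_LATE"]], iqr[[1]])
  expect_lte(q[["POST_LATE"]], iqr[[2]])
})

test_that("phantom orientation statistics match their specification", {
  # near-degenerate concentration: histogram peak at the programmed angle
  ph <- generate_fiber_phantom(
    fiber_phantom_spec(image_size_px = 256, n_fibers = 120,
                       angular_sd_deg = 0.5, channel_offset_deg = 0,
                       mean_orientation_deg = 40), seed = 5)
  res <- analyze_channel(ph$collagen, ph$pixel_size_um)
  pk <- res$histogram$bin_centers[which.max(res$histogram$counts)]
  expect_lt(circ_err(pk, 40), 2.1)

  # kappa ordering: dispersion increases with programmed angular SD
  disps <- sapply(c(5, 10, 20, 40), function(sd) {
    p <- generate_fiber_phantom(
      fiber_phantom_spec(image_size_px = 320, n_fibers = 250,
                         angular_sd_deg = sd, channel_offset_deg = 0),
      seed = 6)
    analyze_channel(p$collagen, p$pixel_size_um)$fit$dispersion_deg
  })
  expect_true(all(diff(disps) > 0))
})

test_that("programmed channel offset is recovered by the full analysis", {
  ph <- generate_fiber_phantom(
    fiber_phantom_spec(angular_sd_deg = 15, channel_offset_deg = 6),
    seed = 21)
  expect_equal(ph$ground_truth$channel_offset_deg, 6)
  res <- analyze_sample(ph$collagen, ph$elastin, ph$pixel_size_um)
  expect_lt(abs(res$summary$alignment_difference_deg - 6), 2)
})

test_that("sub-threshold specks are removed by the particle filter", {
  sp <- fiber_phantom_spec(image_size_px = 320, n_fibers = 150,
                           angular_sd_deg = 10, channel_offset_deg = 0,
                           speck_density = 0.5)
  sp0 <- fiber_phantom_spec(image_size_px = 320, n_fibers = 150,
                            angular_sd_deg = 10, channel_offset_deg = 0,
                            speck_density = 0)
  ph <- generate_fiber_phantom(sp, seed = 13)
  ph0 <- generate_fiber_phantom(sp0, seed = 13)
  clean <- function(img) {
    f <- normalize_intensity(median_filter(img, 2))[[1]]
    remove_small_particles(otsu_threshold(f)$mask, 50, 0.5)
  }
  m <- clean(ph$collagen)
  m0 <- clean(ph0$collagen)
  expect_lt(mean(m != m0), 0.01)
})

test_that("feature-level cohorts program effects in the expected directions", {
  ft0 <- generate_feature_cohort(effect_size = 0, date_sd = 0,
                                 squeals_per_date = 60, seed = 2)
  ft1 <- generate_feature_cohort(effect_size = 1, date_sd = 0,
                                 squeals_per_date = 60, seed = 2)
  dirs <- default_directions()
  for (k in seq_len(nrow(dirs))) {
    f <- dirs$feature[k]
    d_post <- mean(ft1[[f]][ft1$phase == "POST_EARLY"]) -
      mean(ft1[[f]][ft1$phase == "PRE"])
    if (dirs$post_change[k] == "up") expect_gt(d_post, 0.6)
    else expect_lt(d_post, -0.6)
    # null cohort has no shift beyond sampling noise
    d0 <- mean(ft0[[f]][ft0$phase == "POST_EARLY"]) -
      mean(ft0[[f]][ft0$phase == "PRE"])
    expect_lt(abs(d0), 0.35)
  }
})
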