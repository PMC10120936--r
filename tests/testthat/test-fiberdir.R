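test_that("median filter matches the brute-force sort oracle", {
  set.seed(50)
  x <- matrix(runif(400), 20, 20)
  expect_equal(median_filter(x, 2), brute_median_filter(x, 2))
  expect_equal(median_filter(x, 1), brute_median_filter(x, 1))
  # constant image unchanged; isolated hot pixel removed
  cst <- matrix(0.5, 9, 9)
  expect_equal(median_filter(cst, 2), cst)
  hot <- cst; hot[5, 5] <- 1
  expect_equal(median_filter(hot, 2), cst)
})

test_that("mean filter matches direct convolution and spreads impulses", {
  set.seed(51)
  x <- matrix(runif(36), 6, 6)
  expect_equal(mean_filter(x, 3), brute_mean_filter(x, 3), tolerance = 1e-12)
  cst <- matrix(2, 8, 8)
  expect_equal(mean_filter(cst, 1), cst)
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  out <- mean_filter(imp, 1)
  expect_equal(out[5:7, 5:7], matrix(1 / 9, 3, 3))
  expect_equal(sum(out[5:7, 5:7]), 1)
})

test_that("intensity normalization equalizes reference percentiles", {
  set.seed(52)
  a <- matrix(runif(10000), 100, 100)
  b <- a * 2
  out <- normalize_intensity(list(a, b))
  expect_equal(out[[1]], out[[2]], tolerance = 1e-12)
  qa <- quantile(out[[1]], 0.995, names = FALSE)
  qb <- quantile(out[[2]], 0.995, names = FALSE)
  expect_lt(abs(qa - qb), 1e-6)
  expect_error(normalize_intensity(matrix(0, 5, 5)), "dynamic range")
})

test_that("saturation stretch clips the configured pixel share", {
  set.seed(53)
  img <- matrix(rbeta(40000, 2, 5), 200, 200)
  out <- saturate_stretch(img, 0.04)
  frac_clipped <- mean(out == 1) + mean(out == 0)
  expect_lt(abs(frac_clipped - 0.04), 0.005)
  # near-zero fraction approaches a min-max stretch
  out0 <- saturate_stretch(img, 1e-6)
  expect_equal(min(out0), 0, tolerance = 1e-3)
  expect_equal(max(out0), 1, tolerance = 1e-3)
  expect_error(saturate_stretch(matrix(1, 4, 4), 0.04), "constant")
})

test_that("Otsu threshold equals exhaustive search and separates two levels", {
  two <- matrix(c(rep(50, 70), rep(200, 30)) / 255, 10, 10)
  r <- otsu_threshold(two, ignore_black = FALSE)
  expect_gt(r$threshold, 50 / 255)
  expect_lt(r$threshold, 200 / 255)
  expect_equal(r$mask, two > r$threshold)

  set.seed(54)
  vals <- sample(c(0.1, 0.25, 0.4, 0.5, 0.62, 0.75, 0.9, 1),
                 size = 256, replace = TRUE,
                 prob = c(4, 3, 2, 1, 1, 2, 3, 4))
  img <- matrix(vals, 16, 16)
  r2 <- otsu_threshold(img, ignore_black = FALSE)
  expect_equal(r2$threshold, brute_otsu_level(as.vector(img)),
               tolerance = 1e-12)

  # zero pixels are ignored and never enter the foreground
  with_zeros <- rbind(img, matrix(0, 4, 16))
  r3 <- otsu_threshold(with_zeros, ignore_black = TRUE)
  expect_equal(r3$threshold, r2$threshold)
  expect_false(any(r3$mask[17:20, ]))
})

test_that("particle removal equals brute-force labeling plus area rule", {
  set.seed(55)
  mask <- matrix(runif(900) < 0.3, 30, 30)
  px <- 1  # 1 um per pixel: threshold 50 um2 -> 50 px
  got <- remove_small_particles(mask, 50, px)
  lab <- brute_label8(mask)
  keep <- which(tabulate(lab[lab > 0]) >= 50)
  expect_equal(got, matrix(lab %in% keep, 30, 30))

  # exactly-threshold component is retained (inclusive rule)
  sq <- matrix(FALSE, 12, 12); sq[2:6, 2:11] <- TRUE   # 50 px
  expect_equal(remove_small_particles(sq, 50, 1), sq)
  # 1-px specks at 0.5 um/px are far below threshold
  specks <- matrix(FALSE, 9, 9); specks[c(5, 30, 70)] <- TRUE
  expect_false(any(remove_small_particles(specks, 50, 0.5)))
})

test_that("gradient orientation recovers stripe direction and rotates", {
  # vertical stripes: intensity varies along x -> fibers run at 90 degrees
  img <- matrix(rep(sin(2 * pi * (1:40) / 10), each = 40), 40, 40)
  th <- local_gradient_orientation(img, magnitude_floor = 0.2)$orientation_deg
  vals <- th[!is.na(th)]
  expect_lt(max(abs(vals - 90)), 2)

  # horizontal stripes -> 0 degrees (mod 180)
  imgh <- t(img)
  thh <- local_gradient_orientation(imgh, 0.2)$orientation_deg
  valsh <- thh[!is.na(thh)]
  expect_lt(max(pmin(valsh, 180 - valsh)), 2)

  # oblique stripes: constant along row - column, i.e. fibers at 135 degrees
  xy <- outer(1:60, 1:60, function(i, j) sin(2 * pi * (i + j) / 12))
  th45 <- local_gradient_orientation(xy, 0.2)$orientation_deg
  inner <- th45[10:50, 10:50]
  expect_lt(max(abs(inner[!is.na(inner)] - 135)), 3)

  # range is always [0, 180)
  set.seed(56)
  rnd <- matrix(runif(625), 25, 25)
  a <- local_gradient_orientation(rnd)$orientation_deg
  expect_true(all(a[!is.na(a)] >= 0 & a[!is.na(a)] < 180))
  expect_error(local_gradient_orientation(matrix(1, 10, 10)), "flat")
})

test_that("directionality histogram conserves votes and ratios", {
  or <- matrix(c(rep(30, 60), rep(120, 40)), 10, 10)
  h <- directionality_histogram(or, bin_width_deg = 2)
  expect_equal(sum(h$counts), 100)
  expect_equal(h$counts[h$bin_centers == 31], 60)
  expect_equal(h$counts[h$bin_centers == 121], 40)
  expect_equal(sum(h$counts > 0), 2)

  # masking restricts the votes
  m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
  hm <- directionality_histogram(or, m)
  expect_equal(sum(hm$counts), 50)
  expect_error(directionality_histogram(matrix(NA_real_, 3, 3)), "defined")
})

test_that("normal fit recovers wrapped-normal parameters", {
  set.seed(57)
  th <- (30 + rnorm(1e5, 0, 20)) %% 180
  f <- fit_normal(directionality_histogram(matrix(th, 1), bin_width_deg = 2))
  expect_lt(circ_err(f$alignment_deg, 30), 2)
  expect_lt(abs(f$dispersion_deg - 20) / 20, 0.1)
  expect_gt(f$gof, 0.95)

  # symmetric histogram centered at 0 (wrap-around peak)
  th0 <- rnorm(5e4, 0, 15) %% 180
  f0 <- fit_normal(directionality_histogram(matrix(th0, 1), bin_width_deg = 2))
  expect_lt(min(f0$alignment_deg, 180 - f0$alignment_deg), 2)

  # broad distribution: wrapped model still recovers the width
  th40 <- (40 + rnorm(2e5, 0, 40)) %% 180
  f40 <- fit_normal(directionality_histogram(matrix(th40, 1), bin_width_deg = 2))
  expect_lt(abs(f40$dispersion_deg - 40) / 40, 0.1)
})

test_that("alignment difference uses circular distance", {
  expect_equal(alignment_difference(30, 30), 0)
  expect_equal(alignment_difference(10, 175), 15)
  expect_equal(alignment_difference(0, 90), 90)
  expect_equal(alignment_difference(list(alignment_deg = 5),
                                    list(alignment_deg = 175)), 10)
})

test_that("full sample analysis emits the standard schema and handles identical channels", {
  ph <- generate_fiber_phantom(
    fiber_phantom_spec(image_size_px = 320, n_fibers = 200,
                       angular_sd_deg = 15, channel_offset_deg = 0,
                       mean_orientation_deg = 60),
    seed = 58)
  res <- analyze_sample(ph$collagen, ph$collagen, ph$pixel_size_um,
                        sample_id = "twin")
  expect_named(res$summary,
               c("sample_id", "alignment_difference_deg", "gof_collagen",
                 "gof_elastin", "dispersion_collagen", "dispersion_elastin"))
  expect_equal(res$summary$alignment_difference_deg, 0)
  expect_equal(res$summary$dispersion_collagen,
               res$summary$dispersion_elastin)
})

test_that("pipeline is equivariant under exact 90-degree rotation", {
  ph <- generate_fiber_phantom(
    fiber_phantom_spec(image_size_px = 320, n_fibers = 200,
                       angular_sd_deg = 15, channel_offset_deg = 0,
                       mean_orientation_deg = 40),
    seed = 59)
  f0 <- analyze_channel(ph$collagen, ph$pixel_size_um)$fit
  rot <- t(ph$collagen)[ncol(ph$collagen):1, ]
  f90 <- analyze_channel(rot, ph$pixel_size_um)$fit
  expect_lt(circ_err(f90$alignment_deg, f0$alignment_deg + 90), 2)
  expect_lt(abs(f90$dispersion_deg - f0$dispersion_deg), 1e-6)
  expect_lt(abs(f90$gof - f0$gof), 1e-6)
})

test_that("fiber images round-trip through PNG and TIFF", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  # PNG quantizes to 8 bits, TIFF is written at 16 bits
  for (cfg in list(list(ext = ".png", tol = 1 / 255),
                   list(ext = ".tif", tol = 2 / 65535))) {
    path <- withr::local_tempfile(fileext = cfg$ext)
    write_fiber_image(img, path)
    back <- read_fiber_image(path)
    expect_equal(back, img, tolerance = cfg$tol)
  }
})
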