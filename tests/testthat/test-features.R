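fs <- 44100

tone <- function(freq, dur = 0.5, fs. = fs, amp = 1000) {
  amp * sin(2 * pi * freq * (0:(round(dur * fs.) - 1)) / fs.)
}

test_that("energy spectrum concentrates tones and satisfies Parseval", {
  sp <- energy_spectrum(tone(1000), fs)
  expect_lt(abs(sp$freqs[which.max(sp$energy)] - 1000), 5)

  two <- tone(1000) + tone(2000)
  sp2 <- energy_spectrum(two, fs)
  pk <- order(sp2$energy, decreasing = TRUE)[1:2]
  expect_equal(sort(round(sp2$freqs[pk], -1)), c(1000, 2000), tolerance = 0.01)

  # Parseval: sum of the two-sided power spectrum equals windowed energy
  set.seed(1)
  x <- rnorm(1000)
  w <- x * (0.5 - 0.5 * cos(2 * pi * seq_along(x) / (length(x) + 1)))
  nfft <- 1024
  full <- Mod(fft(c(w, rep(0, nfft - length(w)))))^2
  expect_equal(sum(full) / nfft, sum(w^2), tolerance = 1e-6)
})

test_that("spectral quantile follows the cumulative-energy rule", {
  sp <- energy_spectrum(tone(1000), fs)
  expect_lt(abs(q50(sp) - 1000), 25)

  # flat spectrum: q50 at half Nyquist
  flat <- list(freqs = seq(0, 22050, length.out = 513),
               energy = rep(1, 513))
  expect_equal(q50(flat), 22050 / 2, tolerance = 22050 / 512)

  # discrete two-tone case against a cumulative-sum oracle
  spec <- list(freqs = c(500, 1000, 2000, 3000),
               energy = c(0, 4, 0, 4))
  cum <- cumsum(spec$energy)
  k <- which(cum >= 0.5 * sum(spec$energy))[1]
  expect_equal(q50(spec), spec$freqs[k])  # crossing exactly at the 1 kHz bin

  # q is monotone
  qs <- sapply(c(0.25, 0.5, 0.75), spectral_quantile, spectrum = sp)
  expect_true(all(diff(qs) >= 0))
  expect_error(q50(list(freqs = 1:3, energy = rep(0, 3))), "zero-energy")
})

test_that("shifting energy upward strictly increases q50", {
  base <- list(freqs = seq(0, 1000, by = 10), energy = rep(1, 101))
  shifted <- base
  shifted$energy[1:30] <- 0.2
  shifted$energy[70:101] <- 2
  expect_gt(q50(shifted), q50(base))
})

test_that("flux measures vanish for stationary tones and detect change", {
  cfg <- feature_config()
  stationary <- tone(1378.125, dur = 0.3)  # period-synchronous with frames
  expect_lt(flux1(stationary, fs, cfg), 1e-4)
  expect_lt(flux2(stationary, fs, cfg), 0.05)

  # alternating spectra between frames raise both measures
  n <- cfg$frame_length
  alt <- as.vector(sapply(1:12, function(k) {
    tone(if (k %% 2) 1000 else 4000, dur = n / fs)
  }))
  expect_gt(flux1(alt, fs, cfg), flux1(stationary, fs, cfg))
  expect_gt(flux2(alt, fs, cfg), flux2(stationary, fs, cfg))
  expect_error(flux1(tone(500, dur = 0.01), fs, cfg), "2 frames")
})

test_that("two-frame flux matches hand computation", {
  cfg <- feature_config(frame_length = 8, hop = 8, window = "rect")
  x <- c(1, 0, 0, 0, 0, 0, 0, 0,
         0, 1, 0, 0, 0, 0, 0, 0)
  sg <- frame_spectrogram(x, 16, cfg)
  E <- sg$energy / rowSums(sg$energy)
  exp_flux1 <- mean(abs(E[1, ] - E[2, ]))
  expect_equal(flux1(x, 16, cfg), exp_flux1, tolerance = 1e-12)
  M <- sqrt(sg$energy); M <- M / sqrt(rowSums(M^2))
  exp_flux2 <- sqrt(sum((M[1, ] - M[2, ])^2))
  expect_equal(flux2(x, 16, cfg), exp_flux2, tolerance = 1e-12)
})

test_that("flux2 of orthogonal unit-norm frame spectra is sqrt(2)", {
  # two frames whose spectra share no bins: distance sqrt(2) after
  # unit-norm scaling
  cfg <- feature_config(frame_length = 64, hop = 64, window = "rect")
  x <- c(sin(2 * pi * 8 * (0:63) / 64), sin(2 * pi * 16 * (0:63) / 64))
  expect_equal(flux2(x, 64, cfg), sqrt(2), tolerance = 1e-6)
})

test_that("Mel filterbank localizes tones and conserves in-range energy", {
  mel0 <- mel_spectrum(rep(0, 1000) + 0, fs)
  expect_true(all(mel0$band_energy == 0))

  mel <- mel_spectrum(tone(3000), fs)
  k <- which.max(mel$band_energy)
  expect_lt(abs(mel$center_freqs[k] - 3000), 400)
  # energy confined to bands overlapping the tone
  support <- abs(mel$center_freqs - 3000) < 1500
  expect_gt(sum(mel$band_energy[support]), 0.99 * sum(mel$band_energy))
})

test_that("mel spread matches weighted-moment oracle", {
  one <- list(center_freqs = c(100, 200, 300), band_energy = c(0, 5, 0))
  expect_equal(mel_spread(one), 0)

  two <- list(center_freqs = c(100, 300), band_energy = c(2, 2))
  expect_equal(mel_spread(two), 100)  # half the separation

  set.seed(3)
  m5 <- list(center_freqs = c(50, 120, 260, 400, 800),
             band_energy = runif(5))
  p <- m5$band_energy / sum(m5$band_energy)
  cen <- sum(p * m5$center_freqs)
  expect_equal(mel_spread(m5), sqrt(sum(p * (m5$center_freqs - cen)^2)))
  expect_equal(mel_spread(m5, "mad"), sum(p * abs(m5$center_freqs - cen)))
  expect_error(mel_spread(list(center_freqs = 1:3, band_energy = rep(0, 3))),
               "zero-energy")
})

test_that("mel p60 follows the discrete cumulative rule", {
  m1 <- list(center_freqs = 1:10 * 100, band_energy = c(5, rep(0, 9)))
  expect_equal(mel_p60(m1), 100)
  meq <- list(center_freqs = 1:10 * 100, band_energy = rep(1, 10))
  expect_equal(mel_p60(meq), 600)  # 6/10 >= 0.6
  # p60 >= p50 analog (monotone cumulative sum)
  set.seed(4)
  mr <- list(center_freqs = 1:10 * 100, band_energy = runif(10))
  expect_gte(mel_p60(mr, 0.6), mel_p60(mr, 0.5))
})

test_that("LPC recovers AR coefficients and matches Yule-Walker", {
  set.seed(11)
  n <- 1e5
  x <- as.numeric(stats::arima.sim(list(ar = c(1.5, -0.7)), n))
  co <- lpc_coefficients(x, 2)$coefficients
  expect_equal(co, c(1.5, -0.7), tolerance = 0.02)
  expect_equal(co, yule_walker_ar(x, 2), tolerance = 1e-8)

  # white noise: coefficients near zero
  w <- rnorm(5e4)
  expect_lt(max(abs(lpc_coefficients(w, 8)$coefficients)), 0.05)

  # prediction-error energy non-increasing in order
  errs <- sapply(1:10, function(p) lpc_coefficients(x[1:5000], p)$error)
  expect_true(all(diff(errs) <= 1e-10))
  expect_error(lpc_coefficients(rep(0, 1000), 4), "degenerate")
})

test_that("feature vector is deterministic and amplitude-invariant where expected", {
  sq <- generate_squeal(squeal_spec(), seed = 2)
  f1 <- compute_features(sq$samples, sq$sample_rate)
  f2 <- compute_features(sq$samples, sq$sample_rate)
  expect_identical(f1, f2)

  f_scaled <- compute_features(sq$samples * 2.5, sq$sample_rate)
  for (nm in c("q50", "p60", "spread", "flux1", "flux2"))
    expect_equal(unname(f_scaled[nm]), unname(f1[nm]), tolerance = 1e-8)

  # event-scoped computation: padding the recording does not change the
  # features of the same event window
  rec <- audio_recording(c(rep(0, 1000), sq$samples, rep(0, 1000)), fs)
  sig <- event_samples(rec, 1000, 1000 + length(sq$samples))
  expect_equal(compute_features(sig, fs), f1)
})

test_that("pre- vs post-surgery profiles order the features as expected", {
  pre <- generate_squeal(squeal_spec(), seed = 5)
  post <- generate_squeal(squeal_spec(spectral_tilt_db_per_octave = -12,
                                      frame_instability = 0.8,
                                      noise_floor_db = -15), seed = 5)
  f_pre <- compute_features(pre$samples, fs)
  f_post <- compute_features(post$samples, fs)
  expect_gt(f_pre[["q50"]], f_post[["q50"]])
  expect_gt(f_pre[["p60"]], f_post[["p60"]])
  expect_gt(f_post[["flux1"]], f_pre[["flux1"]])
  expect_gt(f_post[["flux2"]], f_pre[["flux2"]])
  expect_gt(f_post[["lpc8"]], f_pre[["lpc8"]])
})
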