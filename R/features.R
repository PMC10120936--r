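#' Acoustic voice parameters for squeals
#'
#' Six parameters summarize each squeal: Q50 (the 50% energy-spectrum
#' quantile), two spectral-flux variants capturing inter-frame instability,
#' the Mel-spectral spread about the centroid, P60 (the Mel frequency at
#' which 60% of the energy is reached) and LPC8 (the 8th coefficient of an
#' order-16 linear predictive model). Q50 and the Mel features are computed
#' on the whole-event spectrum; the flux measures use short-time frames.
#'
#' @name features
NULL

#' Default analysis configuration
#'
#' @param frame_length Samples per short-time frame for the flux measures
#'   (default 1024, about 23 ms at 44.1 kHz).
#' @param hop Hop between frames in samples (default `frame_length / 2`).
#' @param window Analysis window, `"hann"` or `"rect"`.
#' @param mel_bands Number of triangular Mel bands (default 64).
#' @param mel_fmin,mel_fmax Filterbank frequency range in Hz; `mel_fmax`
#'   defaults to the Nyquist frequency at analysis time.
#' @param lpc_order Linear-prediction order (default 16).
#' @param normalize_flux_frames Normalize each frame spectrum to unit total
#'   energy (Flux1) / unit norm (Flux2) before differencing (default TRUE),
#'   so flux reflects spectral shape change rather than loudness drift.
#' @param spread_type `"sd"` for the energy-weighted standard deviation
#'   about the centroid (default) or `"mad"` for the weighted mean absolute
#'   deviation.
#' @return A named list of settings.
#' @export
feature_config <- function(frame_length = 1024, hop = frame_length %/% 2,
                           window = c("hann", "rect"), mel_bands = 64,
                           mel_fmin = 50, mel_fmax = NULL, lpc_order = 16,
                           normalize_flux_frames = TRUE,
                           spread_type = c("sd", "mad")) {
  list(frame_length = frame_length, hop = hop, window = match.arg(window),
       mel_bands = mel_bands, mel_fmin = mel_fmin, mel_fmax = mel_fmax,
       lpc_order = lpc_order,
       normalize_flux_frames = isTRUE(normalize_flux_frames),
       spread_type = match.arg(spread_type))
}

#' Load a feature configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [feature_config()].
#' @return A configuration list.
#' @export
feature_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(feature_config, yaml::yaml.load_file(path))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

analysis_window <- function(n, type) {
  if (type == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)) else rep(1, n)
}

#' One-sided energy spectrum of a signal
#'
#' Squared-magnitude DFT of the (windowed, zero-padded to the next power of
#' two) signal, retained up to the Nyquist bin.
#'
#' @param signal Numeric amplitude vector.
#' @param sample_rate Sampling rate in Hz.
#' @param window `"hann"` (default) or `"rect"`.
#' @return List with `freqs` (Hz, ascending) and `energy` (non-negative).
#' @export
energy_spectrum <- function(signal, sample_rate, window = "hann") {
  stopifnot(length(signal) > 0)
  w <- analysis_window(length(signal), window)
  x <- signal * w
  nfft <- next_pow2(length(x))
  sp <- stats::fft(c(x, rep(0, nfft - length(x))))
  half <- nfft %/% 2 + 1L
  list(freqs = (seq_len(half) - 1) * sample_rate / nfft,
       energy = Mod(sp[seq_len(half)])^2)
}

#' Energy-spectrum quantile frequency
#'
#' Smallest frequency at which the cumulative energy reaches `q` of the
#' total, with linear interpolation inside the crossing bin. `q50()` is the
#' 50% quantile: the frequency splitting the spectrum into two equal-energy
#' halves.
#'
#' @param spectrum List with `freqs` and `energy` (see [energy_spectrum()]).
#' @param q Quantile in (0, 1).
#' @return Frequency in Hz.
#' @export
spectral_quantile <- function(spectrum, q) {
  stopifnot(q > 0, q < 1)
  e <- spectrum$energy
  total <- sum(e)
  if (total <= 0) stop("zero-energy spectrum: quantile undefined")
  cs <- cumsum(e)
  target <- q * total
  k <- which(cs >= target)[1]
  f <- spectrum$freqs
  if (k == 1L) return(f[1] * (target / cs[1]))
  # linear interpolation across the crossing bin
  f[k - 1] + (f[k] - f[k - 1]) * (target - cs[k - 1]) / (cs[k] - cs[k - 1])
}

#' @rdname spectral_quantile
#' @export
q50 <- function(spectrum) spectral_quantile(spectrum, 0.5)

#' Short-time frame spectrogram
#'
#' @param signal Numeric amplitude vector.
#' @param sample_rate Sampling rate in Hz.
#' @param config A [feature_config()].
#' @return List with `frame_times` (s) and `energy` (frames x bins matrix
#'   of one-sided squared magnitudes) and `freqs`.
#' @export
frame_spectrogram <- function(signal, sample_rate, config = feature_config()) {
  n <- length(signal)
  L <- config$frame_length
  hop <- config$hop
  if (n < L + hop)
    stop("signal too short for the configured framing (need >= 2 frames)")
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- analysis_window(L, config$window)
  half <- L %/% 2 + 1L
  E <- matrix(0, nrow = length(starts), ncol = half)
  for (i in seq_along(starts)) {
    fr <- signal[starts[i]:(starts[i] + L - 1L)] * w
    sp <- stats::fft(fr)
    E[i, ] <- Mod(sp[seq_len(half)])^2
  }
  list(frame_times = (starts - 1 + L / 2) / sample_rate,
       freqs = (seq_len(half) - 1) * sample_rate / L,
       energy = E)
}

#' Spectral flux, first variant
#'
#' Mean over neighboring frame pairs of the mean absolute difference
#' between their energy spectra; with per-frame normalization (the
#' default), each frame's spectrum is scaled to unit total energy before
#' differencing.
#'
#' @inheritParams frame_spectrogram
#' @return Non-negative scalar (natural scale; multiply by 1e3 for the
#'   conventional reporting scale).
#' @export
flux1 <- function(signal, sample_rate, config = feature_config()) {
  sg <- frame_spectrogram(signal, sample_rate, config)
  E <- sg$energy
  if (config$normalize_flux_frames) {
    tot <- rowSums(E)
    tot[tot == 0] <- 1
    E <- E / tot
  }
  d <- abs(E[-1, , drop = FALSE] - E[-nrow(E), , drop = FALSE])
  mean(rowMeans(d))
}

#' Spectral flux, second variant
#'
#' Root-mean-square Euclidean distance between consecutive magnitude
#' spectra, each normalized to unit Euclidean norm (the standard
#' music-information-retrieval spectral-flux formulation).
#'
#' @inheritParams frame_spectrogram
#' @return Non-negative scalar (natural scale; multiply by 10 for the
#'   conventional reporting scale).
#' @export
flux2 <- function(signal, sample_rate, config = feature_config()) {
  sg <- frame_spectrogram(signal, sample_rate, config)
  M <- sqrt(sg$energy)
  if (config$normalize_flux_frames) {
    nrm <- sqrt(rowSums(M^2))
    nrm[nrm == 0] <- 1
    M <- M / nrm
  }
  d2 <- rowSums((M[-1, , drop = FALSE] - M[-nrow(M), , drop = FALSE])^2)
  sqrt(mean(d2))
}

# --- Mel features -----------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank applied to a whole-event spectrum
#'
#' @param signal Numeric amplitude vector.
#' @param sample_rate Sampling rate in Hz.
#' @param n_bands Number of triangular bands (default 64).
#' @param fmin,fmax Frequency range in Hz; `fmax` defaults to Nyquist.
#' @param window Analysis window for the underlying spectrum.
#' @return List with `center_freqs` (Hz of the band apexes, ascending) and
#'   `band_energy` (non-negative).
#' @export
mel_spectrum <- function(signal, sample_rate, n_bands = 64, fmin = 50,
                         fmax = NULL, window = "hann") {
  fmax <- fmax %||% (sample_rate / 2)
  stopifnot(n_bands >= 2, fmin < fmax, fmax <= sample_rate / 2)
  sp <- energy_spectrum(signal, sample_rate, window)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_bands + 2))
  f <- sp$freqs
  band_energy <- numeric(n_bands)
  for (k in seq_len(n_bands)) {
    lo <- edges[k]; mid <- edges[k + 1]; hi <- edges[k + 2]
    wgt <- pmax(0, pmin((f - lo) / (mid - lo), (hi - f) / (hi - mid)))
    band_energy[k] <- sum(wgt * sp$energy)
  }
  list(center_freqs = edges[2:(n_bands + 1)], band_energy = band_energy)
}

#' Mel spectral spread
#'
#' Energy-weighted deviation of the Mel band center frequencies about the
#' energy-weighted centroid: the weighted standard deviation by default, or
#' the weighted mean absolute deviation.
#'
#' @param mel A Mel spectrum from [mel_spectrum()].
#' @param type `"sd"` (default) or `"mad"`.
#' @return Non-negative scalar on the Hz scale of the band centers.
#' @export
mel_spread <- function(mel, type = c("sd", "mad")) {
  type <- match.arg(type)
  w <- mel$band_energy
  tot <- sum(w)
  if (tot <= 0) stop("zero-energy Mel spectrum: spread undefined")
  p <- w / tot
  centroid <- sum(p * mel$center_freqs)
  if (type == "sd") sqrt(sum(p * (mel$center_freqs - centroid)^2))
  else sum(p * abs(mel$center_freqs - centroid))
}

#' Mel 60% energy frequency (P60)
#'
#' Center frequency of the first Mel band at which the cumulative band
#' energy reaches 60% of the total. Band centers are discrete frequency
#' components; no interpolation is applied.
#'
#' @param mel A Mel spectrum from [mel_spectrum()].
#' @param q Cumulative-energy fraction (default 0.6).
#' @return Band center frequency.
#' @export
mel_p60 <- function(mel, q = 0.6) {
  tot <- sum(mel$band_energy)
  if (tot <= 0) stop("zero-energy Mel spectrum: P60 undefined")
  k <- which(cumsum(mel$band_energy) >= q * tot)[1]
  mel$center_freqs[k]
}

# --- linear predictive coding ----------------------------------------------

#' Linear-prediction coefficients (autocorrelation method)
#'
#' Levinson-Durbin recursion on the biased sample autocorrelation. The
#' returned coefficients follow the predictor convention
#' `x_hat[n] = sum_k a_k * x[n - k]`, so an AR process
#' `x[n] = 1.5 x[n-1] - 0.7 x[n-2] + e[n]` yields `a = c(1.5, -0.7)` at
#' order 2. LPC8 is `a[8]` at order 16.
#'
#' @param signal Numeric vector, much longer than `order`.
#' @param order Prediction order (default 16).
#' @return List with `coefficients` (length `order`, predictor convention),
#'   `reflection` (PARCOR coefficients) and `error` (final prediction-error
#'   energy).
#' @export
lpc_coefficients <- function(signal, order = 16) {
  n <- length(signal)
  stopifnot(n > 2 * order)
  # biased autocorrelation at lags 0..order
  r <- vapply(0:order, function(k) {
    sum(signal[1:(n - k)] * signal[(1 + k):n]) / n
  }, numeric(1))
  if (r[1] <= 0) stop("degenerate signal: zero autocorrelation at lag 0")
  a <- numeric(order)
  refl <- numeric(order)
  err <- r[1]
  for (m in seq_len(order)) {
    acc <- r[m + 1] - if (m > 1) sum(a[1:(m - 1)] * r[m:2]) else 0
    k <- acc / err
    refl[m] <- k
    a_new <- a
    a_new[m] <- k
    if (m > 1) a_new[1:(m - 1)] <- a[1:(m - 1)] - k * a[(m - 1):1]
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) break
  }
  list(coefficients = a, reflection = refl, error = err)
}

#' @rdname lpc_coefficients
#' @param index Which coefficient to return (default 8).
#' @export
lpc8 <- function(signal, order = 16, index = 8) {
  lpc_coefficients(signal, order)$coefficients[index]
}

# --- feature vector ---------------------------------------------------------

#' Compute the six voice parameters for one squeal
#'
#' All parameters are computed on the event's samples under one shared
#' configuration and reported on their natural scale. The x1e3 (Flux1) and
#' x10 (Flux2) conventions are applied only at presentation.
#'
#' @param signal Numeric amplitude vector of one squeal event.
#' @param sample_rate Sampling rate in Hz.
#' @param config A [feature_config()].
#' @return Named numeric vector with elements `q50`, `flux1`, `flux2`,
#'   `spread`, `p60`, `lpc8`.
#' @export
compute_features <- function(signal, sample_rate, config = feature_config()) {
  sp <- energy_spectrum(signal, sample_rate, config$window)
  mel <- mel_spectrum(signal, sample_rate, n_bands = config$mel_bands,
                      fmin = config$mel_fmin, fmax = config$mel_fmax,
                      window = config$window)
  c(
    q50 = q50(sp),
    flux1 = flux1(signal, sample_rate, config),
    flux2 = flux2(signal, sample_rate, config),
    spread = mel_spread(mel, config$spread_type),
    p60 = mel_p60(mel),
    lpc8 = lpc_coefficients(signal, config$lpc_order)$coefficients[8]
  )
}

#' Feature table for a labeled cohort
#'
#' Computes [compute_features()] for every squeal in a cohort produced by
#' [generate_cohort()] (or assembled from recordings plus a label table)
#' and binds the results to the label metadata.
#'
#' @param cohort List with `recordings` (named list of [audio_recording()])
#'   and `labels` (squeal record data frame with `recording_id`, `start_s`,
#'   `end_s`).
#' @param config A [feature_config()].
#' @return Data frame: label columns plus the six feature columns.
#' @export
cohort_feature_table <- function(cohort, config = feature_config()) {
  lab <- cohort$labels
  feats <- matrix(NA_real_, nrow(lab), 6,
                  dimnames = list(NULL, c("q50", "flux1", "flux2",
                                          "spread", "p60", "lpc8")))
  for (i in seq_len(nrow(lab))) {
    rec <- cohort$recordings[[lab$recording_id[i]]]
    if (is.null(rec)) stop("no recording for id ", lab$recording_id[i])
    s0 <- round(lab$start_s[i] * rec$sample_rate)
    s1 <- round(lab$end_s[i] * rec$sample_rate)
    sig <- event_samples(rec, s0, s1)
    feats[i, ] <- tryCatch(
      compute_features(sig, rec$sample_rate, config),
      error = function(e) stop("feature computation failed for squeal ",
                               i, " (", lab$recording_id[i], "): ",
                               conditionMessage(e))
    )
  }
  cbind(lab, as.data.frame(feats))
}
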