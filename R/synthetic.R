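#' Synthetic squeal cohorts and fiber phantoms
#'
#' Raw cage recordings and microscopy slides are not redistributable, so
#' the package ships seeded generators that emulate their analysis-relevant
#' structure. Squeals are harmonic stacks with a drifting fundamental, a
#' spectral tilt controlling high-frequency content (more negative after
#' surgery), per-frame multiplicative spectral jitter (inter-frame
#' instability), a sharp onset followed by exponential-then-linear decay,
#' and a white noise floor. Fiber phantoms render anti-aliased line
#' segments whose orientations follow a 180-degree-periodic von Mises
#' distribution, with a programmable collagen-elastin orientation offset,
#' background noise and sub-threshold specks. All generators are pure
#' functions of their specification and seed.
#'
#' @name synthetic_data
NULL

#' Squeal generator specification
#'
#' @param f0_range Fundamental frequency range in Hz (drawn uniformly, must
#'   lie within (100, 8000)).
#' @param n_harmonics Number of harmonics in the stack (truncated at
#'   Nyquist).
#' @param spectral_tilt_db_per_octave Per-octave amplitude roll-off of the
#'   harmonics; more negative values remove high-frequency energy
#'   (post-surgery-like).
#' @param frame_instability Standard deviation of the per-frame
#'   multiplicative log-amplitude jitter applied independently per
#'   harmonic; larger values raise the flux measures.
#' @param duration_s Event duration in seconds (>= 0.5 so the event
#'   validates as a squeal).
#' @param onset_s Length of the sharp onset ramp (default 5 ms).
#' @param decay_exp_frac Fraction of the event under exponential decay
#'   before the linear tail (default 0.6).
#' @param noise_floor_db Noise floor relative to signal RMS in dB
#'   (default -30).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param peak_amplitude Target peak on the 16-bit scale (default 12000).
#' @return Specification list of class `squeal_spec`.
#' @export
squeal_spec <- function(f0_range = c(1000, 2200), n_harmonics = 40,
                        spectral_tilt_db_per_octave = -3,
                        frame_instability = 0.05, duration_s = 0.7,
                        onset_s = 0.005, decay_exp_frac = 0.6,
                        noise_floor_db = -30, sample_rate = 44100,
                        peak_amplitude = 12000) {
  stopifnot(duration_s >= 0.5,
            f0_range[1] > 100, f0_range[2] < 8000,
            f0_range[1] <= f0_range[2])
  structure(
    list(f0_range = f0_range, n_harmonics = n_harmonics,
         spectral_tilt_db_per_octave = spectral_tilt_db_per_octave,
         frame_instability = frame_instability, duration_s = duration_s,
         onset_s = onset_s, decay_exp_frac = decay_exp_frac,
         noise_floor_db = noise_floor_db, sample_rate = sample_rate,
         peak_amplitude = peak_amplitude),
    class = "squeal_spec"
  )
}

#' Generate one synthetic squeal
#'
#' @param spec A [squeal_spec()].
#' @param seed Integer seed; the output is a pure function of
#'   `(spec, seed)`.
#' @return An [audio_recording()] containing exactly the squeal (no
#'   silence padding).
#' @export
generate_squeal <- function(spec, seed = 1L) {
  rng <- local_rng(seed)
  fs <- spec$sample_rate
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # slowly drifting fundamental within the configured range
  f0_base <- rng$runif(1, spec$f0_range[1], spec$f0_range[2])
  drift <- 0.03 * f0_base * sin(2 * pi * rng$runif(1, 1, 3) * t +
                                  rng$runif(1, 0, 2 * pi))
  f0 <- f0_base + drift
  phase0 <- 2 * pi * cumsum(f0) / fs

  # per-frame multiplicative jitter (10 ms frames, step interpolation)
  frame_len <- max(1L, round(0.010 * fs))
  n_frames <- ceiling(n / frame_len)
  frame_of <- pmin(n_frames, ((seq_len(n) - 1L) %/% frame_len) + 1L)

  nyq <- fs / 2
  k_max <- min(spec$n_harmonics, floor(nyq / (max(f0) + 1)))
  sig <- numeric(n)
  for (k in seq_len(k_max)) {
    amp <- 10^(spec$spectral_tilt_db_per_octave * log2(k) / 20)
    gains <- exp(spec$frame_instability * rng$rnorm(n_frames))
    sig <- sig + amp * gains[frame_of] * sin(k * phase0 +
                                               rng$runif(1, 0, 2 * pi))
  }

  # envelope: sharp onset, exponential decay, then linear tail to zero
  env <- rep(1, n)
  n_on <- max(1L, round(spec$onset_s * fs))
  env[seq_len(n_on)] <- seq(0, 1, length.out = n_on)
  n_exp <- round(spec$decay_exp_frac * (n - n_on))
  n_lin <- n - n_on - n_exp
  if (n_exp > 0) {
    dec <- exp(-3 * seq(0, 1, length.out = n_exp))
    env[(n_on + 1):(n_on + n_exp)] <- dec
    if (n_lin > 0)
      env[(n_on + n_exp + 1):n] <- seq(dec[n_exp], 0, length.out = n_lin)
  }
  sig <- sig * env

  noise_sd <- stats::sd(sig) * 10^(spec$noise_floor_db / 20)
  sig <- sig + rng$rnorm(n, sd = noise_sd)
  sig <- sig * (spec$peak_amplitude / max(abs(sig)))
  audio_recording(sig, fs, source_id = sprintf("squeal_seed%d", seed))
}

#' Cohort generator specification
#'
#' @param pig_ids Character vector of subject identifiers.
#' @param surgery_day Calendar date of surgery (ISO-8601 string or Date).
#' @param recording_days Signed day offsets of the recording sessions
#'   relative to surgery; must include at least one pre-surgery and one
#'   early post-surgery day.
#' @param squeals_per_day Squeals recorded per session.
#' @param pre_spec,post_spec [squeal_spec()]s for the pre-surgery and
#'   early post-surgery voice.
#' @param recovery_model `"none"` (post voice persists), `"linear"` or
#'   `"logistic"` interpolation of the generation parameters from
#'   `post_spec` back toward `pre_spec` over `recovery_day` days.
#' @param recovery_day Day by which recovery is complete (default 150).
#' @param between_date_variability SD of the per-date random offsets
#'   applied to the tilt (dB/octave) and, proportionally, to the
#'   instability; emulates the strong between-session variability of
#'   spontaneous phonation.
#' @return Specification list of class `cohort_spec`.
#' @export
cohort_spec <- function(pig_ids = c("pig_a", "pig_b"),
                        surgery_day = "2022-06-01",
                        recording_days = c(-21, -10, -3, 1, 5, 10),
                        squeals_per_day = 12,
                        pre_spec = squeal_spec(),
                        post_spec = squeal_spec(
                          spectral_tilt_db_per_octave = -12,
                          frame_instability = 0.8,
                          noise_floor_db = -15),
                        recovery_model = c("none", "linear", "logistic"),
                        recovery_day = 150,
                        between_date_variability = 0.5) {
  recording_days <- sort(recording_days)
  if (!any(recording_days < 0) ||
      !any(recording_days >= 0 & recording_days <= 14))
    stop("recording_days must include a pre-surgery and an early post-surgery day")
  structure(
    list(pig_ids = pig_ids, surgery_day = as.Date(surgery_day),
         recording_days = recording_days, squeals_per_day = squeals_per_day,
         pre_spec = pre_spec, post_spec = post_spec,
         recovery_model = match.arg(recovery_model),
         recovery_day = recovery_day,
         between_date_variability = between_date_variability),
    class = "cohort_spec"
  )
}

# interpolation weight toward the pre-surgery voice: 0 right after surgery,
# 1 at full recovery
recovery_weight <- function(day, model, recovery_day) {
  if (day < 0) return(1)
  switch(model,
    none = 0,
    linear = min(1, day / recovery_day),
    logistic = stats::plogis((day - recovery_day / 2) / (recovery_day / 10))
  )
}

interp_spec <- function(pre, post, w) {
  s <- post
  for (f in c("spectral_tilt_db_per_octave", "frame_instability",
              "noise_floor_db")) {
    s[[f]] <- post[[f]] + w * (pre[[f]] - post[[f]])
  }
  s$f0_range <- post$f0_range + w * (pre$f0_range - post$f0_range)
  s
}

#' Generate a labeled synthetic cohort
#'
#' One recording per pig and session day: the requested squeals embedded in
#' silence, separated by 0.3 s gaps, with a label row (pig, date,
#' days-from-surgery, event bounds) per squeal. Squeals before surgery use
#' `pre_spec`, squeals after surgery use `post_spec` pulled toward
#' `pre_spec` according to the recovery model, with per-date random
#' parameter offsets.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed; every pig/date/squeal stream is derived from
#'   it.
#' @return List with `recordings` (named list of [audio_recording()]) and
#'   `labels` (squeal record data frame with a `phase` column).
#' @export
generate_cohort <- function(spec, seed = 20230421L) {
  stopifnot(inherits(spec, "cohort_spec"))
  recordings <- list()
  rows <- list()
  gap_s <- 0.3
  for (pi in seq_along(spec$pig_ids)) {
    pig <- spec$pig_ids[pi]
    for (di in seq_along(spec$recording_days)) {
      day <- spec$recording_days[di]
      # derived stream seeds kept below 2^31
      base_seed <- (seed %% 1000000L) * 1000L + pi * 37L + di * 101L
      rng <- local_rng(base_seed)
      w <- recovery_weight(day, spec$recovery_model, spec$recovery_day)
      day_spec <- if (day < 0) spec$pre_spec
        else interp_spec(spec$pre_spec, spec$post_spec, w)
      # between-date variability: additive tilt offset, matched relative
      # perturbation of the instability
      tilt_off <- spec$between_date_variability * rng$rnorm(1)
      day_spec$spectral_tilt_db_per_octave <-
        day_spec$spectral_tilt_db_per_octave + tilt_off
      day_spec$frame_instability <- day_spec$frame_instability *
        exp(0.2 * spec$between_date_variability * rng$rnorm(1))

      fs <- day_spec$sample_rate
      gap <- numeric(round(gap_s * fs))
      chunks <- list(gap)
      starts_s <- numeric(spec$squeals_per_day)
      ends_s <- numeric(spec$squeals_per_day)
      pos <- length(gap)
      for (si in seq_len(spec$squeals_per_day)) {
        sq <- generate_squeal(day_spec, seed = base_seed + si)
        starts_s[si] <- pos / fs
        pos <- pos + length(sq$samples)
        ends_s[si] <- pos / fs
        pos <- pos + length(gap)
        chunks[[length(chunks) + 1L]] <- sq$samples
        chunks[[length(chunks) + 1L]] <- gap
      }
      rec_id <- sprintf("%s_day%+04d", pig, day)
      recordings[[rec_id]] <- audio_recording(unlist(chunks), fs, rec_id)
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = rec_id,
        start_s = starts_s, end_s = ends_s,
        pig_id = pig,
        recording_date = spec$surgery_day + day,
        days_from_surgery = day,
        rater_id = "synthetic",
        stringsAsFactors = FALSE
      )
    }
  }
  labels <- do.call(rbind, rows)
  labels$phase <- phase_of_day(labels$days_from_surgery)
  list(recordings = recordings, labels = labels)
}

#' Generate a feature-level cohort table
#'
#' Fast surrogate for [generate_cohort()] followed by
#' [cohort_feature_table()], for calibration studies that need many
#' replicates: feature values are drawn directly from Gaussian
#' distributions with a per-date random intercept, with post-surgery group
#' means shifted by `effect_size` standard deviations in each feature's
#' expected direction (see [default_directions()]). `effect_size = 0`
#' gives a null cohort whose pre and post distributions are identical.
#'
#' @param n_dates_pre,n_dates_post Number of recording dates per phase.
#' @param squeals_per_date Squeals per date.
#' @param effect_size Post-surgery mean shift in SD units (0 = null).
#' @param date_sd SD of the per-date random intercept (default 0.3).
#' @param features Feature names (default the six voice parameters).
#' @param seed Integer seed.
#' @return Data frame with `pig_id`, `recording_date`,
#'   `days_from_surgery`, `phase` and one column per feature.
#' @export
generate_feature_cohort <- function(n_dates_pre = 3, n_dates_post = 3,
                                    squeals_per_date = 15, effect_size = 0,
                                    date_sd = 0.3,
                                    features = default_directions()$feature,
                                    seed = 1L) {
  rng <- local_rng(seed)
  dirs <- default_directions()
  days <- c(seq(-n_dates_pre * 7, -7, length.out = n_dates_pre),
            seq(1, 13, length.out = n_dates_post))
  days <- round(days)
  rows <- list()
  for (d in seq_along(days)) {
    day <- days[d]
    post <- day >= 0
    vals <- sapply(features, function(f) {
      sgn <- if (dirs$post_change[match(f, dirs$feature)] == "up") 1 else -1
      mu <- if (post) sgn * effect_size else 0
      mu + date_sd * rng$rnorm(1) + rng$rnorm(squeals_per_date)
    })
    vals <- matrix(vals, nrow = squeals_per_date,
                   dimnames = list(NULL, features))
    rows[[d]] <- data.frame(
      pig_id = "pig_sim",
      recording_date = as.Date("2022-06-01") + day,
      days_from_surgery = day,
      phase = phase_of_day(day),
      vals,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# --- fiber phantoms ---------------------------------------------------------

#' Fiber phantom specification
#'
#' @param image_size_px Square image edge in pixels (default 560).
#' @param pixel_size_um Micrometers per pixel (default 0.5).
#' @param n_fibers Fibers rendered per channel (default 400).
#' @param fiber_width_um Full width of the fiber cross-profile in
#'   micrometers (default 2; together with the default length this keeps
#'   single-fiber area above the 50 square-micrometer particle threshold).
#' @param fiber_length_um Mean fiber length in micrometers (default 30).
#' @param mean_orientation_deg Mean fiber orientation in [0, 180).
#' @param angular_sd_deg Circular standard deviation of the fiber
#'   orientations in degrees; internally realized as a von Mises
#'   distribution on doubled angles whose concentration is solved
#'   numerically so the circular SD matches exactly.
#' @param angular_dist Angular distribution of fiber orientations:
#'   `"wrapped_normal"` (default; the fitted dispersion then estimates
#'   exactly the programmed SD, since the directionality fit models a
#'   wrapped normal) or `"von_mises"` (concentration solved from the SD;
#'   slightly lighter-shouldered than the fit model at large widths).
#' @param channel_offset_deg Elastin mean orientation minus collagen mean
#'   orientation, in [0, 90].
#' @param background_noise_sd Additive Gaussian noise SD on the [0, 1]
#'   intensity scale (default 0.02).
#' @param speck_density Expected sub-threshold specks (3-4 px squares, a
#'   few square micrometers) per 1000 pixels, for exercising the particle
#'   filter (default 0).
#' @return Specification list of class `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(image_size_px = 560, pixel_size_um = 0.5,
                               n_fibers = 400, fiber_width_um = 2,
                               fiber_length_um = 30,
                               mean_orientation_deg = 40,
                               angular_sd_deg = 20,
                               angular_dist = c("wrapped_normal",
                                                "von_mises"),
                               channel_offset_deg = 5,
                               background_noise_sd = 0.02,
                               speck_density = 0) {
  stopifnot(angular_sd_deg > 0, channel_offset_deg >= 0,
            channel_offset_deg <= 90, pixel_size_um > 0)
  structure(
    list(image_size_px = image_size_px, pixel_size_um = pixel_size_um,
         n_fibers = n_fibers, fiber_width_um = fiber_width_um,
         fiber_length_um = fiber_length_um,
         mean_orientation_deg = mean_orientation_deg,
         angular_sd_deg = angular_sd_deg,
         angular_dist = match.arg(angular_dist),
         channel_offset_deg = channel_offset_deg,
         background_noise_sd = background_noise_sd,
         speck_density = speck_density),
    class = "fiber_phantom_spec"
  )
}

# concentration giving the requested circular standard deviation of the
# doubled-angle von Mises (exact inversion of sd = sqrt(-2 log A(kappa)),
# not the small-angle approximation 1 / (2 sd_rad)^2)
kappa_from_angular_sd <- function(sd_deg) {
  target <- exp(-(2 * sd_deg * pi / 180)^2 / 2)  # mean resultant length
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) A(k) - target, c(1e-8, 1e5), tol = 1e-10)$root
}

# von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu, kappa, rng) {
  out <- numeric(n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  i <- 0L
  while (i < n) {
    u <- rng$runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# axial orientation sample in degrees on [0, 180); for von Mises the
# concentration is chosen so the circular SD of the sampled orientations
# equals sd_deg exactly
sample_orientations <- function(n, mean_deg, sd_deg, rng,
                                dist = "wrapped_normal") {
  if (dist == "wrapped_normal")
    return((mean_deg + sd_deg * rng$rnorm(n)) %% 180)
  kappa <- kappa_from_angular_sd(sd_deg)
  phi <- rvonmises(n, mu = 2 * mean_deg * pi / 180, kappa = kappa, rng = rng)
  (phi / 2 * 180 / pi) %% 180
}

render_fiber_channel <- function(spec, mean_deg, rng) {
  npx <- spec$image_size_px
  img <- matrix(0, npx, npx)
  thetas <- sample_orientations(spec$n_fibers, mean_deg,
                                spec$angular_sd_deg, rng,
                                dist = spec$angular_dist %||% "wrapped_normal")
  half_w_px <- spec$fiber_width_um / spec$pixel_size_um / 2
  len_px <- spec$fiber_length_um / spec$pixel_size_um
  for (k in seq_len(spec$n_fibers)) {
    cx <- rng$runif(1, 1, npx)
    cy <- rng$runif(1, 1, npx)
    L <- len_px * rng$runif(1, 0.6, 1.4)
    th <- thetas[k] * pi / 180
    # sample points along the segment; splat a Gaussian cross-profile
    ts <- seq(-L / 2, L / 2, by = 0.5)
    # orientation is measured from the x (column) axis toward increasing
    # row index, matching the gradient-orientation convention
    xs <- cx + ts * cos(th)
    ys <- cy + ts * sin(th)
    r <- ceiling(2 * half_w_px)
    for (p in seq_along(ts)) {
      x0 <- round(xs[p]); y0 <- round(ys[p])
      if (y0 + r < 1 || y0 - r > npx || x0 + r < 1 || x0 - r > npx) next
      ii <- max(1, y0 - r):min(npx, y0 + r)
      jj <- max(1, x0 - r):min(npx, x0 + r)
      dd <- outer((ii - ys[p])^2, (jj - xs[p])^2, "+")
      img[ii, jj] <- img[ii, jj] + 0.35 * exp(-dd / (2 * half_w_px^2))
    }
  }
  img <- pmin(img, 1)
  if (spec$background_noise_sd > 0)
    img <- img + matrix(abs(rng$rnorm(npx^2, sd = spec$background_noise_sd)),
                        npx, npx)
  if (spec$speck_density > 0) {
    n_specks <- rng$rpois(1, spec$speck_density * npx^2 / 1000)
    if (n_specks > 0) {
      for (s in seq_len(n_specks)) {
        x0 <- ceiling(rng$runif(1, 0, npx))
        y0 <- ceiling(rng$runif(1, 0, npx))
        # 3-4 px squares: large enough to survive the median filter, far
        # below the 50 square-micrometer particle threshold
        sz <- 3L + (rng$runif(1) > 0.5)
        ii <- y0:min(npx, y0 + sz - 1)
        jj <- x0:min(npx, x0 + sz - 1)
        img[ii, jj] <- 1
      }
    }
  }
  pmin(img, 1)
}

#' Generate a two-channel fiber phantom
#'
#' @param spec A [fiber_phantom_spec()].
#' @param seed Integer seed.
#' @return List with `collagen` and `elastin` intensity matrices in
#'   [0, 1], `pixel_size_um` and `ground_truth` (programmed collagen and
#'   elastin mean orientations, angular SD and channel offset).
#' @export
generate_fiber_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  rng_c <- local_rng(seed)
  rng_e <- local_rng(seed + 500000L)
  mean_c <- spec$mean_orientation_deg %% 180
  mean_e <- (spec$mean_orientation_deg + spec$channel_offset_deg) %% 180
  list(
    collagen = render_fiber_channel(spec, mean_c, rng_c),
    elastin = render_fiber_channel(spec, mean_e, rng_e),
    pixel_size_um = spec$pixel_size_um,
    ground_truth = list(
      mean_collagen_deg = mean_c,
      mean_elastin_deg = mean_e,
      angular_sd_deg = spec$angular_sd_deg,
      channel_offset_deg = spec$channel_offset_deg
    )
  )
}
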