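#' Audio recordings and acoustic event segmentation
#'
#' Long-form cage recordings are represented as mono amplitude vectors on
#' the 16-bit PCM integer scale together with their sampling rate. Candidate
#' acoustic events are cut out of a recording wherever a moving-average
#' volume trace exceeds a threshold (default 500 on the raw amplitude
#' scale), and candidates at least 0.5 s long qualify as squeals.
#'
#' @name io_audio
NULL

#' Construct an audio recording object
#'
#' @param samples Numeric vector of mono amplitudes on the 16-bit integer
#'   scale (-32768..32767).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param source_id Opaque identifier carried through segmentation and
#'   labels.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate, source_id = "recording") {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  if (any(samples < -32768 | samples > 32767))
    stop("amplitudes outside the 16-bit integer range")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         source_id = as.character(source_id)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording '%s': %d samples @ %g Hz (%.2f s)>\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Read a recording from a WAV file
#'
#' Stereo (or higher channel count) files are collapsed to mono according
#' to `channel_policy`.
#'
#' @param path Path to an integer-PCM WAV file.
#' @param channel_policy How to collapse multi-channel audio: `"mean"`
#'   (average of the channels, the default), `"left"` or `"right"`.
#' @param source_id Identifier for the recording; defaults to the file name.
#' @return An [audio_recording()].
#' @export
read_recording <- function(path, channel_policy = c("mean", "left", "right"),
                           source_id = NULL) {
  channel_policy <- match.arg(channel_policy)
  w <- read_wav_raw(path)
  samples <- switch(channel_policy,
    mean  = rowMeans(w$samples),
    left  = w$samples[, 1],
    right = w$samples[, min(2L, ncol(w$samples))]
  )
  audio_recording(samples, w$sample_rate,
                  source_id = source_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moving-average volume trace
#'
#' Per-sample volume obtained by averaging the rectified (or squared, for
#' RMS) amplitude over a centered window. Windows are truncated at the
#' recording edges so the trace has the same length as the input.
#'
#' @param recording An [audio_recording()].
#' @param window_s Window length in seconds (default 0.1).
#' @param method `"mean_abs"` (mean absolute amplitude, default) or
#'   `"rms"` (root mean square).
#' @return Numeric vector of volume values, one per sample.
#' @export
moving_average_volume <- function(recording, window_s = 0.1,
                                  method = c("mean_abs", "rms")) {
  method <- match.arg(method)
  stopifnot(window_s > 0)
  x <- recording$samples
  n <- length(x)
  w <- round(window_s * recording$sample_rate)
  if (w > n) stop("window longer than recording")
  half <- w %/% 2
  v <- if (method == "mean_abs") abs(x) else x^2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (method == "rms") out <- sqrt(out)
  out
}

#' Segment a recording into acoustic events
#'
#' Maximal runs of samples whose moving-average volume is at least
#' `threshold`; runs separated by less than `min_gap_s` are merged. Event
#' bounds are 0-based half-open sample indices `[start_sample, end_sample)`.
#'
#' @param recording An [audio_recording()].
#' @param threshold Volume threshold on the 16-bit amplitude scale
#'   (default 500).
#' @param window_s Moving-average window in seconds (default 0.1).
#' @param min_gap_s Gaps shorter than this (seconds) are merged
#'   (default 0.2).
#' @param method Volume statistic, see [moving_average_volume()].
#' @return Data frame with columns `recording_id`, `start_sample`,
#'   `end_sample` (possibly zero rows), ordered by start, non-overlapping.
#' @export
segment_events <- function(recording, threshold = 500, window_s = 0.1,
                           min_gap_s = 0.2, method = "mean_abs") {
  stopifnot(threshold > 0)
  vol <- moving_average_volume(recording, window_s, method)
  above <- vol >= threshold
  empty <- data.frame(recording_id = character(), start_sample = integer(),
                      end_sample = integer(), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])  # 1-based incl.
  # merge runs separated by short gaps
  min_gap <- round(min_gap_s * recording$sample_rate)
  if (nrow(runs) > 1) {
    merged <- list()
    cur <- runs[1, ]
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - cur[2] - 1L < min_gap) {
        cur[2] <- runs[k, 2]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- runs[k, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- do.call(rbind, merged)
  }
  data.frame(
    recording_id = recording$source_id,
    start_sample = as.integer(runs[, 1] - 1L),   # 0-based
    end_sample   = as.integer(runs[, 2]),        # exclusive
    stringsAsFactors = FALSE
  )
}

#' Validate a candidate event as a squeal
#'
#' A candidate qualifies when its duration is at least `min_duration_s`
#' (boundary inclusive) at the recording's sampling rate.
#'
#' @param start_sample,end_sample 0-based half-open sample bounds.
#' @param recording An [audio_recording()].
#' @param min_duration_s Minimum duration in seconds (default 0.5).
#' @return Logical scalar.
#' @export
validate_squeal <- function(start_sample, end_sample, recording,
                            min_duration_s = 0.5) {
  if (start_sample < 0 || end_sample > length(recording$samples) ||
      start_sample >= end_sample)
    stop("event out of bounds")
  (end_sample - start_sample) / recording$sample_rate >= min_duration_s
}

#' Extract the samples of an event from a recording
#'
#' @inheritParams validate_squeal
#' @return Numeric amplitude vector.
#' @export
event_samples <- function(recording, start_sample, end_sample) {
  if (start_sample < 0 || end_sample > length(recording$samples) ||
      start_sample >= end_sample)
    stop("event out of bounds")
  recording$samples[(start_sample + 1L):end_sample]
}

# --- recovery phases --------------------------------------------------------

#' Recovery phase windows
#'
#' The longitudinal analysis buckets recording days (relative to surgery at
#' day 0) into four windows: pre-surgery (up to 33 days before), early
#' post-surgery (0-14 days), mid recovery (50-100 days) and late recovery
#' (150+ days).
#'
#' @return Data frame with columns `phase`, `day_lo`, `day_hi`.
#' @export
recovery_phases <- function() {
  data.frame(
    phase = c("PRE", "POST_EARLY", "POST_MID", "POST_LATE"),
    day_lo = c(-33, 0, 50, 150),
    day_hi = c(-1, 14, 100, Inf),
    stringsAsFactors = FALSE
  )
}

#' Map days-from-surgery to a recovery phase
#'
#' @param days_from_surgery Integer vector of signed day offsets.
#' @return Character vector of phase names; `NA` for days outside every
#'   window (e.g. 15-49 days after surgery).
#' @export
phase_of_day <- function(days_from_surgery) {
  ph <- recovery_phases()
  out <- rep(NA_character_, length(days_from_surgery))
  for (k in seq_len(nrow(ph))) {
    hit <- days_from_surgery >= ph$day_lo[k] & days_from_surgery <= ph$day_hi[k]
    out[hit & is.na(out)] <- ph$phase[k]
  }
  out
}

# --- label tables -----------------------------------------------------------

#' Read or write squeal label tables
#'
#' Label files are comma-separated text with columns `recording_id`,
#' `start_s`, `end_s`, `pig_id`, `recording_date` (ISO-8601),
#' `days_from_surgery` and optional `rater_id`. When `surgery_date` is
#' given, `days_from_surgery` is recomputed from the recording date.
#'
#' @param path File path.
#' @param surgery_date Optional `Date` (or ISO-8601 string); when supplied,
#'   `days_from_surgery` is recomputed as `recording_date - surgery_date`.
#' @return `load_labels`: a data frame of squeal records with an added
#'   `phase` column; `write_labels`: `path`, invisibly.
#' @export
load_labels <- function(path, surgery_date = NULL) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("recording_id", "start_s", "end_s", "pig_id",
                "recording_date", "days_from_surgery")
  missing_cols <- setdiff(required, names(lab))
  if (length(missing_cols))
    stop("label file missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(lab$end_s <= lab$start_s))
    stop("malformed label rows: non-positive durations")
  lab$recording_date <- as.Date(lab$recording_date)
  if (!is.null(surgery_date))
    lab$days_from_surgery <-
      as.integer(lab$recording_date - as.Date(surgery_date))
  lab$phase <- phase_of_day(lab$days_from_surgery)
  lab
}

#' @rdname load_labels
#' @param records Data frame of squeal records as returned by
#'   [load_labels()] or [generate_cohort()].
#' @export
write_labels <- function(records, path) {
  drop <- intersect("phase", names(records))
  utils::write.csv(records[setdiff(names(records), drop)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
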