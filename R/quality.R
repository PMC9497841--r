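#' Quality-gating criteria
#'
#' Thresholds that automate the visual segment-quality screen: a segment is
#' discarded either when it carries a low-frequency (0-2 Hz) spectral peak
#' together with an abnormally large amplitude (drift-type artifact), or
#' when its amplitude range is near zero mV (signal loss, e.g. electrode
#' contact loss).
#'
#' @param lf_band low-frequency band (Hz) screened for drift peaks.
#' @param ref_band physiological reference band (Hz) the low-frequency peak
#'   is compared against.
#' @param lf_peak_ratio flag threshold on (peak PSD in `lf_band`) /
#'   (peak PSD in `ref_band`).
#' @param amp_factor abnormal-amplitude threshold: segment peak must exceed
#'   `amp_factor` times the recording's median per-second peak.
#' @param loss_range_frac signal-loss range floor as a fraction of the
#'   recording's median per-second amplitude range.
#' @param loss_range_mv absolute range floor in mV; overrides
#'   `loss_range_frac` when non-`NULL`.
#' @return an object of class `cfae_quality_criteria`.
#' @export
quality_criteria <- function(lf_band = c(0, 2), ref_band = c(3, 12),
                             lf_peak_ratio = 1, amp_factor = 2,
                             loss_range_frac = 0.1, loss_range_mv = NULL) {
  if (lf_peak_ratio <= 0 || amp_factor <= 0 || loss_range_frac <= 0)
    stop("thresholds must be positive")
  structure(list(lf_band = lf_band, ref_band = ref_band,
                 lf_peak_ratio = lf_peak_ratio, amp_factor = amp_factor,
                 loss_range_frac = loss_range_frac,
                 loss_range_mv = loss_range_mv),
            class = "cfae_quality_criteria")
}

#' Quality vector
#'
#' Binary per-segment quality flags for one recording at window length `w`:
#' 1 for acceptable quality, 0 for a discarded segment. A 16 s recording has
#' `16 / w` elements, indexed 1-based.
#'
#' @param bits vector of 0/1 flags, length `16 / w`.
#' @param w window length in seconds, one of 1, 2, 4.
#' @param recording_id optional identifier.
#' @param duration_s recording duration, s.
#' @return an object of class `cfae_quality_vector`.
#' @export
quality_vector <- function(bits, w, recording_id = NA_character_,
                           duration_s = 16) {
  if (!w %in% c(1, 2, 4)) stop("w must be 1, 2 or 4 seconds")
  if (length(bits) != duration_s / w)
    stop("quality vector must have ", duration_s / w, " elements for w = ", w)
  if (!all(bits %in% c(0, 1))) stop("quality bits must be 0 or 1")
  structure(list(bits = as.integer(bits), w = w,
                 recording_id = recording_id, duration_s = duration_s),
            class = "cfae_quality_vector")
}

#' @export
print.cfae_quality_vector <- function(x, ...) {
  cat(sprintf("<q%d> %s: %s\n", x$w, x$recording_id,
              paste(x$bits, collapse = " ")))
  invisible(x)
}

#' Split a recording into non-overlapping segments
#'
#' Rectangular windowing into 1, 2 or 4 s segments that exactly cover the
#' recording, in time order.
#'
#' @param rec a `cfae_recording` or numeric vector.
#' @param w window length, s; one of 1, 2, 4.
#' @param fs sampling rate when `rec` is a bare vector.
#' @return list of `16 / w` numeric segments.
#' @export
segment_signal <- function(rec, w, fs = 1000) {
  if (!w %in% c(1, 2, 4)) stop("w must be 1, 2 or 4 seconds")
  x <- if (inherits(rec, "cfae_recording")) rec$samples else rec
  if (inherits(rec, "cfae_recording")) fs <- rec$fs
  len <- w * fs
  n_seg <- length(x) %/% len
  lapply(seq_len(n_seg), function(i) x[((i - 1L) * len + 1L):(i * len)])
}

## Welch screening spectrum of a 1 s segment: 256-sample Hamming windows,
## 50% overlap, zero-padded to a 1024-point FFT for sub-hertz bins.
screen_psd <- function(segment, fs = 1000) {
  welch_psd(segment, fs = fs, n_window = 256, overlap = 0.5, n_fft = 1024)
}

#' Flag a low-frequency (drift) artifact in a 1 s segment
#'
#' TRUE (bad segment) iff the peak of the Welch screening spectrum inside
#' the 0-2 Hz band (DC bin excluded) exceeds `lf_peak_ratio` times the peak
#' in the 3-12 Hz reference band AND the segment's peak absolute amplitude
#' exceeds `amp_factor` times the recording's median per-second peak (the
#' abnormal amplitude and/or shape criterion).
#'
#' @param segment numeric 1 s segment.
#' @param crit a [quality_criteria()].
#' @param ref_peak recording-level reference: median per-second peak
#'   absolute amplitude, mV.
#' @param fs sampling rate, Hz.
#' @return logical flag.
#' @export
lowfreq_artifact_flag <- function(segment, crit = quality_criteria(),
                                  ref_peak, fs = 1000) {
  stopifnot(inherits(crit, "cfae_quality_criteria"))
  if (max(abs(segment)) <= crit$amp_factor * ref_peak) return(FALSE)
  psd <- screen_psd(segment, fs)
  lf <- psd$freq > crit$lf_band[1] & psd$freq <= crit$lf_band[2]
  rf <- psd$freq >= crit$ref_band[1] & psd$freq <= crit$ref_band[2]
  pk_lf <- max(psd$power[lf])
  pk_rf <- max(psd$power[rf])
  pk_lf > crit$lf_peak_ratio * pk_rf
}

#' Flag a signal-loss segment
#'
#' TRUE iff the amplitude range (max - min) of the segment is strictly
#' below the loss threshold.
#'
#' @param segment numeric 1 s segment.
#' @param threshold_mv range floor in mV.
#' @return logical flag.
#' @export
signal_loss_flag <- function(segment, threshold_mv) {
  diff(range(segment)) < threshold_mv
}

#' Build the 1 s quality vector of a recording
#'
#' Applies [lowfreq_artifact_flag()] and [signal_loss_flag()] to every 1 s
#' segment; a segment gets bit 0 when either flag fires. A manual override
#' vector, when supplied, replaces the automated bits (mirroring the
#' clinician-adjudicated screen the automation stands in for).
#'
#' @param rec a `cfae_recording`.
#' @param crit a [quality_criteria()].
#' @param override optional 0/1 vector of length 16 replacing the automated
#'   bits; wrong length is an error.
#' @return a `cfae_quality_vector` with `w = 1`.
#' @export
build_q1 <- function(rec, crit = quality_criteria(), override = NULL) {
  stopifnot(inherits(rec, "cfae_recording"))
  segs <- segment_signal(rec, 1)
  if (!is.null(override)) {
    if (length(override) != length(segs))
      stop("override vector must have ", length(segs), " elements")
    return(quality_vector(override, 1, rec$patient_id,
                          duration_s = length(segs)))
  }
  peaks <- vapply(segs, function(s) max(abs(s)), numeric(1))
  ranges <- vapply(segs, function(s) diff(range(s)), numeric(1))
  ref_peak <- median(peaks)
  thr_loss <- crit$loss_range_mv %||% (crit$loss_range_frac * median(ranges))
  bits <- vapply(segs, function(s) {
    bad <- lowfreq_artifact_flag(s, crit, ref_peak, rec$fs) ||
      signal_loss_flag(s, thr_loss)
    if (bad) 0L else 1L
  }, integer(1))
  quality_vector(bits, 1,
                 paste(rec$patient_id, rec$site, sep = "_"),
                 duration_s = length(segs))
}

#' Propagate a 1 s quality vector to a coarser window length
#'
#' Element `j` of the propagated vector is the product of the `w`
#' consecutive 1 s elements it covers, preserving time correspondence: a
#' coarse segment is acceptable only if every 1 s segment inside it is.
#'
#' @param q1 a `cfae_quality_vector` with `w = 1`.
#' @param w target window length, 2 or 4 s.
#' @return a `cfae_quality_vector` at window length `w`.
#' @export
propagate_quality <- function(q1, w) {
  stopifnot(inherits(q1, "cfae_quality_vector"))
  if (q1$w != 1) stop("propagation starts from the 1 s quality vector")
  if (!w %in% c(2, 4)) stop("target w must be 2 or 4 seconds")
  m <- matrix(q1$bits, nrow = w)
  bits <- as.integer(apply(m, 2, prod))
  quality_vector(bits, w, q1$recording_id, duration_s = q1$duration_s)
}

#' Read and write quality vectors as delimited text
#'
#' One row per quality vector: recording id, window length, and the
#' space-separated bits. Manual-override files use the identical format.
#'
#' @param qvs list of `cfae_quality_vector`s.
#' @param path file path.
#' @return `path` invisibly for the writer; a list of quality vectors for
#'   the reader.
#' @export
write_quality_vectors <- function(qvs, path) {
  lines <- vapply(qvs, function(q)
    paste(q$recording_id, q$w, paste(q$bits, collapse = " "), sep = ","),
    character(1))
  writeLines(c("recording_id,w,bits", lines), path)
  invisible(path)
}

#' @rdname write_quality_vectors
#' @export
read_quality_vectors <- function(path) {
  lines <- readLines(path)[-1L]
  lapply(lines, function(l) {
    parts <- strsplit(l, ",")[[1L]]
    bits <- as.integer(strsplit(parts[3L], " ")[[1L]])
    quality_vector(bits, as.numeric(parts[2L]), parts[1L],
                   duration_s = as.numeric(parts[2L]) * length(bits))
  })
}

#' Cohort discard summary
#'
#' For each window length: the percentage of discarded segments (zero
#' elements over all elements) and, for propagated lengths, the embedded
#' information loss - the percentage of good 1 s sub-segments that fall
#' inside discarded coarse segments, relative to all 1 s segments.
#' Optionally broken down by recording site and AF type.
#'
#' @param q1_list list of `cfae_quality_vector`s with `w = 1`, one per
#'   recording.
#' @param meta optional data.frame (one row per recording) with columns
#'   `site` and/or `af_type` for grouped summaries.
#' @param w_values window lengths to summarize.
#' @return data.frame with columns `group_type`, `group`, `w`,
#'   `discard_pct`, `info_loss_pct`.
#' @export
discard_summary <- function(q1_list, meta = NULL, w_values = c(1, 2, 4)) {
  if (length(q1_list) == 0L) stop("empty cohort")
  one <- function(keep) {
    qs <- q1_list[keep]
    do.call(rbind, lapply(w_values, function(w) {
      per <- lapply(qs, function(q) {
        qw <- if (w == 1) q else propagate_quality(q, w)
        bad <- qw$bits == 0L
        info <- if (w == 1) 0 else {
          m <- matrix(q$bits, nrow = w)
          sum(m[, bad, drop = FALSE]) / length(q$bits)
        }
        c(n_bad = sum(bad), n = length(qw$bits), info = info)
      })
      per <- do.call(rbind, per)
      data.frame(w = w,
                 discard_pct = 100 * sum(per[, "n_bad"]) / sum(per[, "n"]),
                 info_loss_pct = 100 * mean(per[, "info"]))
    }))
  }
  out <- cbind(group_type = "all", group = "all", one(TRUE))
  if (!is.null(meta)) {
    for (col in intersect(c("site", "af_type"), names(meta))) {
      for (g in unique(meta[[col]])) {
        out <- rbind(out, cbind(group_type = col, group = g,
                                one(meta[[col]] == g)))
      }
    }
  }
  rownames(out) <- NULL
  out
}
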