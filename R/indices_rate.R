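#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' windowed sections, each zero-padded to `n_fft` points, and the one-sided
#' periodograms are averaged. The defaults are the dominant-frequency
#' settings used throughout the package: a 4096-point Hamming window, 50%
#' overlap, 8192-point FFT, giving a frequency resolution of
#' `fs / 8192` (0.122 Hz at 1 kHz).
#'
#' @param x numeric signal, at least `n_window` samples long.
#' @param fs sampling rate, Hz.
#' @param n_window section length, samples.
#' @param overlap fractional overlap between adjacent sections.
#' @param n_fft FFT length (>= `n_window`).
#' @return list with `freq` (Hz) and `power`, class `cfae_psd`.
#' @export
welch_psd <- function(x, fs = 1000, n_window = 4096, overlap = 0.5,
                      n_fft = 8192) {
  if (length(x) < n_window)
    stop("signal shorter than one Welch window (", n_window, " samples)")
  if (n_fft < n_window) stop("n_fft must be >= n_window")
  w <- signal::hamming(n_window)
  step <- n_window - floor(overlap * n_window)
  starts <- seq(1L, length(x) - n_window + 1L, by = step)
  scale <- fs * sum(w^2)
  n_keep <- n_fft %/% 2L + 1L
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + n_window - 1L)] * w
    X <- stats::fft(c(seg, numeric(n_fft - n_window)))
    P <- Mod(X[seq_len(n_keep)])^2 / scale
    P[2:(n_keep - 1L)] <- 2 * P[2:(n_keep - 1L)]
    acc <- acc + P
  }
  structure(list(freq = (seq_len(n_keep) - 1L) * fs / n_fft,
                 power = acc / length(starts)),
            class = "cfae_psd")
}

#' Dominant frequency of a spectrum
#'
#' Frequency of the largest-power bin inside the fibrillatory band
#' (3-12 Hz by default).
#'
#' @param psd a `cfae_psd` (or a list with `freq` and `power`).
#' @param band frequency band searched, Hz.
#' @return dominant frequency, Hz.
#' @export
dominant_frequency <- function(psd, band = c(3, 12)) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("spectrum does not cover the ", band[1], "-",
                      band[2], " Hz band")
  psd$freq[sel][which.max(psd$power[sel])]
}

#' Detect atrial activations on an equalized envelope
#'
#' Local maxima above an adaptive threshold (`threshold_frac` times the
#' moving 95th percentile of the envelope over a 2 s window), thinned by a
#' refractory period: candidates are accepted in order of decreasing
#' amplitude and any candidate within `refractory_ms` of an accepted one is
#' dropped, so merged deflections yield a single detection.
#'
#' @param envelope non-negative (equalized) envelope series.
#' @param fs sampling rate, Hz.
#' @param threshold_frac threshold fraction of the running 95th percentile.
#' @param refractory_ms minimum separation between detections, ms.
#' @param ref_win_s window of the running percentile, s.
#' @return activation times in ms (possibly empty).
#' @export
detect_activations <- function(envelope, fs = 1000, threshold_frac = 0.3,
                               refractory_ms = 100, ref_win_s = 2) {
  if (all(envelope == 0)) return(numeric(0))
  n <- length(envelope)
  thr <- threshold_frac * moving_quantile(envelope, fs, ref_win_s, 0.95)
  i <- 2:(n - 1L)
  cand <- i[envelope[i] > envelope[i - 1L] & envelope[i] >= envelope[i + 1L] &
              envelope[i] > thr[i]]
  if (length(cand) == 0L) return(numeric(0))
  cand <- cand[order(envelope[cand], decreasing = TRUE)]
  ref_n <- refractory_ms * fs / 1000
  kept <- integer(0)
  for (c0 in cand) {
    if (all(abs(kept - c0) >= ref_n)) kept <- c(kept, c0)
  }
  sort((kept - 1L) / fs * 1000)
}

#' Atrial fibrillation cycle length
#'
#' Arithmetic mean of the successive differences between activation times,
#' over the whole recording. Fewer than two activations give a flagged
#' `NA`.
#'
#' @param times activation times in ms.
#' @return mean cycle length in ms, or flagged `NA`.
#' @export
afcl <- function(times) {
  if (length(times) < 2L)
    return(structure(NA_real_, flag = "insufficient_activations"))
  mean(diff(times))
}

#' AFCL and DF of a full recording
#'
#' Convenience wrapper implementing the per-recording rate indices: the
#' Botteron envelope is computed, activations are equalized and detected
#' for the cycle length, and the dominant frequency is taken from the Welch
#' spectrum of the (non-equalized) envelope, where the activation-rate
#' fundamental dominates the 3-12 Hz band. Both indices are computed on
#' the full 16 s recording by default, regardless of the quality vector;
#' when `q1` is supplied, discarded seconds are masked instead -
#' activations inside them are dropped, inter-activation intervals that
#' span them are excluded from the cycle-length mean, and the envelope is
#' zeroed there before the spectrum.
#'
#' @param rec a `cfae_recording` (powerline-cleaned).
#' @param cfg a [preproc_config()].
#' @param q1 optional `cfae_quality_vector` (w = 1) enabling masking.
#' @return list with `afcl_ms`, `df_hz`, `n_activations`.
#' @export
rate_indices <- function(rec, cfg = preproc_config(), q1 = NULL) {
  env <- botteron_transform(rec, cfg)
  eq <- equalize_activations(env, rec$fs)
  times <- detect_activations(eq, rec$fs)
  if (!is.null(q1)) {
    stopifnot(inherits(q1, "cfae_quality_vector"), q1$w == 1)
    bad <- which(q1$bits == 0L)
    sec_of <- function(t_ms) floor(t_ms / 1000) + 1L
    times_kept <- times[!(sec_of(times) %in% bad)]
    iv <- diff(times_kept)
    spans_bad <- vapply(seq_along(iv), function(i) {
      any(seq(sec_of(times_kept[i]), sec_of(times_kept[i + 1L])) %in% bad)
    }, logical(1))
    iv <- iv[!spans_bad]
    afcl_v <- if (length(iv) == 0L)
      structure(NA_real_, flag = "insufficient_activations") else mean(iv)
    for (b in bad) env[((b - 1L) * rec$fs + 1L):(b * rec$fs)] <- 0
    psd <- welch_psd(env - mean(env), fs = rec$fs)
    return(list(afcl_ms = afcl_v, df_hz = dominant_frequency(psd),
                n_activations = length(times_kept)))
  }
  psd <- welch_psd(env - mean(env), fs = rec$fs)
  list(afcl_ms = afcl(times), df_hz = dominant_frequency(psd),
       n_activations = length(times))
}
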