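#' Synthesis parameters for a fractionated atrial electrogram
#'
#' Bundles the generator settings for one synthetic CFAE: the AF class label,
#' the mean atrial activation cycle length and its beat-to-beat jitter, the
#' degree of fractionation (number of sub-deflections per activation
#' complex), the deflection width, additive baseline noise, and an optional
#' powerline tone. Amplitudes are in millivolts; the rendered activation
#' component is normalized to a 1 mV peak before noise is added.
#'
#' @param af_type AF class label, `"ParAF"` or `"PerAF"`.
#' @param mean_cl mean activation cycle length in ms; must be >= 120 ms,
#'   consistent with the CFAE definition of fractionated activity with cycle
#'   length at or above 120 ms.
#' @param cl_jitter_sd standard deviation of the cycle-length jitter, ms.
#' @param fractionation integer >= 1; number of deflections per activation
#'   complex. 1 gives a single biphasic deflection.
#' @param deflection_width width of one deflection, ms.
#' @param noise_sd baseline white-noise SD, mV.
#' @param powerline_amp amplitude of an additive mains tone, mV.
#' @param powerline_freq mains frequency, Hz.
#' @param seed integer RNG seed; identical `(params, seed)` reproduce the
#'   same recording bit for bit. `NULL` uses the current RNG state.
#' @return an object of class `cfae_synth_params`.
#' @seealso [af_preset()], [generate_cfae()]
#' @export
synth_params <- function(af_type = c("ParAF", "PerAF"),
                         mean_cl = 160, cl_jitter_sd = 10,
                         fractionation = 2L, deflection_width = 12,
                         noise_sd = 0.05, powerline_amp = 0,
                         powerline_freq = 50, seed = NULL) {
  af_type <- match.arg(af_type)
  if (!is.numeric(mean_cl) || mean_cl < 120)
    stop("mean_cl must be >= 120 ms (CFAE definition; refractory floor is 100 ms)")
  if (cl_jitter_sd < 0) stop("cl_jitter_sd must be >= 0")
  if (fractionation < 1) stop("fractionation must be >= 1")
  if (deflection_width <= 0) stop("deflection_width must be positive")
  if (noise_sd < 0 || powerline_amp < 0)
    stop("noise_sd and powerline_amp must be non-negative")
  structure(list(af_type = af_type, mean_cl = mean_cl,
                 cl_jitter_sd = cl_jitter_sd,
                 fractionation = as.integer(fractionation),
                 deflection_width = deflection_width, noise_sd = noise_sd,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq, seed = seed),
            class = "cfae_synth_params")
}

#' Class presets for the synthetic generator
#'
#' Default generator settings for paroxysmal and persistent AF. The presets
#' differ in mean cycle length, jitter, and fractionation so that the index
#' contrasts on synthetic cohorts follow the clinically reported directions:
#' persistent AF has shorter cycle length, more fractionation and jitter,
#' hence higher sample entropy, lower determinism, and higher dominant
#' frequency than paroxysmal AF. Magnitudes are not calibrated to any
#' clinical cohort.
#'
#' @param af_type `"ParAF"` or `"PerAF"`.
#' @param seed optional RNG seed stored in the parameter set.
#' @return a `cfae_synth_params` object.
#' @export
af_preset <- function(af_type = c("ParAF", "PerAF"), seed = NULL) {
  af_type <- match.arg(af_type)
  if (af_type == "ParAF") {
    synth_params("ParAF", mean_cl = 185, cl_jitter_sd = 10,
                 fractionation = 2L, deflection_width = 12,
                 noise_sd = 0.01, powerline_amp = 0.05, seed = seed)
  } else {
    synth_params("PerAF", mean_cl = 145, cl_jitter_sd = 25,
                 fractionation = 5L, deflection_width = 10,
                 noise_sd = 0.01, powerline_amp = 0.05, seed = seed)
  }
}

new_recording <- function(samples, patient_id, af_type, site, fs = 1000,
                          truth = NULL) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  structure(list(patient_id = patient_id, af_type = af_type, site = site,
                 fs = fs, samples = as.numeric(samples), truth = truth),
            class = "cfae_recording")
}

#' @export
print.cfae_recording <- function(x, ...) {
  cat(sprintf("<cfae_recording> %s %s %s: %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$site, x$af_type, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

## Interval generation without seeding; exported wrapper seeds.
gen_train <- function(params, duration_s, refractory_ms = 100) {
  dur_ms <- duration_s * 1000
  n_max <- ceiling(dur_ms / refractory_ms) + 2L
  iv <- pmax(rnorm(n_max, params$mean_cl, params$cl_jitter_sd), refractory_ms)
  times <- params$mean_cl / 2 + cumsum(c(0, iv))
  times[times < dur_ms]
}

#' Generate a train of atrial activation times
#'
#' Draws successive activation intervals around `mean_cl` with SD
#' `cl_jitter_sd`, truncated below at a 100 ms refractory floor, and returns
#' the cumulative activation times. The first activation is placed at half a
#' mean cycle so that trains of any duration start away from the edge.
#'
#' @param params a [synth_params()] object; if `params$seed` is non-`NULL`
#'   the RNG is seeded so the train is reproducible.
#' @param duration_s train duration in seconds.
#' @return strictly increasing activation times in ms.
#' @export
generate_activation_train <- function(params, duration_s = 16) {
  stopifnot(inherits(params, "cfae_synth_params"))
  if (duration_s <= 0) stop("duration must be positive")
  if (!is.null(params$seed)) set.seed(params$seed)
  gen_train(params, duration_s)
}

## Biphasic deflection: derivative-of-Gaussian wavelet with unit peak,
## support truncated at +/- 4 sigma.
biphasic_wavelet <- function(width_ms, fs) {
  sigma <- width_ms / 6 * fs / 1000            # samples
  half <- ceiling(4 * sigma)
  t <- (-half):half
  (t / sigma) * exp(0.5) * exp(-t^2 / (2 * sigma^2))
}

#' Synthesize one fractionated atrial electrogram
#'
#' Renders a 16 s, 1 kHz bipolar-like electrogram: a quasi-periodic train of
#' activation complexes, each a sum of `fractionation` Gaussian-windowed
#' biphasic deflections (one at the activation time, the rest offset within
#' +/- 25 ms with random amplitude and polarity). The sub-deflection
#' layout is drawn once per recording and repeated at every activation -
#' a recording site has a stable local substrate geometry, so its complex
#' morphology is consistent; class differences come from cycle length,
#' jitter, and fractionation. The activation component is normalized to a
#' 1 mV peak, then baseline white noise and an optional powerline tone are
#' added. Ground-truth activation times and the parameter set are stored in
#' `$truth`.
#'
#' @param params a [synth_params()] object.
#' @param patient_id,site metadata stored on the recording.
#' @param duration_s recording length in seconds (default 16).
#' @param fs sampling rate, Hz (default 1000).
#' @return a `cfae_recording`.
#' @export
generate_cfae <- function(params, patient_id = "P00", site = "LSPV",
                          duration_s = 16, fs = 1000) {
  stopifnot(inherits(params, "cfae_synth_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- round(duration_s * fs)
  times <- gen_train(params, duration_s)
  s <- numeric(n)
  wav <- biphasic_wavelet(params$deflection_width, fs)
  half <- (length(wav) - 1L) / 2L
  k <- params$fractionation
  offs <- c(0, if (k > 1) runif(k - 1L, -25, 25))
  amps <- c(1, if (k > 1) runif(k - 1L, 0.4, 0.9))
  sgns <- c(1, if (k > 1) sample(c(-1, 1), k - 1L, replace = TRUE))
  for (a in times) {
    for (j in seq_len(k)) {
      c0 <- round((a + offs[j]) * fs / 1000) + 1L
      lo <- c0 - half
      hi <- c0 + half
      wlo <- max(1L, lo)
      whi <- min(n, hi)
      if (wlo > whi) next
      s[wlo:whi] <- s[wlo:whi] +
        amps[j] * sgns[j] * wav[(wlo - lo + 1L):(whi - lo + 1L)]
    }
  }
  pk <- max(abs(s))
  if (pk > 0) s <- s / pk
  if (params$noise_sd > 0) s <- s + rnorm(n, 0, params$noise_sd)
  if (params$powerline_amp > 0) {
    t <- (seq_len(n) - 1L) / fs
    s <- s + params$powerline_amp *
      sin(2 * pi * params$powerline_freq * t + runif(1, 0, 2 * pi))
  }
  new_recording(s, patient_id, params$af_type, site, fs,
                truth = list(activation_times = times, params = params,
                             schedule = NULL))
}

#' Artifact schedule for a recording
#'
#' Describes where to inject the two artifact classes used for quality
#' gating: low-frequency drift (a high-amplitude sub-2 Hz component) and
#' signal-loss intervals (amplitude suppressed toward 0 mV, emulating loss
#' of electrode contact).
#'
#' @param drift `NULL` or a data.frame with columns `start`, `end` (s),
#'   `amp` (mV) and `freq` (Hz, must be < 2).
#' @param loss `NULL` or a data.frame with columns `start`, `end` (s).
#' @param duration_s recording span the intervals must fall inside.
#' @return an object of class `cfae_artifact_schedule`.
#' @export
artifact_schedule <- function(drift = NULL, loss = NULL, duration_s = 16) {
  chk <- function(df, what) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    if (any(df$start < 0 | df$end > duration_s | df$end < df$start))
      stop(what, " intervals must lie within [0, ", duration_s,
           ") s with non-negative duration")
    df
  }
  drift <- chk(drift, "drift")
  loss <- chk(loss, "loss")
  if (!is.null(drift) && any(drift$freq >= 2))
    stop("drift frequency must be below 2 Hz")
  if (!is.null(drift) && !is.null(loss)) {
    for (i in seq_len(nrow(drift))) {
      if (any(drift$start[i] < loss$end & loss$start < drift$end[i]))
        stop("drift and loss intervals overlap")
    }
  }
  structure(list(drift = drift, loss = loss, duration_s = duration_s),
            class = "cfae_artifact_schedule")
}

#' Inject scheduled artifacts into a recording
#'
#' Drift intervals gain an additive half-sine (sub-2 Hz) component of the
#' scheduled amplitude; signal-loss intervals are attenuated by a factor of
#' 100 (amplitude ranges near, but not exactly, 0 mV, so near-zero detection
#' thresholds are exercised). An empty schedule returns the recording
#' unchanged. The schedule is recorded in `$truth$schedule`.
#'
#' @param rec a `cfae_recording`.
#' @param sched an [artifact_schedule()].
#' @return the modified `cfae_recording`.
#' @export
inject_artifacts <- function(rec, sched) {
  stopifnot(inherits(rec, "cfae_recording"),
            inherits(sched, "cfae_artifact_schedule"))
  fs <- rec$fs
  n <- length(rec$samples)
  s <- rec$samples
  if (!is.null(sched$drift)) {
    for (i in seq_len(nrow(sched$drift))) {
      d <- sched$drift[i, ]
      idx <- (floor(d$start * fs) + 1L):min(n, floor(d$end * fs))
      tt <- (seq_along(idx) - 1L) / fs
      s[idx] <- s[idx] + d$amp * sin(2 * pi * d$freq * tt)
    }
  }
  if (!is.null(sched$loss)) {
    for (i in seq_len(nrow(sched$loss))) {
      l <- sched$loss[i, ]
      idx <- (floor(l$start * fs) + 1L):min(n, floor(l$end * fs))
      s[idx] <- s[idx] * 0.01
    }
  }
  rec$samples <- s
  if (is.null(rec$truth)) rec$truth <- list()
  rec$truth$schedule <- sched
  rec
}

## Patient-level parameter draw around a class preset. Site-level recordings
## additionally perturb the mean cycle length slightly.
draw_patient_params <- function(preset) {
  mean_cl <- max(125, preset$mean_cl + rnorm(1, 0, 8))
  jit <- max(1, preset$cl_jitter_sd + rnorm(1, 0, 3))
  frac <- max(1L, preset$fractionation +
                sample(c(-1L, 0L, 1L), 1, prob = c(.25, .5, .25)))
  list(mean_cl = mean_cl, cl_jitter_sd = jit, fractionation = frac)
}

#' Generate a two-class synthetic CFAE cohort
#'
#' One recording per patient and site. Patient-level generator parameters
#' are drawn around the class preset ([af_preset()]); each site adds a small
#' perturbation of the mean cycle length, emulating regional variation.
#' With probability `artifact_prob` a recording carries one scheduled
#' artifact - a low-frequency drift or a signal-loss interval of one or two
#' seconds at a random (whole-second) position - so the quality gate is
#' exercised at a per-segment discard rate in the range reported for
#' clinical electrograms. The whole cohort is a deterministic function of
#' `seed`.
#'
#' @param n_par,n_per number of paroxysmal / persistent patients (>= 1).
#' @param sites character vector of recording sites.
#' @param seed integer seed.
#' @param duration_s recording length, s.
#' @param artifact_prob per-recording probability of one scheduled artifact.
#' @return a list of `cfae_recording`s with class `cfae_cohort`.
#' @export
generate_cohort <- function(n_par, n_per,
                            sites = c("LSPV", "LIPV", "RSPV", "RIPV",
                                      "ANT", "POS"),
                            seed = 1, duration_s = 16,
                            artifact_prob = 0.5) {
  if (n_par < 1 || n_per < 1) stop("patient counts must be >= 1")
  if (length(sites) == 0L) stop("site list must be non-empty")
  set.seed(seed)
  plan <- list()
  idx <- 0L
  for (cls in c("ParAF", "PerAF")) {
    n_cls <- if (cls == "ParAF") n_par else n_per
    preset <- af_preset(cls)
    for (p in seq_len(n_cls)) {
      pid <- sprintf("%s%02d", if (cls == "ParAF") "PAR" else "PER", p)
      pp <- draw_patient_params(preset)
      for (site in sites) {
        idx <- idx + 1L
        prm <- preset
        prm$mean_cl <- max(122, pp$mean_cl + rnorm(1, 0, 4))
        prm$cl_jitter_sd <- pp$cl_jitter_sd
        prm$fractionation <- max(1L, pp$fractionation +
                                   sample(c(-1L, 0L, 1L), 1,
                                          prob = c(.2, .6, .2)))
        prm$seed <- derive_seed(seed, idx)
        sched <- NULL
        if (runif(1) < artifact_prob) {
          dur <- sample(1:2, 1)
          start <- sample(0:(duration_s - dur), 1)
          sched <- if (runif(1) < 0.5) {
            artifact_schedule(
              drift = data.frame(start = start, end = start + dur,
                                 amp = runif(1, 3, 6),
                                 freq = runif(1, 0.3, 1.0)),
              duration_s = duration_s)
          } else {
            artifact_schedule(
              loss = data.frame(start = start, end = start + dur),
              duration_s = duration_s)
          }
        }
        plan[[idx]] <- list(prm = prm, pid = pid, site = site,
                            sched = sched)
      }
    }
  }
  out <- lapply(plan, function(e) {
    rec <- generate_cfae(e$prm, patient_id = e$pid, site = e$site,
                         duration_s = duration_s)
    if (!is.null(e$sched)) rec <- inject_artifacts(rec, e$sched)
    rec
  })
  class(out) <- c("cfae_cohort", "list")
  out
}

#' Cohort manifest
#'
#' @param cohort a list of `cfae_recording`s.
#' @return data.frame with one row per recording: `patient_id`, `af_type`,
#'   `site`.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(patient_id = vapply(cohort, `[[`, "", "patient_id"),
             af_type = vapply(cohort, `[[`, "", "af_type"),
             site = vapply(cohort, `[[`, "", "site"),
             stringsAsFactors = FALSE)
}
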