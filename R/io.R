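#' Write a recording as delimited text
#'
#' Two columns (time in s, amplitude in mV) preceded by `#`-prefixed header
#' lines carrying the metadata. Amplitudes are written with 17 significant
#' digits so a write/read round trip is bitwise exact.
#'
#' @param rec a `cfae_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "cfae_recording"))
  n <- length(rec$samples)
  t <- (seq_len(n) - 1L) / rec$fs
  hdr <- c(sprintf("# patient_id: %s", rec$patient_id),
           sprintf("# site: %s", rec$site),
           sprintf("# af_type: %s", rec$af_type),
           sprintf("# fs: %g", rec$fs),
           "time_s,amplitude_mv")
  body <- sprintf("%.6f,%.17g", t, rec$samples)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a cohort: signal files, manifest, and ground truth
#'
#' One delimited-text file per recording plus `manifest.csv` (patient_id,
#' af_type, site, file) and, when available, `truth_activations.csv`
#' (programmed activation times) and `truth_artifacts.csv` (scheduled
#' artifact intervals).
#'
#' @param cohort list of `cfae_recording`s.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$file <- sprintf("%s_%s.csv", man$patient_id, man$site)
  act <- list()
  art <- list()
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    write_recording(rec, file.path(dir, man$file[i]))
    if (!is.null(rec$truth$activation_times)) {
      act[[i]] <- data.frame(patient_id = rec$patient_id, site = rec$site,
                             time_ms = rec$truth$activation_times)
    }
    sch <- rec$truth$schedule
    if (!is.null(sch)) {
      for (kind in c("drift", "loss")) {
        df <- sch[[kind]]
        if (!is.null(df)) {
          art[[length(art) + 1L]] <-
            data.frame(patient_id = rec$patient_id, site = rec$site,
                       kind = kind, start = df$start, end = df$end)
        }
      }
    }
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (length(act))
    write.csv(do.call(rbind, act), file.path(dir, "truth_activations.csv"),
              row.names = FALSE)
  if (length(art))
    write.csv(do.call(rbind, art), file.path(dir, "truth_artifacts.csv"),
              row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

read_recording_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m) == 0L) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", m[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[-1L]                       # column header row
  amp <- as.numeric(sub("^[^,]*,", "", body))
  list(patient_id = get("patient_id"), site = get("site"),
       af_type = get("af_type"), fs = as.numeric(get("fs")),
       samples = amp)
}

#' Read a cohort from a manifest
#'
#' Each manifest row points to a delimited-text signal file (format of
#' [write_recording()]). Recordings are validated (1 kHz rate, 16 s
#' length); malformed or missing files are rejected row by row with a
#' per-file diagnostic collected in the `rejected` attribute, and the
#' remaining rows are loaded.
#'
#' @param manifest_path path to `manifest.csv`.
#' @param expected_fs required sampling rate, Hz.
#' @param expected_s required duration, s.
#' @return list of `cfae_recording`s with attribute `rejected`
#'   (data.frame: row, file, reason).
#' @export
read_recordings <- function(manifest_path, expected_fs = 1000,
                            expected_s = 16) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  out <- list()
  rejected <- data.frame(row = integer(0), file = character(0),
                         reason = character(0))
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$file[i])
    reason <- NULL
    if (!file.exists(f)) {
      reason <- "file not found"
    } else {
      r <- tryCatch(read_recording_file(f), error = function(e)
        conditionMessage(e))
      if (is.character(r)) {
        reason <- paste("parse error:", r)
      } else if (!isTRUE(r$fs == expected_fs)) {
        reason <- sprintf("sampling rate %s != %g Hz", r$fs, expected_fs)
      } else if (length(r$samples) != expected_fs * expected_s ||
                 anyNA(r$samples)) {
        reason <- sprintf("length %d != %d samples", length(r$samples),
                          expected_fs * expected_s)
      }
    }
    if (is.null(reason)) {
      out[[length(out) + 1L]] <-
        new_recording(r$samples, man$patient_id[i], man$af_type[i],
                      man$site[i], r$fs)
    } else {
      rejected <- rbind(rejected,
                        data.frame(row = i, file = man$file[i],
                                   reason = reason))
    }
  }
  class(out) <- c("cfae_cohort", "list")
  attr(out, "rejected") <- rejected
  out
}

#' Write the fixture scenarios used by the test suite and examples
#'
#' Produces the two worked artifact scenarios (a drift confined to the
#' sixth second; a signal loss spanning seconds six to eight) and a small
#' two-class mini-cohort, all written as delimited text via
#' [write_cohort()].
#'
#' @param seed integer seed.
#' @param dir output directory (default: a fresh temporary directory).
#' @param n_per_class patients per class in the mini cohort.
#' @param sites sites of the mini cohort.
#' @return list with `dir`, `manifest`, and the fixture recordings
#'   (`drift_rec`, `loss_rec`), invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("cfae_fixtures"),
                          n_per_class = 2L,
                          sites = c("LSPV", "LIPV", "RSPV", "RIPV",
                                    "ANT", "POS")) {
  base <- generate_cfae(synth_params("ParAF", mean_cl = 170,
                                     cl_jitter_sd = 8, fractionation = 2L,
                                     seed = derive_seed(seed, 1L)),
                        patient_id = "FIGA", site = "ANT")
  drift_rec <- inject_artifacts(base, artifact_schedule(
    drift = data.frame(start = 5, end = 6, amp = 4, freq = 0.5)))
  base2 <- generate_cfae(synth_params("ParAF", mean_cl = 170,
                                      cl_jitter_sd = 8, fractionation = 2L,
                                      seed = derive_seed(seed, 2L)),
                         patient_id = "FIGB", site = "ANT")
  loss_rec <- inject_artifacts(base2, artifact_schedule(
    loss = data.frame(start = 5, end = 8)))
  cohort <- generate_cohort(n_per_class, n_per_class, sites = sites,
                            seed = seed)
  manifest <- write_cohort(c(list(drift_rec, loss_rec), cohort), dir)
  invisible(list(dir = dir, manifest = manifest, drift_rec = drift_rec,
                 loss_rec = loss_rec))
}
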