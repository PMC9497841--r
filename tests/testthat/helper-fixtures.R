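# Shared fixtures, built in code at test time.

clean_params <- function(seed, af_type = "ParAF", mean_cl = 163,
                         jitter = 8, frac = 2L, noise_sd = 0.01) {
  synth_params(af_type, mean_cl = mean_cl, cl_jitter_sd = jitter,
               fractionation = frac, noise_sd = noise_sd,
               powerline_amp = 0, seed = seed)
}

fig2a_recording <- function(seed = 5) {
  base <- generate_cfae(clean_params(seed, mean_cl = 170))
  inject_artifacts(base, artifact_schedule(
    drift = data.frame(start = 5, end = 6, amp = 4, freq = 0.5)))
}

fig2b_recording <- function(seed = 5) {
  base <- generate_cfae(clean_params(seed, mean_cl = 170))
  inject_artifacts(base, artifact_schedule(
    loss = data.frame(start = 5, end = 8)))
}

# Minimal segment index table: one recording per (patient, site), `n_seg`
# segments per recording at window length w.
toy_seg_tab <- function(values, patient_id, site, af_type, w = 1,
                        quality = 1L) {
  n <- length(values)
  data.frame(patient_id = rep(patient_id, n), site = rep(site, n),
             af_type = rep(af_type, n), w = w, segment = seq_len(n),
             quality = rep(quality, length.out = n), SE = values,
             DET = values, stringsAsFactors = FALSE)
}
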