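# Small synthetic fixtures shared across test files; everything is built in
# code from fixed seeds.

fix_trials <- function(n_blocks = 4, n_trials = 32, seed = 7, ...) {
  generate_trial_sequence(n_blocks, n_trials, seed = seed, ...)
}

fix_betas <- function(trials, effect = 0, info = "across", n_voxels = 16,
                      roi = "IPS", seed = 11) {
  specs <- if (effect > 0) list(effect_spec(info, effect, roi = roi)) else list()
  simulate_fmri_betas(trials, list(list(roi = roi, n_voxels = n_voxels)),
                      specs, scheme = info, seed = seed)[[roi]]
}

fix_epochs <- function(trials, effect = 0, info = "across",
                       window = c(300, 700), n_sensors = 10,
                       rate = 20, span = c(-200, 1000), seed = 13, ...) {
  specs <- if (effect > 0) list(effect_spec(info, effect, window_ms = window))
           else list()
  simulate_meg_epochs(trials, n_sensors, specs, sampling_rate_hz = rate,
                      span_stim_ms = span, seed = seed, ...)
}

# One group-level fusion replicate in the recovery test-bed: 8 participants,
# 6 blocks x 32 trials each, a 6-voxel ROI and 6 MEG sensors, analysis span
# 150..800 ms at 40 Hz. The planted effect (if any) is hemifield information
# of multivariate amplitude `effect` in the 300..700 ms window, present in
# both modalities.
grp_fusion_replicate <- function(seed, effect = 2, n_perm = 200,
                                 window = c(300, 700)) {
  specs <- if (effect > 0)
    list(effect_spec("across", effect, roi = "IPS", window_ms = window))
  else list()
  parts <- lapply(1:8, function(p) {
    s <- seed + p * 10
    tr <- generate_trial_sequence(6, 32, seed = s)
    bb <- simulate_fmri_betas(tr, list(list(roi = "IPS", n_voxels = 6)),
                              specs, "across", seed = s + 1)$IPS
    ep <- simulate_meg_epochs(tr, 6, specs, alignment = "stimulus",
                              sampling_rate_hz = 40,
                              span_stim_ms = c(150, 800), seed = s + 2)
    list(tr = tr, bb = bb, ep = ep)
  })
  commonality_fusion(lapply(parts, `[[`, "bb"), lapply(parts, `[[`, "ep"),
                     "across", trials = lapply(parts, `[[`, "tr"),
                     n_perm = n_perm, k = 10, seed = seed + 999)
}

# Per-trial binary labels for an info type, restricted to an epochs object.
fix_meg_labels <- function(epochs, trials, info = "across") {
  lv <- rsafusion:::trial_levels(trials, info)
  keep <- !trials$omitted & trials$correct
  lv[!keep] <- NA
  lv[match(epochs$trial_ids, trials$trial_id)]
}
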