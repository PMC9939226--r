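# Row builder: one lesion measurement with sensible defaults.
mrow <- function(patient, lesion, location, timepoint, lad,
                 sad = 0.6 * lad, arm = "A",
                 vol = pi / 6 * lad^3,
                 nodal = location == "lymph_node") {
  tibble::tibble(
    patient_id = patient, arm = arm, lesion_id = lesion, location = location,
    nodal = nodal, timepoint = timepoint,
    lad_mm = lad, sad_mm = sad, volume_mm3 = vol
  )
}

# A lesion observed at both timepoints, its sizes scaled by `factor` at
# follow-up (volume scales by factor^3, i.e. isotropic shrinkage).
two_tp <- function(patient, lesion, location, lad, factor, arm = "A") {
  dplyr::bind_rows(
    mrow(patient, lesion, location, "baseline", lad, arm = arm),
    mrow(patient, lesion, location, "week12", lad * factor, arm = arm,
         vol = pi / 6 * lad^3 * factor^3)
  )
}

# A small cap-compliant random dataset for property tests.
random_dataset <- function(seed, n_patients = c(A = 8, B = 8),
                           patient_sd = 12, lesion_sd = 8, dropout = 0.15) {
  cfg <- synthetic_config(
    n_patients = n_patients,
    location_probs = list(
      A = c(breast = 0.3, lung = 0.3, liver = 0.25, lymph_node = 0.15),
      B = c(breast = 0.25, lung = 0.35, liver = 0.2, lymph_node = 0.2)
    ),
    mu_diameter = rbind(A = c(breast = -40, lung = -20, liver = -5, lymph_node = -30),
                        B = c(breast = -15, lung = -10, liver = -20, lymph_node = -25)),
    mu_volume = rbind(A = c(breast = -70, lung = -40, liver = -10, lymph_node = -55),
                      B = c(breast = -30, lung = -20, liver = -40, lymph_node = -45)),
    patient_sd = patient_sd, lesion_sd = lesion_sd, dropout = dropout
  )
  generate_trial(cfg, seed = seed)
}

# Baseline-only fixture with the published location mix: 88 lesions
# (lung 27, breast 23, liver 20, lymph node 15, other 3), arms split per
# the published per-arm counts; the 3 "other" lesions sit in arm VC.
published_mix_dataset <- function() {
  spec <- tibble::tibble(
    location = rep(c("breast", "lung", "liver", "lymph_node", "other"),
                   times = c(2, 2, 2, 2, 1)),
    arm = c("VC", "LC", "VC", "LC", "VC", "LC", "VC", "LC", "VC"),
    n = c(12, 11, 7, 20, 9, 11, 6, 9, 3)
  )
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    with(spec[i, ], dplyr::bind_rows(lapply(seq_len(n), function(j) {
      mrow(sprintf("%s-%s-%02d", arm, location, j), "L1", location,
           "baseline", lad = 30, arm = arm)
    })))
  })
  trial_dataset(dplyr::bind_rows(rows))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments,
# using the 2 * min(tail) convention.
mw_exact_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs + 1e-9)
  p_hi <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
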