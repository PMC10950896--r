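# Shared small fixtures, built in code at load time.

# A small, quickly generated activity class suitable for model tests:
# 256-bit fingerprints, 16 signal bits, moderate noise.
small_class <- function(n = 300, noise_sd = 0.5, seed = 5) {
  generate_activity_class(
    synthetic_class_config(n_compounds = n, n_bits = 256L,
                           n_signal_bits = 16L, bit_density = 0.1,
                           noise_sd = noise_sd, seed = seed),
    class_id = "fixture")
}

# A noise-free class: pIC50 is an exact linear function of the fingerprint.
noise_free_class <- function(n = 120, seed = 9) {
  generate_activity_class(
    synthetic_class_config(n_compounds = n, n_bits = 128L,
                           n_signal_bits = 12L, bit_density = 0.15,
                           noise_sd = 0, seed = seed),
    class_id = "noise-free")
}

# Hand-rolled prediction sets with known calibration factor.
calibrated_ps <- function(n, c = 1, sigma = 0.5, seed = 1) {
  generate_prediction_set(synthetic_prediction_config(
    n = n, sigma_law = sigma, calibration_factor = c, seed = seed))
}

# A raw-record table spanning the curation boundaries.
raw_record_fixture <- function() {
  data.frame(
    compound_id = sprintf("C%02d", 1:8),
    target_id = "T1",
    mol_mass = c(400, 999.9, 1000.0, 1500, 400, 400, NA, 250),
    potency_molar = c(1e-6, 1e-7, 1e-8, 1e-8, 1e-5, 2e-5, 1e-8, 5e-12),
    stringsAsFactors = FALSE)
}
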