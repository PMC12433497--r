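# Shared fixture builders: everything is generated in code at test time.

trial_feed <- function() {
  feed_composition(dm = 900, nitrogen = 25, fat = 50, ash = 131, sugar = 38)
}

# A tiny hand-built two-bird dataset with round numbers.
tiny_dataset <- function() {
  birds <- data.frame(
    bird_id = c("A001", "B001"), line = c("A", "B"),
    dfc = c(140, 120), dmw = c(120, 150), dbw = c(1700, 1680),
    eggs_laid = c(7L, 8L), mean_egg_weight = c(60, 58))
  assays <- data.frame(
    bird_id = c("A001", "B001"), adm = c(252, 260), dm_ad = c(900, 900),
    ash_ad = c(200, 210), nitrogen_ad = c(30, 32), fat_ad = c(25, 28),
    uric_acid_ad = c(30, 35))
  trial_dataset(birds, assays, trial_feed())
}

# Small zero-noise simulated trial whose latent coefficients the pipeline
# must recover exactly.
zero_noise_sim <- function(seed = 1, n_birds = 5,
                           dc_means = c(dm = 70, fat = 85, n = 75, org = 72)) {
  lp <- line_params(
    n_birds = n_birds, dfc_mean = 130, dfc_sd = 10,
    dbw_mean = 1700, dbw_sd = 100,
    egg_weight_mean = 60, egg_weight_sd = 4, laying_prob = 0.9,
    true_dc_means = dc_means,
    true_dc_sds = c(dm = 0, fat = 0, n = 0, org = 0),
    manure_moisture_frac = 0.75, assay_noise_cv = 0)
  simulate_trial(sim_config(lines = list(L = lp), seed = seed))
}
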