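test_that("same seed reproduces the trial bit-for-bit; different seeds differ", {
  s1 <- simulate_trial(sim_config(seed = 11))
  s2 <- simulate_trial(sim_config(seed = 11))
  s3 <- simulate_trial(sim_config(seed = 12))
  expect_identical(s1$dataset$birds, s2$dataset$birds)
  expect_identical(s1$dataset$assays, s2$dataset$assays)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_false(identical(s1$dataset$birds$dfc, s3$dataset$birds$dfc))
})

test_that("per-bird substreams: enlarging a line never perturbs earlier birds", {
  small <- hen_line_defaults(n_birds = 10)
  big <- hen_line_defaults(n_birds = 25)
  s_small <- simulate_trial(sim_config(seed = 5, lines = small))
  s_big <- simulate_trial(sim_config(seed = 5, lines = big))
  ids <- s_small$dataset$birds$bird_id
  expect_identical(s_small$dataset$birds,
                   s_big$dataset$birds[s_big$dataset$birds$bird_id %in% ids, ])
})

test_that("mass balance holds for every simulated bird", {
  sim <- simulate_trial(sim_config(seed = 9))
  d <- sim$dataset
  # each assayed component, expressed per kg of air-dried sample, fits
  # inside the sample dry matter, so excreted DM bounds every nutrient mass
  with(d$assays, {
    expect_true(all(ash_ad <= dm_ad))
    expect_true(all(nitrogen_ad <= dm_ad))
    expect_true(all(fat_ad <= dm_ad))
    expect_true(all(uric_acid_ad <= dm_ad))
  })
  # fresh manure is excreted DM inflated by the moisture fraction
  dm_ex <- manure_dm_amount(d$assays$adm, d$birds$dmw)
  expect_true(all(dm_ex <= d$birds$dmw))
  expect_true(all(sim$ground_truth$dc_dm >= 0 & sim$ground_truth$dc_dm <= 100))
})

test_that("degenerate laying probability fills the laying window", {
  lp <- line_params(n_birds = 6, dfc_mean = 130, dfc_sd = 5,
                    dbw_mean = 1700, dbw_sd = 50,
                    egg_weight_mean = 60, egg_weight_sd = 2, laying_prob = 1,
                    true_dc_means = c(dm = 70, fat = 85, n = 75, org = 72),
                    true_dc_sds = c(dm = 1, fat = 1, n = 1, org = 1),
                    manure_moisture_frac = 0.75)
  sim <- simulate_trial(sim_config(lines = list(L = lp), seed = 2))
  expect_true(all(sim$dataset$birds$eggs_laid == 8L))
})

test_that("simulated trait means converge to the line parameters", {
  lp <- line_params(n_birds = 10000, dfc_mean = 130, dfc_sd = 8,
                    dbw_mean = 1700, dbw_sd = 60,
                    egg_weight_mean = 60, egg_weight_sd = 3, laying_prob = 0.9,
                    true_dc_means = c(dm = 70, fat = 85, n = 75, org = 72),
                    true_dc_sds = c(dm = 2, fat = 1, n = 2, org = 1.5),
                    manure_moisture_frac = 0.75, assay_noise_cv = 0)
  sim <- simulate_trial(sim_config(lines = list(L = lp), seed = 4))
  b <- sim$dataset$birds
  n <- nrow(b)
  expect_lt(abs(mean(b$dfc) - 130), 3 * 8 / sqrt(n))
  expect_lt(abs(mean(b$dbw) - 1700), 3 * 60 / sqrt(n))
  expect_lt(abs(mean(b$eggs_laid) - 8 * 0.9),
            3 * sqrt(8 * 0.9 * 0.1) / sqrt(n))
  expect_lt(abs(mean(sim$ground_truth$dc_dm) - 70), 3 * 2 / sqrt(n))
})

test_that("infeasible digestibility parameterisations are refused", {
  # near-zero DM digestibility with high organic digestibility cannot close
  lp <- line_params(n_birds = 2, dfc_mean = 130, dfc_sd = 5,
                    dbw_mean = 1700, dbw_sd = 50,
                    egg_weight_mean = 60, egg_weight_sd = 2, laying_prob = 0.9,
                    true_dc_means = c(dm = 95, fat = 85, n = 75, org = 10),
                    true_dc_sds = c(dm = 0, fat = 0, n = 0, org = 0),
                    manure_moisture_frac = 0.75)
  expect_error(simulate_trial(sim_config(lines = list(L = lp), seed = 1)),
               "feasible")
})

test_that("inject_outliers displaces exactly k birds past the fences", {
  lines <- hen_line_defaults(n_birds = 50, assay_noise_cv = 0)
  sim <- simulate_trial(sim_config(seed = 1, lines = lines["A"]))
  out <- inject_outliers(sim$dataset, k = 7, magnitude = 3, seed = 2)
  expect_length(out$bird_ids, 7)
  flt <- iqr_filter(out$dataset$birds, traits = "dfc", k = 1.5)
  expect_setequal(flt$removed$bird_id, out$bird_ids)
  expect_equal(nrow(flt$retained), 43)
  # sub-threshold displacement stays inside the fences
  out2 <- inject_outliers(sim$dataset, k = 3, magnitude = 0.1, seed = 2)
  flt2 <- iqr_filter(out2$dataset$birds, traits = "dfc", k = 1.5)
  expect_equal(nrow(flt2$removed), 0)
  expect_error(inject_outliers(sim$dataset, k = 0), "positive")
  expect_error(inject_outliers(sim$dataset, k = 50), "smaller")
})
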