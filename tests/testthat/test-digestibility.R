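test_that("air-dried assay values convert to the dry-matter basis", {
  a <- data.frame(bird_id = "h1", adm = 260, dm_ad = 900, ash_ad = 180,
                  nitrogen_ad = 25, fat_ad = 20, uric_acid_ad = 30)
  b <- airdry_to_dm_basis(a)
  expect_equal(b$nitrogen_dm, 25 * 1000 / 900)  # 27.78 g/kg DM
  expect_equal(b$org_dm, 1000 - 180 * 1000 / 900)
  # bone-dry sample: identity conversion
  a$dm_ad <- 1000
  b <- airdry_to_dm_basis(a)
  expect_equal(b$nitrogen_dm, 25)
  # zero ash: all dry matter is organic
  a$ash_ad <- 0
  expect_equal(airdry_to_dm_basis(a)$org_dm, 1000)
})

test_that("uric-acid nitrogen correction is stoichiometric, floored at zero", {
  expect_equal(ua_nitrogen_fraction(), 4 * 14.007 / 168.11)
  expect_equal(correct_nitrogen_for_uric_acid(30, 15),
               30 - 4 * 14.007 / 168.11 * 15)
  expect_equal(round(correct_nitrogen_for_uric_acid(30, 15), 2), 25.00)
  expect_equal(correct_nitrogen_for_uric_acid(30, 0), 30)
  expect_warning(out <- correct_nitrogen_for_uric_acid(3, 15), "floored")
  expect_equal(out, 0)
})

test_that("manure and feed dry-matter amounts follow the printed arithmetic", {
  expect_equal(round(manure_dm_amount(260.2, 146.6), 1), 38.1)
  expect_equal(round(manure_dm_amount(252.4, 121.6), 1), 30.7)
  expect_equal(manure_dm_amount(0, 100), 0)
  expect_equal(feed_dm_amount(122.8, 900), 110.52)
  expect_equal(feed_dm_amount(122.8, 1000), 122.8)
  expect_equal(feed_dm_amount(0, 900), 0)
})

test_that("digestibility coefficient formulas cover their boundary cases", {
  expect_equal(round(dc_dry_matter(manure_dm_amount(260.2, 146.6),
                                   feed_dm_amount(122.8, 900)), 1), 65.5)
  expect_equal(dc_dry_matter(0, 110), 100)
  expect_equal(dc_dry_matter(110, 110), 0)
  expect_error(dc_dry_matter(10, 0), "positive")
  expect_equal(dc_nutrient(30, 20, 120, 25), 80)
  expect_equal(dc_nutrient(30, 0, 120, 25), 100)
  expect_equal(dc_nutrient(30, 100, 120, 25), 0)
  expect_error(dc_nutrient(30, 20, 120, 0), "absent")
})

test_that("compute_all_dcs inverts the zero-noise generator exactly", {
  sim <- zero_noise_sim(seed = 3, n_birds = 5)
  dcs <- compute_all_dcs(sim$dataset)
  expect_equal(dcs$dc_dm, rep(70, 5), tolerance = 1e-12)
  expect_equal(dcs$dc_fat, rep(85, 5), tolerance = 1e-12)
  expect_equal(dcs$dc_n, rep(75, 5), tolerance = 1e-12)
  expect_equal(dcs$dc_org, rep(72, 5), tolerance = 1e-12)
  expect_true(all(is.na(dcs$flags)))
})

test_that("dc_dry_matter is monotone and scale-invariant", {
  manure <- seq(10, 100, by = 10)
  dc <- dc_dry_matter(manure, 110)
  expect_true(all(diff(dc) < 0))                     # decreasing in manure DM
  expect_true(all(diff(dc_dry_matter(50, manure + 50)) > 0))  # increasing in feed DM
  # common rescaling of intake and excretion leaves every coefficient unchanged
  d <- tiny_dataset()
  base <- compute_all_dcs(d)
  scaled <- d
  scaled$birds$dfc <- d$birds$dfc * 3.7
  scaled$birds$dmw <- d$birds$dmw * 3.7
  expect_equal(compute_all_dcs(scaled)[c("dc_dm", "dc_fat", "dc_n", "dc_org")],
               base[c("dc_dm", "dc_fat", "dc_n", "dc_org")], tolerance = 1e-12)
})

test_that("uric-acid correction only lowers the manure nitrogen term", {
  d <- tiny_dataset()
  with_ua <- compute_all_dcs(d)
  no_ua <- d
  no_ua$assays$uric_acid_ad <- 0
  without <- compute_all_dcs(no_ua)
  expect_true(all(with_ua$dc_n >= without$dc_n))
  # f_ua = 0 reproduces the uncorrected coefficient
  expect_equal(compute_all_dcs(d, f_ua = 0)$dc_n, without$dc_n)
})

test_that("degenerate excretion and negative balances are flagged, not hidden", {
  d <- tiny_dataset()
  d$birds$dmw[1] <- 0
  expect_warning(dcs <- compute_all_dcs(d), "zero manure")
  expect_equal(unlist(dcs[1, c("dc_dm", "dc_fat", "dc_n", "dc_org")],
                      use.names = FALSE), rep(100, 4))
  expect_match(dcs$flags[1], "zero_manure")
  d2 <- tiny_dataset()
  d2$birds$dmw[2] <- 900  # manure DM far above intake
  dcs2 <- compute_all_dcs(d2)
  expect_true(dcs2$dc_dm[2] < 0)
  expect_match(dcs2$flags[2], "mass_balance")
})
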