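test_that("partial-dissection LMP follows the reference formula", {
  cw <- cut_weights(tenderloin = 0.4,
                    joint_shoulder = 8, joint_loin = 7, joint_ham = 10,
                    joint_belly = 5,
                    lean_shoulder = 6, lean_loin = 5, lean_ham = 8,
                    lean_belly = 2,
                    half_carcass_weight = 45)
  expect_equal(compute_ypd(cw), 100 * 21.4 / 30.4, tolerance = 1e-12)

  # all-lean cuts give exactly 100%
  full <- cut_weights(0.4, 8, 7, 10, 5, 8, 7, 10, 5,
                      half_carcass_weight = 45)
  expect_equal(compute_ypd(full), 100)
})

test_that("YPD and YTD are invariant to a rescaling of all weights", {
  cw <- generate_cut_weights(make_carcass(), seed = 3)
  scaled <- cw
  for (nm in names(scaled))
    scaled[[nm]] <- scaled[[nm]] * 2.5
  expect_equal(compute_ypd(scaled), compute_ypd(cw), tolerance = 1e-12)
  expect_equal(compute_ytd(scaled$total_lean_weight,
                           scaled$half_carcass_weight),
               compute_ytd(cw$total_lean_weight, cw$half_carcass_weight),
               tolerance = 1e-12)
})

test_that("total-dissection LMP is the lean share of the half carcass", {
  expect_equal(compute_ytd(25, 50), 50)
  expect_equal(compute_ytd(50, 50), 100)
  expect_equal(compute_ytd(29.81, 50), 59.62)
  expect_error(compute_ytd(1, 0), "positive")
  expect_error(compute_ytd(51, 50), "total_lean_weight")
})

test_that("malformed cut weights are rejected", {
  expect_error(cut_weights(0.4, 8, 7, 10, 5, 9, 5, 8, 2, 45),
               "lean weight exceeds joint")
  expect_error(compute_ypd(data.frame(tenderloin = 1)), "missing")
})

test_that("the scaling factor is the rounded ratio of subsample means", {
  sf <- compute_sf(59.62, 67.12)
  expect_equal(sf$value, 0.89)
  expect_equal(sf$ytd_mean, 59.62)
  expect_true(sf$rounded)

  # ratio of means, not mean of ratios: 55/65 = 0.8462 -> 0.85
  # (mean of ratios would be 0.8452)
  sf2 <- compute_sf(c(50, 60), c(60, 70))
  expect_equal(sf2$value, 0.85)
  expect_equal(compute_sf(c(50, 60), c(60, 70), round_to = NULL)$value,
               55 / 65, tolerance = 1e-12)

  # self-ratio
  expect_equal(compute_sf(c(55, 60, 65), c(55, 60, 65))$value, 1.00)

  expect_error(compute_sf(numeric(0), numeric(0)), "non-empty")
  expect_error(compute_sf(c(1, 2), 1), "paired")
})

test_that("bias correction is linear and closes over the mean", {
  sf <- compute_sf(59.62, 67.12)
  ypd <- c(54.84, 67.12, 72.57)
  corrected <- apply_sf(ypd, sf)
  expect_equal(mean(corrected), sf$value * mean(ypd), tolerance = 1e-12)
  expect_equal(apply_sf(67.12, sf), 59.7368, tolerance = 1e-12)
  expect_equal(apply_sf(54.84, sf), 48.8076, tolerance = 1e-12)
  expect_equal(apply_sf(ypd, 1), ypd)
  expect_error(apply_sf(101, sf), "0, 100")
})

test_that("a generated subsample calibrated to known means reproduces them", {
  # 12 carcasses whose partial/total LMP pairs average 67.12 and 59.62:
  # the dissection chain (cut weights -> YPD/YTD -> SF) must return those
  # means and the published 0.89 factor
  ytd <- 59.62 + c(-4.5, -3, -2, -1, -0.5, 0, 0.2, 0.8, 1.5, 2.5, 3, 3)
  ytd <- ytd - (mean(ytd) - 59.62)
  ypd <- ytd / 0.89 + c(0.3, -0.2, 0.1, 0, -0.1, 0.2, -0.3, 0.1, 0, -0.1,
                        0.05, -0.05)
  ypd <- ypd + (67.12 - mean(ypd))
  sub <- data.frame(id = sprintf("S%02d", 1:12), sex = "gilt",
                    hot_weight_kg = seq(80, 113, length.out = 12),
                    f2_mm = 15, m2_mm = 62, ytd_true = ytd, ypd_obs = ypd)
  ypd_meas <- ytd_meas <- numeric(12)
  for (i in 1:12) {
    cw <- generate_cut_weights(sub[i, ], seed = i)
    ypd_meas[i] <- compute_ypd(cw)
    ytd_meas[i] <- compute_ytd(cw$total_lean_weight,
                               cw$half_carcass_weight)
  }
  expect_equal(mean(ypd_meas), 67.12, tolerance = 1e-9)
  expect_equal(mean(ytd_meas), 59.62, tolerance = 1e-9)
  sf <- compute_sf(ytd_meas, ypd_meas)
  expect_equal(sf$value, 0.89)
  expect_equal(round_half_up(mean(apply_sf(ypd_meas, sf)), 2), 59.74)
})

test_that("noise-free synthetic subsamples recover sf_true exactly", {
  for (s in c(0.85, 0.89, 1.0)) {
    p <- population_params(n = 200, sf_true = s, sigma_delta = 0,
                           seed = 50)
    pop <- generate_population(p)
    sf <- compute_sf(pop$ytd_true, pop$ypd_obs, round_to = NULL)
    expect_equal(sf$value, s, tolerance = 1e-9)
  }
})
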