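test_that("generated populations recover the truncated-Gaussian moments", {
  p <- population_params(n = 50000, seed = 11)
  pop <- generate_population(p)
  expect_equal(nrow(pop), 50000)

  # box truncation shifts the Gaussian moments slightly (by more than a
  # 3-SE band at this n), so the reference values are the truncated
  # distribution's exact moments from an independent closed-form /
  # quadrature oracle
  wf <- box_moments_wf(p)
  m2 <- tnorm_moments(p$mean_m2, p$sd_m2, p$m2_range[1], p$m2_range[2])
  se3 <- function(sd) 3 * sd / sqrt(nrow(pop))
  expect_lt(abs(mean(pop$f2_mm) - wf$mean_f2), se3(wf$sd_f2))
  expect_lt(abs(mean(pop$hot_weight_kg) - wf$mean_weight),
            se3(wf$sd_weight))
  expect_lt(abs(mean(pop$m2_mm) - m2$mean), se3(m2$sd))
  expect_lt(abs(sd(pop$f2_mm) - wf$sd_f2), se3(wf$sd_f2))
  expect_lt(abs(sd(pop$hot_weight_kg) - wf$sd_weight), se3(wf$sd_weight))

  # and truncation distorts the requested moments only mildly
  expect_lt(abs(wf$mean_f2 - p$mean_f2), 0.3)
  expect_lt(abs(wf$mean_weight - p$mean_weight), 0.3)
  expect_lt(abs(m2$mean - p$mean_m2), 0.3)

  # truncation bounds are honoured
  expect_true(all(pop$hot_weight_kg >= 60 & pop$hot_weight_kg <= 120))
  expect_true(all(pop$f2_mm >= 3 & pop$f2_mm <= 55))
  expect_true(all(pop$m2_mm >= 21 & pop$m2_mm <= 99))
  expect_true(all(pop$ytd_true > 0 & pop$ytd_true < 100))

  # sex split near the requested fraction
  expect_lt(abs(mean(pop$sex == "gilt") - 0.5), 3 * 0.5 / sqrt(nrow(pop)))
})

test_that("noise-free generation reduces to the exact linear model", {
  p <- population_params(n = 500, sigma_ytd = 0, sigma_delta = 0,
                         sf_true = 1, seed = 3)
  pop <- generate_population(p)
  lin <- p$beta0 + p$beta_f * pop$f2_mm + p$beta_m * pop$m2_mm
  expect_equal(pop$ytd_true, lin, tolerance = 1e-12)
  expect_equal(pop$ypd_obs, lin, tolerance = 1e-12)
})

test_that("the generated total/partial ratio matches sf_true", {
  p <- population_params(n = 10000, sf_true = 0.89, sigma_delta = 0,
                         seed = 5)
  pop <- generate_population(p)
  expect_equal(mean(pop$ytd_true / pop$ypd_obs), 0.89, tolerance = 1e-9)
})

test_that("generation is bit-identical for a fixed seed", {
  p <- small_params(n = 300, seed = 99)
  expect_identical(generate_population(p), generate_population(p))
  # and the seed argument overrides the one stored in the parameters
  expect_identical(generate_population(p, seed = 7),
                   generate_population(small_params(n = 300, seed = 1),
                                       seed = 7))
})

test_that("invalid population parameters are rejected with diagnostics", {
  expect_error(population_params(n = 0), "positive integer")
  expect_error(population_params(n = 10, sd_f2 = -1), "positive")
  expect_error(population_params(n = 10, gilt_fraction = 1.4), "gilt")
  expect_error(population_params(n = 10, sf_true = 1.5), "sf_true")
  # perfectly correlated triple -> not positive-definite
  expect_error(population_params(n = 10, corr_weight_f2 = 0.99,
                                 corr_f2_m2 = 0.99,
                                 corr_weight_m2 = -0.99),
               "positive-definite")
})

test_that("cut weights round-trip the carcass's latent LMP values", {
  p <- small_params(n = 50, seed = 12)
  pop <- generate_population(p)
  for (i in c(1, 17, 50)) {
    cw <- generate_cut_weights(pop[i, ], seed = 1000 + i)
    expect_equal(compute_ypd(cw), pop$ypd_obs[i], tolerance = 1e-9)
    expect_equal(compute_ytd(cw$total_lean_weight, cw$half_carcass_weight),
                 pop$ytd_true[i], tolerance = 1e-9)
  }
})

test_that("cut-weight generation is deterministic and mass-consistent", {
  c1 <- make_carcass(hot_weight_kg = 100, ytd_true = 50, ypd_obs = 56)
  cw <- generate_cut_weights(c1, seed = 8)
  expect_identical(cw, generate_cut_weights(c1, seed = 8))
  # 50% of the 50 kg half carcass
  expect_equal(cw$total_lean_weight, 25)
  expect_equal(cw$half_carcass_weight, 50)
  leans <- c(cw$lean_shoulder, cw$lean_loin, cw$lean_ham, cw$lean_belly)
  joints <- c(cw$joint_shoulder, cw$joint_loin, cw$joint_ham,
              cw$joint_belly)
  expect_true(all(leans >= 0 & leans <= joints))
  expect_lte(cw$tenderloin + sum(joints), cw$half_carcass_weight)
})

test_that("infeasible dissection targets are refused", {
  bad <- make_carcass(ytd_true = 105, ypd_obs = 60)
  expect_error(generate_cut_weights(bad, seed = 1), "ytd_true")
  bad2 <- make_carcass(ytd_true = 60, ypd_obs = 0.5)
  expect_error(generate_cut_weights(bad2, seed = 1), "infeasible")
})
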