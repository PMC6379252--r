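test_that("simulation spec validates its inputs", {
  b <- small_bank()
  expect_error(simulation_spec(0, b), "positive")
  expect_error(simulation_spec(10, b, gender_fractions = c(M = 0.6, F = 0.6)),
               "summing to 1")
  expect_error(simulation_spec(10, b, gender_theta_sd = c(M = 0, F = 1)),
               "positive")
  expect_error(
    simulation_spec(10, b, dif = list(dif_injection(99, "gender"))),
    "not in the bank"
  )
  expect_error(dif_injection(1, "gender", discrimination_ratio = -1), "positive")
})

test_that("simulation is seed-deterministic with valid scores", {
  spec <- simulation_spec(300, small_bank())
  d1 <- simulate_responses(spec, seed = 7)
  d2 <- simulate_responses(spec, seed = 7)
  d3 <- simulate_responses(spec, seed = 8)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  m <- as.matrix(d1[grep("^item", names(d1))])
  expect_true(all(m %in% 0:3))
  expect_equal(dim(m), c(300L, 5L))
})

test_that("empirical category frequencies converge to the implied marginals", {
  bank <- bdi2_bank()
  d <- simulate_responses(simulation_spec(200000, bank), seed = 13)
  implied <- implied_marginals(bank)
  for (j in c(1, 10, 16)) {
    emp <- tabulate(d[[paste0("item", sprintf("%02d", j))]] + 1L, 4) / 200000
    imp <- implied$prob[implied$item == j]
    mc_se <- sqrt(imp * (1 - imp) / 200000)
    expect_true(all(abs(emp - imp) <= 3 * mc_se + 1e-12),
                info = paste("item", j))
  }
})

test_that("without DIF or trait shifts the groups are exchangeable", {
  d <- simulate_responses(simulation_spec(20000, small_bank()), seed = 3)
  tot <- rowSums(as.matrix(d[grep("^item", names(d))]))
  diff <- mean(tot[d$gender == "F"]) - mean(tot[d$gender == "M"])
  se <- sqrt(var(tot[d$gender == "F"]) / sum(d$gender == "F") +
               var(tot[d$gender == "M"]) / sum(d$gender == "M"))
  expect_lt(abs(diff), 4 * se)
})

test_that("uniform DIF injection raises focal endorsement at matched theta", {
  bank <- bdi2_bank()
  inj <- dif_injection(10, "gender", "F", threshold_shift = 0.75)
  d <- simulate_responses(
    simulation_spec(40000, bank, dif = list(inj)), seed = 5
  )
  # same theta distribution in both groups, so marginal endorsement of
  # categories >= 1 must be higher for the focal group on the DIF item
  p_f <- mean(d$item10[d$gender == "F"] >= 1)
  p_m <- mean(d$item10[d$gender == "M"] >= 1)
  expect_gt(p_f, p_m + 0.05)
  # and untouched items stay exchangeable
  p_f2 <- mean(d$item05[d$gender == "F"] >= 1)
  p_m2 <- mean(d$item05[d$gender == "M"] >= 1)
  expect_lt(abs(p_f2 - p_m2), 0.02)
})

test_that("calibrate_group_mean inverts the population TCC", {
  bank <- bdi2_bank()
  mo <- implied_moments(bank)
  # fixed point: the implied total at mu = 0 maps back to mu = 0
  expect_equal(calibrate_group_mean(bank, mo$total_mean), 0, tolerance = 1e-5)
  # published overall mean total corresponds to a near-zero latent mean
  expect_lt(abs(calibrate_group_mean(bank, 6.99)), 0.02)
  # monotone in the target
  expect_gt(calibrate_group_mean(bank, 7.85), calibrate_group_mean(bank, 5.92))
  expect_error(calibrate_group_mean(bank, 64), "inside")
  expect_error(calibrate_group_mean(bank, 0), "inside")
})

test_that("the study fixture reproduces the survey's group structure", {
  d <- make_study_fixture(seed = 1)
  expect_equal(nrow(d), 12677L)
  m <- as.matrix(d[grep("^item", names(d))])
  expect_equal(ncol(m), 21L)
  expect_true(all(m %in% 0:3))
  expect_equal(mean(d$gender == "F"), 0.551, tolerance = 0.02)
  expect_equal(mean(d$age_group == "younger"), 0.859, tolerance = 0.02)
  tot <- rowSums(m)
  # calibrated latent shifts should land the group means near the published
  # values (7.85 women / 5.92 men), within Monte-Carlo error
  expect_equal(mean(tot[d$gender == "F"]), 7.85, tolerance = 0.35)
  expect_equal(mean(tot[d$gender == "M"]), 5.92, tolerance = 0.35)
})

test_that("missing-at-random masking respects the requested rate", {
  spec <- simulation_spec(5000, small_bank(), missing_rate = 0.1)
  d <- simulate_responses(spec, seed = 2)
  m <- as.matrix(d[grep("^item", names(d))])
  expect_lt(abs(mean(is.na(m)) - 0.1), 0.01)
})
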