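test_that("sparse categories collapse before fitting", {
  y <- c(rep(0L, 50), rep(1L, 40), rep(2L, 8), rep(3L, 2))
  g <- factor(rep(c("M", "F"), 50))
  y2 <- collapse_sparse_categories(y, g, min_cell = 5)
  expect_lt(length(unique(y2)), length(unique(y)))
  expect_true(all(table(factor(y2), g) >= 5))
})

test_that("a clean item is not flagged and an injected item is", {
  bank <- bdi2_bank()
  inj <- dif_injection(10, "gender", "F", threshold_shift = 0.75)
  d <- simulate_responses(simulation_spec(6000, bank, dif = list(inj)), seed = 19)
  th <- eap_score(d, bank)$theta
  g <- factor(d$gender, levels = c("M", "F"))

  r10 <- dif_single_item(d$item10, th, g)
  expect_true(r10$flagged)
  expect_equal(r10$dif_type, "uniform")
  expect_gt(r10$r2_mcfadden_13, 0.02)
  expect_lt(r10$r2_mcfadden_23, 0.02)
  expect_gt(r10$beta_group, 0)  # focal group endorses more easily

  r05 <- dif_single_item(d$item05, th, g)
  expect_false(r05$flagged)
  expect_equal(r05$dif_type, "none")

  # all LR statistics and McFadden deltas are non-negative for every item
  all_items <- purrr::map_dfr(1:21, function(j) {
    dif_single_item(d[[paste0("item", sprintf("%02d", j))]], th, g)
  })
  expect_true(all(all_items$lr_12 >= 0))
  expect_true(all(all_items$lr_13 >= 0))
  expect_true(all(all_items$lr_23 >= 0))
  expect_true(all(all_items$r2_mcfadden_13 >= -1e-12))
})

test_that("the flag decision is invariant to swapping reference and focal", {
  bank <- small_bank(5)
  inj <- dif_injection(3, "gender", "F", threshold_shift = 0.8)
  d <- simulate_responses(simulation_spec(4000, bank, dif = list(inj)), seed = 20)
  th <- eap_score(d, bank)$theta
  a <- dif_single_item(d$item03, th, factor(d$gender, levels = c("M", "F")))
  b <- dif_single_item(d$item03, th, factor(d$gender, levels = c("F", "M")))
  expect_equal(a$flagged, b$flagged)
  expect_equal(a$r2_mcfadden_13, b$r2_mcfadden_13, tolerance = 1e-8)
  expect_equal(a$beta_group, -b$beta_group, tolerance = 1e-5)
})

test_that("a trait-by-group interaction is classified as non-uniform", {
  # responses generated straight from the working (cumulative-logit) model
  # with a pure interaction: the gain must load on the 2v3 comparison
  set.seed(40)
  n <- 4000
  th <- rnorm(n); g <- rbinom(n, 1, 0.5)
  eta <- 1.2 * th + 2.0 * th * g
  cp <- sapply(c(-0.5, 1, 2), function(z) plogis(z - eta))
  y <- rowSums(runif(n) > cp)
  r <- dif_single_item(y, th, factor(ifelse(g == 1, "F", "M"),
                                     levels = c("M", "F")))
  expect_true(r$flagged)
  expect_gt(r$r2_mcfadden_23, 0.02)
  expect_gt(r$r2_mcfadden_23, r$r2_mcfadden_12)
  expect_true(r$dif_type %in% c("nonuniform", "mixed"))

  # a discrimination-ratio injection moves the overall 1v3 signal even when
  # it stays under the conservative 0.02 flag threshold
  bank <- bdi2_bank()
  inj <- dif_injection(16, "gender", "F", discrimination_ratio = 3)
  d <- simulate_responses(simulation_spec(12000, bank, dif = list(inj)),
                          seed = 25)
  th2 <- eap_score(d, bank)$theta
  g2 <- factor(d$gender, levels = c("M", "F"))
  r16 <- dif_single_item(d$item16, th2, g2)
  r05 <- dif_single_item(d$item05, th2, g2)
  expect_gt(r16$r2_mcfadden_13, 3 * r05$r2_mcfadden_13)
})

test_that("trait-distribution impact alone does not trigger DIF flags", {
  # groups differ only in theta location: the hybrid design must separate
  # impact from DIF
  bank <- bdi2_bank()
  spec <- simulation_spec(6000, bank,
                          gender_theta_mean = c(M = -0.2, F = 0.25))
  d <- simulate_responses(spec, seed = 26)
  rep <- dif_analysis(d, "gender", bank = bank)
  expect_equal(length(rep$flagged_set), 0L)
  expect_equal(rep$anchor_set, 1:21)
  expect_true(rep$converged)
  # an empty flag set is already stable: no purification rounds needed
  expect_equal(rep$n_purification_iters, 0L)
})

test_that("full analysis flags only the injected item and purifies", {
  bank <- bdi2_bank()
  inj <- dif_injection(10, "gender", "F", threshold_shift = 0.75)
  d <- simulate_responses(simulation_spec(4000, bank, dif = list(inj)), seed = 27)
  rep <- dif_analysis(d, "gender", grid = theta_grid(41), grm_tol = 5e-4)
  expect_equal(rep$flagged_set, 10L)
  expect_setequal(rep$anchor_set, setdiff(1:21, 10))
  expect_true(rep$converged)
  expect_lte(rep$n_purification_iters, 10L)
  # purification recalibration recovers the focal group's lowered thresholds
  expect_false(is.null(rep$banks))
  shift_hat <- rep$banks$M$b1[10] - rep$banks$F$b1[10]
  expect_equal(shift_hat, 0.75, tolerance = 0.3)
  # anchors stay shared across groups
  expect_equal(rep$banks$M$a[-10], rep$banks$F$a[-10], tolerance = 1e-10)

  gl <- glance(rep)
  expect_equal(gl$n_flagged, 1L)
  td <- tidy(rep)
  expect_equal(nrow(td), 21L)
})

test_that("the anchors-only purification mode also stabilizes", {
  bank <- small_bank(8)
  inj <- dif_injection(4, "gender", "F", threshold_shift = 0.9)
  d <- simulate_responses(simulation_spec(3000, bank, dif = list(inj)), seed = 28)
  rep <- dif_analysis(d, "gender", bank = bank, anchor_mode = "anchors_only",
                      grid = theta_grid(31), grm_tol = 1e-3)
  expect_true(rep$converged)
  expect_true(4L %in% rep$flagged_set)
})
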