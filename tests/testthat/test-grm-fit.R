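test_that("EM recovers generating parameters within Monte-Carlo error", {
  bank <- small_bank(5)
  d <- simulate_responses(simulation_spec(5000, bank), seed = 10)
  fit <- fit_grm(d, grid = theta_grid(41))
  expect_true(fit$converged)
  # within 3 estimated sampling SEs of the generating truth
  expect_true(all(abs(fit$bank$a - bank$a) <= 3 * fit$bank$se_a))
  for (col in c("b1", "b2", "b3")) {
    expect_true(all(abs(fit$bank[[col]] - bank[[col]]) <=
                      3 * fit$bank[[paste0("se_", col)]]),
                info = col)
  }
})

test_that("the marginal log-likelihood ascends monotonically", {
  d <- simulate_responses(simulation_spec(800, small_bank(3)), seed = 12)
  fit <- fit_grm(d, grid = theta_grid(31))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(fit$loglik, max(fit$loglik_trace))
})

test_that("the EM optimum beats a brute-force grid on a tiny problem", {
  # 2 items, 3 categories, 30 persons; oracle likelihood written directly
  # from the model density in the test helper
  set.seed(31)
  bank2 <- item_bank(data.frame(a = c(1.4, 2.0), b1 = c(-0.5, 0.2),
                                b2 = c(0.8, 1.4)))
  th <- rnorm(30)
  Y <- sapply(1:2, function(j) {
    cum <- plogis(bank2$a[j] * outer(th, c(bank2$b1[j], bank2$b2[j]), `-`))
    rowSums(runif(30) < cum)
  })
  fit <- fit_grm(as_response(Y), grid = theta_grid(31), tol = 1e-6)

  grid <- theta_grid(31)
  best <- -Inf
  for (a in seq(0.4, 3, length.out = 20)) {
    for (b1 in seq(-1.5, 1, length.out = 20)) {
      for (db in seq(0.1, 2.5, length.out = 20)) {
        ll <- toy_marginal_loglik(Y, c(a, a), list(c(b1, b1 + db), c(b1, b1 + db)),
                                  grid$theta, grid$weight)
        if (ll > best) best <- ll
      }
    }
  }
  expect_gte(fit$loglik, best - 1e-3)
  # and the reported loglik agrees with the independent evaluation at the
  # EM solution itself
  ll_check <- toy_marginal_loglik(
    Y, fit$bank$a,
    list(c(fit$bank$b1[1], fit$bank$b2[1]), c(fit$bank$b1[2], fit$bank$b2[2])),
    grid$theta, grid$weight
  )
  expect_equal(fit$loglik, ll_check, tolerance = 1e-6)
})

test_that("degenerate and sparse items are handled as documented", {
  m <- cbind(rep(1L, 60), rbinom(60, 3, 0.5))
  expect_error(fit_grm(as_response(m)), "fewer than 2 observed categories")

  set.seed(8)
  y2 <- sample(c(0L, 1L, 3L), 200, replace = TRUE)  # category 2 never seen
  y1 <- rbinom(200, 3, 0.4)
  expect_warning(
    fit <- fit_grm(as_response(cbind(y1, y2)), grid = theta_grid(21),
                   tol = 1e-3),
    "collapsing"
  )
  # collapsed item keeps a trailing-NA threshold row
  expect_true(is.na(fit$bank$b3[2]))
  expect_false(anyNA(fit$bank$b2[2]))
})

test_that("EAP scores behave like posterior means", {
  bank <- bdi2_bank()
  d <- simulate_responses(simulation_spec(5000, bank), seed = 14)
  sc <- eap_score(d, bank)
  expect_true(all(sc$psd > 0))
  expect_true(all(is.finite(sc$theta)))
  # shrinkage: regression of EAP on the generating theta has slope in (0, 1]
  # and high correlation
  slope <- coef(lm(sc$theta ~ d$theta))[2]
  expect_gt(slope, 0)
  expect_lte(slope, 1 + 1e-6)
  expect_gt(cor(sc$theta, d$theta), 0.9)

  # the all-zero pattern sits below the sample median
  zero_row <- as_response(matrix(0L, 1, 21))
  expect_lt(eap_score(zero_row, bank)$theta, median(sc$theta))

  # raising one response never lowers the EAP
  base <- as_response(matrix(1L, 1, 21))
  th0 <- eap_score(base, bank)$theta
  for (j in c(1, 14, 21)) {
    up <- base
    up[[paste0("item", sprintf("%02d", j))]] <- 2L
    expect_gte(eap_score(up, bank)$theta, th0)
  }

  # all-missing pattern falls back to the prior, flagged
  miss <- as_response(matrix(NA_integer_, 1, 21))
  sm <- eap_score(miss, bank)
  expect_equal(sm$theta, 0)
  expect_equal(sm$psd, 1)
  expect_true(sm$all_missing)
})

test_that("tidy and glance expose the calibration in broom form", {
  d <- simulate_responses(simulation_spec(600, small_bank(3)), seed = 15)
  fit <- fit_grm(d, grid = theta_grid(21), tol = 1e-3)
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("a", "b1", "b2", "b3"))
  expect_equal(nrow(td), 12L)
  expect_true(all(td$std.error > 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$n_items, 3L)
  expect_equal(gl$n_persons, 600L)
})
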