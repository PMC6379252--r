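test_that("alpha is 1 for duplicated items and matches the hand formula", {
  x <- c(0, 1, 2, 3, 1, 2)
  d <- as_response(cbind(x, x, x))
  expect_equal(cronbach_alpha(d), 1)

  # 3-person, 2-item toy table, computed by hand from the variance formula:
  # item vars 1 and 1, total = (3, 2, 4) with var 1 -> alpha = 2 (1 - 2/1) = -2
  toy <- as_response(cbind(c(0, 1, 2), c(3, 1, 2)))
  expect_equal(cronbach_alpha(toy), -2)

  expect_error(cronbach_alpha(as_response(cbind(c(1, 1), c(2, 2)))), "variance")
})

test_that("alpha is invariant under item permutation and listwise-deletes", {
  d <- make_study_fixture(seed = 9, n_persons = 800)
  items <- grep("^item", names(d), value = TRUE)
  perm <- d[c(setdiff(names(d), items), sample(items))]
  names(perm)[-(1:4)] <- items  # relabel so columns are recognized
  expect_equal(cronbach_alpha(d), cronbach_alpha(perm))

  d2 <- d
  d2$item01[1:10] <- NA
  expect_message(a2 <- cronbach_alpha(d2), "listwise")
  expect_equal(a2, cronbach_alpha(d[-(1:10), ]))
})

test_that("sample alpha converges to the model-implied alpha", {
  bank <- bdi2_bank()
  implied <- implied_moments(bank)$alpha
  d <- simulate_responses(simulation_spec(200000, bank), seed = 17)
  expect_equal(cronbach_alpha(d), implied, tolerance = 0.005)
})

test_that("item descriptives flag degenerate items and mirror the totals", {
  m <- cbind(c(0, 1, 2, 3), c(1, 1, 1, 1), c(0, 0, 1, 2))
  rep <- item_descriptives(as_response(m))
  expect_equal(unname(rep$items$sd[2]), 0)
  expect_equal(unname(rep$items$cv[2]), 0)
  expect_true(rep$items$flagged[2])
  expect_equal(rep$total$mean, mean(rowSums(m)))
  expect_equal(rep$total$cv, sd(rowSums(m)) / mean(rowSums(m)))

  big <- make_study_fixture(seed = 4, n_persons = 2000)
  rep2 <- item_descriptives(big)
  # deleting any single item barely moves alpha on a long internally
  # consistent scale
  expect_true(all(abs(rep2$items$alpha_if_deleted - rep2$total$alpha) < 0.02))
})

test_that("cut-off classification is monotone with correct extremes", {
  d <- make_study_fixture(seed = 6, n_persons = 3000)
  overall <- function(cut) {
    tab <- classify_cutoff(d, cutoff = cut)
    tab$prop[tab$group == "overall"]
  }
  expect_equal(overall(63), 0)   # cannot exceed the maximum total
  expect_equal(overall(-1), 1)   # everyone exceeds an impossible cut-off
  cuts <- c(0, 5, 10, 13, 20, 40)
  expect_true(all(diff(sapply(cuts, overall)) <= 0))
  # strict vs non-strict semantics differ by the mass exactly at the cut-off
  tot <- rowSums(as.matrix(d[grep("^item", names(d))]))
  expect_equal(
    classify_cutoff(d, 13, strict = FALSE)$prop[1] - overall(13),
    mean(tot == 13)
  )
  # the calibrated fixture shows more probable depression among women
  tab <- classify_cutoff(d, 13)
  expect_gt(tab$prop[tab$group == "gender" & tab$level == "F"],
            tab$prop[tab$group == "gender" & tab$level == "M"])
})

test_that("group comparison recovers the calibrated mean difference", {
  d <- make_study_fixture(seed = 2)
  cmp <- compare_groups(d, "gender")
  expect_equal(cmp$mean_diff, 7.85 - 5.92, tolerance = 0.4)
  expect_lt(cmp$t_p_value, 0.001)
  expect_lt(cmp$chisq_p_value, 0.001)

  dup <- dplyr::bind_rows(d[1:100, ], d[1:100, ])
  dup$gender <- rep(c("M", "F"), each = 100)
  expect_equal(compare_groups(dup, "gender")$mean_diff, 0)
  expect_error(compare_groups(d[1:2, ], "gender"), "2 members")
})

test_that("the two-sample comparison holds its nominal level under the null", {
  spec <- simulation_spec(400, small_bank())
  p <- vapply(1:200, function(i) {
    d <- simulate_responses(spec, seed = 1000 + i)
    compare_groups(d, "gender")$t_p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
})
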