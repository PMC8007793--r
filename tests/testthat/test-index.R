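test_that("consensus weights give half the index to cognition", {
  bat <- default_battery(empirical_n = 50)
  w <- consensus_weights(bat)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w[bat$id[bat$domain == "cognition"]]), 0.5)
  expect_equal(sum(w[bat$id[bat$domain == "daily_life"]]), 0.2)
  expect_equal(sum(w[bat$id[bat$domain == "social_interaction"]]), 0.2)
  expect_equal(sum(w[bat$id[bat$domain == "well_being"]]), 0.1)
  expect_equal(unname(w["memory"]), 0.5 / 7)
})

test_that("index is a convex combination with component consistency", {
  bat <- make_small_battery()
  # raw scores at each reference median -> all percentiles 50
  rec <- c(cog_a = 50, cog_b = 30, wb_a = 10, dl_a = 40, si_a = 25)
  res <- compute_index(rec, bat)
  expect_equal(res$overall, 50)
  expect_equal(unname(res$components), rep(50, 4), ignore_attr = TRUE)
  # random records: bounds and domain-weighted consistency
  set.seed(7)
  for (i in 1:20) {
    rec <- c(cog_a = rnorm(1, 50, 10), cog_b = rnorm(1, 30, 5),
             wb_a = rnorm(1, 10, 4), dl_a = rnorm(1, 40, 8),
             si_a = rnorm(1, 25, 6))
    res <- compute_index(rec, bat)
    expect_gte(res$overall, min(res$percentiles) - 1e-9)
    expect_lte(res$overall, max(res$percentiles) + 1e-9)
    dw <- tapply(bat$weight, bat$domain, sum)[names(res$components)]
    expect_equal(res$overall, sum(dw * res$components), tolerance = 1e-9)
  }
})

test_that("one-hot weights recover a single percentile", {
  bat <- make_small_battery(weights = c(1, 0, 0, 0, 0))
  raw <- score_for_percentile(83)
  res <- compute_index(c(cog_a = raw, cog_b = 30, wb_a = 10, dl_a = 40,
                         si_a = 25), bat)
  expect_equal(res$overall, 83, tolerance = 1e-9)
})

test_that("raising one percentile never lowers the index", {
  bat <- make_small_battery()
  base <- c(cog_a = 45, cog_b = 30, wb_a = 10, dl_a = 40, si_a = 25)
  prev <- -Inf
  for (x in seq(30, 70, by = 5)) {
    rec <- base; rec["cog_a"] <- x
    cur <- compute_index(rec, bat)$overall
    expect_gte(cur, prev - 1e-9)
    prev <- cur
  }
})

test_that("missing measures renormalize; a missing domain is an error", {
  bat <- make_small_battery()
  rec <- c(cog_a = 50, cog_b = NA, wb_a = 10, dl_a = 40, si_a = 25)
  res <- compute_index(rec, bat)
  expect_equal(res$overall, 50)      # all observed percentiles are 50
  expect_equal(sum(res$weights), 1)
  rec2 <- c(cog_a = NA, cog_b = NA, wb_a = 10, dl_a = 40, si_a = 25)
  expect_error(compute_index(rec2, bat), "cognition")
})

test_that("cohort scoring agrees with per-record scoring", {
  bat <- make_small_battery()
  set.seed(11)
  n <- 8
  a <- data.frame(participant_id = sprintf("P%02d", 1:n), timepoint = 1,
                  cog_a = rnorm(n, 50, 10), cog_b = rnorm(n, 30, 5),
                  wb_a = rnorm(n, 10, 4), dl_a = rnorm(n, 40, 8),
                  si_a = rnorm(n, 25, 6))
  sc <- score_assessments(a, bat)
  for (i in c(1, 4, 8)) {
    res <- compute_index(unlist(a[i, bat$id]), bat)
    expect_equal(sc$overall[i], res$overall, tolerance = 1e-12)
  }
  expect_error(score_assessments(a[, -3], bat), "cog_a")
  expect_error(score_assessments(rbind(a, a[1, ]), bat), "duplicate")
})

test_that("delta_index subtracts overall scores and checks identity", {
  expect_equal(delta_index(44.67, 71.57), 26.9, tolerance = 1e-9)
  expect_equal(delta_index(47.5, 74.84), 27.34, tolerance = 1e-9)
  bat <- make_small_battery()
  rec <- c(cog_a = 50, cog_b = 30, wb_a = 10, dl_a = 40, si_a = 25)
  r1 <- compute_index(rec, bat)
  expect_equal(delta_index(r1, r1), 0)
  expect_error(delta_index(r1, r1, participant_id = c("A", "B")),
               "different participants")
})

test_that("gain summary statistics match direct computation", {
  g <- gain_summary(c(10, 10, 10.00001))
  expect_equal(g$mean, 10, tolerance = 1e-4)
  expect_equal(g$prop_at_least, 1)
  g2 <- gain_summary(c(0, 0, 0, 20))
  expect_equal(g2$prop_at_least, 0.25)
  expect_error(gain_summary(5), "at least 2")
  # d and its noncentral-t CI bracket the point estimate
  set.seed(3)
  x <- rnorm(60, 8, 9)
  g3 <- gain_summary(x)
  expect_equal(g3$d, mean(x) / sd(x))
  expect_lt(g3$d_ci["lower"], g3$d)
  expect_gt(g3$d_ci["upper"], g3$d)
  # CI inversion is exact: at each bound the noncentral-t probability is
  # alpha/2 (independent check of the uniroot solution)
  t_obs <- g3$d * sqrt(g3$n)
  expect_equal(suppressWarnings(
    stats::pt(t_obs, g3$n - 1, ncp = g3$d_ci["lower"] * sqrt(g3$n))),
    0.975, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(suppressWarnings(
    stats::pt(t_obs, g3$n - 1, ncp = g3$d_ci["upper"] * sqrt(g3$n))),
    0.025, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("index is invariant to measure order", {
  bat <- make_small_battery()
  set.seed(5)
  rec <- c(cog_a = 55, cog_b = 28, wb_a = 12, dl_a = 35, si_a = 27)
  perm <- sample(nrow(bat))
  bat2 <- bat[perm, ]
  class(bat2) <- class(bat)
  expect_equal(compute_index(rec, bat2)$overall,
               compute_index(rec, bat)$overall, tolerance = 1e-12)
})
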