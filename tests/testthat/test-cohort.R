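test_that("dose-effect profile and mixture match their stated shape", {
  expect_equal(dose_effect(c(0, 2, 4, 5.5, 7, 8, 9)),
               c(0, 4, 8, 10, 12, 12, 12))
  cfg <- cohort_config(seed = 1)
  expect_equal(sum(cfg$dose_mix$p), 1)
  # expected gain under the default mixture: 0.05*0 + 0.10*4 + 0.13*10 +
  # 0.72*12 = 10.34 index points
  mid <- function(r) mean(dose_effect(seq(r[1], r[2], length.out = 201)))
  eg <- sum(cfg$dose_mix$p * vapply(cfg$dose_mix$ranges, mid, 0))
  expect_equal(eg, 10.34, tolerance = 0.01)
})

test_that("reference simulation is deterministic and self-consistent", {
  bat <- make_small_battery()
  s1 <- simulate_reference(bat, N = 1000, seed = 4)
  s2 <- simulate_reference(bat, N = 1000, seed = 4)
  expect_identical(s1, s2)
  # law-of-large-numbers bound on the mean
  expect_lt(abs(mean(s1$cog_a) - 50), 3 * 10 / sqrt(1000))
  # a reference applied to itself gives near-uniform percentiles
  r <- ref_empirical(s1$cog_a)
  p <- cdf_value(r, s1$cog_a)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_reference(bat, N = 50, seed = 1), "200")
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n = 40, seed = 77, calibration_n = 500)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$assessments, c2$assessments)
  expect_identical(c1$ground_truth, c2$ground_truth)
})

test_that("zero noise and zero dose produce exactly zero change", {
  cfg <- cohort_config(n = 30, retention = 1, seed = 5,
                       residual_sd = 0, factor_noise_sd = 0,
                       dose_mix = list(p = 1, ranges = list(c(0, 0))),
                       calibration_n = 300)
  co <- generate_cohort(cfg)
  a <- co$assessments
  t1 <- a[a$timepoint == 1, co$battery$id]
  t2 <- a[a$timepoint == 2, co$battery$id]
  expect_equal(as.matrix(t2), as.matrix(t1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("retention controls the completer fraction", {
  co_full <- generate_cohort(cohort_config(n = 30, retention = 1, seed = 2,
                                           calibration_n = 300))
  expect_equal(sum(co_full$assessments$timepoint == 2), 30)
  co <- generate_cohort(cohort_config(n = 180, retention = 0.8, seed = 3,
                                      calibration_n = 500))
  n2 <- sum(co$assessments$timepoint == 2)
  # binomial tolerance around 144
  expect_gt(n2, 144 - 3 * sqrt(180 * 0.8 * 0.2))
  expect_lt(n2, 144 + 3 * sqrt(180 * 0.8 * 0.2))
})

test_that("generated change correlations converge to the latent structure", {
  co <- generate_cohort(cohort_config(n = 2500, retention = 1, seed = 13))
  d <- delta_table(co$assessments, co$battery)
  X <- as.matrix(d[, paste0("d_", co$battery$id)])
  R <- change_correlation(X)
  sol <- factor_solution(R, n_obs = nrow(X), m = 3, seed = 21)
  cong <- best_congruence(default_loadings(), sol$rotated)
  expect_true(all(cong > 0.9))
  # smaller cohorts sit farther from the population structure
  co_s <- generate_cohort(cohort_config(n = 300, retention = 1, seed = 13))
  d_s <- delta_table(co_s$assessments, co_s$battery)
  R_s <- change_correlation(as.matrix(d_s[, paste0("d_", co$battery$id)]))
  Sig <- tcrossprod(sol$rotated) + diag(sol$psi)
  diag(Sig) <- 1
  expect_lt(sqrt(sum((R - Sig)[upper.tri(R)]^2)),
            sqrt(sum((R_s - Sig)[upper.tri(R)]^2)))
})

test_that("construct scores track the generator's true factor scores", {
  co <- generate_cohort(cohort_config(n = 600, retention = 1, seed = 27))
  d <- delta_table(co$assessments, co$battery)
  X <- as.matrix(d[, paste0("d_", co$battery$id)])
  sol <- factor_solution(X, m = 3, seed = 3)
  S <- construct_scores(X, sol)
  f_true <- as.matrix(co$ground_truth[, c("f1", "f2", "f3")])
  cors <- abs(stats::cor(f_true, S))
  # regression-score validity is bounded by the communality level the
  # residual-sd budget allows (~0.85 per construct at the default noise)
  expect_true(all(apply(cors, 1, max) > 0.8))
})

test_that("ground truth aligns with emitted records", {
  co <- generate_cohort(cohort_config(n = 50, seed = 9,
                                      calibration_n = 500))
  a1 <- co$assessments[co$assessments$timepoint == 1, ]
  expect_equal(co$ground_truth$participant_id, a1$participant_id)
  expect_equal(co$ground_truth$dose, a1$modules_completed)
  expect_equal(sum(co$ground_truth$completer),
               sum(co$assessments$timepoint == 2))
  expect_equal(co$ground_truth$true_mean_gain,
               dose_effect(co$ground_truth$dose))
})

test_that("end-to-end fixture is fast, reproducible and complete", {
  t0 <- Sys.time()
  f1 <- end_to_end_fixture(seed = 6)
  f2 <- end_to_end_fixture(seed = 6)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10 * 2)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$deltas, f2$deltas)
  expect_true(all(c("dbhi", "modules_completed") %in% names(f1$deltas)))
  f3 <- end_to_end_fixture(seed = 6, retention = 1)
  expect_equal(sum(f3$cohort$assessments$timepoint == 2), 24)
})
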