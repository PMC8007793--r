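test_that("change correlations behave like Pearson correlations", {
  set.seed(2)
  x <- rnorm(40)
  X <- cbind(a = x, b = x, c = -x + 0, d = rnorm(40))
  X[, 3] <- -X[, 1]
  R <- change_correlation(X)
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  # large-n independent columns have near-zero off-diagonals
  set.seed(3)
  Z <- matrix(rnorm(6000 * 4), ncol = 4)
  Rz <- change_correlation(Z)
  expect_lt(max(abs(Rz[upper.tri(Rz)])), 0.06)
  expect_error(change_correlation(cbind(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("ML EFA recovers an exactly structured correlation matrix", {
  str <- make_exact_structure()
  fit <- ml_efa(str$R, n_obs = 200, m = 3)
  expect_lt(fit$criterion, 1e-8)
  expect_lt(procrustes_distance(fit$loadings, str$L), 1e-3)
  expect_equal(unname(fit$psi), str$psi, tolerance = 1e-4)
  # communality + uniqueness = 1 per variable
  expect_equal(rowSums(fit$loadings^2) + fit$psi, rep(1, 9),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("ML EFA on uncorrelated data finds no common variance", {
  # on an exact identity matrix the ML objective is flat (any single
  # uniqueness below 1 still reproduces Sigma = I exactly), so the
  # meaningful contract is a perfect fit with no excess common variance
  fit <- ml_efa(diag(6), n_obs = 100, m = 1)
  expect_lt(fit$criterion, 1e-8)
  expect_equal(tcrossprod(fit$loadings) + diag(fit$psi), diag(6),
               tolerance = 1e-6, ignore_attr = TRUE)
  # a sampled near-identity correlation matrix is not degenerate and the
  # fitted loadings are genuinely small
  set.seed(44)
  R <- stats::cor(matrix(rnorm(5000 * 6), ncol = 6))
  fit2 <- ml_efa(R, n_obs = 5000, m = 1)
  expect_lt(max(abs(fit2$loadings)), 0.2)
  expect_gt(min(fit2$psi), 0.95)
})

test_that("ML EFA agrees with the reference ML implementation", {
  # independent oracle: stats::factanal on a sampled correlation matrix
  set.seed(8)
  str <- make_exact_structure()
  X <- MASS::mvrnorm(300, rep(0, 9), str$R)
  R <- stats::cor(X)
  mine <- ml_efa(R, n_obs = 300, m = 3)
  ref <- stats::factanal(covmat = R, factors = 3, n.obs = 300,
                         rotation = "none")
  expect_equal(unname(mine$psi), unname(ref$uniquenesses), tolerance = 1e-3)
  Sig_mine <- tcrossprod(mine$loadings) + diag(mine$psi)
  L_ref <- matrix(ref$loadings, 9, 3)
  Sig_ref <- tcrossprod(L_ref) + diag(ref$uniquenesses)
  expect_lt(max(abs(Sig_mine - Sig_ref)), 1e-3)
})

test_that("degrees of freedom follow the closed form", {
  expect_equal(efa_df(6, 1), 9)
  expect_equal(efa_df(20, 3), 133)
  expect_error(ml_efa(diag(4), 50, 3), "too many factors")
})

test_that("varimax preserves communalities and does not lower the criterion", {
  set.seed(12)
  L <- matrix(rnorm(24, sd = 0.4), 8, 3)
  Lr <- varimax_rotate(L)
  expect_equal(rowSums(Lr^2), rowSums(L^2), tolerance = 1e-10)
  expect_gte(varimax_criterion(Lr), varimax_criterion(L) - 1e-10)
  # already-simple structure is a fixed point up to permutation/sign
  str <- make_exact_structure()
  Ls <- varimax_rotate(str$L)
  expect_lt(procrustes_distance(Ls, str$L), 1e-6)
  expect_equal(unname(sort(colSums(Ls^2))),
               unname(sort(colSums(str$L^2))), tolerance = 1e-10)
})

test_that("parallel analysis is seeded and retains truth on structure", {
  set.seed(21)
  str <- make_exact_structure()
  X <- MASS::mvrnorm(250, rep(0, 9), str$R)
  p1 <- parallel_analysis(X, reps = 200, seed = 9)
  p2 <- parallel_analysis(X, reps = 200, seed = 9)
  expect_identical(p1$adjusted, p2$adjusted)
  expect_equal(p1$retained, 3L)
  # pure-noise data almost always retain nothing
  ret <- vapply(1:10, function(i) {
    Z <- matrix(rnorm(150 * 8), 150, 8)
    parallel_analysis(Z, reps = 150, seed = 100 + i)$retained
  }, integer(1))
  expect_gte(mean(ret == 0), 0.8)
  expect_warning(parallel_analysis(X, reps = 50, seed = 1), "reps")
})

test_that("fit statistics are exact at a perfect fit and match formulas", {
  str <- make_exact_structure()
  fs <- fit_statistics(str$R, str$L, str$psi, n_obs = 200, m = 3)
  expect_equal(fs$df, efa_df(9, 3))
  expect_equal(fs$chisq, 0, tolerance = 1e-8)
  expect_equal(fs$rms_residual, 0, tolerance = 1e-10)
  expect_equal(fs$fit_offdiag, 1, tolerance = 1e-10)
  expect_equal(fs$RMSEA, 0)
  # RMSEA CI endpoints invert the noncentral chi-square exactly
  set.seed(4)
  X <- MASS::mvrnorm(150, rep(0, 9), str$R)
  R <- stats::cor(X)
  efa <- ml_efa(R, 150, 2)
  fs2 <- fit_statistics(R, efa$loadings, efa$psi, 150, 2)
  if (fs2$RMSEA_ci["upper"] > 0) {
    ncp_u <- fs2$RMSEA_ci["upper"]^2 * fs2$df * 149
    expect_equal(stats::pchisq(fs2$chisq, fs2$df, ncp = ncp_u), 0.025,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("normalization yields unit columns and scale invariance", {
  set.seed(14)
  L <- matrix(rnorm(30, sd = 0.5), 10, 3)
  ns1 <- normalize_and_select(L)
  expect_equal(colSums(ns1$normalized^2), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  ns2 <- normalize_and_select(L %*% diag(c(5, 5, 5)))
  expect_equal(ns2$normalized, ns1$normalized, tolerance = 1e-12)
  expect_error(normalize_and_select(cbind(L[, 1:2], 0)), "zero")
  expect_error(normalize_and_select(L, cutoff = 1.2), "cutoff")
})

test_that("proportion explained converts a cumulative-variance row", {
  expect_equal(round(proportion_explained(c(0.144, 0.229, 0.275)), 3),
               c(0.524, 0.309, 0.167))
  expect_equal(sum(proportion_explained(c(0.1, 0.3, 0.5))), 1)
  expect_error(proportion_explained(c(0.3, 0.2)), "nondecreasing")
})

test_that("construct scores recover a known factor pattern", {
  str <- make_exact_structure()
  set.seed(17)
  n <- 400
  f_true <- matrix(rnorm(n * 3), n, 3)
  X <- f_true %*% t(str$L) +
    matrix(rnorm(n * 9), n, 9) %*% diag(sqrt(str$psi))
  sol <- factor_solution(X, m = 3, seed = 33)
  S <- construct_scores(X, sol)
  cong <- best_congruence(sol$rotated, str$L)
  expect_true(all(cong > 0.95))
  # each true factor correlates with one estimated score about as well as
  # its theoretical factor-score validity allows (3 indicators per factor)
  cors <- abs(stats::cor(f_true, S))
  expect_true(all(apply(cors, 1, max) > 0.8))
  # zero change vector scores zero (centering at the sample mean of X
  # shifted to zero-mean changes)
  X0 <- scale(X, scale = FALSE)
  S0 <- construct_scores(rbind(0, X0), sol)
  expect_lt(max(abs(S0[1, ])), 0.15)
  idx <- data_driven_index(S, sol$variance$proportion_explained)
  expect_true(isTRUE(attr(idx, "provisional")))
  expect_true(all(idx >= 0 & idx <= 100))
})

test_that("factor workflow accepts a correlation matrix entry path", {
  set.seed(19)
  str <- make_exact_structure()
  X <- MASS::mvrnorm(220, rep(0, 9), str$R)
  R <- stats::cor(X)
  s_raw <- factor_solution(X, m = 3, seed = 5)
  s_cor <- factor_solution(R, n_obs = 220, m = 3, seed = 5)
  expect_equal(s_cor$fit$chisq, s_raw$fit$chisq, tolerance = 1e-6)
  expect_equal(s_cor$rotated, s_raw$rotated, tolerance = 1e-6)
})
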