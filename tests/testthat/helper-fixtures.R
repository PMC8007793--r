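# Shared fixtures built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small all-Gaussian battery covering the four domains, for index tests
# where the 20-measure default would be overkill.
make_small_battery <- function(weights = NULL) {
  bat <- data.frame(
    id = c("cog_a", "cog_b", "wb_a", "dl_a", "si_a"),
    name = c("Cognition A", "Cognition B", "Well-being A",
             "Daily life A", "Social A"),
    domain = c("cognition", "cognition", "well_being", "daily_life",
               "social_interaction"),
    direction = c("higher_better", "higher_better", "lower_better",
                  "higher_better", "higher_better"),
    stringsAsFactors = FALSE)
  bat$reference <- list(ref_gaussian(50, 10), ref_gaussian(30, 5),
                        ref_gaussian(10, 4), ref_gaussian(40, 8),
                        ref_gaussian(25, 6))
  bat$family <- "gaussian"
  class(bat) <- c("bhi_battery", "data.frame")
  bat$weight <- if (is.null(weights))
    as.numeric(consensus_weights(bat)[bat$id]) else weights
  bat
}

# Correlation matrix built exactly as Lambda Lambda' + Psi from a known
# simple-structure loading matrix (p = 9, m = 3).
make_exact_structure <- function() {
  L <- matrix(0, 9, 3)
  L[1:3, 1] <- c(0.8, 0.7, 0.6)
  L[4:6, 2] <- c(0.75, 0.65, 0.6)
  L[7:9, 3] <- c(0.7, 0.6, 0.55)
  psi <- 1 - rowSums(L^2)
  R <- tcrossprod(L) + diag(psi)
  list(L = L, psi = psi, R = R)
}

# Orthogonal Procrustes distance between loading matrices (rotation and
# column-sign invariant).
procrustes_distance <- function(A, B) {
  sv <- svd(t(A) %*% B)
  Q <- sv$u %*% t(sv$v)
  sqrt(sum((A %*% Q - B)^2))
}

# Raw varimax simple-structure criterion (Kaiser row-normalized):
# sum over factors of the variance of squared loadings.
varimax_criterion <- function(L) {
  h <- sqrt(rowSums(L^2))
  W <- (L / h)^2
  sum(apply(W, 2, stats::var))
}

# Tucker congruence of each column of A with its best-matching column of B.
best_congruence <- function(A, B) {
  sapply(seq_len(ncol(A)), function(j) {
    max(abs(crossprod(A[, j], B)) /
          (sqrt(sum(A[, j]^2)) * sqrt(colSums(B^2))))
  })
}

# Raw score whose percentile under a unit-weight single measure equals a
# requested overall index value (gaussian reference, higher_better).
score_for_percentile <- function(target, mean = 50, sd = 10) {
  stats::qnorm(target / 100, mean, sd)
}
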