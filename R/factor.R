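#' Correlation matrix of change scores
#'
#' Pearson correlations of the sign-adjusted change scores, using pairwise
#' complete observations so that a participant missing one measure still
#' contributes to the other pairs.
#'
#' @param changes numeric matrix or data frame, participants x measures
#'   (e.g. the `d_` columns of [delta_table()]).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
change_correlation <- function(changes) {
  X <- as.matrix(changes)
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("constant change column(s): ",
         paste(colnames(X)[!is.finite(sds) | sds == 0], collapse = ", "))
  R <- stats::cor(X, use = "pairwise.complete.obs")
  (R + t(R)) / 2
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Minimizes the ML discrepancy
#' \deqn{F = \log|\Sigma| + \mathrm{tr}(R\Sigma^{-1}) - \log|R| - p,\quad
#'   \Sigma = \Lambda\Lambda' + \Psi,}
#' profiling the loadings out analytically: for fixed uniquenesses
#' \eqn{\Psi}, the optimal \eqn{\Lambda} follows from the eigenstructure of
#' \eqn{\Psi^{-1/2} R \Psi^{-1/2}}, and the profiled objective
#' \eqn{\sum_{j>m} (\theta_j - \log\theta_j - 1)} is minimized over
#' \eqn{\Psi} by quasi-Newton (L-BFGS-B) with the Lawley-Maxwell gradient.
#' Heywood cases are bounded at \eqn{\Psi_i \ge} `psi_lower`.
#'
#' @param R correlation matrix (p x p).
#' @param n_obs number of observations behind `R`.
#' @param m number of factors; must leave nonnegative model df.
#' @param psi_lower lower bound for uniquenesses (default 0.005).
#' @param max_iter maximum L-BFGS-B iterations.
#' @return List: `loadings` (p x m, unrotated, columns ordered by explained
#'   variance), `psi`, `criterion` (minimized F), `converged`, `n_obs`, `m`.
#' @export
ml_efa <- function(R, n_obs, m, psi_lower = 0.005, max_iter = 500) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("R must be symmetric")
  if (m < 1) stop("m must be >= 1")
  if (efa_df(p, m) < 0)
    stop("too many factors: model df would be negative")
  profiled <- function(psi) {
    sc <- 1 / sqrt(psi)
    e <- eigen(R * tcrossprod(sc), symmetric = TRUE, only.values = TRUE)$values
    e <- e[(m + 1):p]
    if (any(e <= 0)) return(1e10)
    sum(e - log(e)) - (p - m)
  }
  grad <- function(psi) {
    L <- .profile_loadings(R, psi, m)
    Sigma <- tcrossprod(L) + diag(psi, p)
    Si <- solve(Sigma)
    diag(Si %*% (Sigma - R) %*% Si)
  }
  smc <- 1 - 1 / diag(solve(R))
  start <- pmin(pmax((1 - 0.5 * m / p) * (1 - smc), psi_lower), 1)
  opt <- stats::optim(start, profiled, grad, method = "L-BFGS-B",
                      lower = psi_lower, upper = 1,
                      control = list(maxit = max_iter, factr = 10))
  psi <- opt$par
  L <- .profile_loadings(R, psi, m)
  g <- grad(psi)
  # projected gradient: active bound constraints do not count
  g[(psi <= psi_lower + 1e-8 & g > 0) | (psi >= 1 - 1e-8 & g < 0)] <- 0
  gnorm <- sqrt(sum(g^2))
  # boundary (Heywood) solutions report nonzero codes with tiny gradients;
  # only a genuinely unconverged fit is an error
  if (opt$convergence != 0 && gnorm > 1e-3)
    stop("ML factor estimation did not converge (code ", opt$convergence,
         ", gradient norm ", format(gnorm, digits = 3), ")")
  Sigma <- tcrossprod(L) + diag(psi, p)
  Fml <- .ml_discrepancy(R, Sigma)
  rn <- rownames(R); if (is.null(rn)) rn <- paste0("v", seq_len(p))
  dimnames(L) <- list(rn, paste0("F", seq_len(m)))
  names(psi) <- rn
  list(loadings = L, psi = psi, criterion = Fml,
       converged = opt$convergence == 0 || gnorm <= 1e-3,
       n_obs = n_obs, m = m)
}

# Conditionally optimal loadings for fixed uniquenesses.
.profile_loadings <- function(R, psi, m) {
  p <- ncol(R)
  sc <- 1 / sqrt(psi)
  e <- eigen(R * tcrossprod(sc), symmetric = TRUE)
  theta <- pmax(e$values[seq_len(m)] - 1, 0)
  L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(theta), m)
  L * sqrt(psi)
}

.ml_discrepancy <- function(R, Sigma) {
  p <- ncol(R)
  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus +
               sum(diag(solve(Sigma, R))) -
               determinant(R, logarithm = TRUE)$modulus - p)
}

#' Model degrees of freedom for an m-factor solution on p variables
#' @param p number of variables.
#' @param m number of factors.
#' @return \eqn{((p-m)^2 - (p+m))/2}.
#' @export
efa_df <- function(p, m) ((p - m)^2 - (p + m)) / 2

#' Varimax rotation with Kaiser row-normalization
#'
#' Orthogonal rotation toward simple structure via [stats::varimax()]
#' (`normalize = TRUE`). Communalities (row sums of squares) are preserved.
#' Columns are reordered by decreasing explained variance and sign-fixed so
#' each column's largest-magnitude loading is positive-sum, making the
#' output deterministic.
#'
#' @param loadings p x m loading matrix, m >= 2.
#' @return Rotated p x m loading matrix.
#' @export
varimax_rotate <- function(loadings) {
  L <- as.matrix(loadings)
  if (ncol(L) < 2) return(L)
  rot <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
  Lr <- L %*% rot$rotmat
  ss <- colSums(Lr^2)
  Lr <- Lr[, order(ss, decreasing = TRUE), drop = FALSE]
  sgn <- ifelse(colSums(Lr^3) < 0, -1, 1)
  Lr <- sweep(Lr, 2, sgn, `*`)
  dimnames(Lr) <- list(rownames(L), paste0("F", seq_len(ncol(L))))
  Lr
}

#' Horn's parallel analysis for factor retention
#'
#' Compares the eigenvalues of the reduced correlation matrix (squared
#' multiple correlations on the diagonal, the common-factor convention) with
#' a percentile of the eigenvalues of random uncorrelated Gaussian data of
#' the same dimensions. The adjusted eigenvalue is the observed value minus
#' the random-reference percentile; the leading run of positive adjusted
#' eigenvalues gives the retained factor count.
#'
#' @param x change-score matrix (participants x measures), or a correlation
#'   matrix if `n_obs` is supplied.
#' @param n_obs observation count when `x` is a correlation matrix.
#' @param reps random reference replicates (default 500; below 100 a
#'   warning is signalled).
#' @param percentile reference percentile (default 95).
#' @param seed integer seed; results are deterministic given the seed.
#' @param eigen_type `"factor"` for reduced-matrix eigenvalues (default) or
#'   `"pc"` for principal-component eigenvalues.
#' @param reference `"gaussian"` draws i.i.d. standard normal reference data
#'   (classic Horn formulation); `"permutation"` permutes each observed
#'   column independently (requires raw data).
#' @return List: `eigenvalues`, `reference` (percentile curve),
#'   `adjusted`, `retained`.
#' @export
parallel_analysis <- function(x, n_obs = NULL, reps = 500, percentile = 95,
                              seed, eigen_type = c("factor", "pc"),
                              reference = c("gaussian", "permutation")) {
  eigen_type <- match.arg(eigen_type)
  reference <- match.arg(reference)
  if (missing(seed)) stop("parallel_analysis() requires an explicit seed")
  if (reps < 100) warning("reps < 100: reference percentiles unstable")
  is_corr <- is.matrix(x) && nrow(x) == ncol(x) &&
    isTRUE(all.equal(unname(diag(as.matrix(x))), rep(1, ncol(x)),
                     tolerance = 1e-8)) && !is.null(n_obs)
  if (is_corr) {
    R <- as.matrix(x); n <- n_obs
    if (reference == "permutation")
      stop("permutation reference requires raw data, not a correlation matrix")
  } else {
    X <- as.matrix(x)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    R <- change_correlation(X)
    n <- nrow(X)
  }
  p <- ncol(R)
  ev_of <- function(Rm) {
    if (eigen_type == "factor") diag(Rm) <- 1 - 1 / diag(solve(Rm))
    eigen(Rm, symmetric = TRUE, only.values = TRUE)$values
  }
  obs <- ev_of(R)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rand <- matrix(0, reps, p)
  for (r in seq_len(reps)) {
    Z <- if (reference == "gaussian") {
      matrix(stats::rnorm(n * p), n, p)
    } else {
      apply(X, 2, sample)
    }
    rand[r, ] <- ev_of(stats::cor(Z))
  }
  ref <- apply(rand, 2, stats::quantile, probs = percentile / 100)
  adj <- obs - ref
  pos <- adj > 0
  retained <- if (pos[1]) which.min(c(pos, FALSE)) - 1L else 0L
  list(eigenvalues = obs, reference = ref, adjusted = adj,
       retained = as.integer(retained), reps = reps,
       percentile = percentile, eigen_type = eigen_type)
}

#' Likelihood-based fit statistics for a factor solution
#'
#' Computes the Bartlett-corrected likelihood chi-square
#' \eqn{(n - 1 - (2p+5)/6 - 2m/3)\,F_{ML}} on
#' \eqn{((p-m)^2 - (p+m))/2} df, the Tucker-Lewis index against the
#' independence null, RMSEA with a noncentrality-inversion confidence
#' interval, the RMS off-diagonal residual, and the off-diagonal fit
#' \eqn{1 - \sum r_{resid}^2 / \sum r_{obs}^2}.
#'
#' @param R observed correlation matrix.
#' @param loadings,psi factor solution (rotation-invariant statistics).
#' @param n_obs observation count.
#' @param m factor count.
#' @param rmsea_conf confidence level for the RMSEA interval.
#' @return List of fit statistics.
#' @export
fit_statistics <- function(R, loadings, psi, n_obs, m,
                           rmsea_conf = 0.95) {
  R <- as.matrix(R); L <- as.matrix(loadings)
  p <- ncol(R)
  df <- efa_df(p, m)
  if (df < 0) stop("negative model df: too many factors")
  Sigma <- tcrossprod(L) + diag(psi, p)
  Fml <- .ml_discrepancy(R, Sigma)
  corr_factor <- n_obs - 1 - (2 * p + 5) / 6 - 2 * m / 3
  chisq <- max(corr_factor * Fml, 0)
  pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  # independence null
  F0 <- -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  df0 <- p * (p - 1) / 2
  chisq0 <- max((n_obs - 1 - (2 * p + 5) / 6) * F0, 0)
  tli <- ((chisq0 / df0) - (chisq / df)) / ((chisq0 / df0) - 1)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n_obs - 1)))
  rmsea_ci <- .rmsea_ci(chisq, df, n_obs, rmsea_conf)
  resid <- R - Sigma
  off <- upper.tri(R)
  rms_resid <- sqrt(mean(resid[off]^2))
  fit_off <- 1 - sum(resid[off]^2) / sum(R[off]^2)
  list(F_ML = Fml, chisq = chisq, df = df, p = pval,
       TLI = tli, RMSEA = rmsea, RMSEA_ci = rmsea_ci,
       rms_residual = rms_resid, fit_offdiag = fit_off,
       null_chisq = chisq0, null_df = df0, n_obs = n_obs, m = m)
}

.rmsea_ci <- function(chisq, df, n_obs, conf = 0.95) {
  alpha <- 1 - conf
  f <- function(ncp, target) stats::pchisq(chisq, df, ncp = ncp) - target
  hi_ncp <- if (f(0, alpha / 2) < 0) 0 else
    stats::uniroot(f, c(0, max(10 * chisq, 100)), target = alpha / 2,
                   tol = 1e-8)$root
  lo_ncp <- if (f(0, 1 - alpha / 2) < 0) 0 else
    stats::uniroot(f, c(0, max(10 * chisq, 100)), target = 1 - alpha / 2,
                   tol = 1e-8)$root
  c(lower = sqrt(lo_ncp / (df * (n_obs - 1))),
    upper = sqrt(hi_ncp / (df * (n_obs - 1))))
}

#' Normalize loadings and flag salient measures
#'
#' Scales each loading column to unit Euclidean norm and flags loadings at
#' or above the salience cutoff (default 0.200 in absolute value). The
#' salient squared mass per factor is the share of the column's (unit)
#' squared norm carried by its salient loadings; with the default cutoff the
#' salient set comprises at least 80% of each factor's normed length on a
#' near-simple structure.
#'
#' @param loadings p x m loading matrix.
#' @param cutoff salience cutoff in (0, 1), default 0.200.
#' @return List: `normalized`, `salient` (logical mask), `salient_mass`
#'   (per-factor salient squared mass).
#' @export
normalize_and_select <- function(loadings, cutoff = 0.200) {
  L <- as.matrix(loadings)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  nrm <- sqrt(colSums(L^2))
  if (any(nrm == 0)) stop("zero loading column cannot be normalized")
  Ln <- sweep(L, 2, nrm, `/`)
  mask <- abs(Ln) >= cutoff
  mass <- colSums((Ln * mask)^2)
  list(normalized = Ln, salient = mask, salient_mass = mass)
}

#' Variance decomposition of a factor solution
#'
#' Per-factor explained variance (sum of squared loadings over p), its
#' cumulative share of total variance, and each factor's proportion of the
#' total explained variance (increment over total cumulative).
#'
#' @param loadings p x m loading matrix (rotated).
#' @return List: `ss_loadings`, `cumulative_variance`,
#'   `proportion_explained`.
#' @export
variance_decomposition <- function(loadings) {
  L <- as.matrix(loadings)
  ss <- colSums(L^2)
  cum <- cumsum(ss) / nrow(L)
  list(ss_loadings = ss, cumulative_variance = cum,
       proportion_explained = proportion_explained(cum))
}

#' Proportion of explained variance per factor from a cumulative row
#'
#' Converts a cumulative-variance row (nondecreasing shares of total
#' variance) into per-factor proportions of the explained variance:
#' increments divided by the final cumulative value.
#'
#' @param cumulative numeric nondecreasing vector.
#' @return Proportions summing to 1.
#' @export
proportion_explained <- function(cumulative) {
  if (is.unsorted(cumulative)) stop("cumulative variance must be nondecreasing")
  diff(c(0, cumulative)) / cumulative[length(cumulative)]
}

#' Regression-method factor scores
#'
#' Thomson regression scores \eqn{S = Z R^{-1} \Lambda} on standardized
#' complete-case change scores.
#'
#' @param changes participants x measures change matrix.
#' @param solution a fitted [factor_solution()] (or any list with
#'   `rotated` loadings and `R`).
#' @return n x m matrix of construct scores (complete cases only; rows
#'   carry participant indices as names).
#' @export
construct_scores <- function(changes, solution) {
  X <- as.matrix(changes)
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  Z <- scale(X)
  R <- solution$R
  L <- solution$rotated
  S <- Z %*% solve(R, L)
  rownames(S) <- which(cc)
  S
}

#' Provisional data-driven index from construct scores
#'
#' Combines the construct scores with proportion-explained weights and maps
#' the combination to the percent scale through the standard normal CDF.
#' The weighting of the three constructs is a provisional placeholder until
#' a validated scheme exists; the output carries a `provisional` attribute.
#'
#' @param scores n x m construct-score matrix.
#' @param proportions per-factor proportion-explained weights.
#' @return Numeric vector of percent-scale index values with
#'   `attr(, "provisional") = TRUE`.
#' @export
data_driven_index <- function(scores, proportions) {
  S <- as.matrix(scores)
  w <- proportions / sum(proportions)
  comb <- as.numeric(S %*% w)
  sdc <- stats::sd(comb)
  z <- if (is.na(sdc) || sdc == 0) comb * 0 else (comb - mean(comb)) / sdc
  out <- 100 * stats::pnorm(z)
  attr(out, "provisional") <- TRUE
  out
}

#' Full exploratory factor workflow for a change matrix
#'
#' Runs the complete change-score factor analysis: correlation matrix,
#' Horn's parallel analysis for the retained factor count (unless `m` is
#' forced), ML extraction, varimax rotation, column normalization with
#' salience selection, variance decomposition and fit statistics.
#'
#' @param changes participants x measures change matrix (or a correlation
#'   matrix with `n_obs`).
#' @param n_obs observation count when `changes` is a correlation matrix.
#' @param m forced factor count; `NULL` retains by parallel analysis.
#' @param reps,percentile,eigen_type passed to [parallel_analysis()].
#' @param seed seed for the parallel-analysis reference.
#' @param cutoff salience cutoff for [normalize_and_select()].
#' @return A `bhi_factor_solution` list with elements `R`, `unrotated`,
#'   `rotated`, `normalized`, `salient`, `salient_mass`, `psi`,
#'   `parallel`, `m`, `fit`, `variance`, `n_obs`.
#' @export
factor_solution <- function(changes, n_obs = NULL, m = NULL, reps = 500,
                            percentile = 95, seed,
                            eigen_type = "factor", cutoff = 0.200) {
  if (missing(seed)) stop("factor_solution() requires an explicit seed")
  is_corr <- is.matrix(changes) && nrow(changes) == ncol(changes) &&
    isTRUE(all.equal(unname(diag(as.matrix(changes))),
                     rep(1, ncol(changes)), tolerance = 1e-8)) &&
    !is.null(n_obs)
  if (is_corr) {
    R <- as.matrix(changes); n <- n_obs
  } else {
    X <- as.matrix(changes)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    R <- change_correlation(X)
    n <- nrow(X)
  }
  pa <- parallel_analysis(R, n_obs = n, reps = reps, percentile = percentile,
                          seed = seed, eigen_type = eigen_type)
  if (is.null(m)) m <- max(pa$retained, 1L)
  efa <- ml_efa(R, n, m)
  rot <- if (m >= 2) varimax_rotate(efa$loadings) else efa$loadings
  rownames(rot) <- rownames(efa$loadings)
  sel <- normalize_and_select(rot, cutoff)
  fit <- fit_statistics(R, rot, efa$psi, n, m)
  vd <- variance_decomposition(rot)
  structure(list(R = R, unrotated = efa$loadings, rotated = rot,
                 normalized = sel$normalized, salient = sel$salient,
                 salient_mass = sel$salient_mass, psi = efa$psi,
                 parallel = pa, m = m, fit = fit, variance = vd,
                 n_obs = n, criterion = efa$criterion),
            class = "bhi_factor_solution")
}

#' @export
print.bhi_factor_solution <- function(x, ...) {
  cat("<bhi_factor_solution> m =", x$m,
      "(parallel analysis retained", x$parallel$retained, ")\n")
  cat(sprintf("  chi-square %.2f on %d df (p = %.3f), TLI %.3f, RMSEA %.3f\n",
              x$fit$chisq, as.integer(x$fit$df), x$fit$p, x$fit$TLI,
              x$fit$RMSEA))
  cat(sprintf("  RMS residual %.3f, off-diagonal fit %.3f\n",
              x$fit$rms_residual, x$fit$fit_offdiag))
  invisible(x)
}
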