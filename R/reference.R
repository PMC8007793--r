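#' Reference distributions for percentile scoring
#'
#' A reference distribution represents the population against which a raw
#' instrument score is ranked. Three estimation routes are supported:
#' an empirical reference sample, a moment-matched parametric family
#' (Gaussian, gamma, or negative binomial), and a bootstrap reference built
#' from the sufficient statistics of a model-based score (used for the
#' metabolic-equivalents estimate, see [bootstrap_met_cdf()]).
#'
#' @param sample numeric vector of reference scores (empirical method).
#' @param mean,sd,var target moments for the parametric families.
#' @return An object of class `bhi_ref` with elements `method` and `params`.
#' @seealso [cdf_value()], [percentile()], [moment_match()]
#' @examples
#' r <- ref_gaussian(100, 15)
#' cdf_value(r, 100)        # 0.5
#' percentile(r, 115, "higher_better")
#' @name bhi_ref
NULL

new_bhi_ref <- function(method, params) {
  structure(list(method = method, params = params), class = "bhi_ref")
}

#' @rdname bhi_ref
#' @export
ref_empirical <- function(sample) {
  sample <- as.numeric(sample[!is.na(sample)])
  if (length(sample) == 0L) stop("empirical reference sample is empty")
  new_bhi_ref("empirical", list(sample = sort(sample)))
}

#' @rdname bhi_ref
#' @export
ref_gaussian <- function(mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("gaussian reference requires sd > 0")
  new_bhi_ref("gaussian", list(mean = mean, sd = sd))
}

#' @rdname bhi_ref
#' @export
ref_gamma <- function(mean, sd) {
  new_bhi_ref("gamma", c(list(mean = mean, sd = sd),
                         moment_match("gamma", mean, sd)))
}

#' @rdname bhi_ref
#' @export
ref_negative_binomial <- function(mean, var) {
  new_bhi_ref("negative_binomial",
              c(list(mean = mean, var = var),
                moment_match("negative_binomial", mean, var)))
}

#' @export
print.bhi_ref <- function(x, ...) {
  cat("<bhi_ref:", x$method, "> ")
  if (x$method == "empirical") {
    cat("n =", length(x$params$sample), "\n")
  } else {
    p <- x$params[!vapply(x$params, is.null, logical(1))]
    cat(paste(names(p), signif(unlist(p), 4), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Closed-form moment matching for parametric reference families
#'
#' Maps published summary statistics onto distribution parameters so the
#' fitted family reproduces the target mean and dispersion exactly:
#' gamma shape \eqn{= (\mu/\sigma)^2}, rate \eqn{= \mu/\sigma^2};
#' negative binomial size \eqn{= \mu^2/(v-\mu)}, prob \eqn{= \mu/v}.
#'
#' @param method `"gaussian"`, `"gamma"` or `"negative_binomial"`.
#' @param mean target mean.
#' @param sd_or_var target sd (gaussian, gamma) or variance (negative
#'   binomial; must exceed the mean).
#' @return Named list of family parameters.
#' @export
moment_match <- function(method = c("gaussian", "gamma", "negative_binomial"),
                         mean, sd_or_var) {
  method <- match.arg(method)
  switch(method,
    gaussian = {
      if (sd_or_var <= 0) stop("sd must be > 0")
      list(mean = mean, sd = sd_or_var)
    },
    gamma = {
      if (sd_or_var <= 0) stop("sd must be > 0")
      if (mean <= 0) stop("gamma mean must be > 0")
      list(shape = (mean / sd_or_var)^2, rate = mean / sd_or_var^2)
    },
    negative_binomial = {
      if (mean <= 0) stop("negative binomial mean must be > 0")
      if (sd_or_var <= mean)
        stop("negative binomial requires variance > mean (overdispersion)")
      list(size = mean^2 / (sd_or_var - mean), prob = mean / sd_or_var)
    })
}

#' Cumulative probability of a raw score under a reference distribution
#'
#' The empirical method uses the midrank convention
#' \eqn{p = (\#\{s < x\} + \#\{s = x\}/2)/n}, which keeps ties symmetric and
#' avoids exact 0/1 at the sample extremes. The discrete negative-binomial
#' family uses the mid-distribution function
#' \eqn{P(X < x) + P(X = x)/2} for the same reason.
#'
#' @param ref a [bhi_ref] object.
#' @param x numeric vector of raw scores.
#' @return Probabilities in \[0, 1\], nondecreasing in `x`.
#' @export
cdf_value <- function(ref, x) {
  stopifnot(inherits(ref, "bhi_ref"))
  p <- ref$params
  switch(ref$method,
    empirical = {
      s <- p$sample
      n <- length(s)
      n_le <- findInterval(x, s)                    # #{s <= x}
      n_lt <- findInterval(x, s, left.open = TRUE)  # #{s <  x}
      (n_lt + 0.5 * (n_le - n_lt)) / n
    },
    gaussian = stats::pnorm(x, p$mean, p$sd),
    gamma = stats::pgamma(x, shape = p$shape, rate = p$rate),
    negative_binomial = {
      k <- floor(x)
      plo <- stats::pnbinom(k - 1, size = p$size, prob = p$prob)
      phi <- stats::pnbinom(k, size = p$size, prob = p$prob)
      # mid-distribution at integers; between integers the CDF is flat
      ifelse(x == k, (plo + phi) / 2, phi)
    },
    stop("unknown reference method: ", ref$method))
}

#' Percentile score of a raw value
#'
#' Maps a raw score through its reference CDF to the 0-100 percentile scale,
#' reversing for measures where a lower raw score is better (depression,
#' anxiety, stress, sleep), and clamping to \[0.5, 99.5\] so that no
#' participant sits exactly at the floor or ceiling of the index.
#'
#' @param ref a [bhi_ref] object.
#' @param x numeric vector of raw scores.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param clamp two-element clamp range in percent.
#' @return Percentiles in percent units.
#' @export
percentile <- function(ref, x, direction = c("higher_better", "lower_better"),
                       clamp = c(0.5, 99.5)) {
  direction <- match.arg(direction)
  p <- cdf_value(ref, x)
  if (direction == "lower_better") p <- 1 - p
  pmin(pmax(100 * p, clamp[1]), clamp[2])
}

#' Default linear predictor for the metabolic-equivalents estimate
#'
#' Questionnaire-based cardiorespiratory fitness estimates are linear
#' predictors over simple physiological and activity inputs. The exact
#' scoring equation behind the fitness questionnaire is proprietary, so the
#' scoring function is pluggable; this default follows the form of published
#' non-exercise fitness equations (sex, age, BMI, resting heart rate,
#' self-reported activity).
#'
#' @param inputs matrix or data frame with columns `sex` (1 = male), `age`
#'   (years), `bmi` (kg/m^2), `resting_hr` (bpm), `activity` (0-8 scale).
#' @return Numeric vector of estimated METs.
#' @export
met_score_default <- function(inputs) {
  inputs <- as.data.frame(inputs)
  18.07 + 2.77 * inputs$sex - 0.10 * inputs$age - 0.17 * inputs$bmi -
    0.03 * inputs$resting_hr + 1.00 * inputs$activity
}

#' Default sufficient statistics for the metabolic-equivalents bootstrap
#'
#' Per-input mean and sd for a generally healthy adult cohort; `sex` is the
#' male proportion treated on the 0/1 scale.
#' @return Data frame with columns `input`, `mean`, `sd`.
#' @export
met_default_stats <- function() {
  data.frame(
    input = c("sex", "age", "bmi", "resting_hr", "activity"),
    mean  = c(0.28, 55.9, 27.0, 68.0, 5.0),
    sd    = c(0.45, 17.0,  5.0, 10.0, 2.5)
  )
}

#' Bootstrap reference distribution for a model-based score
#'
#' Builds an empirical reference for the metabolic-equivalents measure by
#' simulating the questionnaire's inputs from a Gaussian matched to their
#' sufficient statistics (means, sds, and optionally their correlation) and
#' pushing each replicate through the MET scoring function.
#'
#' @param stats data frame with columns `input`, `mean`, `sd` (see
#'   [met_default_stats()]).
#' @param B number of bootstrap replicates (default 10000; below 1000 a
#'   warning is signalled because the tails are unstable).
#' @param seed integer seed; the returned reference is deterministic given
#'   the seed.
#' @param score_fn scoring function mapping an input data frame to METs.
#' @param cor_matrix optional correlation matrix of the inputs (identity if
#'   omitted).
#' @return A [bhi_ref] of method `"empirical"` holding the B simulated METs.
#' @export
bootstrap_met_cdf <- function(stats = met_default_stats(), B = 10000, seed,
                              score_fn = met_score_default,
                              cor_matrix = NULL) {
  if (missing(seed)) stop("bootstrap_met_cdf() requires an explicit seed")
  need <- c("input", "mean", "sd")
  if (!all(need %in% names(stats)))
    stop("stats must provide columns: ", paste(need, collapse = ", "))
  if (anyNA(stats$mean) || anyNA(stats$sd))
    stop("missing input statistic in MET sufficient statistics")
  if (B < 1000) warning("B < 1000 bootstrap replicates: CDF tails unstable")
  k <- nrow(stats)
  if (is.null(cor_matrix)) cor_matrix <- diag(k)
  sigma <- diag(stats$sd, k) %*% cor_matrix %*% diag(stats$sd, k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- if (all(stats$sd == 0)) {
    matrix(rep(stats$mean, each = B), nrow = B)
  } else {
    MASS::mvrnorm(B, mu = stats$mean, Sigma = sigma)
  }
  colnames(draws) <- stats$input
  ref_empirical(score_fn(as.data.frame(draws)))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
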